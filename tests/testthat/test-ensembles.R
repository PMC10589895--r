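make_test_map <- function(kind, seed, n_bins = 32) {
  set.seed(seed)
  ctr <- gridtorus:::bin_centers(arena_spec(), n_bins)
  pts <- as.matrix(expand.grid(ctr, ctr))
  v <- switch(kind,
    grid = grid_cell_activity(pts, f = 1.19, theta = 0.2,
                              phase = runif(2, -0.4, 0.4)),
    band = {
      th <- 0.5
      pmax(cos(2 * pi * 1.19 * (cos(th) * pts[, 1] + sin(th) * pts[, 2]) +
                 runif(1) * 2 * pi), 0)
    },
    bump = {
      c0 <- runif(2, -0.6, 0.6)
      exp(-((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2) / (2 * 0.3^2))
    })
  matrix(v, n_bins, n_bins)
}

test_that("rotational fingerprints encode the symmetry group", {
  g <- rotational_autocorrelogram(make_test_map("grid", 1))
  deg <- attr(g, "degrees")
  expect_equal(g[deg == 0], 1)
  expect_true(all(g[deg %in% c(-120, -60, 60, 120)] > 0.9))
  expect_true(all(g[deg %in% c(-90, 30, 90)] < 0.5))
  b <- rotational_autocorrelogram(make_test_map("band", 2))
  expect_gt(b[deg == -180], 0.9)  # central symmetry of the correlogram
  expect_true(all(b[deg %in% c(-60, 60, 120)] < 0.5))
  r <- rotational_autocorrelogram(make_test_map("bump", 3))
  expect_gt(min(r), 0.8)  # radially symmetric: correlated at every angle
  expect_error(rotational_autocorrelogram(matrix(1, 32, 32)))
})

test_that("degenerate units are excluded with the right reasons", {
  set.seed(4)
  maps <- array(abs(rnorm(16 * 16 * 40, mean = 1, sd = 0.1)),
                c(16, 16, 40))
  maps[, , 5] <- 0                       # zero everywhere
  maps[, , 9] <- 50                      # extreme mean rate
  ex <- exclude_units(maps, rate_percentile = 0.95)
  expect_equal(ex$reason[5], "zero-activity")
  expect_equal(ex$reason[9], "high-rate")
  expect_true(ex$keep[1])
  expect_equal(sum(!ex$keep), 1 + sum(ex$reason == "high-rate"))
  # percentile computed on the post-zero-removal population
  expect_equal(sum(ex$reason == "high-rate"),
               sum(ex$mean_rate[-5] >
                     quantile(ex$mean_rate[-5], 0.95)))
})

test_that("clustering recovers planted symmetry families", {
  maps <- c(lapply(1:30, function(i) make_test_map("grid", 100 + i)),
            lapply(1:30, function(i) make_test_map("band", 200 + i)),
            lapply(1:30, function(i) make_test_map("bump", 300 + i)))
  fam <- rep(c("grid", "band", "bump"), each = 30)
  rot <- t(vapply(maps, rotational_autocorrelogram, numeric(360)))
  cl <- cluster_units(rot, min_samples = 10)
  expect_identical(cl$labels, cluster_units(rot, min_samples = 10)$labels)
  lab <- cl$labels
  expect_gte(length(unique(lab[lab > 0])), 3)
  # family purity of every recovered cluster
  for (k in unique(lab[lab > 0])) {
    expect_gte(max(table(fam[lab == k])) / sum(lab == k), 0.9)
  }
  # the band family is flagged band-like, the others are not
  bands <- find_band_clusters(rot, lab)
  band_label <- names(which.max(table(lab[fam == "band" & lab > 0])))
  expect_true(as.integer(band_label) %in% bands)
  grid_label <- names(which.max(table(lab[fam == "grid" & lab > 0])))
  expect_false(as.integer(grid_label) %in% bands)
  # manual override wins
  expect_identical(find_band_clusters(rot, lab, band_clusters = 2L), 2L)
})

test_that("torus-ensemble refinement separates three band orientations", {
  maps3 <- unlist(lapply(c(0, pi / 3, 2 * pi / 3), function(th)
    lapply(1:12, function(i) {
      set.seed(400 + round(th * 100) + i)
      ctr <- gridtorus:::bin_centers(arena_spec(), 32)
      pts <- as.matrix(expand.grid(ctr, ctr))
      matrix(pmax(cos(2 * pi * 1.19 *
                        (cos(th) * pts[, 1] + sin(th) * pts[, 2]) +
                        runif(1) * 2 * pi), 0), 32, 32)
    })), recursive = FALSE)
  acgs <- t(vapply(maps3, function(m) as.vector(autocorrelogram(m)),
                   numeric(63 * 63)))
  rf <- refine_torus_ensemble(acgs, seed = 5)
  truth <- rep(1:3, each = 12)
  tab <- table(truth, rf$subcluster)
  expect_equal(sum(apply(tab, 1, max)), 36)  # exact 3-way separation
  # permutation of input order gives the same partition up to label names
  perm <- sample(36)
  rf2 <- refine_torus_ensemble(acgs[perm, ], seed = 5)
  agree <- outer(rf$subcluster[perm], rf$subcluster[perm], "==") ==
    outer(rf2$subcluster, rf2$subcluster, "==")
  expect_true(all(agree))
  expect_error(refine_torus_ensemble(acgs[1:2, ]), "at least 3")
})

test_that("PCA projection has the right shape and ignores constant units", {
  set.seed(6)
  x <- matrix(rnorm(400 * 10), 400, 10)
  pr <- pca_project(x, 6)
  expect_equal(dim(pr), c(400, 6))
  pr2 <- pca_project(cbind(x, 3), 6)  # add a constant unit
  expect_equal(abs(pr2), abs(pr), tolerance = 1e-8)
})

test_that("fuzzy memberships are calibrated, symmetric, and reject outliers", {
  set.seed(7)
  # dense angular blob around e1, plus 10 outliers along +-e2..+-e6:
  # every outlier is at least 90 degrees (cosine distance 1) from the blob
  blob <- matrix(rnorm(120 * 6, sd = 0.02), 120, 6)
  blob[, 1] <- blob[, 1] + 1
  dirs <- rbind(diag(6)[2:6, ], -diag(6)[2:6, ])
  out <- 3 * dirs + matrix(rnorm(10 * 6, sd = 0.02), 10, 6)
  pts <- rbind(blob, out)
  k <- 20
  d <- gridtorus:::cosine_distance_matrix(pts)
  i <- 4
  nb <- setdiff(seq_len(130), i)[order(d[i, -i])][1:k]
  s <- gridtorus:::calibrate_sigma(d[i, nb], log2(k))
  expect_lt(abs(sum(exp(-d[i, nb] / s)) - log2(k)), 1e-5)
  fd <- fuzzy_downsample(pts, k = k, n_keep = 120)
  expect_setequal(fd$index, 1:120)  # all 10 far outliers dropped
  expect_equal(nrow(fd$points), 120)
})

test_that("greedy permutation is deterministic and spreads landmarks", {
  set.seed(8)
  pts <- matrix(rnorm(500 * 2), 500, 2)
  g1 <- greedy_permutation(pts, 50)
  g2 <- greedy_permutation(pts, 50)
  expect_identical(g1, g2)
  expect_equal(length(unique(g1$index)), 50)
  D <- as.matrix(dist(pts[g1$index, ]))
  diag(D) <- Inf
  # landmark separation is at least the covering radius (maxmin property)
  expect_gte(min(D), g1$cover_radius - 1e-9)
})

test_that("the fast Rips reduction agrees with brute-force reduction", {
  set.seed(9)
  for (rep in 1:4) {
    pts <- matrix(runif(10 * 2), 10, 2)
    D <- as.matrix(dist(pts))
    thr <- quantile(D[upper.tri(D)], 0.7)
    fast <- gridtorus:::cpp_rips_persistence(D, thr, 47L, 2L)
    fast_df <- data.frame(dim = fast$dim, birth = fast$birth,
                          death = fast$death)
    oracle <- rips_oracle(D, thr, p = 47)
    expect_equal(bar_table(fast_df), bar_table(oracle),
                 ignore_attr = TRUE)
  }
})

test_that("persistence recovers the known topology of small controls", {
  set.seed(10)
  th <- runif(120, 0, 2 * pi)
  circ <- cbind(cos(th), sin(th)) + matrix(rnorm(240, 0, 0.02), ncol = 2)
  pd <- rips_persistence(circ, n_landmarks = 100)
  v <- detect_torus(pd)
  expect_equal(v$betti[2], 1)          # one long-lived loop
  expect_false(v$is_torus)
  expect_s3_class(pd, "persistence_diagram")
  expect_true(all(pd$death >= pd$birth))
  blob <- matrix(rnorm(300), 100, 3)
  vb <- detect_torus(rips_persistence(blob, n_landmarks = 80))
  expect_false(vb$is_torus)
  expect_equal(vb$betti[2:3], c(0L, 0L))
})
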