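test_that("ratemaps average activity per visited bin and mark gaps NA", {
  arena <- arena_spec()
  # hand example: two visits to one bin with activities 1 and 3 -> 2
  pos <- matrix(c(-1.09, -1.09, -1.09, -1.09, 1.0, 1.0), ncol = 2,
                byrow = TRUE)
  rm <- compute_ratemap(c(1, 3, 7), pos, arena, n_bins = 4)
  expect_equal(rm[1, 1], 2)
  expect_equal(rm[4, 4], 7)
  expect_true(is.na(rm[2, 3]))
  occ <- attr(rm, "occupancy")
  expect_equal(occ[1, 1], 2L)
  expect_equal(sum(occ), 3L)
  # constant activity -> every visited bin equals the constant
  set.seed(1)
  pos2 <- cbind(runif(500, -1.1, 1.1), runif(500, -1.1, 1.1))
  rm2 <- compute_ratemap(rep(2.5, 500), pos2, arena, n_bins = 8)
  expect_true(all(rm2[is.finite(rm2)] == 2.5))
})

test_that("trajectory-sampled ratemaps agree with analytic evaluation", {
  set.seed(2)
  m <- grid_module(1, seed = 3)
  pos <- cbind(runif(60000, -1.1, 1.1), runif(60000, -1.1, 1.1))
  act <- grid_cell_activity(pos, m$f, m$theta[1], m$phases[1, ])
  rm <- compute_ratemap(act, pos, n_bins = 32)
  direct <- module_ratemaps(m, n_bins = 32)[, , 1]
  ok <- is.finite(rm)
  expect_gt(cor(rm[ok], direct[ok]), 0.99)
})

test_that("the masked correlogram matches a brute-force evaluation", {
  set.seed(4)
  a <- matrix(rnorm(64), 8, 8)
  b <- matrix(rnorm(64), 8, 8)
  a[c(3, 17, 40)] <- NA
  cc <- crosscorrelogram(a, b, min_overlap = 4)
  c0 <- attr(cc, "center")
  direct <- function(dx, dy) {
    av <- c(); bv <- c()
    for (i in 1:8) for (j in 1:8) {
      ii <- i + dx; jj <- j + dy
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8 &&
          is.finite(a[i, j]) && is.finite(b[ii, jj])) {
        av <- c(av, a[i, j]); bv <- c(bv, b[ii, jj])
      }
    }
    if (length(av) < 4) NA_real_ else cor(av, bv)
  }
  for (dx in -4:4) for (dy in -4:4) {
    expect_equal(cc[c0 + dx, c0 + dy], direct(dx, dy), tolerance = 1e-10)
  }
})

test_that("autocorrelograms are centered, symmetric, and hexagonal for grids", {
  m <- grid_module(1, seed = 5)
  rmap <- module_ratemaps(m, n_bins = 64)[, , 1]
  acg <- autocorrelogram(rmap)
  c0 <- attr(acg, "center")
  expect_equal(acg[c0, c0], 1)
  flipped <- acg[nrow(acg):1, ncol(acg):1]
  expect_lt(max(abs(acg - flipped), na.rm = TRUE), 1e-5)
  # six nearest off-center peaks lie at ~60 degree spacing
  pk <- find_local_peaks(acg, smooth_sd = 1, min_value = 0)
  d <- sqrt((pk[, 1] - c0)^2 + (pk[, 2] - c0)^2)
  ring <- pk[d > 2 & d < 1.3 * min(d[d > 2]), , drop = FALSE]
  expect_equal(nrow(ring), 6)
  ang <- sort(atan2(ring[, 2] - c0, ring[, 1] - c0))
  gaps <- diff(ang) * 180 / pi
  expect_true(all(abs(gaps - 60) < 8))
})

test_that("rotation by a cached mapping is exact at 90 degrees", {
  set.seed(6)
  m <- matrix(rnorm(81), 9, 9)
  r0 <- rotate_map(m, 0)
  expect_equal(r0, m, tolerance = 1e-12)
  r90 <- rotate_map(m, 90)
  # inverse mapping at 90 degrees lands on integer pixels: r90[i,j] = m[j, 10-i]
  for (i in 2:8) for (j in 2:8) {
    expect_equal(r90[i, j], m[j, 10 - i], tolerance = 1e-9)
  }
})

test_that("grid score separates grids from bands and is rotation invariant", {
  m <- grid_module(1, seed = 7)
  rmap <- module_ratemaps(m, n_bins = 64)[, , 1]
  gs <- grid_score(rmap)
  expect_gt(gs, 1)
  ctr <- gridtorus:::bin_centers(arena_spec(), 64)
  pts <- as.matrix(expand.grid(ctr, ctr))
  band <- matrix(pmax(cos(2 * pi * 1.19 * pts[, 1]), 0), 64, 64)
  expect_lt(grid_score(band), 0.3)
  m_rot <- apply_remap_scenario(m, "coherent_rotation", angle = 17)
  gs_rot <- grid_score(module_ratemaps(m_rot, n_bins = 64)[, , 1])
  expect_lt(abs(gs - gs_rot), 0.3)
  expect_true(is.nan(grid_score(matrix(1, 32, 32))))
})

test_that("phase shift reads the nearest cross-correlogram peak", {
  m <- grid_module(3, seed = 8)
  rms <- module_ratemaps(m, n_bins = 64)
  expect_equal(phase_shift(rms[, , 1], rms[, , 1]), c(0, 0))
  # constructed one-bin displacement
  r1 <- rms[, , 1]
  r2 <- rbind(r1[-1, ], r1[1, ])
  expect_equal(phase_shift(r1, r2), c(-2.2 / 64, 0), tolerance = 1e-9)
  # antisymmetry within a bin
  mi <- apply_remap_scenario(m, "coherent_phase", delta = c(-0.2, -0.2))
  rmsi <- module_ratemaps(mi, n_bins = 64)
  ab <- phase_shift(rms[, , 2], rmsi[, , 2])
  ba <- phase_shift(rmsi[, , 2], rms[, , 2])
  expect_lt(max(abs(ab + ba)), 2.2 / 64 + 1e-9)
})

test_that("orientation shift recovers constructed rotations and wraps", {
  m <- grid_module(2, seed = 9)
  rms <- module_ratemaps(m, n_bins = 64)
  expect_equal(orientation_shift(rms[, , 1], rms[, , 1]), 0)
  m10 <- apply_remap_scenario(m, "coherent_rotation", angle = 10)
  rms10 <- module_ratemaps(m10, n_bins = 64)
  expect_equal(orientation_shift(rms[, , 1], rms10[, , 1]), 10)
  # wrapped orientation law: output in [-15, 15), congruent mod 30
  x <- c(-180, -44, -15, -1.4, 0, 14.9, 15, 29, 181, 47)
  w <- wrap_orientation(x)
  expect_true(all(w >= -15 & w < 15))
  expect_true(all(abs((x - w) %% 30) < 1e-9))
  expect_equal(wrap_orientation(-47), 13)
})

test_that("spacing estimation matches the analytic lattice constant", {
  for (f in c(1.19, 2.0)) {
    m <- grid_module(1, f = f, seed = 10)
    sp <- grid_spacing(module_ratemaps(m, n_bins = 64)[, , 1])
    expect_lt(abs(sp - grid_spacing_analytic(f)), 2.2 / 64)
  }
  # doubling f halves the estimate (within bin resolution)
  m1 <- grid_module(1, f = 1, seed = 11)
  m2 <- grid_module(1, f = 2, seed = 11)
  s1 <- grid_spacing(module_ratemaps(m1, n_bins = 64)[, , 1])
  s2 <- grid_spacing(module_ratemaps(m2, n_bins = 64)[, , 1])
  expect_lt(abs(s1 / s2 - 2), 0.15)
})

test_that("the shift KDE integrates to one and contrasts coherence", {
  set.seed(12)
  sh_coh <- matrix(rnorm(100, c(-0.2, -0.2), 0.01), ncol = 2, byrow = TRUE)
  kde <- shift_density(sh_coh, grid_n = 48)
  dx <- diff(kde$x[1:2]); dy <- diff(kde$y[1:2])
  expect_equal(sum(kde$z) * dx * dy, 1, tolerance = 0.05)
  peak_xy <- which(kde$z == max(kde$z), arr.ind = TRUE)
  expect_lt(abs(kde$x[peak_xy[1]] + 0.2), 0.05)
  sh_inc <- matrix(runif(200, -0.5, 0.5), ncol = 2)
  kde2 <- shift_density(sh_inc, grid_n = 48,
                        limits = c(-0.6, 0.6, -0.6, 0.6))
  expect_gt(max(kde$z), 3 * max(kde2$z))
})

test_that("circular variance separates coherent from incoherent shifts", {
  expect_lt(circular_variance(rep(-5, 40), period = 30), 1e-9)
  set.seed(13)
  expect_gt(circular_variance(runif(500, -15, 15), period = 30), 0.8)
  sh_coh <- matrix(rep(c(-0.2, -0.2), 30), ncol = 2, byrow = TRUE)
  expect_lt(phase_shift_coherence(sh_coh), 1e-9)
})
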