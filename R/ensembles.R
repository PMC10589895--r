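#' Rotational symmetry fingerprint of a ratemap
#'
#' Forms the spatial autocorrelogram of the ratemap (which is centered and
#' invariant to the pattern's phase), cuts out the central disk of radius
#' `n/2` pixels, normalises it to zero mean and unit variance, and computes
#' the Pearson correlation between the disk and copies of itself rotated by
#' `n_theta` angles spanning -180..180 degrees (bilinear interpolation).
#' The value at rotation 0 is 1; the vector fingerprints the map's
#' rotational symmetry: hexagonal patterns peak near multiples of 60
#' degrees, stripe/band patterns only near 180 (a correlogram is centrally
#' symmetric, so 180 degrees correlates highly for every pattern), and
#' radially symmetric blobs correlate highly everywhere.
#'
#' @param ratemap Square ratemap matrix (32 x 32 in the clustering
#'   pipeline; its correlogram disk then has radius 16 pixels).
#' @param n_theta Number of rotation angles. Default 360.
#' @return Numeric vector of length `n_theta` with attribute `degrees`.
#' @export
rotational_autocorrelogram <- function(ratemap, n_theta = 360L) {
  nr <- nrow(ratemap)
  stopifnot(nr == ncol(ratemap))
  acg <- autocorrelogram(ratemap, min_overlap = max(10L, nr %/% 3))
  # central (n+1) x (n+1) window of the (2n-1) x (2n-1) correlogram
  half <- nr %/% 2
  ctr <- attr(acg, "center")
  win <- (ctr - half):(ctr + half)
  disk <- acg[win, win]
  n <- nrow(disk)
  c0 <- (n + 1) / 2
  rad2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")
  disk_sel <- rad2 <= (n / 2)^2
  disk[!disk_sel] <- NA_real_
  mu <- mean(disk, na.rm = TRUE)
  sg <- stats::sd(disk, na.rm = TRUE)
  if (!is.finite(sg) || sg == 0)
    stop("rotational autocorrelogram undefined for a constant disk")
  disk <- (disk - mu) / sg
  degrees <- seq(-180, 180, length.out = n_theta + 1L)[seq_len(n_theta)]
  dv <- as.vector(disk)
  out <- vapply(degrees, function(d) {
    if (d == 0) return(1)
    cor_complete(dv, as.vector(rotate_map(disk, d)))
  }, numeric(1))
  attr(out, "degrees") <- degrees
  out
}

#' Exclude degenerate units before clustering
#'
#' Two-stage exclusion: units with zero activity everywhere, then units
#' whose mean spatial firing rate exceeds the given percentile of the
#' remaining (nonzero) population — high-rate, weakly tuned units.
#'
#' @param ratemaps n_bins x n_bins x n_units array.
#' @param rate_percentile Upper percentile for the rate exclusion (fraction).
#'   Default 0.9975.
#' @return List with `keep` (logical vector) and `reason` (character:
#'   `"ok"`, `"zero-activity"` or `"high-rate"`).
#' @export
exclude_units <- function(ratemaps, rate_percentile = 0.9975) {
  n_units <- dim(ratemaps)[3]
  mean_rate <- apply(ratemaps, 3, function(m) mean(m[is.finite(m)]))
  zero <- vapply(seq_len(n_units), function(u) {
    m <- ratemaps[, , u]
    all(!is.finite(m) | m == 0)
  }, logical(1))
  reason <- rep("ok", n_units)
  reason[zero] <- "zero-activity"
  thr <- stats::quantile(mean_rate[!zero], rate_percentile, names = FALSE)
  high <- !zero & mean_rate > thr
  reason[high] <- "high-rate"
  list(keep = reason == "ok", reason = reason, mean_rate = mean_rate)
}

#' Density-based clustering of rotational symmetry fingerprints
#'
#' Embeds the matrix of rotational autocorrelograms into two dimensions
#' (principal components of the fingerprints) and clusters the embedding
#' with DBSCAN. Label -1 marks noise points. Deterministic.
#'
#' @param rotacgs n_units x n_theta matrix of rotational
#'   autocorrelograms.
#' @param n_components Embedding dimensionality. Default 2.
#' @param eps DBSCAN radius on the embedding; `NULL` (default) uses the
#'   0.75 quantile of the distances to each point's `min_samples`-th
#'   neighbour.
#' @param min_samples DBSCAN core-point threshold (neighbourhood includes
#'   the point itself). Default 30.
#' @return List with `labels` (integer, -1 = noise), `embedding`
#'   (n x n_components) and `eps` used.
#' @export
cluster_units <- function(rotacgs, n_components = 2L, eps = NULL,
                          min_samples = 30L) {
  rotacgs <- as.matrix(rotacgs)
  stopifnot(nrow(rotacgs) >= min_samples)
  pc <- stats::prcomp(rotacgs, center = TRUE, scale. = FALSE)
  emb <- pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
  d <- as.matrix(stats::dist(emb))
  if (is.null(eps)) {
    kdist <- apply(d, 1, function(r) sort(r)[min_samples])
    eps <- stats::quantile(kdist, 0.75, names = FALSE)
  }
  labels <- dbscan_labels(d, eps, min_samples)
  list(labels = labels, embedding = emb, eps = eps)
}

## plain DBSCAN on a precomputed distance matrix
dbscan_labels <- function(d, eps, min_samples) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      if (labels[q] == -1L) {
        labels[q] <- cl
        if (core[q]) queue <- c(queue, nb[[q]][labels[nb[[q]]] == -1L])
      }
    }
  }
  labels
}

#' Identify band-like clusters from mean rotational fingerprints
#'
#' A band (stripe) pattern is invariant under 180-degree rotation but has
#' no other rotational symmetry, so its rotational autocorrelogram has a
#' single non-trivial peak, at 180 degrees. A cluster is flagged band-like
#' when the 180-degree correlation of its mean fingerprint exceeds
#' `peak_threshold`, no other rotation in (30, 330) degrees does, and the
#' fingerprint is not globally flat (radially symmetric units correlate
#' highly at every rotation).
#'
#' @param rotacgs n_units x n_theta matrix.
#' @param labels Cluster labels from [cluster_units()].
#' @param peak_threshold Correlation threshold for a symmetry peak.
#'   Default 0.5.
#' @param band_clusters Optional manual override: integer vector of cluster
#'   ids to treat as band-like, bypassing the automatic rule.
#' @return Integer vector of band-like cluster ids.
#' @export
find_band_clusters <- function(rotacgs, labels, peak_threshold = 0.5,
                               band_clusters = NULL) {
  if (!is.null(band_clusters)) return(as.integer(band_clusters))
  degrees <- seq(-180, 180, length.out = ncol(rotacgs) + 1L)[
    seq_len(ncol(rotacgs))]
  out <- integer(0)
  for (cl in sort(unique(labels[labels > 0]))) {
    m <- colMeans(rotacgs[labels == cl, , drop = FALSE])
    near180 <- abs(abs(degrees) - 180) <= 15
    inner <- abs(degrees) >= 30 & abs(degrees) <= 150
    flat <- min(m) > 0.8  # radially symmetric fingerprint
    if (!flat && max(m[near180]) >= peak_threshold &&
        max(m[inner]) < peak_threshold)
      out <- c(out, cl)
  }
  out
}

#' Rank units by their band-likeness
#'
#' Unit-level form of the band signature used for cluster identification:
#' the fingerprint's correlation near 180 degrees minus its best
#' correlation in the 30-150 degree range. Stripe-like (band) units score
#' high; hexagonal units score low (their 60/120 degree peaks cancel the
#' 180 peak); radially symmetric units score near zero. Useful when
#' density clustering does not separate a band-like cluster (e.g. early in
#' training), in which case the top-scoring units are the toroidal-cell
#' candidates.
#'
#' @param rotacgs n_units x n_theta matrix of rotational fingerprints.
#' @return Numeric vector of band scores, one per unit.
#' @export
band_score <- function(rotacgs) {
  rotacgs <- as.matrix(rotacgs)
  degrees <- seq(-180, 180, length.out = ncol(rotacgs) + 1L)[
    seq_len(ncol(rotacgs))]
  near180 <- abs(abs(degrees) - 180) <= 10
  inner <- abs(degrees) >= 30 & abs(degrees) <= 150
  apply(rotacgs[, near180, drop = FALSE], 1, max) -
    apply(rotacgs[, inner, drop = FALSE], 1, max)
}

#' Split a torus-ensemble candidate set into three band orientations
#'
#' K-means (k = 3) applied to the rows of the Pearson-correlation matrix
#' between the units' (flattened) spatial autocorrelograms: band cells at
#' the three lattice orientations (about 60 degrees apart) correlate highly
#' within an orientation and weakly across, so the correlation rows
#' separate cleanly.
#'
#' @param acgs n_units x n_features matrix of flattened spatial
#'   autocorrelograms of the candidate units.
#' @param k Number of subclusters. Default 3.
#' @param seed Optional seed for the K-means initialisation.
#' @return List with `subcluster` (integer labels 1..k) and `correlation`
#'   (the n x n feature matrix).
#' @export
refine_torus_ensemble <- function(acgs, k = 3L, seed = NULL) {
  acgs <- as.matrix(acgs)
  if (nrow(acgs) < k)
    stop("need at least ", k, " candidate units to split into ", k,
         " subclusters")
  if (!is.null(seed)) set.seed(seed)
  cc <- suppressWarnings(stats::cor(t(acgs), use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  km <- stats::kmeans(cc, centers = k, nstart = 10)
  list(subcluster = km$cluster, correlation = cc)
}

#' Project population activity to its leading principal components
#'
#' Rows of `ratemap_stack_matrix` are spatial bins, columns are units; the
#' projection returns one point per spatial bin in `n_components`
#' dimensions, a low-dimensional picture of the ensemble activity over
#' space. Bins with any missing unit value are dropped.
#'
#' @param ratemap_stack_matrix (n_bins^2) x n_units matrix (e.g. from
#'   [module_pointcloud()] or flattened unit ratemaps).
#' @param n_components Number of components. Default 6.
#' @return n_kept x n_components score matrix; attribute `var_explained`
#'   carries the per-component variance fractions.
#' @export
pca_project <- function(ratemap_stack_matrix, n_components = 6L) {
  x <- as.matrix(ratemap_stack_matrix)
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  if (k < n_components)
    warning("only ", k, " non-degenerate components available")
  out <- pc$x[, seq_len(k), drop = FALSE]
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Fuzzy-neighbourhood downsampling of a point cloud
#'
#' Assigns every point a neighbourhood membership: `a_ij = exp(-d_ij /
#' sigma_i)` over its `k` nearest neighbours (cosine distance), with
#' `sigma_i` calibrated by bisection so that `sum_j a_ij = log2(k)` (within
#' `tol`), then symmetrises `m_ij = a_ij + a_ji - a_ij a_ji` and keeps the
#' `n_keep` points with the largest mean membership. Outliers have weak
#' memberships and are dropped first, protecting downstream persistence
#' computations from spurious topological features.
#'
#' @param points n x d matrix.
#' @param k Number of nearest neighbours. Default 1000 (clamped to n - 1
#'   with a warning).
#' @param n_keep Number of points retained. Default 3000.
#' @param tol Calibration tolerance on the membership sum. Default 1e-5.
#' @return List with `points` (the retained subset), `index` (their row
#'   indices) and `mean_membership` (all points).
#' @export
fuzzy_downsample <- function(points, k = 1000L, n_keep = 3000L,
                             tol = 1e-5) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2)
  n_keep <- min(n_keep, n)
  if (k >= n) {
    warning("k >= number of points; clamping to n - 1")
    k <- n - 1L
  }
  d <- cosine_distance_matrix(points)
  target <- log2(k)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    nb <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    dn <- d[i, nb]
    sigma <- calibrate_sigma(dn, target, tol)
    a[i, nb] <- exp(-dn / sigma)
  }
  m <- a + t(a) - a * t(a)
  mean_mem <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0 | a[, i] > 0)
    mean(m[i, nb])
  }, numeric(1))
  idx <- order(-mean_mem)[seq_len(n_keep)]
  list(points = points[idx, , drop = FALSE], index = idx,
       mean_membership = mean_mem)
}

cosine_distance_matrix <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  s <- tcrossprod(x / nrm)
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

## bisection on log(sigma) for sum(exp(-d/sigma)) = target
calibrate_sigma <- function(d, target, tol = 1e-5, max_iter = 100L) {
  lo <- 1e-8
  hi <- max(max(d), 1e-6)
  while (sum(exp(-d / hi)) < target) hi <- hi * 2
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    s <- sum(exp(-d / mid))
    if (abs(s - target) < tol) return(mid)
    if (s > target) hi <- mid else lo <- mid
  }
  mid
}

#' Greedy (farthest-point) permutation of a point cloud
#'
#' Maxmin traversal: starting from the first point, repeatedly picks the
#' point farthest from the already selected set. The first `n_landmarks`
#' points form a well-spread landmark subset whose covering radius is
#' reported.
#'
#' @param points n x d matrix.
#' @param n_landmarks Number of landmarks.
#' @return List with `index` (landmark rows), `cover_radius`.
#' @export
greedy_permutation <- function(points, n_landmarks) {
  points <- as.matrix(points)
  n <- nrow(points)
  n_landmarks <- min(n_landmarks, n)
  sel <- integer(n_landmarks)
  sel[1] <- 1L
  dmin <- sqrt(rowSums(sweep(points, 2, points[1, ])^2))
  if (n_landmarks > 1) {
    for (m in 2:n_landmarks) {
      sel[m] <- which.max(dmin)
      dm <- sqrt(rowSums(sweep(points, 2, points[sel[m], ])^2))
      dmin <- pmin(dmin, dm)
    }
  }
  list(index = sel, cover_radius = max(dmin))
}

#' Vietoris-Rips persistence diagram of a point cloud
#'
#' Subsamples the cloud to `n_landmarks` points by greedy permutation,
#' computes Euclidean distances, and runs the Rips boundary-matrix
#' reduction over the field of characteristic `prime` for homology
#' dimensions 0..`max_dim`. Classes alive at the filtration threshold are
#' reported with `death = Inf`.
#'
#' The default threshold is `connect_factor` times the longest edge of the
#' landmark minimum spanning tree -- a few multiples of the connectivity
#' scale, which is where genuine low-dimensional structure of a
#' well-sampled manifold expresses itself -- capped at the enclosing radius
#' and at the distance that would give the landmarks a mean graph degree of
#' `max_mean_degree` (which bounds the size of the simplicial complex).
#' Classes still alive at the threshold count as persistent through their
#' essential (infinite) death.
#'
#' @param points n x d matrix.
#' @param max_dim Highest homology dimension. Default 2.
#' @param n_landmarks Landmarks kept by the greedy permutation. Default
#'   300.
#' @param threshold Filtration cutoff; `NULL` for the automatic rule.
#' @param connect_factor Multiplier for the automatic threshold. Default 3.
#' @param max_mean_degree Mean landmark-graph degree permitted by the
#'   automatic threshold. Default 80.
#' @param prime Field characteristic. Default 47.
#' @return `data.frame` (class `persistence_diagram`) with columns `dim`,
#'   `birth`, `death`; attributes `threshold`, `n_points`, `cover_radius`.
#' @export
rips_persistence <- function(points, max_dim = 2L, n_landmarks = 300L,
                             threshold = NULL, connect_factor = 3,
                             max_mean_degree = 80, prime = 47L) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 4)
  gp <- greedy_permutation(points, n_landmarks)
  lm <- points[gp$index, , drop = FALSE]
  D <- as.matrix(stats::dist(lm))
  if (is.null(threshold)) {
    mst_max <- max_mst_edge(D)
    enclosing <- min(apply(D, 1, max))
    off <- D[upper.tri(D)]
    frac <- min(1, max_mean_degree / (nrow(D) - 1))
    t_deg <- stats::quantile(off, frac, names = FALSE)
    threshold <- min(connect_factor * mst_max, enclosing, t_deg)
  }
  res <- cpp_rips_persistence(D, threshold, as.integer(prime),
                              as.integer(max_dim))
  out <- data.frame(dim = res$dim, birth = res$birth, death = res$death)
  out <- out[order(out$dim, out$birth), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_points") <- nrow(lm)
  attr(out, "cover_radius") <- gp$cover_radius
  class(out) <- c("persistence_diagram", "data.frame")
  out
}

## longest edge of the minimum spanning tree (Prim)
max_mst_edge <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  dmin <- D[1, ]
  best <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(dmin[cand])]
    best <- max(best, dmin[nxt])
    in_tree[nxt] <- TRUE
    dmin <- pmin(dmin, D[nxt, ])
  }
  best
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("persistence_diagram: %d points, threshold %.3g\n",
              attr(x, "n_points"), attr(x, "threshold")))
  for (d in sort(unique(x$dim))) {
    sub <- x[x$dim == d, ]
    cat(sprintf("  H%d: %d bars (%d essential)\n", d, nrow(sub),
                sum(!is.finite(sub$death))))
  }
  invisible(x)
}

#' Decide whether a persistence diagram shows a torus
#'
#' Counts the long-lived bars in each homology dimension with a
#' persistence-gap rule. In dimension 0 the long-lived count is simply the
#' number of essential bars: the connected components alive at the
#' threshold. In dimensions 1 and 2, bars shorter than `floor_frac` times
#' the filtration threshold are discarded as noise; the remaining bars are
#' sorted by persistence (essential deaths capped at the threshold) and
#' the count is placed at the largest multiplicative gap between
#' consecutive bars, provided that gap exceeds `gap_factor` (otherwise the
#' dimension counts zero long-lived bars). A 2-torus has Betti numbers
#' (1, 2, 1).
#'
#' @param diagram A `persistence_diagram`.
#' @param gap_factor Minimum persistence ratio across the signal/noise gap.
#'   Default 1.8.
#' @param floor_frac Minimum persistence, as a fraction of the filtration
#'   threshold, for a bar to be considered at all. Default 0.1.
#' @return List with `is_torus`, `betti` (long-lived counts for H0..H2),
#'   `persistence_gaps` (the gap ratio used in each dimension).
#' @export
detect_torus <- function(diagram, gap_factor = 1.8, floor_frac = 0.1) {
  thr <- attr(diagram, "threshold")
  pers <- ifelse(is.finite(diagram$death), diagram$death - diagram$birth,
                 thr - diagram$birth)
  betti <- integer(3)
  gaps <- rep(NA_real_, 3)
  betti[1] <- sum(diagram$dim == 0 & !is.finite(diagram$death))
  for (d in 1:2) {
    sel <- diagram$dim == d
    p_all <- sort(pers[sel], decreasing = TRUE)
    cand <- p_all[p_all >= floor_frac * thr]
    if (length(cand) == 0) next
    # the noise floor terminates the candidate list, so a final candidate
    # barely above the floor cannot manufacture a spurious gap
    sentinel <- floor_frac * thr
    ratios <- cand / c(cand[-1], sentinel)
    i_star <- which.max(ratios)
    if (ratios[i_star] > gap_factor) {
      betti[d + 1] <- i_star
      gaps[d + 1] <- ratios[i_star]
    }
  }
  list(is_torus = all(betti == c(1L, 2L, 1L)), betti = betti,
       persistence_gaps = gaps)
}

#' Three-dimensional view of a point cloud
#'
#' Linear projection onto the first three principal components, intended
#' for visual inspection of population manifolds only; all quantitative
#' statements should be made on the persistence diagrams.
#'
#' @param points n x d matrix (typically a [pca_project()] output).
#' @return n x 3 score matrix.
#' @export
embed3d <- function(points) {
  pca_project(points, n_components = 3L)
}
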