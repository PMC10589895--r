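#' Spatially binned ratemap of one unit
#'
#' Bins the arena into an `n_bins` x `n_bins` grid and averages the unit's
#' activity over all visits to each bin. Bins that are never visited are
#' `NA` (missing), never zero.
#'
#' @param activity Numeric vector, one value per sample.
#' @param positions m x 2 matrix of sample positions, aligned with
#'   `activity`.
#' @param arena An [arena_spec()].
#' @param n_bins Spatial resolution per axis. Default 64.
#' @return n_bins x n_bins matrix (x indexes rows, y columns) with an
#'   `occupancy` attribute holding per-bin visit counts and a `bin_size`
#'   attribute.
#' @export
compute_ratemap <- function(activity, positions, arena = arena_spec(),
                            n_bins = 64L) {
  stopifnot(length(activity) == nrow(positions))
  rm_stack <- ratemap_stack(matrix(activity, ncol = 1), positions, arena,
                            n_bins)
  out <- rm_stack[, , 1]
  attr(out, "occupancy") <- attr(rm_stack, "occupancy")
  attr(out, "bin_size") <- attr(rm_stack, "bin_size")
  out
}

#' Ratemaps for many units at once
#'
#' @param activity m x n_units matrix: samples in rows, units in columns.
#' @param positions m x 2 matrix of positions aligned with the rows.
#' @param arena An [arena_spec()].
#' @param n_bins Resolution per axis.
#' @return n_bins x n_bins x n_units array with `occupancy` and `bin_size`
#'   attributes.
#' @export
ratemap_stack <- function(activity, positions, arena = arena_spec(),
                          n_bins = 64L) {
  half <- arena$side_length / 2
  edges <- seq(-half, half, length.out = n_bins + 1)
  ix <- findInterval(positions[, 1], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(positions[, 2], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  bin <- ix + (iy - 1L) * n_bins
  counts <- tabulate(bin, nbins = n_bins * n_bins)
  sums <- rowsum(activity, bin, reorder = FALSE)
  ids <- as.integer(rownames(sums))
  acc <- matrix(0, n_bins * n_bins, ncol(activity))
  acc[ids, ] <- sums
  means <- acc / counts          # 0/0 -> NaN for unvisited bins
  means[counts == 0L, ] <- NA_real_
  out <- array(means, c(n_bins, n_bins, ncol(activity)))
  attr(out, "occupancy") <- matrix(counts, n_bins, n_bins)
  attr(out, "bin_size") <- arena$side_length / n_bins
  out
}

## Activities of network units along a trajectory batch, flattened so that
## row k of the result is aligned with flatten_positions(batch, t_slice).
## g: Ng x batch x T array of unit states (as returned by rnn_forward).
flatten_activity <- function(g, t_slice = NULL) {
  if (!is.null(t_slice)) g <- g[, , t_slice, drop = FALSE]
  ng <- dim(g)[1]
  # reorder to (batch, T, unit) then flatten batch-fastest within timestep
  matrix(aperm(g, c(2, 3, 1)), ncol = ng)
}

## ---- masked 2D Pearson cross-correlogram (FFT-based) ----

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

## Sum_{x} A(x) * B(x + d) for all integer lags d in [-(n-1), n-1]^2,
## returned as a (2n-1) x (2n-1) matrix with the zero lag at the center.
lag_sums <- function(fa_conj, fb, n, L) {
  s <- ifft2(fa_conj * fb)
  # s[1 + ((dx) mod L), 1 + ((dy) mod L)] corresponds to lag (dx, dy)
  d <- c(seq(L - n + 2, L), seq_len(n))  # lags -(n-1) .. (n-1)
  s[d, d]
}

#' Masked Pearson cross-correlogram of two maps
#'
#' For every integer 2D lag, the Pearson correlation between the overlapping
#' (pairwise-valid) bins of `a` and the lag-shifted `b`. Missing bins are
#' excluded pairwise; lags with fewer than `min_overlap` overlapping valid
#' bins are `NA`. Computed with FFTs for speed.
#'
#' @param a,b Equal-sized numeric matrices, possibly containing `NA`.
#' @param min_overlap Minimum number of overlapping valid bins per lag.
#'   Default 20.
#' @return (2n-1) x (2n-1) matrix of correlations, zero lag at the center
#'   (`attr(x, "center")`).
#' @export
crosscorrelogram <- function(a, b, min_overlap = 20L) {
  stopifnot(all(dim(a) == dim(b)), nrow(a) == ncol(a))
  n <- nrow(a)
  L <- stats::nextn(2 * n - 1, c(2, 3, 5))
  ma <- is.finite(a) * 1
  mb <- is.finite(b) * 1
  a0 <- ifelse(is.finite(a), a, 0)
  b0 <- ifelse(is.finite(b), b, 0)
  pad <- function(x) {
    p <- matrix(0, L, L)
    p[1:n, 1:n] <- x
    p
  }
  f_ma <- Conj(fft2(pad(ma)));  f_a0 <- Conj(fft2(pad(a0)))
  f_a2 <- Conj(fft2(pad(a0^2)))
  g_mb <- fft2(pad(mb));  g_b0 <- fft2(pad(b0));  g_b2 <- fft2(pad(b0^2))
  nn  <- lag_sums(f_ma, g_mb, n, L)
  sa  <- lag_sums(f_a0, g_mb, n, L)
  sb  <- lag_sums(f_ma, g_b0, n, L)
  sab <- lag_sums(f_a0, g_b0, n, L)
  saa <- lag_sums(f_a2, g_mb, n, L)
  sbb <- lag_sums(f_ma, g_b2, n, L)
  nn <- round(nn)
  num <- nn * sab - sa * sb
  den2 <- (nn * saa - sa^2) * (nn * sbb - sb^2)
  r <- ifelse(nn >= min_overlap & den2 > 1e-12, num / sqrt(pmax(den2, 0)),
              NA_real_)
  r <- pmin(pmax(r, -1), 1)
  attr(r, "center") <- n  # index of the zero lag on both axes
  r
}

#' Spatial autocorrelogram of a ratemap
#'
#' Masked Pearson autocorrelation over all integer 2D lags; the zero-lag
#' value is 1 by construction and the map is centrally symmetric.
#'
#' @inheritParams crosscorrelogram
#' @param ratemap Square numeric matrix (missing bins `NA`).
#' @return (2n-1) x (2n-1) correlogram.
#' @export
autocorrelogram <- function(ratemap, min_overlap = 20L) {
  crosscorrelogram(ratemap, ratemap, min_overlap = min_overlap)
}

## ---- image rotation with bilinear interpolation (cached mappings) ----

.rot_cache <- new.env(parent = emptyenv())

rotation_mapping <- function(n, deg) {
  key <- paste0(n, ":", round(deg, 6))
  hit <- .rot_cache[[key]]
  if (!is.null(hit)) return(hit)
  th <- deg * pi / 180
  c0 <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  # inverse map: source coords of each destination pixel (counterclockwise
  # rotation of the image content by +deg, with x = rows, y = columns)
  dx <- g$i - c0
  dy <- g$j - c0
  sx <- c0 + cos(th) * dx + sin(th) * dy
  sy <- c0 - sin(th) * dx + cos(th) * dy
  valid <- sx >= 1 - 1e-9 & sx <= n + 1e-9 & sy >= 1 - 1e-9 & sy <= n + 1e-9
  sx <- pmin(pmax(sx, 1), n)
  sy <- pmin(pmax(sy, 1), n)
  x0 <- pmin(floor(sx), n - 1)  # border pixels interpolate from inside
  y0 <- pmin(floor(sy), n - 1)
  fx <- sx - x0;   fy <- sy - y0
  idx <- function(xi, yi) (pmin(pmax(xi, 1L), n) - 1L) +
    (pmin(pmax(yi, 1L), n) - 1L) * n + 1L
  m <- list(valid = valid,
            i00 = idx(x0, y0), i10 = idx(x0 + 1L, y0),
            i01 = idx(x0, y0 + 1L), i11 = idx(x0 + 1L, y0 + 1L),
            w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
            w01 = (1 - fx) * fy, w11 = fx * fy)
  .rot_cache[[key]] <- m
  m
}

#' Rotate a square map about its center
#'
#' Bilinear interpolation; pixels whose source falls outside the map (or on
#' a missing value) become `NA`. Positive angles rotate the map content
#' counterclockwise.
#'
#' @param m Square numeric matrix.
#' @param deg Rotation angle in degrees.
#' @return Rotated matrix of the same size.
#' @export
rotate_map <- function(m, deg) {
  n <- nrow(m)
  stopifnot(n == ncol(m))
  mp <- rotation_mapping(n, deg)
  v <- rep(NA_real_, n * n)
  x <- as.vector(m)
  v[mp$valid] <- x[mp$i00[mp$valid]] * mp$w00[mp$valid] +
    x[mp$i10[mp$valid]] * mp$w10[mp$valid] +
    x[mp$i01[mp$valid]] * mp$w01[mp$valid] +
    x[mp$i11[mp$valid]] * mp$w11[mp$valid]
  matrix(v, n, n)
}

## Pearson correlation over pairwise-complete entries of two vectors
cor_complete <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(a[ok], b[ok]))
}

## ---- grid score ----

#' Hexagonality (grid) score of a ratemap
#'
#' The autocorrelogram is masked with an annulus (central peak and periphery
#' removed) and correlated with rotated copies of itself. The score is
#' `min(corr at 60, 120 deg) - max(corr at 30, 90, 150 deg)`, maximised over
#' a sweep of annulus radii. Hexagonal patterns score high (> 1 for ideal
#' grids); stripes and blobs score low. Degenerate (constant or
#' near-empty) maps give `NaN`.
#'
#' @param ratemap Square numeric matrix.
#' @param inner_radii,outer_radii Annulus radii swept, as fractions of the
#'   largest disk that fits in the autocorrelogram.
#' @return Scalar grid score (or `NaN`).
#' @export
grid_score <- function(ratemap,
                       inner_radii = c(0.15, 0.2, 0.25, 0.3),
                       outer_radii = seq(0.4, 1, by = 0.1)) {
  acg <- autocorrelogram(ratemap)
  if (all(!is.finite(acg))) return(NaN)
  n <- nrow(acg)
  c0 <- (n + 1) / 2
  rad <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  rmax <- (n - 1) / 2
  rots <- lapply(c(30, 60, 90, 120, 150),
                 function(d) as.vector(rotate_map(acg, d)))
  acg_v <- as.vector(acg)
  best <- NaN
  for (ri in inner_radii) {
    for (ro in outer_radii) {
      if (ro <= ri + 0.05) next
      sel <- rad >= ri * rmax & rad <= ro * rmax
      if (sum(sel) < 50) next
      cors <- vapply(rots, function(rv) cor_complete(acg_v[sel], rv[sel]),
                     numeric(1))
      if (any(!is.finite(cors))) next
      score <- min(cors[c(2, 4)]) - max(cors[c(1, 3, 5)])
      if (!is.finite(best) || score > best) best <- score
    }
  }
  best
}

## ---- peak detection on correlograms ----

## NA-aware Gaussian blur (sd in bins); renormalises by the blurred mask.
gaussian_blur <- function(m, sd = 1) {
  if (sd <= 0) return(m)
  r <- ceiling(3 * sd)
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  mask <- is.finite(m) * 1
  m0 <- ifelse(is.finite(m), m, 0)
  conv1 <- function(x, along) {
    # separable convolution via filter on rows/cols with zero padding
    apply_dim <- if (along == 1) 2 else 1
    t0 <- function(z) if (along == 1) z else t(z)
    z <- t0(x)
    z <- apply(z, 2, function(col) {
      stats::convolve(col, rev(k), type = "open")[(r + 1):(r + length(col))]
    })
    t0(z)
  }
  num <- conv1(conv1(m0, 1), 2)
  den <- conv1(conv1(mask, 1), 2)
  out <- num / den
  out[mask == 0] <- NA_real_
  out
}

#' Local peaks of a correlogram
#'
#' Local maxima over a 3x3 neighbourhood after light Gaussian smoothing
#' (sd = `smooth_sd` bins). Smoothing is used for peak localisation only.
#'
#' @param m Square correlogram matrix.
#' @param smooth_sd Gaussian sd (bins) for pre-smoothing. Default 1.
#' @param min_value Minimum (smoothed) value for a peak. Default `-Inf`.
#' @return Two-column matrix of (row, col) peak positions.
#' @export
find_local_peaks <- function(m, smooth_sd = 1, min_value = -Inf) {
  s <- gaussian_blur(m, smooth_sd)
  n <- nrow(s); p <- ncol(s)
  big <- matrix(-Inf, n + 2, p + 2)
  big[2:(n + 1), 2:(p + 1)] <- ifelse(is.finite(s), s, -Inf)
  ctr <- big[2:(n + 1), 2:(p + 1)]
  ismax <- ctr > min_value & is.finite(ctr)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- big[(2 + di):(n + 1 + di), (2 + dj):(p + 1 + dj)]
    ismax <- ismax & (ctr >= nb)
  }
  # collapse plateaus: require strictly greater than at least one neighbour
  which(ismax, arr.ind = TRUE)
}

#' Phase shift between two ratemaps
#'
#' Cross-correlates the two maps, finds all local peaks of the
#' cross-correlogram, and returns the offset of the peak closest to the
#' center, in box units. For periodic patterns this reads out the
#' translation (modulo the lattice) taking pattern `a` to pattern `b`.
#'
#' @param ratemap_a,ratemap_b Equal-sized square ratemaps.
#' @param bin_size Physical size of one bin; defaults to `2.2 / n`.
#' @return Length-2 numeric `(dx, dy)`; `NA` if no peak is detectable.
#' @export
phase_shift <- function(ratemap_a, ratemap_b,
                        bin_size = 2.2 / nrow(ratemap_a)) {
  cc <- crosscorrelogram(ratemap_a, ratemap_b)
  c0 <- attr(cc, "center")
  pk <- find_local_peaks(cc, smooth_sd = 1, min_value = 0)
  if (nrow(pk) == 0) return(c(NA_real_, NA_real_))
  d2 <- (pk[, 1] - c0)^2 + (pk[, 2] - c0)^2
  best <- pk[which.min(d2), ]
  unname(c(best[1], best[2]) - c0) * bin_size
}

#' Orientation shift between two ratemaps
#'
#' Both maps' autocorrelograms are computed; one is rotated against the
#' other in one-degree increments over (-180, 180], correlating the largest
#' overlapping central disk at each rotation. (Pearson correlation makes any
#' sum-normalisation of the correlograms immaterial, so none is applied.)
#' The shift is the rotation maximising the correlation; ties (within 1e-4,
#' the interpolation noise floor between the symmetry-equivalent angles of a
#' hexagonal pattern) are broken toward the smallest absolute rotation.
#'
#' @param ratemap_a,ratemap_b Equal-sized square ratemaps.
#' @param degrees Candidate rotations. Default `-179:180`.
#' @return Orientation shift in degrees: the rotation of pattern `b`
#'   relative to pattern `a`.
#' @export
orientation_shift <- function(ratemap_a, ratemap_b, degrees = -179:180) {
  acg_a <- autocorrelogram(ratemap_a)
  acg_b <- autocorrelogram(ratemap_b)
  n <- nrow(acg_a)
  c0 <- (n + 1) / 2
  rad2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")
  disk <- as.vector(rad2 <= ((n - 1) / 2)^2)
  av <- as.vector(acg_a)[disk]
  cors <- vapply(degrees, function(d) {
    rb <- as.vector(rotate_map(acg_b, -d))[disk]
    cor_complete(av, rb)
  }, numeric(1))
  top <- max(cors, na.rm = TRUE)
  cand <- degrees[which(cors >= top - 1e-4)]
  cand[which.min(abs(cand))]
}

#' Wrap orientation shifts to the hexagonal fundamental range
#'
#' Hexagonal patterns are 60-degree symmetric and their autocorrelograms
#' 30-degree quasi-symmetric; shifts are wrapped to `[-15, 15)` by shifting
#' 15 degrees, taking modulo 30, and recentring.
#'
#' @param deg Numeric vector of shifts in degrees.
#' @return Shifts wrapped to `[-15, 15)`.
#' @export
wrap_orientation <- function(deg) ((deg + 15) %% 30) - 15

#' Grid spacing from a ratemap
#'
#' Finds autocorrelogram peaks, sorts their center distances, and locates
#' the first jump in consecutive distance differences exceeding the mean
#' plus two standard deviations of the differences. The spacing is the
#' median distance of the isodistant peaks before the jump (all peaks if no
#' jump is found). For a three-wave hexagonal pattern at frequency f this
#' recovers the lattice constant `2 / (sqrt(3) f)`.
#'
#' @param ratemap Square ratemap matrix.
#' @param bin_size Physical bin size; defaults to `2.2 / n`.
#' @return Scalar spacing (box units); `NA` if fewer than 2 off-center
#'   peaks are found.
#' @export
grid_spacing <- function(ratemap, bin_size = 2.2 / nrow(ratemap)) {
  acg <- autocorrelogram(ratemap)
  c0 <- attr(acg, "center")
  pk <- find_local_peaks(acg, smooth_sd = 1, min_value = 0)
  if (nrow(pk) == 0) return(NA_real_)
  d <- sqrt((pk[, 1] - c0)^2 + (pk[, 2] - c0)^2)
  d <- sort(d[d > 2])  # drop the central peak
  if (length(d) < 2) return(NA_real_)
  dd <- diff(d)
  jump <- which(dd > mean(dd) + 2 * stats::sd(dd))
  keep <- if (length(jump) > 0) d[seq_len(jump[1])] else d
  stats::median(keep) * bin_size
}

#' Gaussian kernel density estimate of 2D shift distributions
#'
#' Scott's-rule bandwidth (`n^(-1/6)` scaling of the data covariance),
#' matching the common default for 2D KDEs. Near-singular covariances are
#' regularised with a small diagonal jitter (with a message).
#'
#' @param shifts m x 2 matrix of shift vectors.
#' @param grid_n Evaluation grid resolution per axis. Default 64.
#' @param limits Optional `c(xmin, xmax, ymin, ymax)`; defaults to the data
#'   range expanded by 3 bandwidths.
#' @return List with `x`, `y` (grid coordinates) and `z` (density matrix).
#' @export
shift_density <- function(shifts, grid_n = 64L, limits = NULL) {
  shifts <- as.matrix(shifts)
  stopifnot(ncol(shifts) == 2, nrow(shifts) >= 2)
  n <- nrow(shifts)
  fac <- n^(-1 / 6)  # Scott's rule, d = 2
  S <- stats::cov(shifts) * fac^2
  if (!is.finite(determinant_2x2(S)) || determinant_2x2(S) < 1e-12) {
    message("shift_density: near-singular covariance; adding jitter")
    S <- S + diag(1e-6, 2)
  }
  Sinv <- solve(S)
  norm <- 1 / (2 * pi * sqrt(determinant_2x2(S)))
  if (is.null(limits)) {
    bw <- sqrt(diag(S))
    limits <- c(range(shifts[, 1]) + c(-3, 3) * bw[1],
                range(shifts[, 2]) + c(-3, 3) * bw[2])
  }
  gx <- seq(limits[1], limits[2], length.out = grid_n)
  gy <- seq(limits[3], limits[4], length.out = grid_n)
  pts <- as.matrix(expand.grid(gx, gy))
  z <- numeric(nrow(pts))
  for (i in seq_len(n)) {
    dxy <- sweep(pts, 2L, shifts[i, ])
    q <- rowSums((dxy %*% Sinv) * dxy)
    z <- z + exp(-q / 2)
  }
  list(x = gx, y = gy, z = matrix(norm * z / n, grid_n, grid_n))
}

determinant_2x2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]

#' Circular variance of a set of angular shifts
#'
#' Shifts with period `period` are mapped to the unit circle and the
#' circular variance `1 - |mean resultant|` is returned: near 0 for
#' coherent (unimodal) shift distributions, near 1 for incoherent
#' (uniform) ones.
#'
#' @param shifts Numeric vector of shifts.
#' @param period Period of the shift variable (e.g. 30 for wrapped
#'   orientation shifts in degrees).
#' @return Circular variance in `[0, 1]`.
#' @export
circular_variance <- function(shifts, period = 30) {
  a <- shifts / period * 2 * pi
  1 - Mod(mean(exp(1i * a)))
}

#' Coherence of phase-shift vectors with respect to a grid lattice
#'
#' Maps 2D phase shifts to fractional coordinates of the module's lattice
#' basis (where they live on a torus), computes the circular variance along
#' each lattice direction, and returns the mean. Coherent modules give
#' values near 0, incoherent ones near 1.
#'
#' @param shifts m x 2 matrix of phase-shift vectors (box units).
#' @param f,theta Frequency and orientation of the underlying lattice.
#' @return Mean circular variance across the two lattice directions.
#' @export
phase_shift_coherence <- function(shifts, f = 1 / 0.838, theta = 0) {
  basis <- grid_lattice_basis(f, theta)
  frac <- t(solve(basis, t(as.matrix(shifts))))
  mean(c(circular_variance(frac[, 1], period = 1),
         circular_variance(frac[, 2], period = 1)))
}
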