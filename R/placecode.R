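#' Place-cell ensemble with difference-of-softmax tuning
#'
#' An environment is defined by the center locations of its place cells.
#' Each cell responds with a difference of two softmaxes over squared
#' distances (a Mexican-hat-like profile): narrow width `s1` minus broad
#' width `s2 = 2 * s1` by default. Centers are sampled iid uniformly over
#' the arena.
#'
#' @param arena An [arena_spec()].
#' @param n_cells Number of place cells (>= 3: the decoder averages the top-3
#'   centers). Default 512.
#' @param s1 Narrow tuning width (box units). Default 0.12.
#' @param s2 Broad tuning width. Default `2 * s1`.
#' @param seed Optional integer seed for the center draw.
#' @param environment_id Label for the environment. Default 0.
#' @return An object of class `place_ensemble` with fields `centers`
#'   (n_cells x 2), `s1`, `s2`, `arena`, `environment_id`.
#' @examples
#' ens <- place_cell_ensemble(n_cells = 64, seed = 1)
#' @export
place_cell_ensemble <- function(arena = arena_spec(), n_cells = 512L,
                                s1 = 0.12, s2 = 2 * s1, seed = NULL,
                                environment_id = 0L) {
  if (n_cells < 3)
    stop("n_cells must be >= 3: position decoding averages the centers of ",
         "the three most active cells")
  stopifnot(s1 > 0, s2 > s1)
  if (!is.null(seed)) set.seed(seed)
  half <- arena$side_length / 2
  centers <- cbind(stats::runif(n_cells, -half, half),
                   stats::runif(n_cells, -half, half))
  structure(list(centers = centers, s1 = s1, s2 = s2, arena = arena,
                 environment_id = environment_id),
            class = "place_ensemble")
}

#' @export
print.place_ensemble <- function(x, ...) {
  cat(sprintf("place_ensemble: %d cells, s1 = %g, s2 = %g, environment %s\n",
              nrow(x$centers), x$s1, x$s2, x$environment_id))
  invisible(x)
}

#' Globally remap a place-cell ensemble
#'
#' Draws fresh uniform center locations while keeping the tuning widths and
#' cell count, emulating global remapping: the same cells fire at
#' statistically independent locations in the new environment.
#'
#' @param ensemble A `place_ensemble`.
#' @param seed Optional integer seed.
#' @param environment_id Label for the new environment; defaults to the old
#'   label plus one.
#' @return A new `place_ensemble`.
#' @export
remap_ensemble <- function(ensemble, seed = NULL, environment_id = NULL) {
  stopifnot(inherits(ensemble, "place_ensemble"))
  if (is.null(environment_id)) {
    environment_id <- tryCatch(ensemble$environment_id + 1L,
                               error = function(e) "remapped")
  }
  place_cell_ensemble(arena = ensemble$arena,
                      n_cells = nrow(ensemble$centers),
                      s1 = ensemble$s1, s2 = ensemble$s2, seed = seed,
                      environment_id = environment_id)
}

row_softmax <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  e / rowSums(e)
}

#' Encode positions as place-cell population activity
#'
#' Computes, for each position x, the difference of softmaxes
#' `softmax(-d^2 / (2 s1^2)) - softmax(-d^2 / (2 s2^2))` over all cells
#' (d = distance to each center), then shift-normalises per location: the
#' absolute value of the minimum entry is added to every entry and the vector
#' is divided by its sum. The result is nonnegative and sums to one at every
#' location, so it can serve as a cross-entropy target.
#'
#' @param x Position: length-2 vector or m x 2 matrix.
#' @param ensemble A `place_ensemble`.
#' @return m x n_cells matrix of activities (rows sum to 1).
#' @export
encode_position <- function(x, ensemble) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  d2 <- sq_dist(x, ensemble$centers)
  p <- row_softmax(-d2 / (2 * ensemble$s1^2)) -
       row_softmax(-d2 / (2 * ensemble$s2^2))
  row_min <- -(-p)[cbind(seq_len(nrow(p)), max.col(-p, ties.method = "first"))]
  p <- p + abs(row_min)
  p / rowSums(p)
}

## squared Euclidean distances between rows of a (m x 2) and b (n x 2)
sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Decode positions from place-cell activity
#'
#' Center-of-mass readout: the three most active cells are selected (ties at
#' rank 3 broken by lowest cell index) and the unweighted mean of their
#' center locations is returned.
#'
#' @param p Activity: length-n vector or m x n matrix (one row per location).
#' @param ensemble A `place_ensemble` providing the centers.
#' @return m x 2 matrix of decoded positions.
#' @export
decode_position <- function(p, ensemble) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  stopifnot(ncol(p) >= 3, ncol(p) == nrow(ensemble$centers))
  out <- matrix(NA_real_, nrow(p), 2)
  cx <- ensemble$centers[, 1]
  cy <- ensemble$centers[, 2]
  for (i in seq_len(nrow(p))) {
    top3 <- order(-p[i, ])[1:3]  # stable: ties broken by lowest index
    out[i, ] <- c(mean(cx[top3]), mean(cy[top3]))
  }
  out
}

#' Baseline decoding error of an ensemble
#'
#' Mean Euclidean distance between true positions and
#' `decode(encode(position))` over uniform random positions: the resolution
#' floor of the top-3 center-of-mass code, against which the network's
#' path-integration error is compared.
#'
#' @param ensemble A `place_ensemble`.
#' @param n_eval Number of uniform evaluation positions. Default 1000.
#' @param seed Optional seed.
#' @return Scalar mean error (box units).
#' @export
baseline_decoding_error <- function(ensemble, n_eval = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  half <- ensemble$arena$side_length / 2
  x <- cbind(stats::runif(n_eval, -half, half),
             stats::runif(n_eval, -half, half))
  xh <- decode_position(encode_position(x, ensemble), ensemble)
  mean(sqrt(rowSums((x - xh)^2)))
}
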