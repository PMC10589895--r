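#' Ideal grid-cell activity from three interfering plane waves
#'
#' Evaluates the classic three-plane-wave construction of a hexagonal firing
#' pattern: the rectified sum of three cosines whose unit wave vectors point
#' at 0, 60 and 120 degrees (rotated by the pattern orientation `theta`),
#' with spatial frequency `f` and a 2D phase offset. The activity peaks at
#' `ReLU(3) = 3` on the triangular lattice of points congruent to `phase`.
#'
#' @param positions m x 2 matrix (or length-2 vector) of spatial coordinates.
#' @param f Spatial frequency of the pattern.
#' @param theta Pattern orientation (radians).
#' @param phase Length-2 phase offset (box units).
#' @return Length-m vector of nonnegative activities.
#' @examples
#' grid_cell_activity(c(0, 0), f = 1, theta = 0, phase = c(0, 0))  # 3
#' @export
grid_cell_activity <- function(positions, f = 1 / 0.838, theta = 0,
                               phase = c(0, 0)) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  ang <- theta + c(0, pi / 3, 2 * pi / 3)
  dx <- positions[, 1] - phase[1]
  dy <- positions[, 2] - phase[2]
  s <- 0
  for (a in ang) s <- s + cos(2 * pi * f * (cos(a) * dx + sin(a) * dy))
  pmax(s, 0)
}

#' Real-space lattice basis of the hexagonal pattern
#'
#' Primitive vectors `a1`, `a2` of the triangular peak lattice generated by
#' the three-wave pattern at frequency `f` and orientation `theta`. Both have
#' length `2 / (sqrt(3) * f)`, the nearest-peak spacing.
#'
#' @param f Spatial frequency.
#' @param theta Orientation (radians).
#' @return 2 x 2 matrix with columns `a1`, `a2`.
#' @export
grid_lattice_basis <- function(f = 1 / 0.838, theta = 0) {
  # duals of wave vectors b1 = 2 pi f (1,0), b2 = 2 pi f (1/2, sqrt(3)/2)
  a1 <- c(1, -1 / sqrt(3)) / f
  a2 <- c(0, 2 / sqrt(3)) / f
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot %*% cbind(a1, a2)
}

#' Analytic grid spacing of the three-wave pattern
#'
#' Nearest-peak distance `2 / (sqrt(3) * f)` of the triangular lattice
#' produced by three plane waves at 60 degrees with frequency `f`. Note this
#' differs from the reciprocal wavelength `1 / f` by the factor
#' `2 / sqrt(3)`; both conventions appear in the literature.
#'
#' @param f Spatial frequency.
#' @return Lattice constant (box units).
#' @export
grid_spacing_analytic <- function(f) 2 / (sqrt(3) * f)

#' Build a synthetic grid module
#'
#' All cells of a module share the same frequency and orientation; phases
#' are sampled iid uniformly over one unit cell of the lattice (the
#' fundamental parallelogram spanned by the primitive lattice vectors, an
#' equal-area fundamental domain of the hexagonal Wigner-Seitz cell).
#'
#' @param n_cells Number of cells. Default 50.
#' @param f Shared spatial frequency. Default `1 / 0.838`.
#' @param theta Shared orientation (radians). Default 0.
#' @param seed Optional integer seed.
#' @return An object of class `grid_module` with fields `f`, `theta`
#'   (length-n, shared unless remapped incoherently), `phases` (n x 2) and
#'   `frac` (n x 2 fractional lattice coordinates of the phases).
#' @export
grid_module <- function(n_cells = 50L, f = 1 / 0.838, theta = 0,
                        seed = NULL) {
  stopifnot(n_cells >= 1, f > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- cbind(stats::runif(n_cells), stats::runif(n_cells))
  basis <- grid_lattice_basis(f, theta)
  structure(list(f = f, theta = rep(theta, n_cells),
                 phases = u %*% t(basis), frac = u,
                 n_cells = as.integer(n_cells)),
            class = "grid_module")
}

#' @export
print.grid_module <- function(x, ...) {
  cat(sprintf(
    "grid_module: %d cells, f = %.4g (spacing %.4g), orientation %s deg\n",
    x$n_cells, x$f, grid_spacing_analytic(x$f),
    if (length(unique(x$theta)) == 1) sprintf("%.2f", x$theta[1] * 180 / pi)
    else "per-cell"))
  invisible(x)
}

#' Apply a remapping scenario to a grid module
#'
#' The five scenarios of idealized module remapping:
#' \describe{
#'   \item{identity}{no change.}
#'   \item{coherent_phase}{every phase shifted by the same `delta`
#'     (default `c(-0.2, -0.2)`).}
#'   \item{coherent_rotation}{shared orientation rotated by `angle`
#'     (default -5 degrees). Patterns rotate about their own phase, so
#'     phases are unchanged.}
#'   \item{incoherent_phase}{phases independently resampled uniformly in the
#'     unit cell.}
#'   \item{incoherent_rotation}{each cell rotated by its own uniform random
#'     angle.}
#' }
#'
#' @param module A `grid_module`.
#' @param scenario One of `"identity"`, `"coherent_phase"`,
#'   `"coherent_rotation"`, `"incoherent_phase"`, `"incoherent_rotation"`.
#' @param delta Coherent phase offset (box units).
#' @param angle Coherent rotation (degrees).
#' @param seed Optional seed for the incoherent scenarios.
#' @return A remapped `grid_module`.
#' @export
apply_remap_scenario <- function(module,
                                 scenario = c("identity", "coherent_phase",
                                              "coherent_rotation",
                                              "incoherent_phase",
                                              "incoherent_rotation"),
                                 delta = c(-0.2, -0.2), angle = -5,
                                 seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(module, "grid_module"))
  if (!is.null(seed)) set.seed(seed)
  out <- module
  n <- module$n_cells
  if (scenario == "coherent_phase") {
    out$phases <- sweep(module$phases, 2L, delta, "+")
  } else if (scenario == "coherent_rotation") {
    out$theta <- module$theta + angle * pi / 180
  } else if (scenario == "incoherent_phase") {
    u <- cbind(stats::runif(n), stats::runif(n))
    basis <- grid_lattice_basis(module$f, module$theta[1])
    out$phases <- u %*% t(basis)
    out$frac <- u
  } else if (scenario == "incoherent_rotation") {
    out$theta <- module$theta + stats::runif(n, -pi, pi)
  }
  attr(out, "scenario") <- scenario
  out
}

#' Evaluate all cells of a module at a set of positions
#'
#' @param module A `grid_module`.
#' @param positions m x 2 matrix of coordinates.
#' @return m x n_cells activity matrix.
#' @export
module_activity <- function(module, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  vapply(seq_len(module$n_cells), function(i) {
    grid_cell_activity(positions, module$f, module$theta[i],
                       module$phases[i, ])
  }, numeric(nrow(positions)))
}

#' Analytic ratemaps of a module over the arena
#'
#' Evaluates every cell at the centers of an `n_bins` x `n_bins` grid
#' covering the arena: the noiseless equivalent of a trajectory-sampled
#' ratemap.
#'
#' @param module A `grid_module`.
#' @param arena An [arena_spec()].
#' @param n_bins Spatial resolution per axis. Default 64.
#' @return n_bins x n_bins x n_cells array; x indexes rows, y columns.
#' @export
module_ratemaps <- function(module, arena = arena_spec(), n_bins = 64L) {
  ctr <- bin_centers(arena, n_bins)
  pts <- as.matrix(expand.grid(x = ctr, y = ctr))
  act <- module_activity(module, pts)
  array(act, c(n_bins, n_bins, module$n_cells))
}

#' Population point cloud of a module
#'
#' Stacks per-position population activity vectors over a regular spatial
#' grid: one point per spatial bin, one dimension per cell. For a hexagonal
#' module this cloud lies on a two-dimensional torus (phases wrap in both
#' lattice directions), which makes it a ground-truth positive control for
#' topology detection.
#'
#' @param module A `grid_module` (>= 3 cells recommended).
#' @param arena An [arena_spec()].
#' @param n_bins Grid resolution per axis. Default 64.
#' @return (n_bins^2) x n_cells matrix.
#' @export
module_pointcloud <- function(module, arena = arena_spec(), n_bins = 64L) {
  ctr <- bin_centers(arena, n_bins)
  pts <- as.matrix(expand.grid(x = ctr, y = ctr))
  module_activity(module, pts)
}

bin_centers <- function(arena, n_bins) {
  half <- arena$side_length / 2
  edges <- seq(-half, half, length.out = n_bins + 1)
  (edges[-1] + edges[-(n_bins + 1)]) / 2
}
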