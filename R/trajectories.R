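#' Square foraging arena
#'
#' Describes the square enclosure the simulated agent forages in. The arena is
#' centered at the origin, so coordinates live in
#' `[-side_length/2, side_length/2]` on both axes. Walls carry a soft margin:
#' inside the margin the agent is steered away from the wall before a hard
#' clamp guarantees containment.
#'
#' @param side_length Side of the square box (box units). Default 2.2.
#' @param soft_margin Width of the soft-boundary band at each wall. Default
#'   0.03.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()
#' @export
arena_spec <- function(side_length = 2.2, soft_margin = 0.03) {
  stopifnot(is.numeric(side_length), length(side_length) == 1L,
            side_length > 0)
  stopifnot(is.numeric(soft_margin), length(soft_margin) == 1L,
            soft_margin >= 0, soft_margin < side_length / 2)
  structure(list(side_length = side_length, soft_margin = soft_margin),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("Square arena %.3g x %.3g (soft margin %.3g), centered at 0\n",
              x$side_length, x$side_length, x$soft_margin))
  invisible(x)
}

#' Motion statistics of the random forager
#'
#' Speeds are Rayleigh distributed and headings follow a Gaussian random walk,
#' emulating rodent foraging statistics. `speed_scale` and `heading_sd` are
#' per-second rates; each step advances time by `tau`, so the per-step heading
#' increment has standard deviation `heading_sd * tau` and the per-step
#' displacement is `speed * tau`.
#'
#' @param tau Integration time constant (s). Default 0.02.
#' @param speed_scale Rayleigh scale parameter b of the speed distribution.
#'   Default `2 * 0.13 * pi`.
#' @param heading_sd Standard deviation of the heading rotation rate
#'   (radians/s). Default `2 * 5.76`.
#' @param n_steps Number of timesteps per trajectory. Default 20.
#' @param wall_slowdown Multiplicative speed factor applied when the
#'   soft-boundary rule triggers. Default 0.25.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(tau = 0.02, speed_scale = 2 * 0.13 * pi,
                          heading_sd = 2 * 5.76, n_steps = 20L,
                          wall_slowdown = 0.25) {
  stopifnot(tau > 0, speed_scale > 0, heading_sd >= 0, n_steps >= 1,
            wall_slowdown > 0, wall_slowdown <= 1)
  structure(list(tau = tau, speed_scale = speed_scale,
                 heading_sd = heading_sd, n_steps = as.integer(n_steps),
                 wall_slowdown = wall_slowdown),
            class = "motion_params")
}

#' Sample initial positions and headings
#'
#' Positions are uniform over the square arena, headings uniform on
#' `[-pi, pi)`.
#'
#' @param arena An [arena_spec()].
#' @param n Number of agents to initialise.
#' @return List with `position` (n x 2 matrix) and `heading` (length-n
#'   vector).
#' @export
sample_initial_state <- function(arena, n = 1L) {
  stopifnot(inherits(arena, "arena_spec"), n >= 1)
  half <- arena$side_length / 2
  list(position = cbind(stats::runif(n, -half, half),
                        stats::runif(n, -half, half)),
       heading = stats::runif(n, -pi, pi))
}

## Rayleigh(b) sampler via inverse transform.
rrayleigh <- function(n, scale) scale * sqrt(-2 * log(stats::runif(n)))

#' Advance a population of agents by one timestep
#'
#' Draws a fresh speed from Rayleigh(`speed_scale`) and a heading from a
#' Gaussian centered on the previous heading (sd `heading_sd * tau`). Agents
#' within `soft_margin` of a wall and heading within 90 degrees of the outward
#' wall normal have the corresponding velocity component reflected inward and
#' their speed reduced by `wall_slowdown`; a final hard clamp keeps every
#' position inside the box. Positions advance by `tau * velocity`, where the
#' stored velocity is the effective (post-boundary-rule) one, so the
#' integration identity `x_t = x_{t-1} + tau * v_t` holds exactly.
#'
#' @param position n x 2 matrix of current positions.
#' @param heading length-n vector of current headings (radians).
#' @param arena An [arena_spec()].
#' @param motion A [motion_params()].
#' @return List with updated `position`, `heading`, `velocity` (n x 2) and
#'   `speed`.
#' @export
step_agent <- function(position, heading, arena, motion) {
  n <- nrow(position)
  half <- arena$side_length / 2
  speed <- rrayleigh(n, motion$speed_scale)
  heading <- heading + stats::rnorm(n, 0, motion$heading_sd * motion$tau)
  heading <- wrap_angle(heading)
  vx <- speed * cos(heading)
  vy <- speed * sin(heading)

  # soft boundary: reflect the outward velocity component and slow down
  slowed <- rep(FALSE, n)
  for (axis in 1:2) {
    v <- if (axis == 1) vx else vy
    p <- position[, axis]
    hit_hi <- p > half - arena$soft_margin & v > 0
    hit_lo <- p < -half + arena$soft_margin & v < 0
    v[hit_hi] <- -v[hit_hi]
    v[hit_lo] <- -v[hit_lo]
    if (axis == 1) vx <- v else vy <- v
    slowed <- slowed | hit_hi | hit_lo
  }
  vx[slowed] <- vx[slowed] * motion$wall_slowdown
  vy[slowed] <- vy[slowed] * motion$wall_slowdown
  heading[slowed] <- atan2(vy[slowed], vx[slowed])

  new_pos <- position + motion$tau * cbind(vx, vy)
  new_pos <- pmin(pmax(new_pos, -half), half)
  # effective velocity after the hard clamp (rarely differs)
  vel <- (new_pos - position) / motion$tau
  list(position = new_pos, heading = heading, velocity = vel,
       speed = sqrt(rowSums(vel^2)))
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Simulate a batch of foraging trajectories
#'
#' Generates `n_traj` independent random walks of `motion$n_steps` steps each.
#' All randomness flows through R's RNG, so a fixed `seed` reproduces the
#' batch bitwise.
#'
#' @param n_traj Number of trajectories.
#' @param arena An [arena_spec()].
#' @param motion A [motion_params()].
#' @param seed Optional integer seed.
#' @return An object of class `trajectory_batch`: list with `x0` (n x 2),
#'   `positions` (n x T x 2), `velocities` (n x T x 2), `headings` (n x T),
#'   plus the `arena` and `motion` used.
#' @examples
#' walks <- simulate_trajectories(10, seed = 1)
#' dim(walks$velocities)
#' @export
simulate_trajectories <- function(n_traj, arena = arena_spec(),
                                  motion = motion_params(), seed = NULL) {
  stopifnot(n_traj >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_traj <- as.integer(n_traj)
  T <- motion$n_steps
  init <- sample_initial_state(arena, n_traj)
  pos <- array(NA_real_, c(n_traj, T, 2))
  vel <- array(NA_real_, c(n_traj, T, 2))
  hd <- matrix(NA_real_, n_traj, T)
  state <- list(position = init$position, heading = init$heading)
  for (t in seq_len(T)) {
    state <- step_agent(state$position, state$heading, arena, motion)
    pos[, t, ] <- state$position
    vel[, t, ] <- state$velocity
    hd[, t] <- state$heading
  }
  structure(list(x0 = init$position, positions = pos, velocities = vel,
                 headings = hd, arena = arena, motion = motion),
            class = "trajectory_batch")
}

#' @export
print.trajectory_batch <- function(x, ...) {
  cat(sprintf("trajectory_batch: %d walks x %d steps (tau = %g)\n",
              nrow(x$x0), dim(x$positions)[2], x$motion$tau))
  invisible(x)
}

#' Flatten a trajectory batch to a position matrix
#'
#' Stacks all timesteps of all trajectories into one (n*T) x 2 matrix,
#' trajectory-major. Useful for ratemap binning and batched encoding.
#'
#' @param batch A `trajectory_batch`.
#' @param t_slice Optional integer vector of timesteps to keep.
#' @return Matrix of positions.
#' @export
flatten_positions <- function(batch, t_slice = NULL) {
  p <- batch$positions
  if (!is.null(t_slice)) p <- p[, t_slice, , drop = FALSE]
  matrix(p, ncol = 2)
}
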