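#' Inactivate recurrent units by zeroing their incoming weights
#'
#' Pruning a unit sets its incoming recurrent row (`Wg`) and velocity input
#' row (`Wv`) to zero. With no bias terms the unit's recurrent activity is
#' identically zero from the first timestep on; the encoder and decoder are
#' untouched. The input model is not modified.
#'
#' @param model A `pathint_model`.
#' @param indices Unique unit indices to prune (may be empty).
#' @return A pruned copy of the model.
#' @export
prune_units <- function(model, indices) {
  stopifnot(inherits(model, "pathint_model"))
  if (length(indices) == 0) return(model)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("pruning indices must be unique")
  if (any(indices < 1 | indices > model$n_units))
    stop("pruning index out of range 1..", model$n_units)
  model$Wg[indices, ] <- 0
  model$Wv[indices, ] <- 0
  model
}

#' Rank units by cumulative grid score across environments
#'
#' Sums each unit's grid score over environments (NaN scores from
#' degenerate ratemaps count as the population minimum, keeping such units
#' at the bottom of the ranking) and returns the indices of the top `n`.
#'
#' @param scores n_units x n_envs matrix of grid scores.
#' @param n Number of units to select.
#' @return Integer vector of `n` unit indices, highest cumulative score
#'   first.
#' @export
select_top_grid <- function(scores, n) {
  scores <- as.matrix(scores)
  stopifnot(n >= 1, n <= nrow(scores))
  floor_val <- min(scores[is.finite(scores)], na.rm = TRUE) - 1
  scores[!is.finite(scores)] <- floor_val
  order(-rowSums(scores))[seq_len(n)]
}

#' Pruning plan
#'
#' @param step Units pruned per increment. Default 10.
#' @param max_units Largest pruning count (truncated to the target set
#'   size). Default 100.
#' @param repeats Independent repetitions (fresh random orders and fresh
#'   evaluation batches). Default 30.
#' @param eval_timestep Timestep at which decoding error is read out.
#'   Default 20.
#' @param batch Evaluation trajectories per repeat (split equally across
#'   environments). Default 200.
#' @return An object of class `pruning_plan`.
#' @export
pruning_plan <- function(step = 10L, max_units = 100L, repeats = 30L,
                         eval_timestep = 20L, batch = 200L) {
  stopifnot(step >= 1, repeats >= 1, batch >= 1)
  structure(list(step = as.integer(step), max_units = as.integer(max_units),
                 repeats = as.integer(repeats),
                 eval_timestep = as.integer(eval_timestep),
                 batch = as.integer(batch)),
            class = "pruning_plan")
}

## decoding error at one timestep, averaged over environments, for a fresh
## evaluation batch (batch split equally across environments)
eval_pruned_error <- function(model, environments, plan, arena, motion) {
  n_env <- length(environments)
  per <- plan$batch %/% n_env
  errs <- vapply(environments, function(ens) {
    b <- simulate_trajectories(per, arena, motion)
    decoding_error(model, b, ens, timesteps = plan$eval_timestep)
  }, numeric(1))
  mean(errs)
}

#' Decoding error as a function of the number of pruned units
#'
#' Within each repeat, units are drawn without replacement from the target
#' set and pruned cumulatively in increments of `plan$step`; at every
#' increment the decoding error at `plan$eval_timestep` is measured on a
#' fresh evaluation batch split equally across the familiar environments.
#' Curves aggregate repeats as median and median absolute deviation.
#'
#' @param model A trained `pathint_model`.
#' @param environments List of familiar `place_ensemble`s.
#' @param target_units Indices the strategy may prune (e.g. all units for
#'   random pruning, or an identified ensemble). The curve is truncated at
#'   the target set size.
#' @param plan A [pruning_plan()].
#' @param arena,motion Trajectory settings for evaluation batches.
#' @param seed Optional seed.
#' @param strategy Label stored with the curve.
#' @return `data.frame` with `n_pruned`, `median`, `mad`, `strategy`.
#' @export
pruning_curve <- function(model, environments, target_units,
                          plan = pruning_plan(), arena = arena_spec(),
                          motion = motion_params(), seed = NULL,
                          strategy = "custom") {
  if (!is.null(seed)) set.seed(seed)
  target_units <- as.integer(target_units)
  n_grid <- seq(0L, min(plan$max_units, length(target_units)),
                by = plan$step)
  errs <- matrix(NA_real_, plan$repeats, length(n_grid))
  for (r in seq_len(plan$repeats)) {
    ord <- sample(target_units)
    for (j in seq_along(n_grid)) {
      pm <- prune_units(model, ord[seq_len(n_grid[j])])
      errs[r, j] <- eval_pruned_error(pm, environments, plan, arena, motion)
    }
  }
  data.frame(n_pruned = n_grid,
             median = apply(errs, 2, stats::median),
             mad = apply(errs, 2, stats::mad),
             strategy = strategy)
}

#' Decoding error over time at a fixed pruning level
#'
#' Prunes `n_fixed` units drawn without replacement from the target set and
#' reports the median (over repeats) decoding error at every timestep,
#' averaged over the familiar environments.
#'
#' @inheritParams pruning_curve
#' @param n_fixed Number of units pruned. Default 100.
#' @return `data.frame` with `timestep`, `median`, `mad`, `strategy`.
#' @export
pruning_time_course <- function(model, environments, target_units,
                                n_fixed = 100L, plan = pruning_plan(),
                                arena = arena_spec(),
                                motion = motion_params(), seed = NULL,
                                strategy = "custom") {
  if (!is.null(seed)) set.seed(seed)
  target_units <- as.integer(target_units)
  n_fixed <- min(n_fixed, length(target_units))
  T <- motion$n_steps
  n_env <- length(environments)
  per <- plan$batch %/% n_env
  errs <- matrix(NA_real_, plan$repeats, T)
  for (r in seq_len(plan$repeats)) {
    pm <- prune_units(model, sample(target_units, n_fixed))
    e <- rowMeans(vapply(environments, function(ens) {
      b <- simulate_trajectories(per, arena, motion)
      decoding_error(pm, b, ens)
    }, numeric(T)))
    errs[r, ] <- e
  }
  data.frame(timestep = seq_len(T),
             median = apply(errs, 2, stats::median),
             mad = apply(errs, 2, stats::mad),
             strategy = strategy)
}
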