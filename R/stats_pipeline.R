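#' Tail probability of an ensemble overlap under a Binomial model
#'
#' Probability that two subsets of sizes `n_a` and `n_b`, drawn from a
#' population of `n_total` units, overlap in at most `x` units, under the
#' Binomial model `X ~ Bin(n_a, n_b / n_total)` (each member of the first
#' set independently has probability `n_b / n_total` of also belonging to
#' the second). Computed by exact summation of the mass function. The
#' hypergeometric (without-replacement) alternative is reported alongside
#' for sensitivity.
#'
#' @param n_total Population size.
#' @param n_a,n_b Sizes of the two subsets.
#' @param x Observed overlap.
#' @return List with `p_binomial`, `p_hypergeometric`, and the inputs.
#' @examples
#' overlap_tail_probability(4096, 604, 604, 56)
#' @export
overlap_tail_probability <- function(n_total, n_a, n_b, x) {
  stopifnot(n_total >= 1, n_a >= 0, n_b >= 0, n_a <= n_total,
            n_b <= n_total)
  if (x < 0 || x > min(n_a, n_b))
    stop("overlap x must lie in [0, min(n_a, n_b)]")
  p <- n_b / n_total
  p_binom <- sum(stats::dbinom(0:x, size = n_a, prob = p))
  p_hyper <- stats::phyper(x, m = n_b, n = n_total - n_b, k = n_a)
  list(p_binomial = p_binom, p_hypergeometric = p_hyper,
       n_total = n_total, n_a = n_a, n_b = n_b, x = x)
}

#' Experiment configuration
#'
#' Bundles all module parameters for an end-to-end run. The `desk` preset
#' is a reduced problem size that exercises every stage on a single CPU in
#' minutes; `paper` holds the full-scale settings (4096 units, 512 place
#' cells, 1e5 minibatches per environment) for reference.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ... Named overrides of any field.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(n_units = 256L, n_place = 64L, n_envs = 3L,
         total_minibatches = 2000L, batch = 200L, lr = 1e-4, lambda = 1e-4,
         ratemap_bins = 32L, ratemap_trajectories = 1000L,
         n_landmarks = 300L, downsample_keep = 900L, fuzzy_k = 200L,
         pruning_repeats = 10L, pruning_step = 10L, pruning_max = 60L,
         seed = 0L)
  } else {
    list(n_units = 4096L, n_place = 512L, n_envs = 3L,
         total_minibatches = NULL, minibatches_per_env = 100000L,
         batch = 200L, lr = 1e-4, lambda = 1e-4,
         ratemap_bins = 64L, ratemap_trajectories = 5000L,
         n_landmarks = 500L, downsample_keep = 3000L, fuzzy_k = 1000L,
         pruning_repeats = 30L, pruning_step = 10L, pruning_max = 360L,
         seed = 0L)
  }
  over <- list(...)
  cfg[names(over)] <- over
  cfg$preset <- preset
  structure(cfg, class = "experiment_config")
}

## derive a bounded child seed from a base seed and a stage label
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1103L + as.integer(stage) * 12347L) %% 2147480000L
}

#' Ratemaps of all recurrent units in one environment
#'
#' Runs the network over fresh trajectories in the given environment and
#' bins each unit's recurrent activity over space.
#'
#' @param model A `pathint_model`.
#' @param ensemble The environment's `place_ensemble`.
#' @param n_trajectories Trajectories to simulate. Default 1000.
#' @param n_bins Ratemap resolution. Default 32.
#' @param t_slice Timesteps retained (default `NULL` = all; the clustering
#'   pipeline uses the final half to avoid transient initial states).
#' @param arena,motion Trajectory settings.
#' @param seed Optional seed.
#' @return n_bins x n_bins x n_units array.
#' @export
unit_ratemaps <- function(model, ensemble, n_trajectories = 1000L,
                          n_bins = 32L, t_slice = NULL,
                          arena = arena_spec(), motion = motion_params(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- simulate_trajectories(n_trajectories, arena, motion)
  p0 <- encode_position(b$x0, ensemble)
  fw <- rnn_forward(model, p0, b$velocities, return_states = TRUE)
  act <- flatten_activity(fw$g, t_slice)
  pos <- flatten_positions(b, t_slice)
  ratemap_stack(act, pos, arena, n_bins)
}

#' Identify the torus ensemble of a trained model
#'
#' The full unit-type analysis: ratemaps in every environment, exclusion of
#' degenerate units, rotational-symmetry clustering, band-like cluster
#' identification, and K-means refinement of the candidate set into three
#' band orientations. Falls back to an empty result (with a message) when
#' no band-like cluster is found.
#'
#' @param ratemaps32 List (one per environment) of n_bins x n_bins x
#'   n_units ratemap arrays.
#' @param min_samples DBSCAN core threshold. Default 30.
#' @param band_clusters Optional manual override of band-like cluster ids.
#' @return List with `ensemble` (unit indices), `labels`, `keep`,
#'   `rotacgs`, `band_clusters`, `subcluster`.
#' @export
identify_torus_ensemble <- function(ratemaps32, min_samples = 30L,
                                    band_clusters = NULL) {
  n_units <- dim(ratemaps32[[1]])[3]
  # average ratemaps across environments unit-wise for exclusion, but
  # cluster on the concatenated per-environment fingerprints
  excl <- exclude_units(ratemaps32[[1]])
  keep <- excl$keep
  acg_rows <- lapply(ratemaps32, function(rs) {
    t(vapply(seq_len(n_units), function(u) {
      if (!keep[u]) return(rep(NA_real_, 360))
      m <- rs[, , u]
      if (all(!is.finite(m)) || stats::sd(m, na.rm = TRUE) == 0) {
        keep[u] <<- FALSE
        return(rep(NA_real_, 360))
      }
      as.numeric(rotational_autocorrelogram(m))
    }, numeric(360)))
  })
  rot <- do.call(cbind, acg_rows)[keep, , drop = FALSE]
  idx_keep <- which(keep)
  cl <- cluster_units(rot, min_samples = min_samples)
  # average the per-environment fingerprints for the symmetry signature
  rot_mean <- Reduce(`+`, lapply(seq_along(acg_rows), function(i)
    acg_rows[[i]][keep, , drop = FALSE])) / length(acg_rows)
  bands <- find_band_clusters(rot_mean, cl$labels,
                              band_clusters = band_clusters)
  if (length(bands) == 0) {
    message("no band-like cluster found; torus ensemble empty")
    return(list(ensemble = integer(0), labels = cl$labels, keep = keep,
                rotacgs = rot, band_clusters = bands, subcluster = NULL))
  }
  cand_local <- which(cl$labels %in% bands)
  sub <- NULL
  if (length(cand_local) >= 3) {
    acgs <- t(vapply(idx_keep[cand_local], function(u) {
      as.vector(autocorrelogram(ratemaps32[[1]][, , u]))
    }, numeric((2 * dim(ratemaps32[[1]])[1] - 1)^2)))
    sub <- refine_torus_ensemble(acgs, seed = 1)$subcluster
  }
  list(ensemble = idx_keep[cand_local], labels = cl$labels, keep = keep,
       rotacgs = rot, band_clusters = bands, subcluster = sub)
}

#' Grid scores of all units in every environment
#'
#' @param ratemaps List (one per environment) of ratemap arrays.
#' @return n_units x n_envs matrix of grid scores.
#' @export
unit_grid_scores <- function(ratemaps) {
  n_units <- dim(ratemaps[[1]])[3]
  vapply(ratemaps, function(rs) {
    vapply(seq_len(n_units), function(u) grid_score(rs[, , u]), numeric(1))
  }, numeric(n_units))
}

#' Run the full pipeline end to end
#'
#' Simulate -> encode -> train -> spatial metrics -> cluster -> topology ->
#' prune, at the scale given by the configuration, collecting a
#' machine-readable summary. Every stage is seeded from `config$seed`, so
#' reruns reproduce the summary.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, the summary is written
#'   to `summary.json` and the training log to `training_log.csv`.
#' @param verbose Print stage progress.
#' @return List with `summary` (flat list of headline numbers), `model`,
#'   `fit`, `ensembles`, `torus`, `pruning`.
#' @export
run_experiment <- function(config = experiment_config("desk"),
                           out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  arena <- arena_spec()
  motion <- motion_params()
  set.seed(stage_seed(config$seed, 1L))
  envs <- lapply(seq_len(config$n_envs) - 1L, function(i)
    place_cell_ensemble(arena, config$n_place, environment_id = i))
  novel <- place_cell_ensemble(arena, config$n_place,
                               environment_id = "novel")

  say("training (", config$total_minibatches, " minibatches)")
  model0 <- init_pathint_model(config$n_place, config$n_units,
                               seed = stage_seed(config$seed, 2L))
  tc <- train_config(lambda = config$lambda, lr = config$lr,
                     batch = config$batch,
                     total_minibatches = config$total_minibatches)
  fit <- train_pathint(model0, envs, tc, arena, motion,
                       seed = stage_seed(config$seed, 3L),
                       novel_environment = novel, verbose = verbose)
  model <- fit$model

  say("ratemaps and spatial metrics")
  rmaps <- lapply(seq_along(envs), function(i)
    unit_ratemaps(model, envs[[i]], config$ratemap_trajectories,
                  config$ratemap_bins,
                  t_slice = seq.int(motion$n_steps %/% 2 + 1L,
                                    motion$n_steps),
                  arena, motion, seed = stage_seed(config$seed, 10L + i)))
  scores <- unit_grid_scores(rmaps)

  say("clustering and torus ensemble")
  tor <- identify_torus_ensemble(rmaps)

  say("topology")
  stack <- vapply(seq_len(dim(rmaps[[1]])[3]), function(u)
    as.vector(rmaps[[1]][, , u]), numeric(config$ratemap_bins^2))
  use <- if (length(tor$ensemble) >= 6) tor$ensemble
         else select_top_grid(scores, min(64L, nrow(scores)))
  cloud <- pca_project(stack[, use, drop = FALSE], 6L)
  fd <- fuzzy_downsample(cloud, k = config$fuzzy_k,
                         n_keep = config$downsample_keep)
  pd <- rips_persistence(fd$points, n_landmarks = config$n_landmarks)
  verdict <- detect_torus(pd)

  say("pruning")
  n_sel <- min(64L, config$n_units)
  top_grid <- select_top_grid(scores, n_sel)
  plan <- pruning_plan(step = config$pruning_step,
                       max_units = config$pruning_max,
                       repeats = config$pruning_repeats)
  set.seed(stage_seed(config$seed, 20L))
  curves <- rbind(
    pruning_curve(model, envs, seq_len(config$n_units), plan, arena,
                  motion, strategy = "random"),
    pruning_curve(model, envs, top_grid, plan, arena, motion,
                  strategy = "top_grid"),
    if (length(tor$ensemble) >= plan$step)
      pruning_curve(model, envs, tor$ensemble, plan, arena, motion,
                    strategy = "torus_ensemble"))

  final <- fit$decode_log[fit$decode_log$step == max(fit$decode_log$step), ]
  summary <- list(
    preset = config$preset,
    final_kl = mean(final$kl[final$environment != "novel"]),
    final_decode_error = mean(final$error[final$environment != "novel"]),
    novel_decode_error = final$error[final$environment == "novel"],
    baseline_decode_error = baseline_decoding_error(envs[[1]], 500L),
    n_torus_ensemble = length(tor$ensemble),
    n_clusters = length(unique(tor$labels[tor$labels > 0])),
    torus_detected = verdict$is_torus,
    betti = verdict$betti,
    max_grid_score = max(scores[is.finite(scores)]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(fit$log, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "pruning_curves.csv"),
                     row.names = FALSE)
  }
  list(summary = summary, model = model, fit = fit, ensembles = envs,
       torus = tor, pruning = curves, diagram = pd, scores = scores)
}

#' Smoke test: training strain with many environments
#'
#' Trains reduced models in increasing numbers of environments at matched
#' total gradient steps and reports the final evaluation KL per model:
#' with more environments the shared capacity is strained and the final KL
#' is expected to be no better (qualitatively nondecreasing).
#'
#' @param env_counts Environment counts to compare. Default `c(1, 3)`.
#' @param n_units,n_place Model size. Defaults 128 / 32.
#' @param total_minibatches Gradient steps per model. Default 300.
#' @param seed Base seed.
#' @return `data.frame` with `n_envs`, `final_kl`, `final_error`.
#' @export
many_env_smoke <- function(env_counts = c(1L, 3L), n_units = 128L,
                           n_place = 32L, total_minibatches = 300L,
                           seed = 0L) {
  arena <- arena_spec()
  motion <- motion_params()
  out <- lapply(env_counts, function(ne) {
    set.seed(stage_seed(seed, 30L + ne))
    envs <- lapply(seq_len(ne) - 1L, function(i)
      place_cell_ensemble(arena, n_place, environment_id = i))
    m0 <- init_pathint_model(n_place, n_units,
                             seed = stage_seed(seed, 40L + ne))
    fit <- train_pathint(m0, envs,
                         train_config(total_minibatches = total_minibatches,
                                      log_every = total_minibatches),
                         arena, motion, seed = stage_seed(seed, 50L + ne))
    fin <- fit$decode_log[fit$decode_log$step == max(fit$decode_log$step), ]
    data.frame(n_envs = ne, final_kl = mean(fin$kl),
               final_error = mean(fin$error))
  })
  do.call(rbind, out)
}
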