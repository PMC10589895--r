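#' Initialise a path-integration network
#'
#' The network is a single-layer recurrent model with four bias-free weight
#' matrices: a linear encoder `We` mapping the initial place-cell activity to
#' the initial recurrent state, a recurrent matrix `Wg`, a velocity input
#' matrix `Wv`, and a linear decoder `Wd` whose output is passed through a
#' softmax to predict place-cell activity. All matrices use Xavier uniform
#' initialisation with unity gain: entries iid uniform on
#' `[-sqrt(6/(fan_in + fan_out)), +sqrt(6/(fan_in + fan_out))]`.
#'
#' @param n_place Number of place cells Np.
#' @param n_units Number of recurrent units Ng.
#' @param seed Optional integer seed.
#' @return An object of class `pathint_model`: list with `We` (Ng x Np),
#'   `Wg` (Ng x Ng), `Wv` (Ng x 2), `Wd` (Np x Ng).
#' @export
init_pathint_model <- function(n_place, n_units, seed = NULL) {
  stopifnot(n_place >= 1, n_units >= 1)
  if (!is.null(seed)) set.seed(seed)
  xavier <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  structure(list(We = xavier(n_units, n_place),
                 Wg = xavier(n_units, n_units),
                 Wv = xavier(n_units, 2),
                 Wd = xavier(n_place, n_units),
                 n_units = as.integer(n_units),
                 n_place = as.integer(n_place)),
            class = "pathint_model")
}

#' @export
print.pathint_model <- function(x, ...) {
  cat(sprintf("pathint_model: %d recurrent units, %d place cells\n",
              x$n_units, x$n_place))
  invisible(x)
}

#' Run the network along trajectories
#'
#' The initial state is the linear encoding `g0 = We p0` (no rectification);
#' each step applies `g_t = ReLU(Wg g_{t-1} + Wv v_t)` and decodes
#' `p_hat_t = softmax(Wd g_t)`.
#'
#' @param model A `pathint_model`.
#' @param p0 B x Np matrix of initial place-cell activities (rows =
#'   trajectories).
#' @param velocities B x T x 2 array of Cartesian velocities.
#' @param return_states If `TRUE` (default) include the recurrent states.
#' @return List with `p_hat` (Np x B x T array of predicted distributions),
#'   `g0` (Ng x B), and optionally `g` (Ng x B x T).
#' @export
rnn_forward <- function(model, p0, velocities, return_states = TRUE) {
  stopifnot(inherits(model, "pathint_model"),
            ncol(p0) == model$n_place,
            dim(velocities)[1] == nrow(p0), dim(velocities)[3] == 2)
  cpp_rnn_forward(model$We, model$Wg, model$Wv, model$Wd, t(p0),
                  velocities, return_states)
}

#' Path-integration training loss
#'
#' Time-averaged cross-entropy between target and predicted place-cell
#' activity, averaged over the batch, plus an added L2 penalty
#' `lambda * ||Wg||_F^2` on the recurrent weights. Predictions are clamped
#' at `eps` before the logarithm.
#'
#' @param p_hat Np x B x T array of predicted distributions.
#' @param labels Np x B x T array of target distributions.
#' @param Wg Recurrent weight matrix.
#' @param lambda L2 penalty weight. Default 1e-4.
#' @param eps Clamp for predicted probabilities. Default 1e-12.
#' @return Scalar loss.
#' @export
pathint_loss <- function(p_hat, labels, Wg, lambda = 1e-4, eps = 1e-12) {
  stopifnot(all(dim(p_hat) == dim(labels)))
  B <- dim(p_hat)[2]; T <- dim(p_hat)[3]
  ce <- -sum(labels * log(pmax(p_hat, eps))) / (B * T)
  ce + lambda * sum(Wg^2)
}

#' Kullback-Leibler divergence between label and predicted activity
#'
#' `sum p * log(p / p_hat)`, averaged over batch and time. Nonnegative and
#' zero iff the distributions agree; unlike the cross-entropy its optimum
#' does not depend on the entropy of the labels, which makes it the training
#' convergence monitor.
#'
#' @param labels,p_hat Matching arrays (Np vectors, Np x B matrices or
#'   Np x B x T arrays) of probability vectors along the first dimension.
#' @param eps Clamp for both arguments inside the log. Default 1e-12.
#' @return Scalar mean KL divergence (nats).
#' @export
kl_divergence <- function(labels, p_hat, eps = 1e-12) {
  stopifnot(all(dim(labels) == dim(p_hat)) ||
              length(labels) == length(p_hat))
  n_dist <- length(labels) / ifelse(is.null(dim(labels)), length(labels),
                                    dim(labels)[1])
  kl <- sum(labels * (log(pmax(labels, eps)) - log(pmax(p_hat, eps))))
  kl / n_dist
}

#' Training configuration
#'
#' @param lambda L2 penalty weight. Default 1e-4.
#' @param lr Adam learning rate. Default 1e-4.
#' @param batch Minibatch size (trajectories). Default 200.
#' @param minibatches_per_env Minibatches per environment; total steps are
#'   `minibatches_per_env * n_envs`. Default 2000 (a desk-scale setting; the
#'   full-scale regime uses 1e5).
#' @param total_minibatches Optional override of the total step count.
#' @param schedule `"multi_env"` (each minibatch mixes all environments
#'   equally) or `"continual"` (environments presented in sequential
#'   blocks).
#' @param log_every Metric logging cadence (steps). Default 100.
#' @param eval_batch Trajectories per environment for logged decoding
#'   error. Default 100.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lambda = 1e-4, lr = 1e-4, batch = 200L,
                         minibatches_per_env = 2000L,
                         total_minibatches = NULL,
                         schedule = c("multi_env", "continual"),
                         log_every = 100L, eval_batch = 100L) {
  schedule <- match.arg(schedule)
  stopifnot(lambda >= 0, lr > 0, batch >= 1, minibatches_per_env >= 1)
  structure(list(lambda = lambda, lr = lr, batch = as.integer(batch),
                 minibatches_per_env = as.integer(minibatches_per_env),
                 total_minibatches = total_minibatches,
                 schedule = schedule, log_every = as.integer(log_every),
                 eval_batch = as.integer(eval_batch)),
            class = "train_config")
}

## Build one minibatch: trajectories + place-cell encodings.
## envs: list of place_ensemble; sizes: trajectories drawn per environment.
make_minibatch <- function(envs, sizes, arena, motion) {
  keep <- sizes > 0
  parts <- lapply(which(keep), function(e) {
    b <- simulate_trajectories(sizes[e], arena, motion)
    p0 <- encode_position(b$x0, envs[[e]])
    lab <- encode_position(flatten_positions(b), envs[[e]])
    list(v = b$velocities, p0 = p0, lab = lab, n = sizes[e])
  })
  T <- dim(parts[[1]]$v)[2]
  np <- ncol(parts[[1]]$p0)
  v <- do.call(abind3, lapply(parts, `[[`, "v"))
  p0 <- do.call(rbind, lapply(parts, `[[`, "p0"))
  B <- nrow(p0)
  # reassemble labels: each part is (n_e * T) x Np, trajectory-fastest
  lab <- array(NA_real_, c(np, B, T))
  off <- 0L
  for (pt in parts) {
    lab_part <- array(t(pt$lab), c(np, pt$n, T))
    lab[, off + seq_len(pt$n), ] <- lab_part
    off <- off + pt$n
  }
  list(p0 = p0, v = v, labels = lab)
}

## bind 3d arrays along the first dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], integer(1)))
  out <- array(NA_real_, c(n, d[2], d[3]))
  off <- 0L
  for (x in xs) {
    out[off + seq_len(dim(x)[1]), , ] <- x
    off <- off + dim(x)[1]
  }
  out
}

#' Decoding error of the network along trajectories
#'
#' Runs the network on a trajectory batch and, at each timestep, decodes
#' both the prediction and the label through the top-3 center-of-mass
#' readout, returning the mean Euclidean distance between the two decoded
#' positions ("predicted vs estimated true position").
#'
#' @param model A `pathint_model`.
#' @param batch A `trajectory_batch`.
#' @param ensemble The `place_ensemble` of the batch's environment.
#' @param timesteps Which timesteps to evaluate (default all).
#' @return Numeric vector of mean errors, one per evaluated timestep.
#' @export
decoding_error <- function(model, batch, ensemble, timesteps = NULL) {
  p0 <- encode_position(batch$x0, ensemble)
  fw <- rnn_forward(model, p0, batch$velocities, return_states = FALSE)
  T <- dim(fw$p_hat)[3]
  if (is.null(timesteps)) timesteps <- seq_len(T)
  vapply(timesteps, function(t) {
    lab <- encode_position(batch$positions[, t, ], ensemble)
    xh <- decode_position(t(fw$p_hat[, , t]), ensemble)
    xt <- decode_position(lab, ensemble)
    mean(sqrt(rowSums((xh - xt)^2)))
  }, numeric(1))
}

#' Train the network to path integrate across environments
#'
#' Minimises the cross-entropy + L2 objective with Adam. Under the
#' `multi_env` schedule every minibatch contains an equal share of
#' trajectories from each environment; under `continual` each environment's
#' minibatches are exhausted before the next environment is presented.
#' Training metrics (minibatch KL divergence, recurrent L2, per-environment
#' decoding error at the final timestep) are logged every `log_every` steps.
#'
#' @param model A `pathint_model`.
#' @param environments List of `place_ensemble` objects (>= 1).
#' @param config A [train_config()].
#' @param arena,motion Trajectory settings.
#' @param seed Optional integer seed governing all training randomness.
#' @param novel_environment Optional held-out `place_ensemble` whose
#'   decoding error is logged alongside the familiar ones.
#' @param verbose Print progress every log interval.
#' @return List with `model` (trained), `log` (data.frame: step, minibatch
#'   kl, l2, loss), `decode_log` (data.frame: step, environment, decoding
#'   error at the final timestep and evaluation KL on a fixed batch), and
#'   `config`.
#' @export
train_pathint <- function(model, environments, config = train_config(),
                          arena = arena_spec(), motion = motion_params(),
                          seed = NULL, novel_environment = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "pathint_model"), length(environments) >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_env <- length(environments)
  total <- if (!is.null(config$total_minibatches))
    as.integer(config$total_minibatches)
  else config$minibatches_per_env * n_env

  params <- model[c("We", "Wg", "Wv", "Wd")]
  adam <- list()
  for (nm in names(params)) {
    adam[[paste0("m", nm)]] <- params[[nm]] * 0
    adam[[paste0("v", nm)]] <- params[[nm]] * 0
  }

  # per-environment share of each multi_env minibatch (remainder rotates)
  base <- config$batch %/% n_env
  rem <- config$batch %% n_env
  eval_envs <- c(environments,
                 if (!is.null(novel_environment)) list(novel_environment))
  eval_names <- c(paste0("env", seq_len(n_env) - 1L),
                  if (!is.null(novel_environment)) "novel")
  eval_batches <- lapply(seq_along(eval_envs), function(i)
    simulate_trajectories(config$eval_batch, arena, motion))
  # cached per-environment evaluation labels (Np x B x T)
  eval_labels <- lapply(seq_along(eval_envs), function(i) {
    b <- eval_batches[[i]]
    lab <- encode_position(flatten_positions(b), eval_envs[[i]])
    array(t(lab), c(ncol(lab), nrow(b$x0), motion$n_steps))
  })

  log_rows <- list()
  decode_rows <- list()
  block <- max(1L, ceiling(total / n_env))  # continual block length
  for (step in seq_len(total)) {
    if (config$schedule == "multi_env") {
      sizes <- rep(base, n_env)
      if (rem > 0) {
        extra <- ((step - 1L + seq_len(rem) - 1L) %% n_env) + 1L
        sizes[extra] <- sizes[extra] + 1L
      }
      mb <- make_minibatch(environments, sizes, arena, motion)
    } else {
      env_now <- min(n_env, (step - 1L) %/% block + 1L)
      sizes <- integer(n_env)
      sizes[env_now] <- config$batch
      mb <- make_minibatch(environments, sizes, arena, motion)
    }
    res <- cpp_train_step(params, adam, t(mb$p0), mb$v, mb$labels,
                          config$lr, config$lambda, step)
    params <- res$params
    adam <- res$adam
    if (step %% config$log_every == 0L || step == 1L || step == total) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = step, kl = res$kl, l2 = res$l2, loss = res$loss)
      mtmp <- model
      mtmp[c("We", "Wg", "Wv", "Wd")] <- params
      T_eval <- motion$n_steps
      for (i in seq_along(eval_envs)) {
        b <- eval_batches[[i]]
        p0_ev <- encode_position(b$x0, eval_envs[[i]])
        fw <- rnn_forward(mtmp, p0_ev, b$velocities, return_states = FALSE)
        lab_T <- t(eval_labels[[i]][, , T_eval])
        xh <- decode_position(t(fw$p_hat[, , T_eval]), eval_envs[[i]])
        xt <- decode_position(lab_T, eval_envs[[i]])
        err <- mean(sqrt(rowSums((xh - xt)^2)))
        kl_ev <- kl_divergence(eval_labels[[i]], fw$p_hat)
        decode_rows[[length(decode_rows) + 1L]] <-
          data.frame(step = step, environment = eval_names[i], error = err,
                     kl = kl_ev)
      }
      if (verbose)
        message(sprintf("step %d/%d  kl = %.4f  l2 = %.2f", step, total,
                        res$kl, res$l2))
    }
  }
  model[c("We", "Wg", "Wv", "Wd")] <- params
  list(model = model, log = do.call(rbind, log_rows),
       decode_log = do.call(rbind, decode_rows), config = config)
}
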