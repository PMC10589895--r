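test_that("Xavier initialisation respects bounds, moments, determinism", {
  m1 <- init_pathint_model(64, 256, seed = 1)
  m2 <- init_pathint_model(64, 256, seed = 1)
  expect_identical(m1$Wg, m2$Wg)
  lim <- sqrt(6 / (256 + 256))
  expect_true(all(abs(m1$Wg) <= lim))
  big <- init_pathint_model(512, 4096, seed = 2)
  v_emp <- var(as.vector(big$We))
  expect_lt(abs(v_emp - 2 / (512 + 4096)) / (2 / (512 + 4096)), 0.05)
})

test_that("forward pass matches a hand-rolled recurrence", {
  set.seed(3)
  Np <- 4; Ng <- 6; B <- 3; T <- 5
  model <- init_pathint_model(Np, Ng, seed = 4)
  p0 <- matrix(runif(B * Np), B)
  p0 <- p0 / rowSums(p0)
  v <- array(rnorm(B * T * 2), c(B, T, 2))
  fw <- rnn_forward(model, p0, v)
  softmax <- function(u) { e <- exp(u - max(u)); e / sum(e) }
  for (b in 1:B) {
    g <- model$We %*% p0[b, ]
    expect_equal(as.vector(g), fw$g0[, b], tolerance = 1e-12)
    for (t in 1:T) {
      g <- pmax(model$Wg %*% g + model$Wv %*% v[b, t, ], 0)
      expect_equal(as.vector(g), fw$g[, b, t], tolerance = 1e-12)
      expect_equal(as.vector(softmax(model$Wd %*% g)), fw$p_hat[, b, t],
                   tolerance = 1e-12)
    }
  }
  # predictions are probability vectors at every step
  expect_lt(max(abs(apply(fw$p_hat, c(2, 3), sum) - 1)), 1e-9)
})

test_that("zero weights yield uniform predictions; rectification silences", {
  model <- init_pathint_model(5, 8, seed = 5)
  model$We[] <- 0; model$Wg[] <- 0; model$Wv[] <- 0; model$Wd[] <- 0
  p0 <- matrix(rep(0.2, 5), 1)
  v <- array(rnorm(6), c(1, 3, 2))
  fw <- rnn_forward(model, p0, v)
  expect_equal(as.vector(fw$p_hat), rep(0.2, 15), tolerance = 1e-12)
  # a unit with all-negative incoming weights and nonnegative inputs stays 0
  m2 <- init_pathint_model(5, 8, seed = 6)
  m2$Wg[3, ] <- -abs(m2$Wg[3, ])
  m2$Wv[3, ] <- -abs(m2$Wv[3, ])
  m2$We <- abs(m2$We)
  m2$Wg[-3, ] <- abs(m2$Wg[-3, ])
  m2$Wv[-3, ] <- abs(m2$Wv[-3, ])
  v_pos <- array(abs(rnorm(10)), c(1, 5, 2))
  fw2 <- rnn_forward(m2, p0, v_pos)
  expect_true(all(fw2$g[3, 1, ] == 0))
})

test_that("loss and KL match hand computations", {
  Np <- 4; B <- 1; T <- 2
  unif <- array(1 / Np, c(Np, B, T))
  Wg <- matrix(rnorm(9), 3, 3)
  expect_equal(pathint_loss(unif, unif, Wg, lambda = 0), log(Np))
  expect_equal(pathint_loss(unif, unif, Wg, lambda = 1e-4),
               log(Np) + 1e-4 * sum(Wg^2))
  expect_equal(pathint_loss(unif, unif, 2 * Wg, lambda = 1) - log(Np),
               4 * (pathint_loss(unif, unif, Wg, lambda = 1) - log(Np)))
  # 2-cell 2-step hand example
  p <- array(c(0.3, 0.7, 0.6, 0.4), c(2, 1, 2))
  ph <- array(c(0.5, 0.5, 0.2, 0.8), c(2, 1, 2))
  ce_hand <- -(0.3 * log(0.5) + 0.7 * log(0.5) +
                 0.6 * log(0.2) + 0.4 * log(0.8)) / 2
  expect_equal(pathint_loss(ph, p, Wg * 0), ce_hand)
  expect_equal(kl_divergence(p, p), 0)
  kl_hand <- (0.3 * log(0.3 / 0.5) + 0.7 * log(0.7 / 0.5) +
                0.6 * log(0.6 / 0.2) + 0.4 * log(0.4 / 0.8)) / 2
  expect_equal(kl_divergence(p, ph), kl_hand)
  # KL = cross-entropy - entropy
  ent <- -(0.3 * log(0.3) + 0.7 * log(0.7) +
             0.6 * log(0.6) + 0.4 * log(0.4)) / 2
  expect_equal(kl_divergence(p, ph), ce_hand - ent)
  # uniform labels vs near-one-hot predictions on 4 cells
  p4 <- array(0.25, c(4, 1, 1))
  ph4 <- array(c(0.97, 0.01, 0.01, 0.01), c(4, 1, 1))
  expect_equal(kl_divergence(p4, ph4),
               0.25 * (log(0.25 / 0.97) + 3 * log(0.25 / 0.01)))
})

test_that("analytic BPTT gradient matches finite differences", {
  set.seed(7)
  Np <- 3; Ng <- 4; B <- 2; T <- 3
  model <- init_pathint_model(Np, Ng, seed = 8)
  p0 <- matrix(runif(B * Np), B); p0 <- p0 / rowSums(p0)
  v <- array(rnorm(B * T * 2), c(B, T, 2))
  labels <- array(runif(Np * B * T), c(Np, B, T))
  for (t in 1:T) for (b in 1:B)
    labels[, b, t] <- labels[, b, t] / sum(labels[, b, t])
  lambda <- 1e-3
  loss_at <- function(m) {
    fw <- rnn_forward(m, p0, v, return_states = FALSE)
    pathint_loss(fw$p_hat, labels, m$Wg, lambda = lambda)
  }
  params <- model[c("We", "Wg", "Wv", "Wd")]
  adam <- list()
  for (nm in names(params)) {
    adam[[paste0("m", nm)]] <- params[[nm]] * 0
    adam[[paste0("v", nm)]] <- params[[nm]] * 0
  }
  res <- gridtorus:::cpp_train_step(params, adam, t(p0), v, labels,
                                    lr = 0, lambda = lambda, step = 1)
  expect_equal(res$loss, loss_at(model), tolerance = 1e-10)
  eps <- 1e-6
  for (nm in c("We", "Wg", "Wv", "Wd")) {
    g_ana <- res$adam[[paste0("m", nm)]] / 0.1  # m / (1 - beta1) at step 1
    idx <- sample(length(g_ana), min(12, length(g_ana)))
    for (i in idx) {
      mp <- model; mp[[nm]][i] <- mp[[nm]][i] + eps
      mm <- model; mm[[nm]][i] <- mm[[nm]][i] - eps
      expect_equal(g_ana[i], (loss_at(mp) - loss_at(mm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("decoding error has the right shape and chance behaviour", {
  arena <- arena_spec()
  s1 <- desk_place_width(64)
  ens <- place_cell_ensemble(arena, 64, s1 = s1, seed = 11)
  b <- simulate_trajectories(100, seed = 12)
  un <- init_pathint_model(64, 64, seed = 13)
  err <- decoding_error(un, b, ens)
  expect_length(err, 20)
  expect_true(all(is.finite(err)) && all(err >= 0))
  # untrained error at late timesteps is near the uniform-prediction level
  unif_model <- un
  unif_model$We[] <- 0; unif_model$Wg[] <- 0
  unif_model$Wv[] <- 0; unif_model$Wd[] <- 0
  err_unif <- decoding_error(unif_model, b, ens, timesteps = 20)
  expect_lt(abs(decoding_error(un, b, ens, timesteps = 20) - err_unif) /
              err_unif, 0.5)
})

test_that("training schedules split minibatches as configured", {
  cfg <- train_config(batch = 10, total_minibatches = 4, log_every = 4,
                      eval_batch = 5)
  s1 <- desk_place_width(16)
  envs <- lapply(0:2, function(i)
    place_cell_ensemble(n_cells = 16, s1 = s1, seed = 20 + i))
  m0 <- init_pathint_model(16, 12, seed = 21)
  fit <- train_pathint(m0, envs, cfg, seed = 22)
  expect_s3_class(fit$log, "data.frame")
  expect_true(all(is.finite(fit$log$kl)))
  expect_true(all(c("step", "environment", "error", "kl") %in%
                    names(fit$decode_log)))
  # continual schedule runs too and produces finite metrics
  cfg2 <- train_config(batch = 10, total_minibatches = 6, log_every = 6,
                       eval_batch = 5, schedule = "continual")
  fit2 <- train_pathint(m0, envs, cfg2, seed = 23)
  expect_true(all(is.finite(fit2$log$loss)))
})
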