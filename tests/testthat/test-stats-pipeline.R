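test_that("overlap tail probabilities are exact", {
  # (10, 3, 3, 0): (1 - 0.3)^3 by hand
  r <- overlap_tail_probability(10, 3, 3, 0)
  expect_equal(r$p_binomial, 0.7^3)
  # full support
  expect_equal(overlap_tail_probability(50, 7, 9, 7)$p_binomial, 1)
  expect_error(overlap_tail_probability(10, 3, 3, 5), "min")
  expect_error(overlap_tail_probability(10, 12, 3, 1))
})

test_that("the Binomial tail matches Monte-Carlo overlap simulation", {
  set.seed(1)
  cases <- list(c(200, 40, 60, 8), c(500, 100, 100, 15),
                c(100, 30, 20, 5), c(1000, 150, 300, 40),
                c(64, 10, 25, 2))
  for (cs in cases) {
    n_total <- cs[1]; n_a <- cs[2]; n_b <- cs[3]; x <- cs[4]
    exact <- overlap_tail_probability(n_total, n_a, n_b, x)$p_binomial
    draws <- rbinom(20000, n_a, n_b / n_total)
    mc <- mean(draws <= x)
    se <- sqrt(mc * (1 - mc) / 20000)
    expect_lt(abs(exact - mc), 3 * max(se, 1e-4))
  }
  # hypergeometric sensitivity value is also a probability
  r <- overlap_tail_probability(200, 40, 60, 8)
  expect_true(r$p_hypergeometric >= 0 && r$p_hypergeometric <= 1)
})

test_that("experiment configurations validate and override", {
  cfg <- experiment_config("desk")
  expect_equal(cfg$n_units, 256L)
  cfg2 <- experiment_config("desk", n_units = 32L, seed = 5L)
  expect_equal(cfg2$n_units, 32L)
  expect_equal(cfg2$seed, 5L)
  paper <- experiment_config("paper")
  expect_equal(paper$n_units, 4096L)
  expect_equal(paper$n_place, 512L)
  # stage seeds stay within 32-bit integer range
  for (s in c(0L, 1L, 999L)) {
    expect_lt(gridtorus:::stage_seed(s, 50L), 2^31)
  }
})

test_that("unit ratemaps align network activity with positions", {
  s1 <- desk_place_width(16)
  ens <- place_cell_ensemble(n_cells = 16, s1 = s1, seed = 30)
  model <- init_pathint_model(16, 12, seed = 31)
  rm <- unit_ratemaps(model, ens, n_trajectories = 200, n_bins = 8,
                      seed = 32)
  expect_equal(dim(rm), c(8, 8, 12))
  # spot-check one unit against a manual forward pass
  set.seed(32)
  b <- simulate_trajectories(200)
  p0 <- encode_position(b$x0, ens)
  fw <- rnn_forward(model, p0, b$velocities)
  act <- gridtorus:::flatten_activity(fw$g)
  pos <- flatten_positions(b)
  manual <- compute_ratemap(act[, 7], pos, n_bins = 8)
  expect_equal(rm[, , 7], manual, ignore_attr = TRUE)
})

test_that("the end-to-end pipeline runs and reproduces its summary", {
  cfg <- experiment_config("desk", n_units = 48L, n_place = 16L,
                           n_envs = 2L, total_minibatches = 60L,
                           batch = 40L, ratemap_bins = 16L,
                           ratemap_trajectories = 150L, n_landmarks = 80L,
                           downsample_keep = 230L, fuzzy_k = 50L,
                           pruning_repeats = 2L, pruning_step = 10L,
                           pruning_max = 20L, seed = 3L)
  out_dir <- tempfile("run")
  res <- run_experiment(cfg, out_dir = out_dir)
  expect_true(all(c("final_kl", "final_decode_error", "novel_decode_error",
                    "baseline_decode_error", "n_torus_ensemble",
                    "n_clusters", "torus_detected", "betti",
                    "max_grid_score") %in% names(res$summary)))
  expect_true(is.finite(res$summary$final_kl))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir, "training_log.csv")))
  expect_s3_class(res$pruning, "data.frame")
  expect_true(all(res$pruning$median >= 0))
  # rerun with the same config reproduces the headline numbers
  res2 <- run_experiment(cfg)
  expect_equal(res2$summary$final_kl, res$summary$final_kl)
  expect_equal(res2$summary$final_decode_error,
               res$summary$final_decode_error)
  expect_identical(res2$summary$betti, res$summary$betti)
})

test_that("the many-environment smoke comparison returns matched logs", {
  sm <- many_env_smoke(env_counts = c(1L, 3L), n_units = 64L,
                       n_place = 16L, total_minibatches = 120L, seed = 1L)
  expect_equal(sm$n_envs, c(1L, 3L))
  expect_true(all(is.finite(sm$final_kl)))
  expect_true(all(sm$final_kl > 0))
  expect_true(all(is.finite(sm$final_error)))
})

test_that("grid scores are computed for every unit and environment", {
  m <- grid_module(2, seed = 33)
  rms <- module_ratemaps(m, n_bins = 32)
  scores <- unit_grid_scores(list(rms, rms))
  expect_equal(dim(scores), c(2, 2))
  expect_equal(scores[, 1], scores[, 2])
  expect_true(all(scores[, 1] > 1))
})
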