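# Desk-scale trained model, built once per test session and reused by the
# training / pruning acceptance tests. 256 recurrent units, 64 place cells
# (tuning width scaled as 0.12 * sqrt(512 / 64) to keep the cell density
# within a tuning radius comparable to the full-scale code), 3 familiar
# environments plus one held-out novel environment, 2000 Adam minibatches.
.desk_cache <- new.env(parent = emptyenv())

desk_place_width <- function(n_place) 0.12 * sqrt(512 / n_place)

get_desk_fit <- function() {
  if (!is.null(.desk_cache$fit)) return(.desk_cache$fit)
  arena <- arena_spec()
  motion <- motion_params()
  s1 <- desk_place_width(64)
  envs <- lapply(0:2, function(i)
    place_cell_ensemble(arena, 64, s1 = s1, seed = 100 + i,
                        environment_id = i))
  novel <- place_cell_ensemble(arena, 64, s1 = s1, seed = 999,
                               environment_id = "novel")
  model0 <- init_pathint_model(64, 256, seed = 1)
  fit <- train_pathint(model0, envs,
                       train_config(total_minibatches = 2000,
                                    log_every = 200),
                       arena, motion, seed = 2,
                       novel_environment = novel)
  out <- list(fit = fit, model0 = model0, envs = envs, novel = novel,
              arena = arena, motion = motion)
  .desk_cache$fit <- out
  out
}
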