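# Shared fixture builders: everything is generated in code at test time.

fixture_models <- function() {
  dplyr::bind_rows(
    biosensor_model("bs_strong", "strong"),
    biosensor_model("bs_middle", "middle"),
    biosensor_model("bs_weak", "weak")
  )
}

fixture_conditions <- function(stim_time = 30, gamma = 0) {
  condition_table(
    condition_spec("vehicle", NULL, stim_time),
    condition_spec("egf", c(EGF = 100), stim_time),
    condition_spec("igf", c(IGF1 = 100), stim_time),
    condition_spec("egf_igf", c(EGF = 100, IGF1 = 100), stim_time,
                   interaction_gamma = gamma)
  )
}

# Render a small noiseless (or noisy) stack with known ground truth.
fixture_stack <- function(n_cells = 5, n_frames = 10, noise_sd = 0,
                          seed = 11, width = 192, height = 192,
                          amplitude = 0.3, baseline_ratio = 1.2,
                          stim_frame = 3, jitter_sd = 0) {
  cam <- camera_params(width = width, height = height, noise_sd = noise_sd)
  time_grid <- seq(0, by = 3, length.out = n_frames)
  model <- biosensor_model("bs", "strong", amplitude = amplitude,
                           baseline_ratio = baseline_ratio)
  cond <- condition_spec("egf", c(EGF = 100),
                         stimulation_time = time_grid[stim_frame])
  withr::with_seed(seed, {
    cells <- place_cells(n_cells, cam)
    cells$e0 <- 2000 * stats::rlnorm(n_cells, 0, 0.2)
    cells$baseline_ratio <- baseline_ratio
    activity <- fretarray:::simulate_activity_matrix(
      model, cond, n_cells, time_grid,
      cell_noise_params(amplitude_cv = 0.2))
    frames <- render_frames(cells, activity, time_grid, cam,
                            jitter_sd = jitter_sd)
    list(frames = frames, cells = cells, activity = activity,
         time_grid = time_grid, model = model, cond = cond,
         positions = attr(frames, "positions"))
  })
}

# One full interaction trial: simulate the four arms, normalize, AUC, test.
interaction_trial <- function(gamma, n_cells, seed,
                              time_grid = seq(0, 120, 5),
                              stim_time = 30) {
  model <- biosensor_model("bs", "strong")
  conds <- fixture_conditions(stim_time, gamma)
  traj <- simulate_trajectory_experiment(model, conds, n_cells = n_cells,
                                         time_grid = time_grid, seed = seed)
  traj_b <- normalize_baseline(traj, stim_time)
  veh <- condition_mean_sem(
    dplyr::filter(traj_b, condition_id == "vehicle"))
  resp <- synergy_normalize(
    dplyr::filter(traj, condition_id != "vehicle"),
    dplyr::select(veh, -"condition_id"), stim_time)
  aucs <- compute_aucs(resp, stim_time)
  pairs <- derive_pairs(conds)
  a <- dplyr::filter(aucs, condition_id == "egf")
  b <- dplyr::filter(aucs, condition_id == "igf")
  obs <- dplyr::filter(aucs, condition_id == "egf_igf")$auc
  exp_add <- expected_additive(mean(a$auc), sd(a$auc) / sqrt(nrow(a)),
                               mean(b$auc), sd(b$auc) / sqrt(nrow(b)))
  synergy_test(obs, exp_add$mean_expected, exp_add$sem_expected,
               arm_sems = c(sd(a$auc) / sqrt(nrow(a)),
                            sd(b$auc) / sqrt(nrow(b))),
               arm_ns = c(nrow(a), nrow(b)))
}

# Six well-separated planted trajectory patterns on a fixed grid.
planted_patterns <- function(n_time = 30) {
  t <- seq(0, 1, length.out = n_time)
  rbind(
    flat      = rep(0, n_time),
    sustained = 0.4 * (1 - exp(-t * 8)),
    transient = 0.5 * exp(-((t - 0.25) / 0.12)^2),
    late      = 0.4 * pmax(t - 0.5, 0) * 2,
    pulsatile = 0.25 * (1 + sin(2 * pi * t * 3)) / 2,
    inhibited = -0.3 * (1 - exp(-t * 8))
  )
}

# Sample cells from planted patterns with given mixture weights.
sample_pattern_cells <- function(weights, n_cells, noise_sd = 0.02,
                                 seed = 1) {
  pats <- planted_patterns()
  withr::with_seed(seed, {
    cl <- sample(nrow(pats), n_cells, replace = TRUE, prob = weights)
    x <- pats[cl, , drop = FALSE] +
      matrix(rnorm(n_cells * ncol(pats), 0, noise_sd), n_cells)
    rownames(x) <- sprintf("cell_%04d", seq_len(n_cells))
    list(matrix = x, truth = cl)
  })
}
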