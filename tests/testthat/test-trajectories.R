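traj_tbl <- function(values, times = seq_along(values) - 1,
                     cell = "c1", biosensor = "b", condition = "x") {
  tibble::tibble(cell_id = cell, biosensor_id = biosensor,
                 condition_id = condition, replicate_id = 1,
                 time_min = times, ratio = values)
}

test_that("baseline normalization divides by the pre-stimulus mean", {
  tr <- traj_tbl(c(2, 2, 3), times = c(0, 1, 2))
  out <- normalize_baseline(tr, stimulation_time = 2)
  expect_equal(out$ratio, c(1, 1, 1.5))
  # property: pre-stimulus mean of output is 1 for random traces
  set.seed(7)
  for (i in 1:10) {
    v <- runif(20, 0.5, 2)
    out <- normalize_baseline(traj_tbl(v, times = 0:19), 8)
    expect_equal(mean(out$ratio[out$time_min < 8]), 1)
  }
  expect_error(normalize_baseline(traj_tbl(c(1, 2, 3), times = 0:2), 1),
               "at least 2 pre-stimulus")
})

test_that("vehicle normalization cancels shared drift exactly", {
  times <- 0:10
  drift <- 1 + 0.1 * times
  treated <- dplyr::bind_rows(traj_tbl(drift, times, cell = "t1"),
                              traj_tbl(drift, times, cell = "t2"))
  vehicle <- dplyr::bind_rows(
    traj_tbl(drift, times, cell = "v1", condition = "vehicle"),
    traj_tbl(drift, times, cell = "v2", condition = "vehicle"))
  veh_summary <- condition_mean_sem(vehicle) |>
    dplyr::select(-condition_id)
  out <- normalize_vehicle(treated, veh_summary)
  expect_equal(out$ratio, rep(1, 22))
  # missing time point errors
  expect_error(
    normalize_vehicle(traj_tbl(1:3, times = c(0, 1, 99)), veh_summary),
    "cover all time points")
})

test_that("vehicle-drift cancellation recovers the true response", {
  model <- biosensor_model("bs", "strong")
  conds <- fixture_conditions(stim_time = 30)
  traj <- simulate_trajectory_experiment(
    model, conds, n_cells = 150, time_grid = seq(0, 120, 5), seed = 5,
    cell_noise = cell_noise_params(sigma = 0.01,
                                   ratio_drift_per_min = 0.002))
  traj <- normalize_baseline(traj, 30)
  veh <- condition_mean_sem(dplyr::filter(traj, condition_id == "vehicle"))
  out <- normalize_vehicle(dplyr::filter(traj, condition_id == "egf"),
                           dplyr::select(veh, -condition_id))
  summary <- condition_mean_sem(out)
  truth <- 1 + fretarray:::response_profile(
    model, dplyr::filter(conds, condition_id == "egf"), summary$time_min)
  expect_lt(max(abs(summary$mean - truth)), 0.02)
})

test_that("max normalization scales the peak to one and keeps the argmax", {
  s <- tibble::tibble(biosensor_id = "b", condition_id = "x",
                      time_min = 0:2, mean = c(1, 1.2, 1.5),
                      sem = c(0.1, 0.1, 0.1))
  out <- normalize_max(s)
  expect_equal(out$mean, c(1 / 1.5, 1.2 / 1.5, 1), tolerance = 1e-12)
  expect_equal(which.max(out$mean), which.max(s$mean))
  expect_equal(normalize_max(out)$mean, out$mean) # idempotent
  expect_error(normalize_max(dplyr::mutate(s, mean = -mean)), "positive")
})

test_that("condition mean and SEM pool cells correctly", {
  two <- dplyr::bind_rows(traj_tbl(c(1, 1), 0:1, cell = "c1"),
                          traj_tbl(c(1, 3), 0:1, cell = "c2"))
  s <- condition_mean_sem(two)
  expect_equal(s$mean, c(1, 2))
  expect_equal(s$sem, c(0, 1)) # sd(1,3)/sqrt(2) = 1
  expect_equal(s$n_cells, c(2L, 2L))
  # oracle: direct sd/sqrt(n) on random data
  set.seed(11)
  cells <- purrr::map(1:8, function(i) {
    traj_tbl(rnorm(5, 2, 0.3), 0:4, cell = paste0("c", i))
  })
  s2 <- condition_mean_sem(dplyr::bind_rows(cells))
  vals <- sapply(cells, function(df) df$ratio)
  expect_equal(s2$sem, apply(vals, 1, sd) / sqrt(8))
  # mismatched grids error
  expect_error(condition_mean_sem(dplyr::bind_rows(
    traj_tbl(1:3, 0:2, cell = "a"), traj_tbl(1:3, c(0, 2, 4), cell = "b"))),
    "different time grids")
})

test_that("replicate CV matches hand arithmetic and injected noise", {
  reps <- tibble::tibble(replicate_id = rep(1:2, each = 2),
                         time_min = rep(0:1, 2),
                         mean = c(2, 2, 4, 2))
  cv <- replicate_cv(reps)
  expect_equal(cv$cv_trace$cv_pct, c(100 * sqrt(2) / 3, 0))
  expect_equal(cv$cv_trace$cv_pct[1], 47.14, tolerance = 1e-3)
  # identical replicates: CV identically zero
  same <- dplyr::mutate(reps, mean = rep(c(2, 3), 2))
  expect_equal(replicate_cv(same)$average_cv_pct, 0)
  # CV is scale invariant
  expect_equal(replicate_cv(dplyr::mutate(reps, mean = mean * 7)),
               replicate_cv(reps))
  # 5% multiplicative replicate noise gives ~5% average CV
  set.seed(13)
  base <- runif(40, 0.8, 1.6)
  noisy <- purrr::map_dfr(1:12, function(r) {
    tibble::tibble(replicate_id = r, time_min = seq_along(base),
                   mean = base * rnorm(length(base), 1, 0.05))
  })
  expect_equal(replicate_cv(noisy)$average_cv_pct, 5, tolerance = 0.15)
})

test_that("expression-response correlation follows Kendall tau", {
  mk <- function(expr, resp) {
    purrr::imap_dfr(expr, function(e, i) {
      tibble::tibble(cell_id = paste0("c", i), time_min = c(0, 1, 10),
                     mean_cfp = e, ratio = c(1, 1, resp[i]))
    })
  }
  perfect <- expression_response_correlation(mk(1:6, 2 + (1:6) / 10), 5)
  expect_equal(perfect$tau, 1)
  inverted <- expression_response_correlation(mk(1:6, 2 - (1:6) / 10), 5)
  expect_equal(inverted$tau, -1)
  # tau equals explicit O(n^2) pair counting on random data
  set.seed(17)
  e <- runif(8); r <- 2 + runif(8)
  got <- expression_response_correlation(mk(e, r), 5)
  expect_equal(got$tau, oracle_kendall(e, r), tolerance = 1e-12)
  expect_error(expression_response_correlation(mk(1:2, c(2, 3)), 5),
               "at least 3")
})

test_that("baseline and vehicle normalization commute on shared grids", {
  times <- 0:9
  set.seed(19)
  veh_cells <- purrr::map_dfr(1:5, function(i) {
    traj_tbl(runif(10, 0.9, 1.4), times, cell = paste0("v", i),
             condition = "vehicle")
  })
  treated <- purrr::map_dfr(1:5, function(i) {
    traj_tbl(runif(10, 0.9, 1.8), times, cell = paste0("t", i))
  })
  veh_baselined <- condition_mean_sem(normalize_baseline(veh_cells, 4))
  a <- normalize_vehicle(normalize_baseline(treated, 4),
                         dplyr::select(veh_baselined, -condition_id))
  b <- normalize_baseline(
    normalize_vehicle(treated, dplyr::select(veh_baselined,
                                             -condition_id)), 4)
  # same cells, same grid: the two orders agree up to each cell's constant
  # pre-stimulus factor, which baseline normalization re-fixes to 1
  expect_equal(dplyr::arrange(b, cell_id, time_min)$ratio,
               dplyr::arrange(
                 normalize_baseline(a, 4), cell_id, time_min)$ratio,
               tolerance = 1e-12)
})
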