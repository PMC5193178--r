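test_that("interaction normalization centers traces at zero", {
  mk <- function(vals, cell = "c1") {
    tibble::tibble(cell_id = cell, biosensor_id = "b", condition_id = "x",
                   time_min = seq_along(vals) - 1, ratio = vals)
  }
  flat_untreated <- tibble::tibble(biosensor_id = "b", time_min = 0:2,
                                   mean = 1)
  out <- synergy_normalize(mk(c(2, 2, 4)), flat_untreated, 2)
  expect_equal(out$response, c(0, 0, 1))
  # a trace identical to the untreated mean maps to zero
  unt <- tibble::tibble(biosensor_id = "b", time_min = 0:2,
                        mean = c(1, 1, 1.3))
  out2 <- synergy_normalize(mk(c(2, 2, 2.6)), unt, 2)
  expect_equal(out2$response, c(0, 0, 0))
})

test_that("noiseless synthetic responses recover a(t) exactly", {
  model <- biosensor_model("bs", "strong")
  conds <- fixture_conditions(stim_time = 30)
  traj <- simulate_trajectory_experiment(
    model, conds, n_cells = 3, time_grid = seq(0, 90, 5), seed = 3,
    cell_noise = cell_noise_params(sigma = 0))
  veh <- condition_mean_sem(
    normalize_baseline(dplyr::filter(traj, condition_id == "vehicle"), 30))
  out <- synergy_normalize(dplyr::filter(traj, condition_id == "egf"),
                           dplyr::select(veh, -condition_id), 30)
  expect_equal(out$response, out$activity_true, tolerance = 1e-12)
})

test_that("trapezoidal AUC matches hand values and a refined-grid oracle", {
  expect_equal(trace_auc(c(0, 1, 1, 0), 0:3), 2)
  expect_equal(trace_auc(rep(0, 5), 0:4), 0)
  expect_error(trace_auc(1, 1), "at least 2")
  # negative excursions subtract
  expect_equal(trace_auc(c(0, -1, -1, 0), 0:3), -2)
  # integration starts at the stimulation time
  expect_equal(trace_auc(c(9, 9, 0, 1, 1, 0), c(-2, -1, 0:3), 0), 2)
  # smooth curve: coarse trapezoid approaches a fine Riemann sum
  f <- function(t) 0.4 * (1 - exp(-t / 8)) * exp(-t / 60)
  coarse <- trace_auc(f(seq(0, 120, 5)), seq(0, 120, 5))
  fine_grid <- seq(0, 120, 0.01)
  fine <- sum(f(fine_grid[-1] - 0.005) * 0.01)
  expect_equal(coarse, fine, tolerance = 0.01)
})

test_that("normality check reports W and flags gross violations", {
  set.seed(47)
  normal <- rnorm(10)
  nc <- normality_check(normal)
  expect_lte(nc$W, 1)
  expect_gt(nc$W, 0.9)
  bimodal <- c(rnorm(25, -10, 0.5), rnorm(25, 10, 0.5))
  expect_lt(normality_check(bimodal)$p_value, 0.01)
  expect_error(normality_check(c(1, 2)), "3 <= n")
})

test_that("additive expectation propagates SEMs by the variance formula", {
  e <- expected_additive(2.0, 0.3, 1.0, 0.4)
  expect_equal(e$mean_expected, 3.0)
  expect_equal(e$sem_expected, 0.5)
  expect_equal(expected_additive(5, 0, 7, 0),
               tibble::tibble(mean_expected = 12, sem_expected = 0))
  # symmetric in its arguments
  expect_equal(expected_additive(1, 0.2, 4, 0.7),
               expected_additive(4, 0.7, 1, 0.2))
})

test_that("the interaction test behaves at the null and under shifts", {
  set.seed(53)
  obs <- rnorm(50, 3, 1)
  t0 <- synergy_test(obs, mean(obs), 0.1)
  expect_equal(t0$ss_raw, 0)
  expect_equal(t0$t_stat, 0)
  expect_equal(t0$p, 1)
  # +5 combined-SE shift is decisively significant
  sem_exp <- 0.1
  se <- sqrt((sd(obs) / sqrt(50))^2 + sem_exp^2)
  t5 <- synergy_test(obs, mean(obs) - 5 * se, sem_exp)
  expect_lt(t5$p, 0.001)
  expect_equal(sign(t5$ss_raw), sign(t5$t_stat))
  # matches the t tail for known df
  expect_equal(t5$p, 2 * pt(-abs(t5$t_stat), t5$df))
  # zero combined SE with a difference
  expect_warning(tz <- synergy_test(c(2, 2, 2), 1, 0), "zero combined")
  expect_equal(tz$p, 0)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  set.seed(59)
  p <- runif(20)
  expect_true(all(adjust_pvalues(p) >= p))
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(p * 20, 1))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("scaling maps scores to [-1, 1] and masks insignificant entries", {
  res <- tibble::tibble(biosensor_id = c("a", "a", "b"),
                        ss_raw = c(0.2, -0.4, 0),
                        p_adj = c(0.01, 0.06, 0.2))
  out <- scale_and_mask(res, alpha = 0.05)
  expect_equal(out$ss_scaled, c(0.5, -1, 0))
  expect_equal(out$masked, c(FALSE, TRUE, TRUE))
  # per-biosensor: at least one scaled value hits +-1 when nonzero
  set.seed(61)
  many <- tibble::tibble(biosensor_id = rep(c("x", "y"), each = 5),
                         ss_raw = rnorm(10), p_adj = runif(10))
  sc <- scale_and_mask(many)
  maxima <- tapply(abs(sc$ss_scaled), sc$biosensor_id, max)
  expect_equal(as.numeric(maxima), c(1, 1))
  expect_true(all(sc$ss_scaled >= -1 & sc$ss_scaled <= 1))
})

test_that("scaled scores are invariant to rescaling a biosensor's AUCs", {
  set.seed(67)
  aucs <- tidyr::expand_grid(biosensor_id = "b",
                             condition_id = c("egf", "igf", "egf_igf"),
                             i = 1:30) |>
    dplyr::mutate(cell_id = paste0(condition_id, "_", i),
                  auc = rnorm(90, rep(c(2, 1, 3.2), each = 30), 0.5)) |>
    dplyr::select(-i)
  pairs <- tibble::tibble(pair_id = "pair", condition_a = "egf",
                          condition_b = "igf", condition_ab = "egf_igf")
  s1 <- synergy_scores(aucs, pairs)
  s2 <- synergy_scores(dplyr::mutate(aucs, auc = auc * 3.7), pairs)
  expect_equal(s2$ss_scaled, s1$ss_scaled, tolerance = 1e-9)
  expect_equal(s2$p, s1$p, tolerance = 1e-9)
})

test_that("synergy maps cluster structure and preserve the values", {
  set.seed(71)
  mk_res <- function(bios, pair, ss) {
    tibble::tibble(biosensor_id = bios, pair_id = pair, ss_raw = ss,
                   ss_scaled = ss, p_adj = 0.01, masked = FALSE)
  }
  # planted two-block structure
  res <- tidyr::expand_grid(biosensor_id = sprintf("b%02d", 1:8),
                            pair_id = sprintf("p%d", 1:4)) |>
    dplyr::mutate(
      block = ifelse(biosensor_id <= "b04", 1, -1),
      ss_raw = block * 0.8 + rnorm(32, 0, 0.05),
      ss_scaled = pmax(pmin(ss_raw, 1), -1),
      p_adj = 0.01, masked = FALSE)
  map <- synergy_map(res)
  expect_setequal(as.vector(map$matrix), res$ss_scaled)
  cut2 <- cutree(map$row_hclust, 2)
  expect_equal(ari(cut2, ifelse(sort(unique(res$biosensor_id)) <= "b04",
                                1, 2)), 1)
  # identical rows merge at height 0 and sit adjacent
  res2 <- dplyr::bind_rows(mk_res("a", c("p1", "p2"), c(1, 0)),
                           mk_res("b", c("p1", "p2"), c(1, 0)),
                           mk_res("c", c("p1", "p2"), c(-1, 0.4)))
  map2 <- synergy_map(res2)
  expect_equal(map2$row_hclust$height[1], 0)
  expect_equal(abs(diff(match(c("a", "b"), map2$row_order))), 1)
  # single row: identity ordering, no tree
  map3 <- synergy_map(mk_res("a", c("p1", "p2"), c(1, -0.5)))
  expect_equal(map3$row_order, "a")
  expect_null(map3$row_hclust)
})

test_that("full synergy analysis recovers injected interaction signs", {
  up <- interaction_trial(gamma = 0.6, n_cells = 120, seed = 73)
  expect_gt(up$ss_raw, 0)
  expect_lt(up$p, 0.05)
  down <- interaction_trial(gamma = -0.6, n_cells = 120, seed = 74)
  expect_lt(down$ss_raw, 0)
  expect_lt(down$p, 0.05)
  none <- interaction_trial(gamma = 0, n_cells = 120, seed = 75)
  expect_gt(none$p, 0.001) # no systematic false positive
})
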