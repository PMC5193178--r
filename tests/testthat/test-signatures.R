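test_that("identical fingerprint rows merge first at height zero", {
  mat <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  fc <- cluster_fingerprints(mat, k = 2)
  expect_equal(fc$hclust$height[1], 0)
  expect_equal(fc$labels[["a"]], fc$labels[["b"]])
  expect_false(fc$labels[["a"]] == fc$labels[["c"]])
  # Ward merge heights are non-decreasing
  expect_true(all(diff(fc$hclust$height) >= 0))
})

test_that("response classes separate into pure clusters at low noise", {
  set.seed(23)
  grid <- seq(0, 120, 5)
  mk_class <- function(model, n) {
    cond <- condition_spec("egf", c(EGF = 100), 30)
    profile <- fretarray:::response_profile(model, cond, grid)
    t(replicate(n, 1 + profile + rnorm(length(grid), 0, 0.01)))
  }
  models <- fixture_models()
  mat <- rbind(mk_class(models[1, ], 6), mk_class(models[2, ], 6),
               mk_class(models[3, ], 6))
  rownames(mat) <- sprintf("r%02d", 1:18)
  truth <- rep(1:3, each = 6)
  fc <- cluster_fingerprints(mat, k = 3)
  expect_equal(ari(fc$labels, truth), 1)
  expect_true(all(diff(fc$hclust$height) >= 0))
  expect_error(cluster_fingerprints(rbind(c(1, NA), c(2, 3))), "NaN|NA")
})

test_that("k-means with k = 1 returns the pointwise mean trajectory", {
  set.seed(29)
  x <- matrix(rnorm(50 * 10), 50, 10)
  rownames(x) <- sprintf("c%02d", 1:50)
  km <- kmeans_patterns(x, k = 1, seed = 1, n_restarts = 3)
  expect_equal(as.vector(km$centroids), colMeans(x), tolerance = 1e-12)
})

test_that("two planted patterns are recovered exactly", {
  sim <- sample_pattern_cells(c(0.5, 0.5, 0, 0, 0, 0), 200, seed = 31)
  km <- kmeans_patterns(sim$matrix, k = 2, seed = 2)
  expect_equal(ari(km$labels, sim$truth), 1)
  # objective beats an arbitrary labeling
  rand_lab <- rep(1:2, 100)
  wss_rand <- sum(sapply(1:2, function(cl) {
    xs <- sim$matrix[rand_lab == cl, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }))
  expect_lte(km$tot_withinss, wss_rand)
})

test_that("k-means is deterministic and invariant to row order", {
  sim <- sample_pattern_cells(rep(1 / 6, 6), 120, seed = 37)
  km1 <- kmeans_patterns(sim$matrix, k = 3, seed = 5)
  km2 <- kmeans_patterns(sim$matrix, k = 3, seed = 5)
  expect_identical(km1$labels, km2$labels)
  perm <- withr::with_seed(1, sample(nrow(sim$matrix)))
  km3 <- kmeans_patterns(sim$matrix[perm, ], k = 3, seed = 5)
  expect_equal(ari(km3$labels[rownames(sim$matrix)], km1$labels), 1)
  expect_error(kmeans_patterns(sim$matrix[1:2, ], k = 3), "fewer")
})

test_that("long-format trajectories are interpolated before clustering", {
  sim <- sample_pattern_cells(c(1, 1, 0, 0, 0, 0) / 2, 60, seed = 41)
  colnames(sim$matrix) <- sprintf("t%02d", seq_len(ncol(sim$matrix)))
  long <- tibble::as_tibble(sim$matrix, rownames = "cell_id") |>
    tidyr::pivot_longer(-cell_id, names_to = "col", values_to = "ratio") |>
    dplyr::group_by(cell_id) |>
    dplyr::mutate(time_min = 3 * (dplyr::row_number() - 1)) |>
    dplyr::ungroup()
  km <- kmeans_patterns(long, k = 2, seed = 3)
  expect_equal(ari(km$labels[rownames(sim$matrix)], sim$truth), 1)
})

test_that("cluster proportions count correctly and sum to one", {
  labels <- c(a = 1L, b = 1L, c = 2L, d = 3L)
  assign <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                           condition_id = "x")
  pr <- cluster_proportions(labels, assign, k = 3)
  expect_equal(pr$proportion, c(0.5, 0.25, 0.25))
  # all cells in one cluster
  pr1 <- cluster_proportions(c(a = 1L, b = 1L),
                             tibble::tibble(cell_id = c("a", "b"),
                                            condition_id = "y"), k = 4)
  expect_equal(pr1$proportion, c(1, 0, 0, 0))
  # random labelings always sum to 1 per condition
  set.seed(43)
  for (i in 1:5) {
    n <- 30
    lab <- sample(4, n, replace = TRUE)
    names(lab) <- sprintf("c%02d", 1:n)
    asg <- tibble::tibble(cell_id = names(lab),
                          condition_id = sample(c("p", "q"), n, TRUE))
    pr <- cluster_proportions(lab, asg, k = 4)
    sums <- dplyr::summarise(dplyr::group_by(pr, condition_id),
                             s = sum(proportion))
    expect_equal(sums$s, rep(1, nrow(sums)))
  }
})

test_that("fingerprint matrices have unit row maxima when max-normalized", {
  s <- tidyr::expand_grid(biosensor_id = c("a", "b"),
                          condition_id = "x", time_min = 0:4) |>
    dplyr::mutate(mean = runif(10, 0.5, 2), sem = 0.1)
  mat <- build_fingerprint_matrix(s)
  expect_equal(unname(apply(mat, 1, max)), c(1, 1))
})
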