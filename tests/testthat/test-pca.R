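make_summaries <- function(n_groups, n_time, n_bios, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(group_id = sprintf("g%02d", seq_len(n_groups)),
                       biosensor_id = sprintf("b%02d", seq_len(n_bios)),
                       time_min = seq_len(n_time)) |>
      dplyr::mutate(mean = runif(dplyr::n(), 0.8, 1.6))
  })
}

test_that("condition matrix assembly yields groups x time rows", {
  s <- make_summaries(4, 85, 14)
  mat <- build_condition_matrix(s)
  expect_equal(dim(mat), c(340, 14))
  expect_equal(nrow(attr(mat, "row_info")), 340)
  tiny <- build_condition_matrix(make_summaries(1, 1, 3))
  expect_equal(dim(tiny), c(1, 3))
  for (g in c(2, 3)) {
    for (tp in c(4, 7)) {
      expect_equal(nrow(build_condition_matrix(make_summaries(g, tp, 2))),
                   g * tp)
    }
  }
  # a missing (group, biosensor) pair is reported by name
  gap <- dplyr::filter(s, !(group_id == "g02" & biosensor_id == "b03"))
  expect_error(build_condition_matrix(gap), "g02/b03")
  expect_error(build_condition_matrix(dplyr::select(s, -mean)),
               "missing column")
})

test_that("PCA is centered, scaled, and reconstructs the data", {
  s <- make_summaries(3, 20, 5, seed = 2)
  mat <- build_condition_matrix(s)
  emb <- fret_pca(mat)
  expect_equal(sum(emb$explained), 1, tolerance = 1e-9)
  scores <- as.matrix(emb$scores[, paste0("PC", 1:5)])
  expect_equal(colMeans(scores), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  loadings <- as.matrix(emb$loadings[, paste0("PC", 1:5)])
  standardized <- scale(mat)
  expect_equal(scores %*% t(loadings), unclass(standardized),
               tolerance = 1e-9, ignore_attr = TRUE)
  # deterministic sign: largest-|loading| entry positive per PC
  for (j in 1:5) {
    expect_gt(loadings[which.max(abs(loadings[, j])), j], 0)
  }
})

test_that("collinear data load entirely on PC1", {
  x <- cbind(a = 1:20, b = 2 * (1:20) + 3)
  emb <- fret_pca(x)
  expect_equal(emb$explained[1], 1, tolerance = 1e-12)
})

test_that("PCA standardization is idempotent and names bad columns", {
  mat <- build_condition_matrix(make_summaries(2, 10, 4, seed = 3))
  emb_raw <- fret_pca(mat)
  emb_std <- fret_pca(scale(mat))
  expect_equal(as.matrix(emb_std$scores[, paste0("PC", 1:4)]),
               as.matrix(emb_raw$scores[, paste0("PC", 1:4)]),
               tolerance = 1e-9)
  bad <- cbind(mat, flatliner = 1)
  expect_error(fret_pca(bad), "flatliner")
})

test_that("planted group separation appears in the PC1 sign", {
  set.seed(5)
  s <- make_summaries(2, 30, 6)
  s <- dplyr::mutate(s, mean = mean + ifelse(group_id == "g01", 0.8, 0))
  emb <- fret_pca(build_condition_matrix(s))
  pc1 <- split(emb$scores$PC1, emb$scores$group_id)
  expect_true(all(sign(pc1$g01) != sign(pc1$g02)))
})

test_that("coverage ellipses reach the requested empirical coverage", {
  set.seed(7)
  pts <- matrix(rnorm(400), 200, 2)
  el <- coverage_ellipse(pts, 0.7)
  expect_gte(el$achieved_coverage, 0.7)
  expect_lte(el$achieved_coverage, 0.7 + 1 / 200 + 1e-12)
  # fraction 1 covers everything
  el1 <- coverage_ellipse(pts, 1)
  expect_equal(el1$achieved_coverage, 1)
  # rotating the cloud rotates the ellipse by the same angle
  ang <- pi / 6
  rot <- cbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
  el_rot <- coverage_ellipse(pts %*% t(rot), 0.7)
  d <- (el_rot$angle_rad - el$angle_rad - ang) %% pi
  expect_true(min(d, pi - d) < 0.15)
  expect_equal(el_rot$axes, el$axes, tolerance = 1e-6)
  # degenerate cloud falls back with warning
  expect_warning(coverage_ellipse(cbind(1:5, 2 * (1:5)), 0.7),
                 "degenerate")
  expect_error(coverage_ellipse(pts[1:2, ], 0.7), "at least 3")
})
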