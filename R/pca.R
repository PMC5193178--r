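#' Assemble the condition-level PCA input matrix
#'
#' Stacks normalized mean response traces group-by-group over time points:
#' each row is one (group, time point), each column one biosensor. Four
#' groups of 85 time points over 14 biosensors give a 340 x 14 matrix.
#'
#' @param summaries Tibble with `group_id`, `biosensor_id`, `time_min`,
#'   `mean`; every (group, biosensor) pair must be present on an identical
#'   time grid.
#' @return A numeric matrix with attributes `row_info` (tibble `group_id`,
#'   `time_min`) and column names = biosensor ids.
#' @export
build_condition_matrix <- function(summaries) {
  need <- c("group_id", "biosensor_id", "time_min", "mean")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  full <- tidyr::expand_grid(
    group_id = unique(summaries$group_id),
    biosensor_id = unique(summaries$biosensor_id)
  )
  have <- dplyr::distinct(summaries, .data$group_id, .data$biosensor_id)
  gaps <- dplyr::anti_join(full, have, by = c("group_id", "biosensor_id"))
  if (nrow(gaps) > 0) {
    stop("missing (group, biosensor) summaries: ",
         paste(paste(gaps$group_id, gaps$biosensor_id, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  wide <- summaries |>
    dplyr::select("group_id", "time_min", "biosensor_id", "mean") |>
    tidyr::pivot_wider(names_from = "biosensor_id", values_from = "mean") |>
    dplyr::arrange(.data$group_id, .data$time_min)
  if (anyNA(wide)) {
    stop("(group, biosensor) summaries are not on identical time grids",
         call. = FALSE)
  }
  mat <- as.matrix(wide[, -(1:2)])
  attr(mat, "row_info") <- dplyr::select(wide, "group_id", "time_min")
  mat
}

#' Centered and scaled PCA of a condition matrix
#'
#' Standardizes each column (biosensor) to mean 0 and unit variance and
#' performs PCA by singular value decomposition, with a deterministic sign
#' convention: in each component, the loading of largest magnitude is
#' positive.
#'
#' @param mat Matrix from [build_condition_matrix()] (or any numeric matrix
#'   with >= 2 rows).
#' @return An object of class `fret_pca`: `scores` (tibble with row info
#'   and `PC1..PCk`), `loadings` (tibble), `explained` (variance
#'   fractions), and the underlying `prcomp` fit.
#' @export
fret_pca <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  row_info <- attr(mat, "row_info") %||%
    tibble::tibble(row = seq_len(nrow(mat)))
  scores <- dplyr::bind_cols(row_info, tibble::as_tibble(fit$x))
  loadings <- tibble::as_tibble(fit$rotation, rownames = "biosensor_id")
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, fit = fit),
            class = "fret_pca")
}

#' @export
print.fret_pca <- function(x, ...) {
  cat("PCA of condition-level responses:", nrow(x$scores), "rows x",
      nrow(x$loadings), "biosensors\n")
  cat("Variance explained (first PCs):",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$explained, 4)),
             collapse = ", "), "\n")
  invisible(x)
}

#' Empirical coverage ellipse of a score cloud
#'
#' Gaussian-fit ellipse (mean and covariance of the points) scaled to the
#' smallest Mahalanobis radius whose empirical coverage reaches the target
#' fraction of points — the "oval containing 70% of time points" style of
#' group outline on PCA score plots.
#'
#' @param scores Two-column matrix or data frame of PC coordinates of one
#'   group (>= 3 points).
#' @param fraction Target coverage fraction in (0, 1].
#' @return A list: `center`, `axes` (half-axis lengths), `angle_rad`,
#'   `radius` (Mahalanobis), `achieved_coverage`, and `path` (tibble of the
#'   ellipse outline for plotting).
#' @export
coverage_ellipse <- function(scores, fraction = 0.7) {
  x <- as.matrix(scores)[, 1:2, drop = FALSE]
  storage.mode(x) <- "double"
  if (nrow(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]",
                                          call. = FALSE)
  ctr <- colMeans(x)
  S <- stats::cov(x)
  if (!all(is.finite(S)) || det(S) <= 1e-12 * prod(diag(S) + 1e-30)) {
    warning("degenerate covariance; using axis-aligned bounding ellipse",
            call. = FALSE)
    half <- pmax((apply(x, 2, max) - apply(x, 2, min)) / 2, 1e-12)
    S <- diag(half^2)
  }
  d2 <- stats::mahalanobis(x, ctr, S)
  d2s <- sort(d2)
  k <- ceiling(fraction * nrow(x))
  r2 <- d2s[k]
  eg <- eigen(S, symmetric = TRUE)
  axes <- sqrt(pmax(eg$values, 0) * r2)
  angle <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  theta <- seq(0, 2 * pi, length.out = 181)
  rot <- cbind(c(cos(angle), sin(angle)), c(-sin(angle), cos(angle)))
  pts <- t(rot %*% rbind(axes[1] * cos(theta), axes[2] * sin(theta))) +
    matrix(ctr, 181, 2, byrow = TRUE)
  list(center = ctr, axes = axes, angle_rad = angle, radius = sqrt(r2),
       achieved_coverage = mean(d2 <= r2 + 1e-12),
       path = tibble::tibble(x = pts[, 1], y = pts[, 2]))
}

#' @export
tidy.fret_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") x$scores else x$loadings
}

#' @export
glance.fret_pca <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$scores),
    n_biosensors = nrow(x$loadings),
    pc1_var = x$explained[1],
    pc2_var = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}

#' Score plot with group coverage ellipses
#'
#' @param object A `fret_pca` object.
#' @param fraction Coverage fraction for the group ellipses; `NULL` for no
#'   ellipses.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fret_pca <- function(object, fraction = 0.7, ...) {
  scores <- object$scores
  has_group <- "group_id" %in% names(scores)
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
  if (has_group) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group_id),
                                 size = 0.8)
    if (!is.null(fraction)) {
      paths <- scores |>
        dplyr::group_by(.data$group_id) |>
        dplyr::group_modify(function(df, key) {
          coverage_ellipse(df[, c("PC1", "PC2")], fraction)$path
        }) |>
        dplyr::ungroup()
      p <- p + ggplot2::geom_path(
        data = paths,
        ggplot2::aes(.data$x, .data$y, colour = .data$group_id)
      )
    }
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  p
}
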