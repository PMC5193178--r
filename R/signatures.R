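#' Build a response fingerprint matrix
#'
#' Assembles normalized mean responses into a biosensor x time matrix — the
#' "fingerprint" used to compare response kinetics across biosensors.
#'
#' @param summaries Output of [condition_mean_sem()] (one condition).
#' @param max_normalize Scale each row to peak 1 (see [normalize_max()]).
#' @return A numeric matrix, rows named by `biosensor_id`, columns by time.
#' @export
build_fingerprint_matrix <- function(summaries, max_normalize = TRUE) {
  if (max_normalize) summaries <- normalize_max(summaries)
  wide <- summaries |>
    dplyr::select("biosensor_id", "time_min", "mean") |>
    tidyr::pivot_wider(names_from = "time_min", values_from = "mean")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$biosensor_id
  if (anyNA(mat)) stop("fingerprint matrix has missing cells", call. = FALSE)
  mat
}

#' Hierarchical clustering of response fingerprints
#'
#' Agglomerative clustering with the Euclidean metric and Ward's linkage
#' (the `ward.D2` criterion); cutting the tree at `k = 3` separates strong,
#' middle and weak responders on fingerprint matrices.
#'
#' @param mat Numeric matrix (rows are clustered).
#' @param k Number of flat clusters to cut.
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Linkage method for [stats::hclust()].
#' @return A list of class `fingerprint_clustering`: `hclust`, `order`
#'   (row order), `labels` (named cluster assignment at `k`), `k`.
#' @export
cluster_fingerprints <- function(mat, k = 3, metric = "euclidean",
                                 linkage = "ward.D2") {
  if (anyNA(mat)) stop("matrix has NaN/NA cells; impute before clustering",
                       call. = FALSE)
  d <- stats::dist(mat, method = metric)
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = min(k, nrow(mat)))
  structure(list(hclust = hc, order = hc$order, labels = labels, k = k),
            class = "fingerprint_clustering")
}

# k-means++ seeding: spread initial centres proportional to squared
# distance from the nearest already-chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = p)
    centers[j + 1, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' K-means dynamic trajectory patterns
#'
#' Clusters pooled single-cell trajectories (all treatments of one
#' biosensor) into `k` representative dynamic patterns by squared-Euclidean
#' K-means, best of `n_restarts` k-means++ initializations. Trajectories
#' are linearly interpolated onto a common time grid first.
#'
#' @param trajectories Long tibble with `cell_id`, `time_min` and the value
#'   column, or a cells x time matrix.
#' @param k Number of patterns (default 6).
#' @param seed Integer seed (clustering is deterministic given it).
#' @param n_restarts Number of k-means++ restarts.
#' @param value_col Value column for the long-tibble input.
#' @param grid_length Length of the common interpolation grid (defaults to
#'   the median trajectory length).
#' @return A list of class `kmeans_patterns`: `centroids` (k x time
#'   matrix), `labels` (named by `cell_id`), `time_grid`, `tot_withinss`.
#' @export
kmeans_patterns <- function(trajectories, k = 6, seed = 1, n_restarts = 25,
                            value_col = "ratio", grid_length = NULL) {
  if (is.matrix(trajectories)) {
    x <- trajectories
    grid <- as.numeric(colnames(x) %||% seq_len(ncol(x)))
  } else {
    val <- rlang::sym(value_col)
    spans <- trajectories |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(lo = min(.data$time_min), hi = max(.data$time_min),
                       n = dplyr::n(), .groups = "drop")
    # common span: overlap of all trajectories
    lo <- max(spans$lo); hi <- min(spans$hi)
    if (hi <= lo) stop("trajectories have no common time span",
                       call. = FALSE)
    grid <- seq(lo, hi,
                length.out = grid_length %||% round(stats::median(spans$n)))
    x <- trajectories |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::group_map(function(df, key) {
        stats::approx(df$time_min, dplyr::pull(df, !!val), xout = grid)$y
      }) |>
      do.call(what = rbind)
    rownames(x) <- sort(unique(trajectories$cell_id))
  }
  if (anyNA(x)) stop("trajectories contain missing values", call. = FALSE)
  if (nrow(x) < k) stop("fewer trajectories (", nrow(x), ") than clusters (",
                        k, ")", call. = FALSE)
  fit <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cen <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = cen, iter.max = 100, algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  labels <- fit$cluster
  names(labels) <- rownames(x)
  structure(list(centroids = fit$centers, labels = labels,
                 time_grid = grid, tot_withinss = fit$tot.withinss, k = k),
            class = "kmeans_patterns")
}

#' Cluster-proportion dynamic signatures
#'
#' Per condition, the fraction of its cells falling into each trajectory
#' cluster — a compact signature of the condition's dynamic repertoire.
#'
#' @param labels Named integer vector of cluster labels (names = cell ids),
#'   e.g. from [kmeans_patterns()].
#' @param assignment Tibble mapping `cell_id` to `condition_id` (extra
#'   columns such as `biosensor_id` are carried through).
#' @param k Number of clusters (defaults to `max(labels)`).
#' @return A tibble: grouping columns, `cluster`, `proportion`, `n_cells`;
#'   proportions sum to 1 within each condition.
#' @export
cluster_proportions <- function(labels, assignment, k = max(labels)) {
  stopifnot(!is.null(names(labels)))
  df <- assignment |>
    dplyr::distinct(dplyr::across(dplyr::everything())) |>
    dplyr::mutate(cluster = unname(labels[.data$cell_id]))
  if (anyNA(df$cluster)) stop("unlabeled cells in assignment",
                              call. = FALSE)
  groups <- setdiff(names(assignment), "cell_id")
  if (length(groups) == 0) stop("assignment needs a condition column",
                                call. = FALSE)
  sizes <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(groups)), name = "n_cells")
  if (any(sizes$n_cells == 0)) stop("empty condition", call. = FALSE)
  df |>
    dplyr::count(dplyr::across(dplyr::all_of(groups)), .data$cluster,
                 name = "n_in") |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(groups)),
                    cluster = seq_len(k), fill = list(n_in = 0L)) |>
    dplyr::left_join(sizes, by = groups) |>
    dplyr::mutate(proportion = .data$n_in / .data$n_cells) |>
    dplyr::select(dplyr::all_of(groups), "cluster", "proportion", "n_cells")
}
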