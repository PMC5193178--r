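#' Centered response normalization for interaction scoring
#'
#' Per cell: divide each time point by the cell's pre-stimulus mean and by
#' the untreated (vehicle) mean at that time point, then subtract 1. The
#' result is a centered response trace that is ~0 at rest and equals the
#' true fractional activity for noiseless data.
#'
#' @param trajectories Long tibble with `cell_id`, `biosensor_id`,
#'   `time_min` and the value column.
#' @param untreated_summary Per-biosensor mean trace of untreated cells on
#'   the same time grid (columns `biosensor_id`, `time_min`, `mean`),
#'   itself baseline-normalized.
#' @param stimulation_time Stimulus addition time, minutes.
#' @param value_col Value column (default `"ratio"`).
#' @return The input with a new `response` column.
#' @export
synergy_normalize <- function(trajectories, untreated_summary,
                              stimulation_time, value_col = "ratio") {
  val <- rlang::sym(value_col)
  base <- normalize_baseline(trajectories, stimulation_time, value_col)
  veh <- dplyr::select(untreated_summary, "biosensor_id", "time_min",
                       veh_mean = "mean")
  out <- dplyr::left_join(base, veh, by = c("biosensor_id", "time_min"))
  if (any(is.na(out$veh_mean))) {
    stop("untreated summary does not cover all time points", call. = FALSE)
  }
  if (any(out$veh_mean <= 0)) {
    stop("untreated mean must be positive", call. = FALSE)
  }
  out |>
    dplyr::mutate(response = !!val / .data$veh_mean - 1) |>
    dplyr::select(-"veh_mean")
}

#' Trapezoidal area under a response trace
#'
#' Signed trapezoidal integral of the centered response from the
#' stimulation time to the end of the trace; negative excursions subtract.
#'
#' @param values Response values.
#' @param times Times in minutes (strictly increasing).
#' @param stimulation_time Lower integration bound; `NULL` integrates the
#'   whole trace.
#' @return The area (dimensionless x minutes).
#' @export
trace_auc <- function(values, times, stimulation_time = NULL) {
  stopifnot(length(values) == length(times))
  if (!is.null(stimulation_time)) {
    keep <- times >= stimulation_time
    values <- values[keep]; times <- times[keep]
  }
  if (length(values) < 2) {
    stop("need at least 2 points after the stimulation time", call. = FALSE)
  }
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Per-cell AUCs of centered responses
#'
#' @param responses Output of [synergy_normalize()].
#' @param stimulation_time Stimulus addition time, minutes.
#' @return A tibble `cell_id`, `biosensor_id`, `condition_id`, `auc`.
#' @export
compute_aucs <- function(responses, stimulation_time) {
  responses |>
    dplyr::group_by(.data$cell_id, .data$biosensor_id,
                    .data$condition_id) |>
    dplyr::summarise(
      auc = trace_auc(.data$response, .data$time_min, stimulation_time),
      .groups = "drop"
    )
}

#' Shapiro-Wilk normality check of AUC samples
#'
#' The interaction test assumes approximately normal per-cell AUCs; this
#' check is reported, not used to abort the analysis.
#'
#' @param aucs Numeric vector, 3 <= n <= 5000.
#' @return A tibble `W`, `p_value`, `n`.
#' @export
normality_check <- function(aucs) {
  n <- sum(is.finite(aucs))
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(aucs[is.finite(aucs)])
  tibble::tibble(W = unname(sw$statistic), p_value = sw$p.value, n = n)
}

#' Additive expectation with propagated error
#'
#' Expected mean response of a combined stimulus under independence: the
#' sum of the single-stimulus means, with SEMs combined by the variance
#' formula `sqrt(sem_a^2 + sem_b^2)`.
#'
#' @param mean_a,sem_a,mean_b,sem_b Means and SEMs of the two
#'   single-stimulus AUC samples (vectorized).
#' @return A tibble `mean_expected`, `sem_expected`.
#' @export
expected_additive <- function(mean_a, sem_a, mean_b, sem_b) {
  stopifnot(all(sem_a >= 0), all(sem_b >= 0))
  tibble::tibble(mean_expected = mean_a + mean_b,
                 sem_expected = sqrt(sem_a^2 + sem_b^2))
}

#' Interaction test of observed versus additive AUC
#'
#' Welch-type test of the observed combined-stimulus AUC sample against the
#' additive expectation: `ss_raw = mean(observed) - mean_expected`,
#' `t = ss_raw / sqrt(sem_obs^2 + sem_expected^2)`, with
#' Welch-Satterthwaite degrees of freedom built from the contributing
#' samples' SEMs and sizes.
#'
#' @param observed Per-cell AUCs of the combined condition (n >= 2).
#' @param mean_expected,sem_expected From [expected_additive()].
#' @param arm_sems,arm_ns SEMs and sample sizes of the single-stimulus arms
#'   contributing to the expectation (used for the degrees of freedom);
#'   when omitted, df falls back to `length(observed) - 1`.
#' @return A tibble `ss_raw`, `t_stat`, `df`, `p`, `mean_observed`,
#'   `sem_observed`, `n_obs`.
#' @export
synergy_test <- function(observed, mean_expected, sem_expected,
                         arm_sems = NULL, arm_ns = NULL) {
  n <- length(observed)
  if (n < 2) stop("need at least 2 observed AUCs", call. = FALSE)
  m_obs <- mean(observed)
  sem_obs <- stats::sd(observed) / sqrt(n)
  ss_raw <- m_obs - mean_expected
  se2 <- sem_obs^2 + sem_expected^2
  sems <- c(sem_obs, arm_sems)
  ns <- c(n, arm_ns)
  if (length(sems) == length(ns) && length(ns) > 1) {
    denom <- sum(sems^4 / (ns - 1))
    df <- if (denom > 0) se2^2 / denom else Inf
  } else {
    df <- n - 1
  }
  if (se2 == 0) {
    if (ss_raw != 0) {
      warning("zero combined standard error with nonzero difference",
              call. = FALSE)
      t_stat <- sign(ss_raw) * Inf; p <- 0
    } else {
      t_stat <- 0; p <- 1
    }
  } else {
    t_stat <- ss_raw / sqrt(se2)
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  tibble::tibble(ss_raw = ss_raw, t_stat = t_stat, df = df, p = p,
                 mean_observed = m_obs, sem_observed = sem_obs, n_obs = n)
}

#' Multiple-testing correction
#'
#' @param p P values in `[0, 1]`.
#' @param method `"BH"` (Benjamini-Hochberg step-up, default), `"holm"` or
#'   `"bonferroni"`.
#' @return Adjusted p values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Scale interaction scores and mask insignificant ones
#'
#' Within each biosensor, divides the raw scores by the maximum absolute
#' raw score, giving values in `[-1, 1]` (+1 strongest synergy, -1
#' strongest antagonism); entries whose adjusted p value is at or above
#' `alpha` are flagged `masked`.
#'
#' @param results Tibble with `biosensor_id`, `ss_raw`, `p_adj`.
#' @param alpha Significance threshold (default 0.05).
#' @return The input with `ss_scaled` and `masked` columns.
#' @export
scale_and_mask <- function(results, alpha = 0.05) {
  results |>
    dplyr::group_by(.data$biosensor_id) |>
    dplyr::mutate(
      .max = max(abs(.data$ss_raw)),
      ss_scaled = dplyr::if_else(.data$.max > 0, .data$ss_raw / .data$.max,
                                 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(masked = .data$p_adj >= alpha) |>
    dplyr::select(-".max")
}

#' Derive stimulus pairs from a condition table
#'
#' Finds combined conditions (two stimuli) whose single-stimulus
#' counterparts (same stimulus and concentration) exist in the table.
#'
#' @param conditions A [condition_table()].
#' @return A tibble `pair_id`, `condition_a`, `condition_b`,
#'   `condition_ab`.
#' @export
derive_pairs <- function(conditions) {
  key <- function(s) paste(names(s), s, sep = "=", collapse = "+")
  singles <- conditions |>
    dplyr::filter(purrr::map_int(.data$stimuli, length) == 1)
  single_keys <- purrr::map_chr(singles$stimuli, key)
  combos <- conditions |>
    dplyr::filter(purrr::map_int(.data$stimuli, length) == 2)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    s <- combos$stimuli[[i]]
    ka <- key(s[1]); kb <- key(s[2])
    ia <- match(ka, single_keys); ib <- match(kb, single_keys)
    if (is.na(ia) || is.na(ib)) {
      warning("no single-stimulus arms for ", combos$condition_id[i],
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(pair_id = combos$condition_id[i],
                   condition_a = singles$condition_id[ia],
                   condition_b = singles$condition_id[ib],
                   condition_ab = combos$condition_id[i])
  })
}

#' Full interaction-score analysis
#'
#' Runs the whole chain on per-cell AUCs: per biosensor x pair, arm
#' summaries, Shapiro-Wilk check of the observed arm, additive expectation
#' with error propagation, Welch-type test, multiple-testing correction
#' over all biosensor x pair tests, per-biosensor scaling and significance
#' masking.
#'
#' @param aucs Tibble from [compute_aucs()].
#' @param pairs Tibble from [derive_pairs()] (or hand-built with the same
#'   columns).
#' @param alpha Mask threshold on adjusted p values.
#' @param adjust Correction method, see [adjust_pvalues()].
#' @return A tibble of class `synergy_result`, one row per biosensor x
#'   pair.
#' @export
synergy_scores <- function(aucs, pairs, alpha = 0.05, adjust = "BH") {
  arm_stats <- aucs |>
    dplyr::group_by(.data$biosensor_id, .data$condition_id) |>
    dplyr::summarise(mean = mean(.data$auc),
                     sem = stats::sd(.data$auc) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  rows <- tidyr::expand_grid(biosensor_id = unique(aucs$biosensor_id),
                             pairs)
  res <- purrr::pmap_dfr(rows, function(biosensor_id, pair_id, condition_a,
                                        condition_b, condition_ab) {
    get_arm <- function(cond) {
      a <- arm_stats[arm_stats$biosensor_id == biosensor_id &
                       arm_stats$condition_id == cond, ]
      if (nrow(a) != 1) stop("missing AUCs for ", biosensor_id, " / ",
                             cond, call. = FALSE)
      a
    }
    a <- get_arm(condition_a); b <- get_arm(condition_b)
    obs <- aucs$auc[aucs$biosensor_id == biosensor_id &
                      aucs$condition_id == condition_ab]
    if (length(obs) < 2) stop("missing AUCs for ", biosensor_id, " / ",
                              condition_ab, call. = FALSE)
    exp_add <- expected_additive(a$mean, a$sem, b$mean, b$sem)
    test <- synergy_test(obs, exp_add$mean_expected, exp_add$sem_expected,
                         arm_sems = c(a$sem, b$sem), arm_ns = c(a$n, b$n))
    sw <- if (length(obs) >= 3 && length(obs) <= 5000 &&
              stats::sd(obs) > 0) normality_check(obs) else
      tibble::tibble(W = NA_real_, p_value = NA_real_, n = length(obs))
    tibble::tibble(
      biosensor_id = biosensor_id, pair_id = pair_id,
      condition_a = condition_a, condition_b = condition_b,
      mean_observed = test$mean_observed, sem_observed = test$sem_observed,
      n_obs = test$n_obs,
      mean_expected = exp_add$mean_expected,
      sem_expected = exp_add$sem_expected,
      ss_raw = test$ss_raw, t_stat = test$t_stat, df = test$df,
      p = test$p, shapiro_w = sw$W, shapiro_p = sw$p_value
    )
  })
  res$p_adj <- adjust_pvalues(res$p, adjust)
  res <- scale_and_mask(res, alpha)
  attr(res, "alpha") <- alpha
  attr(res, "adjust") <- adjust
  class(res) <- c("synergy_result", class(res))
  res
}

#' @export
glance.synergy_result <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(!x$masked),
    n_synergistic = sum(!x$masked & x$ss_raw > 0),
    n_antagonistic = sum(!x$masked & x$ss_raw < 0),
    alpha = attr(x, "alpha")
  )
}

#' Clustered synergy map
#'
#' Arranges the scaled scores into a biosensor x pair matrix, imputes
#' masked entries as 0 for the distance computation, and orders rows and
#' columns by hierarchical clustering (Euclidean metric, Ward's linkage).
#'
#' @param results A `synergy_result` from [synergy_scores()].
#' @return A list of class `synergy_map`: `matrix` (reordered), `mask`
#'   (same shape), `row_order`, `col_order`, `row_hclust`, `col_hclust`
#'   (`NULL` when a dimension has a single element).
#' @export
synergy_map <- function(results) {
  wide <- results |>
    dplyr::mutate(ss_for_dist = dplyr::if_else(.data$masked, 0,
                                               .data$ss_scaled)) |>
    dplyr::select("biosensor_id", "pair_id", "ss_for_dist")
  mat <- wide |>
    tidyr::pivot_wider(names_from = "pair_id",
                       values_from = "ss_for_dist") |>
    tibble::column_to_rownames("biosensor_id") |>
    as.matrix()
  if (anyNA(mat)) stop("incomplete biosensor x pair matrix", call. = FALSE)
  mask <- results |>
    dplyr::select("biosensor_id", "pair_id", "masked") |>
    tidyr::pivot_wider(names_from = "pair_id", values_from = "masked") |>
    tibble::column_to_rownames("biosensor_id") |>
    as.matrix()
  order_of <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), hc = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "ward.D2")
    list(order = hc$order, hc = hc)
  }
  ro <- order_of(mat)
  co <- order_of(t(mat))
  structure(list(matrix = mat[ro$order, co$order, drop = FALSE],
                 mask = mask[ro$order, co$order, drop = FALSE],
                 row_order = rownames(mat)[ro$order],
                 col_order = colnames(mat)[co$order],
                 row_hclust = ro$hc, col_hclust = co$hc),
            class = "synergy_map")
}

#' Heatmap of a clustered synergy map
#'
#' Red = synergy, blue = antagonism, white = insignificant (masked).
#'
#' @param map A `synergy_map`.
#' @return A ggplot.
#' @export
plot_synergy_map <- function(map) {
  df <- tibble::as_tibble(map$matrix, rownames = "biosensor_id") |>
    tidyr::pivot_longer(-"biosensor_id", names_to = "pair_id",
                        values_to = "ss_scaled")
  mk <- tibble::as_tibble(map$mask, rownames = "biosensor_id") |>
    tidyr::pivot_longer(-"biosensor_id", names_to = "pair_id",
                        values_to = "masked")
  df <- dplyr::left_join(df, mk, by = c("biosensor_id", "pair_id")) |>
    dplyr::mutate(
      ss_shown = dplyr::if_else(.data$masked, NA_real_, .data$ss_scaled),
      biosensor_id = factor(.data$biosensor_id, levels = map$row_order),
      pair_id = factor(.data$pair_id, levels = map$col_order)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$pair_id, .data$biosensor_id,
                                   fill = .data$ss_shown)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  limits = c(-1, 1), na.value = "white",
                                  name = "scaled\nscore") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
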