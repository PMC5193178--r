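#' Baseline normalization of single-cell trajectories
#'
#' Divides each cell's ratio trace by the mean of its own pre-stimulus time
#' points, so resting activity is 1.
#'
#' @param trajectories Long tibble with `cell_id`, `time_min` and the value
#'   column.
#' @param stimulation_time Stimulus addition time (minutes); points strictly
#'   before it form the baseline (at least 2 required per cell).
#' @param value_col Name of the column to normalize (default `"ratio"`).
#' @return The input with the value column replaced by its baseline-
#'   normalized version.
#' @export
normalize_baseline <- function(trajectories, stimulation_time,
                               value_col = "ratio") {
  val <- rlang::sym(value_col)
  out <- trajectories |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      .n_pre = sum(.data$time_min < stimulation_time),
      .base = mean((!!val)[.data$time_min < stimulation_time])
    ) |>
    dplyr::ungroup()
  if (any(out$.n_pre < 2)) {
    stop("every cell needs at least 2 pre-stimulus points for baseline ",
         "normalization", call. = FALSE)
  }
  out |>
    dplyr::mutate(!!val := !!val / .data$.base) |>
    dplyr::select(-".n_pre", -".base")
}

#' Condition-level mean and SEM traces
#'
#' Pointwise mean and standard error over all cells pooled across replicate
#' experiments of the same biosensor x condition.
#'
#' @param trajectories Long tibble with `biosensor_id`, `condition_id`,
#'   `time_min` and the value column; every cell must sit on the same time
#'   grid within a condition.
#' @param value_col Value column name.
#' @return A tibble `biosensor_id`, `condition_id`, `time_min`, `mean`,
#'   `sem`, `n_cells`.
#' @export
condition_mean_sem <- function(trajectories, value_col = "ratio") {
  val <- rlang::sym(value_col)
  grids <- trajectories |>
    dplyr::group_by(.data$biosensor_id, .data$condition_id, .data$cell_id) |>
    dplyr::summarise(g = paste(signif(.data$time_min, 10), collapse = ","),
                     .groups = "drop_last") |>
    dplyr::summarise(k = dplyr::n_distinct(.data$g), .groups = "drop")
  if (any(grids$k > 1)) {
    stop("cells within a condition are on different time grids",
         call. = FALSE)
  }
  trajectories |>
    dplyr::group_by(.data$biosensor_id, .data$condition_id,
                    .data$time_min) |>
    dplyr::summarise(
      mean = mean(!!val),
      sem = stats::sd(!!val) / sqrt(dplyr::n()),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem = dplyr::coalesce(.data$sem, 0))
}

#' Vehicle normalization
#'
#' Divides each cell's value at time `t` by the vehicle-condition mean at
#' `t` (same biosensor), removing shared drift such as rising biosensor
#' expression or photobleaching.
#'
#' @param trajectories Long tibble (treated cells).
#' @param vehicle_summary Output of [condition_mean_sem()] computed on the
#'   vehicle condition; must cover every `(biosensor_id, time_min)` present.
#' @param value_col Value column name.
#' @return Normalized trajectories.
#' @export
normalize_vehicle <- function(trajectories, vehicle_summary,
                              value_col = "ratio") {
  val <- rlang::sym(value_col)
  veh <- vehicle_summary |>
    dplyr::select("biosensor_id", "time_min", veh_mean = "mean")
  out <- dplyr::left_join(trajectories, veh,
                          by = c("biosensor_id", "time_min"))
  if (any(is.na(out$veh_mean))) {
    stop("vehicle summary does not cover all time points", call. = FALSE)
  }
  if (any(out$veh_mean <= 0)) {
    stop("vehicle mean must be positive at every time point",
         call. = FALSE)
  }
  out |>
    dplyr::mutate(!!val := !!val / .data$veh_mean) |>
    dplyr::select(-"veh_mean")
}

#' Maximum normalization of a summary trace
#'
#' Scales a trace (or each group's trace) by its maximum so the peak is 1,
#' making response shapes comparable across biosensors.
#'
#' @param summaries Tibble with a `mean` column (and optionally `sem`,
#'   scaled alongside); grouped per `biosensor_id` x `condition_id` when
#'   those columns are present.
#' @return The input with `mean` (and `sem`) divided by the per-group
#'   maximum of `mean`.
#' @export
normalize_max <- function(summaries) {
  groups <- intersect(c("biosensor_id", "condition_id"), names(summaries))
  out <- summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::mutate(.max = max(.data$mean)) |>
    dplyr::ungroup()
  if (any(out$.max <= 0)) {
    stop("trace maximum must be positive for max-normalization",
         call. = FALSE)
  }
  out <- dplyr::mutate(out, mean = .data$mean / .data$.max)
  if ("sem" %in% names(out)) {
    out <- dplyr::mutate(out, sem = .data$sem / .data$.max)
  }
  dplyr::select(out, -".max")
}

#' Replicate reproducibility as coefficient of variation
#'
#' At each time point, CV (%) = 100 * sd / mean over the replicate mean
#' traces; the average CV over time points summarizes reproducibility of
#' the platform across replicate experiments.
#'
#' @param replicate_summaries Tibble with `replicate_id`, `time_min`,
#'   `mean` (one mean trace per replicate, common grid).
#' @return A list: `cv_trace` (tibble `time_min`, `cv_pct`, `n_replicates`)
#'   and `average_cv_pct`.
#' @export
replicate_cv <- function(replicate_summaries) {
  trace <- replicate_summaries |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      cv_pct = 100 * stats::sd(.data$mean) / mean(.data$mean),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  if (any(trace$n_replicates < 2)) {
    stop("at least 2 replicates required at every time point",
         call. = FALSE)
  }
  if (any(!is.finite(trace$cv_pct))) {
    warning("zero replicate mean at some time points; excluded from the ",
            "average CV", call. = FALSE)
  }
  list(cv_trace = trace,
       average_cv_pct = mean(trace$cv_pct[is.finite(trace$cv_pct)]))
}

#' Expression-response correlation (Kendall tau)
#'
#' Correlates per-cell biosensor expression (pre-stimulus mean CFP) with the
#' maximal normalized ratio, testing whether expression level biases the
#' reported response. Kendall's tau-b with the exact p value for fewer than
#' 50 untied pairs and the normal approximation otherwise.
#'
#' @param trajectories Long tibble with `cell_id`, `time_min`, `mean_cfp`
#'   and the normalized value column.
#' @param stimulation_time Pre-stimulus window end for the expression level.
#' @param value_col Normalized value column.
#' @return A tibble with `tau`, `p_value`, `n_cells`.
#' @export
expression_response_correlation <- function(trajectories, stimulation_time,
                                            value_col = "ratio") {
  val <- rlang::sym(value_col)
  per_cell <- trajectories |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      expression = mean(.data$mean_cfp[.data$time_min < stimulation_time]),
      max_response = max(!!val),
      .groups = "drop"
    )
  if (nrow(per_cell) < 3) {
    stop("at least 3 cells required for the correlation", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(per_cell$expression, per_cell$max_response,
                    method = "kendall")
  )
  tibble::tibble(tau = unname(ct$estimate), p_value = ct$p.value,
                 n_cells = nrow(per_cell))
}
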