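#' Link ROIs across frames into cell trajectories
#'
#' Greedy nearest-centroid linking: for consecutive frames, ROI pairs are
#' matched in order of increasing centroid distance up to
#' `max_displacement`; unmatched ROIs start new tracks. Tracks shorter than
#' `min_length` frames are discarded.
#'
#' @param measurements Tibble from [quantify_stack()] (needs `frame`, `x`,
#'   `y`, and `roi_id`); linking is done within each `spot_id`.
#' @param max_displacement Maximum frame-to-frame centroid displacement in
#'   pixels.
#' @param min_length Minimum track length (frames) to keep.
#' @return The measurements with a `cell_id` column (`<spot_id>_track_k`),
#'   filtered to retained tracks.
#' @export
link_rois <- function(measurements, max_displacement = 15, min_length = 1) {
  stopifnot(nrow(measurements) >= 1)
  linked <- measurements |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::group_modify(function(df, key) link_one_spot(df, max_displacement)) |>
    dplyr::ungroup() |>
    dplyr::mutate(cell_id = sprintf("%s_track_%03d", .data$spot_id,
                                    .data$track))
  keep <- linked |>
    dplyr::count(.data$cell_id) |>
    dplyr::filter(.data$n >= min_length) |>
    dplyr::pull(.data$cell_id)
  linked |>
    dplyr::filter(.data$cell_id %in% keep) |>
    dplyr::select(-"track")
}

link_one_spot <- function(df, max_displacement) {
  frames <- sort(unique(df$frame))
  df$track <- NA_integer_
  next_track <- 1L
  prev <- NULL
  for (f in frames) {
    idx <- which(df$frame == f)
    cur <- df[idx, c("x", "y")]
    assigned <- rep(NA_integer_, length(idx))
    if (!is.null(prev) && nrow(prev) > 0 && length(idx) > 0) {
      d <- outer(seq_len(nrow(cur)), seq_len(nrow(prev)),
                 function(i, j) sqrt((cur$x[i] - prev$x[j])^2 +
                                       (cur$y[i] - prev$y[j])^2))
      repeat {
        m <- which(d == min(d), arr.ind = TRUE)
        if (!length(m) || min(d) > max_displacement) break
        i <- m[1, 1]; j <- m[1, 2]
        assigned[i] <- prev$track[j]
        d[i, ] <- Inf; d[, j] <- Inf
        if (all(!is.finite(d))) break
      }
    }
    new <- which(is.na(assigned))
    if (length(new)) {
      assigned[new] <- next_track + seq_along(new) - 1L
      next_track <- next_track + length(new)
    }
    df$track[idx] <- assigned
    prev <- data.frame(x = cur$x, y = cur$y, track = assigned)
  }
  df
}

#' Expression gate on trajectories
#'
#' Keeps cells whose mean pre-stimulus CFP intensity lies within the
#' expression window (default 700-8,000 a.u.), excluding low expressors
#' (unreliable ratios) and very high expressors.
#'
#' @param trajectories Long tibble with `cell_id`, `time_min`, `mean_cfp`.
#' @param cfp_min,cfp_max Inclusive intensity bounds (a.u.).
#' @param stimulation_time Pre-stimulus window end (minutes); `NULL` uses
#'   all time points.
#' @return The trajectories restricted to retained cells.
#' @export
filter_expression <- function(trajectories, cfp_min = 700, cfp_max = 8000,
                              stimulation_time = NULL) {
  pre <- if (is.null(stimulation_time)) trajectories else
    dplyr::filter(trajectories, .data$time_min < stimulation_time)
  keep <- pre |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(cfp = mean(.data$mean_cfp, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$cfp >= cfp_min, .data$cfp <= cfp_max) |>
    dplyr::pull(.data$cell_id)
  out <- dplyr::filter(trajectories, .data$cell_id %in% keep)
  if (nrow(out) == 0) {
    warning("expression filter removed all cells", call. = FALSE)
  }
  out
}
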