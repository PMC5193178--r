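#' Read / write ROI measurement tables
#'
#' Measurements are plain CSV (comma, UTF-8, `.` decimal) with one row per
#' ROI per frame. `read_measurements()` validates the required columns and
#' preserves any extra columns.
#'
#' @param path CSV file path.
#' @return A tibble of measurement records.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("spot_id", "cell_id", "frame", "time_min", "mean_cfp",
                "mean_fret", "ratio")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_measurements
#' @param measurements Tibble to write.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}

#' Read / write condition tables
#'
#' Long CSV format: one row per stimulus per condition (`condition_id`,
#' `stimulus`, `concentration_ng_ml`, `stimulation_time_min`,
#' `interaction_gamma`); vehicle conditions have an empty `stimulus`.
#'
#' @param path CSV file path.
#' @return A [condition_table()] tibble.
#' @export
read_conditions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          condition_id = readr::col_character(),
                          stimulus = readr::col_character()
                        ))
  specs <- df |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::group_map(function(rows, key) {
      stim <- rows[!is.na(rows$stimulus) & nzchar(rows$stimulus), ]
      stimuli <- if (nrow(stim)) {
        stats::setNames(stim$concentration_ng_ml, stim$stimulus)
      } else NULL
      condition_spec(key$condition_id, stimuli,
                     stimulation_time = rows$stimulation_time_min[1],
                     interaction_gamma = rows$interaction_gamma[1] %||% 0)
    })
  dplyr::bind_rows(specs)
}

#' @rdname read_conditions
#' @param conditions A [condition_table()] tibble.
#' @export
write_conditions <- function(conditions, path) {
  long <- purrr::pmap_dfr(conditions, function(condition_id, stimuli,
                                               stimulation_time, is_vehicle,
                                               interaction_gamma) {
    if (length(stimuli) == 0) {
      tibble::tibble(condition_id = condition_id, stimulus = NA_character_,
                     concentration_ng_ml = NA_real_,
                     stimulation_time_min = stimulation_time,
                     interaction_gamma = interaction_gamma)
    } else {
      tibble::tibble(condition_id = condition_id, stimulus = names(stimuli),
                     concentration_ng_ml = unname(stimuli),
                     stimulation_time_min = stimulation_time,
                     interaction_gamma = interaction_gamma)
    }
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return A validated config list (see [run_pipeline()] for the schema).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  config <- yaml::read_yaml(path)
  validate_config(config)
}

validate_config <- function(config) {
  for (field in c("seed", "models", "conditions")) {
    if (is.null(config[[field]])) {
      stop("config is missing required field: ", field, call. = FALSE)
    }
  }
  config$layout <- utils::modifyList(
    list(n_rows = 1, n_cols = 1, spot_diameter_um = 200, pitch_um = 1125),
    config$layout %||% list())
  config$simulate <- utils::modifyList(
    list(n_cells_per_spot = 6, time_interval_min = 3, duration_min = 30),
    config$simulate %||% list())
  config$image <- utils::modifyList(
    list(width = 96, height = 96, offset = 100, noise_sd = 2),
    config$image %||% list())
  config$analysis <- utils::modifyList(
    list(cfp_min = 700, cfp_max = 8000, k_patterns = 3, alpha = 0.05,
         adjust = "BH", min_area = 50, max_displacement = 15,
         min_track_length = 2),
    config$analysis %||% list())
  config$stages <- config$stages %||%
    c("simulate", "segment", "trajectories", "signatures", "pca", "synergy")
  config
}
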