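#' Build a printed-spot array layout
#'
#' Constructs the grid layout of a cell microarray: spots printed at a fixed
#' pitch, each carrying one biosensor plasmid. The default geometry is a
#' 16 x 24 grid (384 spots) of 200 um spots at 1125 um pitch.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param spot_diameter_um Printed spot diameter in micrometres.
#' @param pitch_um Centre-to-centre spot distance in micrometres; must be at
#'   least `spot_diameter_um` so spots do not overlap.
#' @param biosensor_assignment Character vector of biosensor identifiers, one
#'   per grid position in row-major order, or a single identifier recycled to
#'   every spot. Repeated identifiers get increasing `replicate_index`
#'   (0-based) in row-major order.
#'
#' @return A tibble with one row per spot and columns `spot_id`, `row_index`,
#'   `col_index`, `center_x_um`, `center_y_um`, `diameter_um`, `biosensor_id`,
#'   `replicate_index`, plus attributes `pitch_um` and `dims`.
#' @examples
#' layout <- make_layout(16, 24, 200, 1125, "ERK")
#' nrow(layout) # 384
#' @export
make_layout <- function(n_rows, n_cols, spot_diameter_um = 200,
                        pitch_um = 1125,
                        biosensor_assignment = "biosensor_1") {
  if (length(n_rows) != 1 || length(n_cols) != 1 ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != as.integer(n_rows) || n_cols != as.integer(n_cols)) {
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  }
  if (spot_diameter_um <= 0) {
    stop("`spot_diameter_um` must be positive", call. = FALSE)
  }
  if (pitch_um < spot_diameter_um) {
    stop("`pitch_um` must be at least `spot_diameter_um`", call. = FALSE)
  }
  n_spots <- as.integer(n_rows) * as.integer(n_cols)
  if (length(biosensor_assignment) == 1) {
    biosensor_assignment <- rep(biosensor_assignment, n_spots)
  }
  if (length(biosensor_assignment) != n_spots) {
    stop("`biosensor_assignment` must have one entry per grid position (",
         n_spots, "), got ", length(biosensor_assignment), call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    row_index = seq_len(n_rows),
    col_index = seq_len(n_cols)
  )
  layout <- grid |>
    dplyr::mutate(
      spot_id = sprintf("spot_r%02dc%02d", .data$row_index, .data$col_index),
      center_x_um = (.data$col_index - 1) * pitch_um,
      center_y_um = (.data$row_index - 1) * pitch_um,
      diameter_um = spot_diameter_um,
      biosensor_id = as.character(biosensor_assignment)
    ) |>
    dplyr::group_by(.data$biosensor_id) |>
    dplyr::mutate(replicate_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("spot_id", "row_index", "col_index", "center_x_um",
                  "center_y_um", "diameter_um", "biosensor_id",
                  "replicate_index")
  attr(layout, "pitch_um") <- pitch_um
  attr(layout, "dims") <- c(n_rows = as.integer(n_rows),
                            n_cols = as.integer(n_cols))
  layout
}

#' Write / read an array layout as CSV
#'
#' @param layout Layout tibble from [make_layout()].
#' @param path File path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` returns
#'   the layout tibble.
#' @export
write_layout <- function(layout, path) {
  readr::write_csv(layout, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    spot_id = readr::col_character(),
                    biosensor_id = readr::col_character()
                  ))
}
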