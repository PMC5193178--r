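#' Nucleus-seeded cell segmentation
#'
#' Thresholds the nuclear-marker image (Triangle, foreground above
#' threshold) to obtain nucleus seeds, then partitions the cell mask by
#' seeded region growing on its distance transform (each masked pixel is
#' assigned to the nearest nucleus seed, splitting touching cells along the
#' midline between their nuclei). Regions smaller than `min_area` pixels are
#' discarded, mirroring a particle-analyzer size gate.
#'
#' @param nuclear_img Nuclear-marker intensity image (matrix).
#' @param cell_mask Logical matrix from [huang_mask()].
#' @param min_area Minimum ROI area in pixels.
#' @return A list of class `label_map`: `nucleus_mask` (logical),
#'   `cell_labels` (integer matrix, 0 = background), `roi_count`.
#' @export
segment_cells <- function(nuclear_img, cell_mask, min_area = 50) {
  stopifnot(all(dim(nuclear_img) == dim(cell_mask)))
  v <- as.vector(nuclear_img)
  if (max(v) == min(v)) {
    nucleus_mask <- matrix(FALSE, nrow(nuclear_img), ncol(nuclear_img))
  } else {
    tb <- triangle_background(nuclear_img)
    nucleus_mask <- nuclear_img > tb$threshold
  }
  seeds <- EBImage::bwlabel(nucleus_mask)
  if (max(seeds) == 0) {
    warning("no nuclei found; returning empty segmentation", call. = FALSE)
    return(structure(list(nucleus_mask = nucleus_mask,
                          cell_labels = matrix(0L, nrow(nuclear_img),
                                               ncol(nuclear_img)),
                          roi_count = 0L), class = "label_map"))
  }
  storage <- matrix(as.numeric(cell_mask), nrow(cell_mask), ncol(cell_mask))
  dist <- EBImage::distmap(storage)
  # seeded growth on the distance landscape; large lambda makes the metric
  # purely spatial, i.e. watershed split along the midline between seeds
  labels <- EBImage::propagate(x = dist, seeds = seeds,
                               mask = cell_mask, lambda = 1e4)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(cell_mask), ncol(cell_mask))
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  fg <- labels > 0
  out[fg] <- relabel[labels[fg]]
  structure(list(nucleus_mask = nucleus_mask, cell_labels = out,
                 roi_count = length(keep)), class = "label_map")
}

#' Measure ROI intensities and ratios
#'
#' Per labelled region: mean CFP and FRET over non-`NaN` pixels, their
#' ratio, pixel counts and the intensity-free centroid. `NaN`-masked pixels
#' never contribute to a mean; a fully masked ROI yields `NaN` means and is
#' kept with `all_masked = TRUE`.
#'
#' @param labels A `label_map` from [segment_cells()] (or an integer label
#'   matrix).
#' @param cfp_masked,fret_masked Masked channel images (`NaN` background).
#' @param spot_id,frame,time_min Identifiers copied into the output.
#' @return A tibble with one row per ROI: `spot_id`, `roi_id`, `frame`,
#'   `time_min`, `mean_cfp`, `mean_fret`, `ratio`, `n_pixels`, `x`, `y`,
#'   `all_masked`.
#' @export
measure_rois <- function(labels, cfp_masked, fret_masked,
                         spot_id = NA_character_, frame = NA_integer_,
                         time_min = NA_real_) {
  lab <- if (inherits(labels, "label_map")) labels$cell_labels else labels
  stopifnot(all(dim(lab) == dim(cfp_masked)),
            all(dim(lab) == dim(fret_masked)))
  n_roi <- max(lab)
  if (n_roi == 0) {
    return(tibble::tibble(spot_id = character(0), roi_id = integer(0),
                          frame = integer(0), time_min = numeric(0),
                          mean_cfp = numeric(0), mean_fret = numeric(0),
                          ratio = numeric(0), n_pixels = integer(0),
                          x = numeric(0), y = numeric(0),
                          all_masked = logical(0)))
  }
  fg <- lab > 0
  l <- lab[fg]
  cfp <- cfp_masked[fg]
  fret <- fret_masked[fg]
  rows <- row(lab)[fg]
  cols <- col(lab)[fg]
  nan_safe_mean <- function(v, g) {
    ok <- !is.na(v)
    s <- rep(NaN, n_roi)
    if (any(ok)) {
      m <- tapply(v[ok], factor(g[ok], levels = seq_len(n_roi)), mean)
      s[!is.na(m)] <- m[!is.na(m)]
    }
    s
  }
  mean_cfp <- nan_safe_mean(cfp, l)
  mean_fret <- nan_safe_mean(fret, l)
  n_valid <- tabulate(l[!is.na(cfp)], nbins = n_roi)
  tibble::tibble(
    spot_id = spot_id,
    roi_id = seq_len(n_roi),
    frame = frame,
    time_min = time_min,
    mean_cfp = mean_cfp,
    mean_fret = mean_fret,
    ratio = mean_fret / mean_cfp,
    n_pixels = tabulate(l, nbins = n_roi),
    x = as.numeric(tapply(cols, factor(l, levels = seq_len(n_roi)), mean)),
    y = as.numeric(tapply(rows, factor(l, levels = seq_len(n_roi)), mean)),
    all_masked = n_valid == 0
  )
}

#' Quantify a three-channel movie
#'
#' Runs the full per-frame quantification chain on a spot movie: Triangle
#' background subtraction on CFP and FRET, circular median filtering, Huang
#' masking on the CFP channel (the mask and its `NaN` background are applied
#' to both channels), nucleus-seeded segmentation, and ROI measurement.
#' Frames are processed independently.
#'
#' @param frames List of per-frame `list(cfp, fret, nuclear)` matrices (as
#'   from [read_spot_stack()] or [render_frames()]).
#' @param time_grid Acquisition times (minutes), one per frame.
#' @param spot_id Identifier copied into the measurements.
#' @param median_radius Radius of the median filter disc.
#' @param min_area Particle-analyzer area gate (pixels).
#' @return A tibble of ROI measurements across frames (see
#'   [measure_rois()]).
#' @export
quantify_stack <- function(frames, time_grid, spot_id = "spot",
                           median_radius = 2, min_area = 50) {
  stopifnot(length(frames) == length(time_grid))
  purrr::map2_dfr(frames, seq_along(frames), function(fr, f) {
    cfp <- preprocess_frame(triangle_background(fr$cfp)$corrected,
                            median_radius)
    fret <- preprocess_frame(triangle_background(fr$fret)$corrected,
                             median_radius)
    hm <- huang_mask(cfp)
    fret_masked <- fret
    fret_masked[!hm$mask] <- NaN
    seg <- segment_cells(fr$nuclear, hm$mask, min_area = min_area)
    measure_rois(seg, hm$masked, fret_masked, spot_id = spot_id,
                 frame = f, time_min = time_grid[f])
  })
}
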