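#' Camera / rendering parameters
#'
#' @param width,height Image size in pixels.
#' @param offset Constant camera offset (a.u.), added to every pixel.
#' @param noise_sd Gaussian read-noise standard deviation (a.u.); 0 for
#'   noiseless renders.
#' @param nuclear_intensity Intensity of the nuclear-marker discs (a.u.).
#' @param bit_max Saturation value; images are clamped to `[0, bit_max]`
#'   (16-bit unsigned by default).
#' @return A named list.
#' @export
camera_params <- function(width = 128, height = 128, offset = 100,
                          noise_sd = 2, nuclear_intensity = 3000,
                          bit_max = 65535) {
  stopifnot(offset >= 0, noise_sd >= 0)
  list(width = width, height = height, offset = offset, noise_sd = noise_sd,
       nuclear_intensity = nuclear_intensity, bit_max = bit_max)
}

#' Place cells in an image without overlap
#'
#' Rejection-samples cell centres inside the image (with margin) keeping a
#' minimum centre-to-centre separation, emulating transfected cells settled
#' on a printed spot.
#'
#' @param n_cells Number of cells.
#' @param camera [camera_params()].
#' @param cell_radius,nucleus_radius Cell and nuclear radii in pixels.
#' @param min_separation Minimum distance between cell centres (pixels).
#' @param eccentricity Maximum relative elongation of the cell ellipse.
#' @return A tibble with `cell_id`, `x`, `y`, `rx`, `ry`, `nucleus_radius`.
#' @export
place_cells <- function(n_cells, camera = camera_params(),
                        cell_radius = 9, nucleus_radius = 4,
                        min_separation = 2.6 * cell_radius,
                        eccentricity = 0.25) {
  if (n_cells == 0) {
    return(tibble::tibble(cell_id = character(0), x = numeric(0),
                          y = numeric(0), rx = numeric(0), ry = numeric(0),
                          nucleus_radius = numeric(0)))
  }
  margin <- cell_radius * (1 + eccentricity) + 2
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_cells && tries < 20000) {
    tries <- tries + 1
    x <- stats::runif(1, margin, camera$width - margin)
    y <- stats::runif(1, margin, camera$height - margin)
    if (length(xs) == 0 ||
        min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_separation) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n_cells) {
    stop("could not place ", n_cells, " cells without overlap; ",
         "reduce `n_cells` or `min_separation`", call. = FALSE)
  }
  ecc <- stats::runif(n_cells, 0, eccentricity)
  tibble::tibble(
    cell_id = sprintf("cell_%03d", seq_len(n_cells)),
    x = xs, y = ys,
    rx = cell_radius * (1 + ecc),
    ry = cell_radius / (1 + ecc),
    nucleus_radius = nucleus_radius
  )
}

# Fill an ellipse into matrix `img` (rows = y) with value `value`.
fill_ellipse <- function(img, cx, cy, rx, ry, value) {
  x0 <- max(1L, floor(cx - rx)); x1 <- min(ncol(img), ceiling(cx + rx))
  y0 <- max(1L, floor(cy - ry)); y1 <- min(nrow(img), ceiling(cy + ry))
  xs <- x0:x1; ys <- y0:y1
  inside <- outer((ys - cy)^2 / ry^2, (xs - cx)^2 / rx^2, `+`) <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- value
  img[ys, xs] <- sub
  img
}

#' Render multi-channel frames for one spot
#'
#' Draws cells as filled ellipses with concentric nuclear discs and composes
#' the three acquisition channels per frame. For a cell with expression
#' `E(t)` and activity `a(t)`: CFP foreground = `E(t)`, FRET foreground =
#' `E(t) * R0 * (1 + a(t))`, so the noiseless foreground FRET/CFP ratio is
#' `R0 * (1 + a(t))` independent of expression. Expression rises linearly
#' over time; camera offset and Gaussian read noise are added to all
#' channels.
#'
#' @param cells Cell table from [place_cells()], plus columns `e0`
#'   (pre-movie expression, a.u.) and `baseline_ratio` (`R0`).
#' @param activity `n_cells x n_time` matrix of true activity `a(t)`.
#' @param time_grid Acquisition times in minutes.
#' @param camera [camera_params()].
#' @param expression_slope_per_min Relative linear expression increase.
#' @param jitter_sd Per-frame centroid jitter (pixels); 0 = static cells.
#' @return A list of frames; each frame is
#'   `list(cfp, fret, nuclear, time_min)` with matrices in a.u.
#' @export
render_frames <- function(cells, activity, time_grid,
                          camera = camera_params(),
                          expression_slope_per_min = 0.002,
                          jitter_sd = 0) {
  n_cells <- nrow(cells)
  stopifnot(is.matrix(activity) || n_cells == 0,
            n_cells == 0 || nrow(activity) == n_cells,
            n_cells == 0 || ncol(activity) == length(time_grid))
  if (n_cells > 0) {
    bad <- cells$x - cells$rx < 1 | cells$x + cells$rx > camera$width |
      cells$y - cells$ry < 1 | cells$y + cells$ry > camera$height
    if (any(bad)) {
      stop("cells outside image bounds: ",
           paste(cells$cell_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  frames <- vector("list", length(time_grid))
  positions <- vector("list", length(time_grid))
  for (f in seq_along(time_grid)) {
    t <- time_grid[f]
    cfp <- matrix(0, camera$height, camera$width)
    fret <- matrix(0, camera$height, camera$width)
    nuc <- matrix(0, camera$height, camera$width)
    if (n_cells > 0) {
      dx <- if (jitter_sd > 0) stats::rnorm(n_cells, 0, jitter_sd) else
        numeric(n_cells)
      dy <- if (jitter_sd > 0) stats::rnorm(n_cells, 0, jitter_sd) else
        numeric(n_cells)
      xs <- pmin(pmax(cells$x + dx, cells$rx + 1),
                 camera$width - cells$rx - 1)
      ys <- pmin(pmax(cells$y + dy, cells$ry + 1),
                 camera$height - cells$ry - 1)
      e_t <- cells$e0 * (1 + expression_slope_per_min * t)
      for (i in seq_len(n_cells)) {
        cfp <- fill_ellipse(cfp, xs[i], ys[i], cells$rx[i], cells$ry[i],
                            e_t[i])
        fret <- fill_ellipse(fret, xs[i], ys[i], cells$rx[i], cells$ry[i],
                             e_t[i] * cells$baseline_ratio[i] *
                               (1 + activity[i, f]))
        nuc <- fill_ellipse(nuc, xs[i], ys[i], cells$nucleus_radius[i],
                            cells$nucleus_radius[i],
                            camera$nuclear_intensity)
      }
      positions[[f]] <- tibble::tibble(cell_id = cells$cell_id,
                                       frame = f, x = xs, y = ys)
    } else {
      positions[[f]] <- tibble::tibble(cell_id = character(0),
                                       frame = integer(0),
                                       x = numeric(0), y = numeric(0))
    }
    add_camera <- function(img) {
      img <- img + camera$offset
      if (camera$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, camera$noise_sd),
                            nrow(img), ncol(img))
      }
      pmin(pmax(img, 0), camera$bit_max)
    }
    frames[[f]] <- list(cfp = add_camera(cfp), fret = add_camera(fret),
                        nuclear = add_camera(nuc), time_min = t)
  }
  attr(frames, "positions") <- dplyr::bind_rows(positions)
  frames
}

#' Simulate a full imaging experiment to disk
#'
#' For each spot of the layout: places cells, simulates their activity under
#' the spot's condition, renders the three-channel movie, and writes one
#' multi-page TIFF per channel (`<spot_id>_<CFP|FRET|NUC>.tif`) plus
#' `ground_truth.csv`, `layout.csv` and `config.yaml`. Deterministic given
#' `seed`.
#'
#' @param layout From [make_layout()]; `biosensor_id` of each spot selects
#'   the model.
#' @param models Tibble of [biosensor_model()] rows covering every biosensor
#'   in the layout.
#' @param conditions Tibble of [condition_spec()] rows.
#' @param spot_conditions Character vector mapping each layout row to a
#'   `condition_id` (recycled if length 1); defaults to the first condition
#'   for all spots.
#' @param n_cells_per_spot Cells per spot (single value or per-spot vector).
#' @param time_grid Acquisition times in minutes.
#' @param camera [camera_params()].
#' @param cell_noise [cell_noise_params()].
#' @param expression [expression_params()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Invisibly, a list with `dir`, `files`, `ground_truth` (tibble),
#'   and `layout`.
#' @export
simulate_experiment <- function(layout, models, conditions,
                                spot_conditions = NULL,
                                n_cells_per_spot = 8,
                                time_grid = seq(0, 60, by = 3),
                                camera = camera_params(),
                                cell_noise = cell_noise_params(),
                                expression = expression_params(),
                                out_dir, seed = 1) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  n_spots <- nrow(layout)
  spot_conditions <- spot_conditions %||% conditions$condition_id[1]
  if (length(spot_conditions) == 1) {
    spot_conditions <- rep(spot_conditions, n_spots)
  }
  stopifnot(length(spot_conditions) == n_spots)
  if (length(n_cells_per_spot) == 1) {
    n_cells_per_spot <- rep(n_cells_per_spot, n_spots)
  }
  files <- character(0)
  gt <- list()
  withr::with_seed(seed, {
    for (si in seq_len(n_spots)) {
      spot <- layout[si, ]
      model <- models[models$biosensor_id == spot$biosensor_id, ]
      if (nrow(model) != 1) {
        stop("no unique model for biosensor ", spot$biosensor_id,
             call. = FALSE)
      }
      condition <- conditions[conditions$condition_id ==
                                spot_conditions[si], ]
      if (nrow(condition) != 1) {
        stop("unknown condition: ", spot_conditions[si], call. = FALSE)
      }
      cells <- place_cells(n_cells_per_spot[si], camera)
      s_e <- sqrt(log(1 + expression$cv^2))
      cells$e0 <- expression$mean_au *
        stats::rlnorm(nrow(cells), -s_e^2 / 2, s_e)
      cells$baseline_ratio <- model$baseline_ratio
      activity <- simulate_activity_matrix(model, condition, nrow(cells),
                                           time_grid, cell_noise)
      frames <- render_frames(cells, activity, time_grid, camera,
                              expression$slope_per_min)
      for (ch in c("CFP", "FRET", "NUC")) {
        key <- c(CFP = "cfp", FRET = "fret", NUC = "nuclear")[[ch]]
        path <- file.path(out_dir, paste0(spot$spot_id, "_", ch, ".tif"))
        pages <- lapply(frames, function(fr) fr[[key]] / camera$bit_max)
        tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
        files <- c(files, path)
      }
      if (nrow(cells) > 0) {
        pos <- attr(frames, "positions")
        gt[[length(gt) + 1L]] <- pos |>
          dplyr::mutate(
            spot_id = spot$spot_id,
            time_min = time_grid[.data$frame],
            a_true = as.vector(activity[cbind(
              match(.data$cell_id, cells$cell_id), .data$frame)]),
            ratio_true = model$baseline_ratio * (1 + .data$a_true),
            E = cells$e0[match(.data$cell_id, cells$cell_id)] *
              (1 + expression$slope_per_min * .data$time_min)
          ) |>
          dplyr::select("spot_id", "cell_id", "frame", "time_min",
                        "x", "y", "a_true", "ratio_true", "E")
      }
    }
  })
  ground_truth <- if (length(gt)) dplyr::bind_rows(gt) else
    tibble::tibble(spot_id = character(0), cell_id = character(0),
                   frame = integer(0), time_min = numeric(0),
                   x = numeric(0), y = numeric(0), a_true = numeric(0),
                   ratio_true = numeric(0), E = numeric(0))
  readr::write_csv(ground_truth, file.path(out_dir, "ground_truth.csv"))
  write_layout(layout, file.path(out_dir, "layout.csv"))
  yaml::write_yaml(list(seed = seed, n_spots = n_spots,
                        time_grid = time_grid,
                        spot_conditions = as.list(spot_conditions)),
                   file.path(out_dir, "config.yaml"))
  invisible(list(dir = out_dir, files = files, ground_truth = ground_truth,
                 layout = layout))
}

#' Read a rendered spot movie back from disk
#'
#' @param dir Directory written by [simulate_experiment()].
#' @param spot_id Spot identifier.
#' @param bit_max Intensity scale used at write time.
#' @return A list of per-frame `list(cfp, fret, nuclear)` matrices in a.u.
#' @export
read_spot_stack <- function(dir, spot_id, bit_max = 65535) {
  chans <- lapply(c(CFP = "CFP", FRET = "FRET", NUC = "NUC"), function(ch) {
    path <- file.path(dir, paste0(spot_id, "_", ch, ".tif"))
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) p * bit_max)
  })
  lapply(seq_along(chans$CFP), function(f) {
    list(cfp = chans$CFP[[f]], fret = chans$FRET[[f]],
         nuclear = chans$NUC[[f]])
  })
}
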