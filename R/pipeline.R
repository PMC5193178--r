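#' Demo pipeline configuration
#'
#' A small end-to-end configuration: two biosensors, a vehicle condition,
#' two single stimuli and their combination, one dish (spot layout) per
#' condition.
#'
#' @param out_dir Output directory for pipeline artifacts.
#' @param seed Integer seed.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("fretarray_demo_"), seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    layout = list(n_rows = 1, n_cols = 2, spot_diameter_um = 200,
                  pitch_um = 1125,
                  biosensors = c("ERK_strong", "AKT_middle")),
    models = list(
      list(biosensor_id = "ERK_strong", response_class = "strong"),
      list(biosensor_id = "AKT_middle", response_class = "middle")
    ),
    conditions = list(
      list(condition_id = "vehicle"),
      list(condition_id = "egf", stimuli = list(EGF = 100),
           stimulation_time = 9),
      list(condition_id = "igf", stimuli = list(IGF1 = 100),
           stimulation_time = 9),
      list(condition_id = "egf_igf", stimuli = list(EGF = 100, IGF1 = 100),
           stimulation_time = 9, interaction_gamma = 0)
    ),
    simulate = list(n_cells_per_spot = 5, time_interval_min = 3,
                    duration_min = 36),
    image = list(width = 96, height = 96, offset = 100, noise_sd = 2),
    analysis = list(cfp_min = 700, cfp_max = 8000, k_patterns = 3,
                    alpha = 0.05, adjust = "BH", min_area = 30,
                    max_displacement = 15, min_track_length = 2)
  )
}

config_models <- function(config) {
  dplyr::bind_rows(lapply(config$models, function(m) {
    do.call(biosensor_model, m)
  }))
}

config_conditions <- function(config) {
  dplyr::bind_rows(lapply(config$conditions, function(co) {
    stimuli <- if (!is.null(co$stimuli)) unlist(co$stimuli) else NULL
    condition_spec(co$condition_id, stimuli,
                   stimulation_time = co$stimulation_time %||% 30,
                   interaction_gamma = co$interaction_gamma %||% 0)
  }))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order:
#' `simulate` (render one image-stack directory per condition),
#' `segment` (quantify and track every spot movie into measurements),
#' `trajectories` (expression gate, baseline and vehicle normalization,
#' condition summaries, QC), `signatures` (per-biosensor K-means patterns
#' and cluster proportions), `pca` (condition-level embedding), and
#' `synergy` (interaction scores for derived stimulus pairs). All artifacts
#' are plain CSV/JSON under `config$out_dir`; re-running with the same
#' config and seed reproduces them bit for bit.
#'
#' @param config Config list (see [demo_config()] /
#'   [read_pipeline_config()]).
#' @return Invisibly, a manifest list (stages run, timings, artifact
#'   paths, cell counts); also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir %||% stop("config needs `out_dir`",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- config_models(config)
  conditions <- config_conditions(config)
  stim_time <- max(conditions$stimulation_time)
  lay <- config$layout
  layout <- make_layout(lay$n_rows, lay$n_cols, lay$spot_diameter_um,
                        lay$pitch_um,
                        unlist(lay$biosensors %||% models$biosensor_id[1]))
  camera <- camera_params(width = config$image$width,
                          height = config$image$height,
                          offset = config$image$offset,
                          noise_sd = config$image$noise_sd)
  time_grid <- seq(0, config$simulate$duration_min,
                   by = config$simulate$time_interval_min)
  manifest <- list(seed = config$seed, stages = list(), artifacts = list())
  timer <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    manifest$stages[[stage]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[fretarray] stage %-12s done (%.1fs)", stage,
                    manifest$stages[[stage]]$seconds))
    value
  }
  stages <- config$stages
  an <- config$analysis

  if ("simulate" %in% stages) {
    timer("simulate", {
      for (ci in seq_len(nrow(conditions))) {
        cond <- conditions[ci, ]
        simulate_experiment(
          layout, models, cond,
          n_cells_per_spot = config$simulate$n_cells_per_spot,
          time_grid = time_grid, camera = camera,
          out_dir = file.path(out_dir, "images", cond$condition_id),
          seed = config$seed + ci)
      }
    })
  }

  measurements <- NULL
  if ("segment" %in% stages) {
    measurements <- timer("segment", {
      purrr::map_dfr(seq_len(nrow(conditions)), function(ci) {
        cond <- conditions[ci, ]
        dir <- file.path(out_dir, "images", cond$condition_id)
        purrr::map_dfr(seq_len(nrow(layout)), function(si) {
          spot <- layout[si, ]
          frames <- read_spot_stack(dir, spot$spot_id)
          m <- quantify_stack(frames, time_grid, spot_id = spot$spot_id,
                              min_area = an$min_area)
          m <- link_rois(m, max_displacement = an$max_displacement,
                         min_length = an$min_track_length)
          m$cell_id <- paste(cond$condition_id, m$cell_id, sep = "_")
          m$biosensor_id <- spot$biosensor_id
          m$condition_id <- cond$condition_id
          m$replicate_id <- spot$replicate_index + 1
          m
        })
      })
    })
    write_measurements(measurements,
                       file.path(out_dir, "measurements.csv"))
    manifest$artifacts$measurements <- "measurements.csv"
  }

  trajectories <- NULL
  summaries <- NULL
  if ("trajectories" %in% stages) {
    if (is.null(measurements)) {
      measurements <- read_measurements(file.path(out_dir,
                                                  "measurements.csv"))
    }
    res <- timer("trajectories", {
      traj <- filter_expression(measurements, an$cfp_min, an$cfp_max,
                                stimulation_time = stim_time)
      traj <- normalize_baseline(traj, stim_time)
      vehicle_id <- conditions$condition_id[conditions$is_vehicle]
      if (length(vehicle_id) >= 1) {
        veh <- condition_mean_sem(
          dplyr::filter(traj, .data$condition_id == vehicle_id[1]))
        traj <- normalize_vehicle(traj, dplyr::select(veh, -"condition_id"))
      }
      list(traj = traj, summaries = condition_mean_sem(traj))
    })
    trajectories <- res$traj
    summaries <- res$summaries
    readr::write_csv(trajectories, file.path(out_dir, "trajectories.csv"))
    readr::write_csv(summaries, file.path(out_dir, "summaries.csv"))
    qc <- list(
      n_cells = length(unique(trajectories$cell_id)),
      cells_per_condition = trajectories |>
        dplyr::distinct(.data$condition_id, .data$cell_id) |>
        dplyr::count(.data$condition_id) |>
        as.list()
    )
    jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$artifacts$trajectories <- "trajectories.csv"
  }

  if ("signatures" %in% stages) {
    timer("signatures", {
      sigs <- purrr::map_dfr(unique(trajectories$biosensor_id),
                             function(b) {
        sub <- dplyr::filter(trajectories, .data$biosensor_id == b)
        k <- min(an$k_patterns, length(unique(sub$cell_id)))
        km <- kmeans_patterns(sub, k = k, seed = config$seed)
        cluster_proportions(
          km$labels,
          dplyr::distinct(sub, .data$cell_id, .data$condition_id) |>
            dplyr::mutate(biosensor_id = b),
          k = k)
      })
      readr::write_csv(sigs, file.path(out_dir, "signatures.csv"))
    })
    manifest$artifacts$signatures <- "signatures.csv"
  }

  if ("pca" %in% stages) {
    timer("pca", {
      pm <- build_condition_matrix(
        dplyr::rename(summaries, group_id = "condition_id"))
      emb <- fret_pca(pm)
      readr::write_csv(emb$scores, file.path(out_dir, "pca_scores.csv"))
      readr::write_csv(emb$loadings, file.path(out_dir, "pca_loadings.csv"))
    })
    manifest$artifacts$pca <- c("pca_scores.csv", "pca_loadings.csv")
  }

  if ("synergy" %in% stages) {
    timer("synergy", {
      vehicle_id <- conditions$condition_id[conditions$is_vehicle]
      if (length(vehicle_id) == 0) {
        stop("synergy stage requires a vehicle condition", call. = FALSE)
      }
      # untreated mean on the raw (pre-vehicle-normalized) scale
      raw <- filter_expression(measurements, an$cfp_min, an$cfp_max,
                               stimulation_time = stim_time)
      raw <- normalize_baseline(raw, stim_time)
      veh <- condition_mean_sem(
        dplyr::filter(raw, .data$condition_id == vehicle_id[1]))
      responses <- synergy_normalize(
        dplyr::filter(raw, !.data$condition_id %in% vehicle_id),
        dplyr::select(veh, -"condition_id"), stim_time)
      aucs <- compute_aucs(responses, stim_time)
      pairs <- derive_pairs(conditions)
      if (nrow(pairs) > 0) {
        scores <- synergy_scores(aucs, pairs, alpha = an$alpha,
                                 adjust = an$adjust)
        readr::write_csv(scores, file.path(out_dir, "synergy.csv"))
        map <- synergy_map(scores)
        jsonlite::write_json(
          list(row_order = map$row_order, col_order = map$col_order,
               mask = map$mask),
          file.path(out_dir, "synergy_map.json"), auto_unbox = TRUE)
        manifest$artifacts$synergy <- "synergy.csv"
      }
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
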