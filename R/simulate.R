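#' @importFrom rlang .data
NULL

#' Default per-cell variability and noise parameters
#'
#' @param sigma Additive measurement noise on the FRET ratio, expressed as a
#'   standard deviation relative to the baseline ratio `R0`.
#' @param amplitude_cv Coefficient of variation of the per-cell log-normal
#'   amplitude factor (mean fixed at 1).
#' @param ratio_drift_per_min Multiplicative linear drift of the measured
#'   ratio per minute, shared by all conditions (what vehicle normalization
#'   removes).
#' @param pulse_period,pulse_depth Period (minutes) and relative depth of the
#'   periodic modulation applied to pulsatile cells.
#' @return A named list.
#' @export
cell_noise_params <- function(sigma = 0.01, amplitude_cv = 0.25,
                              ratio_drift_per_min = 0,
                              pulse_period = 30, pulse_depth = 0.5) {
  list(sigma = sigma, amplitude_cv = amplitude_cv,
       ratio_drift_per_min = ratio_drift_per_min,
       pulse_period = pulse_period, pulse_depth = pulse_depth)
}

#' Default biosensor expression parameters
#'
#' Expression rises roughly linearly over the movie (biosensor keeps being
#' produced), which raises both emission channels while leaving their ratio
#' untouched.
#'
#' @param mean_au Typical pre-stimulus mean CFP intensity (a.u.).
#' @param cv Log-normal coefficient of variation across cells.
#' @param slope_per_min Relative linear increase of expression per minute.
#' @return A named list.
#' @export
expression_params <- function(mean_au = 2000, cv = 0.4,
                              slope_per_min = 0.002) {
  list(mean_au = mean_au, cv = cv, slope_per_min = slope_per_min)
}

# Deterministic population-level response profile (amplitude included),
# before per-cell variability. Returns numeric vector over time_grid.
response_profile <- function(model, condition, time_grid) {
  stimuli <- condition$stimuli[[1]]
  t0 <- condition$stimulation_time
  dt <- pmax(time_grid - t0, 0)
  active <- time_grid >= t0
  if (length(stimuli) == 0) {
    return(numeric(length(time_grid)))
  }
  hill <- function(c) {
    if (c <= 0) return(0)
    c^model$hill_n / (c^model$hill_n + model$hill_ec50^model$hill_n)
  }
  shape <- (1 - exp(-dt / model$rise_tau)) * exp(-dt / model$decay_tau)
  shape[!active] <- 0
  terms <- vapply(stimuli, function(c) hill(c), numeric(1))
  base <- sum(terms) * shape
  if (length(stimuli) >= 2 && condition$interaction_gamma != 0) {
    base <- base + condition$interaction_gamma * mean(terms) * shape
  }
  model$amplitude * base
}

# Vectorized activity simulation: n_cells x n_time matrix of a(t).
simulate_activity_matrix <- function(model, condition, n_cells, time_grid,
                                     noise = cell_noise_params()) {
  profile <- response_profile(model, condition, time_grid)
  s <- sqrt(log(1 + noise$amplitude_cv^2))
  amp <- stats::rlnorm(n_cells, meanlog = -s^2 / 2, sdlog = s)
  a <- outer(amp, profile)
  pulsatile <- stats::runif(n_cells) < model$pulsatile_fraction
  if (any(pulsatile)) {
    t0 <- condition$stimulation_time
    phase <- stats::runif(n_cells, 0, 2 * pi)
    dt <- pmax(time_grid - t0, 0)
    for (i in which(pulsatile)) {
      mod <- 1 + noise$pulse_depth *
        sin(2 * pi * dt / noise$pulse_period + phase[i])
      a[i, ] <- a[i, ] * ifelse(time_grid >= t0, mod, 1)
    }
  }
  a
}

#' Simulate a single-cell activity trajectory
#'
#' Draws one cell's activity trace `a(t)` under the rise-times-decay Hill
#' model: zero before the stimulation time, then the summed per-stimulus
#' transient with optional interaction cross-term, a log-normal per-cell
#' amplitude, and (for pulsatile cells) a periodic modulation.
#'
#' @param model A [biosensor_model()].
#' @param condition A [condition_spec()].
#' @param time_grid Strictly increasing acquisition times in minutes.
#' @param cell_noise See [cell_noise_params()]; `sigma` is ignored here
#'   (activity is noiseless ground truth; noise enters the measured ratio).
#' @param seed Integer seed; the same seed reproduces the same trace.
#' @return A tibble with columns `time_min`, `activity`, `ratio_true`
#'   (`R0 * (1 + a(t))`).
#' @export
simulate_trajectory <- function(model, condition, time_grid,
                                cell_noise = cell_noise_params(),
                                seed = 1) {
  if (length(time_grid) == 0) {
    stop("`time_grid` must be non-empty", call. = FALSE)
  }
  if (any(diff(time_grid) <= 0)) {
    stop("`time_grid` must be strictly increasing", call. = FALSE)
  }
  a <- withr::with_seed(seed, {
    simulate_activity_matrix(model, condition, 1, time_grid, cell_noise)
  })[1, ]
  tibble::tibble(
    time_min = time_grid,
    activity = a,
    ratio_true = model$baseline_ratio * (1 + a)
  )
}

#' Simulate a single-cell trajectory experiment
#'
#' Generates measured single-cell FRET-ratio time courses for every
#' biosensor x condition x replicate combination, with per-cell amplitude
#' variability, measurement noise on the ratio, shared multiplicative drift,
#' and per-cell expression levels (pre-stimulus mean CFP) for the expression
#' gate and expression-response correlation.
#'
#' @param models Tibble of [biosensor_model()] rows.
#' @param conditions Tibble of [condition_spec()] rows (see
#'   [condition_table()]).
#' @param n_cells Cells per biosensor x condition x replicate.
#' @param time_grid Acquisition times, minutes (default 3-min interval over
#'   300 min).
#' @param n_replicates Replicate experiments per combination.
#' @param cell_noise See [cell_noise_params()].
#' @param expression See [expression_params()].
#' @param seed Integer seed for full reproducibility.
#' @return A long tibble: `cell_id`, `biosensor_id`, `condition_id`,
#'   `replicate_id`, `time_min`, `ratio`, `mean_cfp`, `activity_true`.
#' @export
simulate_trajectory_experiment <- function(models, conditions, n_cells = 50,
                                           time_grid = seq(0, 300, by = 3),
                                           n_replicates = 1,
                                           cell_noise = cell_noise_params(),
                                           expression = expression_params(),
                                           seed = 1) {
  stopifnot(nrow(models) >= 1, nrow(conditions) >= 1, n_cells >= 1)
  n_t <- length(time_grid)
  withr::with_seed(seed, {
    blocks <- list()
    cell_counter <- 0L
    for (bi in seq_len(nrow(models))) {
      model <- models[bi, ]
      for (ci in seq_len(nrow(conditions))) {
        condition <- conditions[ci, ]
        for (rep_i in seq_len(n_replicates)) {
          a <- simulate_activity_matrix(model, condition, n_cells, time_grid,
                                        cell_noise)
          drift <- 1 + cell_noise$ratio_drift_per_min * time_grid
          ratio_true <- model$baseline_ratio * (1 + a)
          ratio <- sweep(ratio_true, 2, drift, `*`) +
            matrix(stats::rnorm(n_cells * n_t, 0,
                                cell_noise$sigma * model$baseline_ratio),
                   n_cells, n_t)
          s_e <- sqrt(log(1 + expression$cv^2))
          e0 <- expression$mean_au *
            stats::rlnorm(n_cells, -s_e^2 / 2, s_e)
          cfp <- outer(e0, 1 + expression$slope_per_min * time_grid)
          ids <- sprintf("cell_%06d", cell_counter + seq_len(n_cells))
          cell_counter <- cell_counter + n_cells
          blocks[[length(blocks) + 1L]] <- tibble::tibble(
            cell_id = rep(ids, each = n_t),
            biosensor_id = model$biosensor_id,
            condition_id = condition$condition_id,
            replicate_id = rep_i,
            time_min = rep(time_grid, times = n_cells),
            ratio = as.vector(t(ratio)),
            mean_cfp = as.vector(t(cfp)),
            activity_true = as.vector(t(a))
          )
        }
      }
    }
    dplyr::bind_rows(blocks)
  })
}
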