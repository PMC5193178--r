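#' Biosensor response model
#'
#' Parameterizes the activity kinetics of one FRET biosensor. The response to
#' a step stimulus is a rise-times-decay transient scaled by a Hill dose
#' factor: after stimulation at time `t0`,
#' `a(t) = A * H(c) * (1 - exp(-dt/rise_tau)) * exp(-dt/decay_tau)` with
#' `H(c) = c^n / (c^n + ec50^n)` and `dt = t - t0`. Response classes carry
#' amplitude presets (fractional ratio change at saturating dose):
#' strong 0.4, middle 0.15, weak 0.05, nonresponding 0.
#'
#' @param biosensor_id Identifier string.
#' @param response_class One of `"strong"`, `"middle"`, `"weak"`,
#'   `"nonresponding"`; sets the default amplitude and kinetics.
#' @param amplitude Peak fractional ratio change at saturating dose
#'   (overrides the class preset).
#' @param rise_tau,decay_tau Rise and decay time constants in minutes.
#' @param hill_ec50 Half-maximal concentration in ng/mL.
#' @param hill_n Hill coefficient (dimensionless).
#' @param pulsatile_fraction Probability in `[0, 1]` that a cell shows
#'   periodic (pulsatile) modulation of its response.
#' @param baseline_ratio Resting FRET/CFP ratio `R0` (> 0).
#'
#' @return A one-row tibble of class `biosensor_model`.
#' @examples
#' biosensor_model("ERK", "strong")
#' @export
biosensor_model <- function(biosensor_id,
                            response_class = c("strong", "middle", "weak",
                                               "nonresponding"),
                            amplitude = NULL,
                            rise_tau = NULL, decay_tau = NULL,
                            hill_ec50 = 10, hill_n = 1,
                            pulsatile_fraction = 0,
                            baseline_ratio = 1.2) {
  response_class <- match.arg(response_class)
  presets <- list(
    strong        = list(amplitude = 0.40, rise_tau = 8,  decay_tau = 60),
    middle        = list(amplitude = 0.15, rise_tau = 15, decay_tau = 90),
    weak          = list(amplitude = 0.05, rise_tau = 25, decay_tau = 120),
    nonresponding = list(amplitude = 0.00, rise_tau = 15, decay_tau = 90)
  )[[response_class]]
  amplitude <- amplitude %||% presets$amplitude
  rise_tau <- rise_tau %||% presets$rise_tau
  decay_tau <- decay_tau %||% presets$decay_tau
  stopifnot(amplitude >= 0, rise_tau > 0, decay_tau > 0,
            pulsatile_fraction >= 0, pulsatile_fraction <= 1,
            baseline_ratio > 0, hill_ec50 >= 0)
  out <- tibble::tibble(
    biosensor_id = as.character(biosensor_id),
    response_class = response_class,
    amplitude = amplitude,
    rise_tau = rise_tau,
    decay_tau = decay_tau,
    hill_ec50 = hill_ec50,
    hill_n = hill_n,
    pulsatile_fraction = pulsatile_fraction,
    baseline_ratio = baseline_ratio
  )
  class(out) <- c("biosensor_model", class(out))
  out
}

#' Stimulation condition
#'
#' Describes one treatment condition: zero (vehicle), one, or two stimuli
#' with concentrations, a stimulation time, and an injected interaction term
#' for combined stimuli. With `interaction_gamma = 0` a combined condition is
#' additive by construction: its activity is the sum of the single-stimulus
#' responses. A nonzero `interaction_gamma` adds
#' `gamma * (r_A(t) + r_B(t)) / 2` on top, injecting synergy (> 0) or
#' antagonism (< 0) whose AUC is `gamma` times the mean single-stimulus AUC.
#'
#' @param condition_id Identifier string.
#' @param stimuli Named numeric vector of concentrations in ng/mL (e.g.
#'   `c(EGF = 100)`), or `NULL` for a vehicle condition.
#' @param stimulation_time Time of stimulus addition, minutes.
#' @param interaction_gamma Dimensionless non-additivity; 0 = additive.
#'
#' @return A one-row tibble of class `condition_spec` with a `stimuli`
#'   list-column.
#' @examples
#' condition_spec("egf100", c(EGF = 100))
#' condition_spec("vehicle", NULL)
#' @export
condition_spec <- function(condition_id, stimuli = NULL,
                           stimulation_time = 30, interaction_gamma = 0) {
  if (!is.null(stimuli)) {
    stopifnot(is.numeric(stimuli), all(stimuli >= 0),
              !is.null(names(stimuli)), all(nzchar(names(stimuli))))
  }
  is_vehicle <- is.null(stimuli) || length(stimuli) == 0
  out <- tibble::tibble(
    condition_id = as.character(condition_id),
    stimuli = list(if (is_vehicle) numeric(0) else stimuli),
    stimulation_time = stimulation_time,
    is_vehicle = is_vehicle,
    interaction_gamma = interaction_gamma
  )
  class(out) <- c("condition_spec", class(out))
  out
}

#' Bind several condition specs into one table
#' @param ... `condition_spec` rows (or lists of them).
#' @return A tibble with one row per condition.
#' @export
condition_table <- function(...) {
  specs <- unlist(lapply(list(...), function(x) {
    if (inherits(x, "tbl_df")) list(x) else x
  }), recursive = FALSE)
  dplyr::bind_rows(specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
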