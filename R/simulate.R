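## Sensorgram simulation: mono-exponential 1:1 kinetics plus Gaussian
## instrument noise and optional linear baseline drift.

sample_times <- function(window, interval) {
  seq(0, window, by = interval)
}

add_instrument_effects <- function(clean, times, instrument, seed) {
  y <- clean + instrument$baseline_drift * times
  if (instrument$noise_sd > 0) {
    if (is.null(seed)) {
      stop("a `seed` must be supplied when `noise_sd` > 0 so that every ",
           "noisy trace is reproducible", call. = FALSE)
    }
    y <- y + with_seed(seed, stats::rnorm(length(times), 0,
                                          instrument$noise_sd))
  }
  y
}

#' Simulate an association-phase sensorgram
#'
#' The noiseless trace follows the mono-exponential approach to
#' equilibrium
#' \deqn{R_t = (R_{eq} - R_0)(1 - e^{-k_{on} t}) + R_0,}
#' with \eqn{k_{on} = k_{ass} C + k_{diss}} and \eqn{R_{eq}} from the
#' binding isotherm. Injection is treated as instantaneous and well mixed;
#' mass-transport limitation is not modelled.
#'
#' @param system A [binding_system()].
#' @param concentration Analyte concentration, M (>= 0).
#' @param R0 Initial response, arcsec.
#' @param instrument An [instrument_config()].
#' @param condition A [buffer_condition()] carried as metadata.
#' @param seed Integer seed; required whenever `instrument$noise_sd > 0`.
#'   The same seed reproduces the trace bit for bit.
#' @return A [sensorgram()] with `truth` set to `system`.
#' @examples
#' sys <- binding_system(4.1e4, 2.5e-3, R_max = 100)
#' sg <- simulate_association(sys, 6e-7, instrument = instrument_config(
#'   noise_sd = 0))
#' @export
simulate_association <- function(system, concentration, R0 = 0,
                                 instrument = instrument_config(),
                                 condition = buffer_condition(),
                                 seed = NULL) {
  stopifnot(inherits(system, "binding_system"),
            inherits(instrument, "instrument_config"))
  check_scalar(concentration, "concentration", lower = 0)
  check_scalar(R0, "R0")
  times <- sample_times(instrument$association_window,
                        instrument$sampling_interval)
  kon <- kon_observed(system, concentration)
  Req <- if (system$K_D > 0) equilibrium_response(system, concentration)
         else system$R_max * (concentration > 0)
  clean <- (Req - R0) * (1 - exp(-kon * times)) + R0
  responses <- add_instrument_effects(clean, times, instrument, seed)
  sensorgram("association", times, responses,
             analyte_concentration = concentration, R0 = R0,
             condition = condition, truth = system, seed = seed)
}

#' Simulate a dissociation-phase sensorgram
#'
#' After the analyte is washed out the surface-bound complex decays
#' mono-exponentially,
#' \deqn{R_t = A e^{-k_{diss} t} + \mathrm{offset},}
#' with amplitude `A = R_start - offset`. A non-zero offset models
#' incomplete dissociation; the default 0 matches the ideal wash-out.
#'
#' @param system A [binding_system()] supplying `k_diss`.
#' @param R_start Response at the start of the dissociation phase, arcsec
#'   (>= 0).
#' @param instrument An [instrument_config()].
#' @param offset Residual response the trace decays towards, arcsec.
#' @param condition Buffer metadata.
#' @param seed Integer seed; required when noise is on.
#' @return A [sensorgram()] with phase `"dissociation"`.
#' @export
simulate_dissociation <- function(system, R_start,
                                  instrument = instrument_config(),
                                  offset = 0,
                                  condition = buffer_condition(),
                                  seed = NULL) {
  stopifnot(inherits(system, "binding_system"),
            inherits(instrument, "instrument_config"))
  check_scalar(R_start, "R_start", lower = 0)
  check_scalar(offset, "offset")
  times <- sample_times(instrument$dissociation_window,
                        instrument$sampling_interval)
  clean <- (R_start - offset) * exp(-system$k_diss * times) + offset
  responses <- add_instrument_effects(clean, times, instrument, seed)
  sensorgram("dissociation", times, responses, R0 = R_start,
             condition = condition, truth = system, seed = seed)
}

#' Default titration grid: six log-spaced concentrations, 16 to 600 nM
#'
#' @param n Number of concentrations.
#' @param from,to Range in M.
#' @return Numeric vector of concentrations in M.
#' @export
default_concentration_grid <- function(n = 6, from = 16e-9, to = 600e-9) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate a full titration series
#'
#' One association curve per concentration (optionally a paired
#' dissociation starting from each curve's final noiseless response),
#' sharing one buffer condition and instrument configuration. Per-curve
#' noise seeds are derived deterministically from `seed`.
#'
#' @param system A [binding_system()].
#' @param concentrations Analyte concentrations, M; >= 2 distinct values.
#' @param instrument An [instrument_config()].
#' @param condition A [buffer_condition()].
#' @param seed Integer seed; required when noise is on.
#' @param with_dissociation Also simulate a paired dissociation per curve.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(system,
                               concentrations = default_concentration_grid(),
                               instrument = instrument_config(),
                               condition = buffer_condition(),
                               seed = NULL,
                               with_dissociation = FALSE) {
  stopifnot(inherits(system, "binding_system"))
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) < 2L) {
    stop("need at least 2 concentrations", call. = FALSE)
  }
  if (anyDuplicated(concentrations)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  ## per-curve sub-seeds: deterministic, well separated, < 2^31
  ## (double arithmetic before the modulo avoids integer overflow)
  sub_seed <- function(i, k) {
    if (is.null(seed)) NULL else
      as.integer((as.numeric(seed) * 1000 + i * 10 + k) %%
                   .Machine$integer.max)
  }
  assoc <- vector("list", length(concentrations))
  dissoc <- if (with_dissociation) vector("list", length(concentrations))
            else NULL
  for (i in seq_along(concentrations)) {
    assoc[[i]] <- simulate_association(system, concentrations[i],
                                       instrument = instrument,
                                       condition = condition,
                                       seed = sub_seed(i, 1L))
    if (with_dissociation) {
      R_end <- if (system$K_D > 0) {
        Req <- equilibrium_response(system, concentrations[i])
        kon <- kon_observed(system, concentrations[i])
        Req * (1 - exp(-kon * instrument$association_window))
      } else {
        system$R_max
      }
      dissoc[[i]] <- simulate_dissociation(system, R_end,
                                           instrument = instrument,
                                           condition = condition,
                                           seed = sub_seed(i, 2L))
    }
  }
  titration_series(assoc, condition = condition, dissociations = dissoc)
}
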