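#' Ground-truth kinetic description of a 1:1 binding interaction
#'
#' A `binding_system` holds the intrinsic rate constants of a reversible
#' bimolecular interaction between a soluble analyte and an immobilised
#' receptor, together with the asymptotic instrument response at receptor
#' saturation. It is the "truth" object from which sensorgrams are
#' simulated and against which inference is checked.
#'
#' @param k_ass Association rate constant, in 1/(M s). Must be > 0.
#' @param k_diss Dissociation rate constant, in 1/s. Must be >= 0; zero
#'   describes an effectively irreversible binder.
#' @param R_max Asymptotic equilibrium response at saturating analyte
#'   concentration, in arcsec. Must be > 0.
#' @param label Free-text label for reports.
#' @return An object of class `binding_system` with fields `k_ass`,
#'   `k_diss`, `R_max`, `label` and the derived `K_D = k_diss/k_ass` (M).
#' @examples
#' sys <- binding_system(k_ass = 4.1e4, k_diss = 2.5e-3, R_max = 100)
#' sys$K_D  # 6.1e-8 M
#' @export
binding_system <- function(k_ass, k_diss, R_max = 100, label = "") {
  check_scalar(k_ass, "k_ass")
  check_scalar(k_diss, "k_diss", lower = 0)
  check_scalar(R_max, "R_max")
  if (k_ass <= 0) stop("`k_ass` must be > 0", call. = FALSE)
  if (R_max <= 0) stop("`R_max` must be > 0", call. = FALSE)
  structure(
    list(k_ass = k_ass, k_diss = k_diss, R_max = R_max,
         K_D = k_diss / k_ass, label = as.character(label)[1]),
    class = "binding_system"
  )
}

#' @export
print.binding_system <- function(x, ...) {
  cat("1:1 binding system", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat(sprintf("  k_ass = %.3g 1/(M s), k_diss = %.3g 1/s, K_D = %.3g M\n",
              x$k_ass, x$k_diss, x$K_D))
  cat(sprintf("  R_max = %.3g arcsec\n", x$R_max))
  invisible(x)
}

#' Instrument acquisition settings for simulated sensorgrams
#'
#' Defaults describe a cuvette-based resonant mirror instrument: short-term
#' Gaussian noise well below 1 arcsec, 0.4 s sampling, a 6-minute
#' association window and a 10-minute dissociation window, negligible
#' baseline drift, thermostatted at 37 degrees C.
#'
#' @param noise_sd Gaussian noise standard deviation, arcsec (>= 0).
#' @param sampling_interval Time between samples, s (> 0).
#' @param association_window Association acquisition length, s (> 0).
#' @param dissociation_window Dissociation acquisition length, s (> 0).
#' @param baseline_drift Linear drift, arcsec/s.
#' @param temperature Cell temperature, degrees C (metadata only).
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(noise_sd = 0.5,
                              sampling_interval = 0.4,
                              association_window = 360,
                              dissociation_window = 600,
                              baseline_drift = 0,
                              temperature = 37) {
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(sampling_interval, "sampling_interval")
  check_scalar(association_window, "association_window")
  check_scalar(dissociation_window, "dissociation_window")
  check_scalar(baseline_drift, "baseline_drift")
  if (sampling_interval <= 0) stop("`sampling_interval` must be > 0",
                                   call. = FALSE)
  if (association_window <= 0 || dissociation_window <= 0) {
    stop("acquisition windows must be > 0", call. = FALSE)
  }
  structure(
    list(noise_sd = noise_sd, sampling_interval = sampling_interval,
         association_window = association_window,
         dissociation_window = dissociation_window,
         baseline_drift = baseline_drift, temperature = temperature),
    class = "instrument_config"
  )
}

#' Buffer condition metadata
#'
#' @param pH Buffer pH, in (0, 14).
#' @param nacl Added NaCl, mM (>= 0).
#' @param label Free-text label, e.g. "PBS + 140 mM NaCl".
#' @return An object of class `buffer_condition`.
#' @export
buffer_condition <- function(pH = 7.4, nacl = 140, label = "") {
  check_scalar(pH, "pH")
  check_scalar(nacl, "nacl", lower = 0)
  if (pH <= 0 || pH >= 14) stop("`pH` must be in (0, 14)", call. = FALSE)
  structure(list(pH = pH, nacl = nacl, label = as.character(label)[1]),
            class = "buffer_condition")
}

#' Observed pseudo-first-order association rate
#'
#' Under pseudo-first-order conditions (analyte in large excess over
#' binding sites) the observed exponential rate of the association phase is
#' affine in the analyte concentration:
#' \deqn{k_{on} = k_{ass} C + k_{diss}.}
#' Its slope and intercept over a titration recover the intrinsic rate
#' constants.
#'
#' @param system A [binding_system()].
#' @param concentration Analyte concentration, M (>= 0).
#' @return Observed rate in 1/s.
#' @examples
#' sys <- binding_system(4.1e4, 2.5e-3)
#' kon_observed(sys, 6e-7)  # 0.0271 1/s
#' @export
kon_observed <- function(system, concentration) {
  stopifnot(inherits(system, "binding_system"))
  check_scalar(concentration, "concentration", lower = 0)
  system$k_ass * concentration + system$k_diss
}

#' Equilibrium response of the binding isotherm
#'
#' The plateau (extent of binding) of an association curve follows the
#' rectangular hyperbola
#' \deqn{R_{eq} = R_{max} \frac{C/K_D}{1 + C/K_D},}
#' where \eqn{K_D = k_{diss}/k_{ass}}.
#'
#' @param system A [binding_system()]; must have `k_diss > 0` so that the
#'   isotherm is non-degenerate.
#' @param concentration Analyte concentration, M (>= 0).
#' @return Equilibrium response in arcsec, in `[0, R_max)`.
#' @examples
#' sys <- binding_system(4.1e4, 2.5e-3, R_max = 100)
#' equilibrium_response(sys, sys$K_D)      # half-saturation: 50
#' equilibrium_response(sys, 3 * sys$K_D)  # 75
#' @export
equilibrium_response <- function(system, concentration) {
  stopifnot(inherits(system, "binding_system"))
  check_scalar(concentration, "concentration", lower = 0)
  if (system$K_D <= 0) {
    stop("degenerate isotherm: K_D = 0 (k_diss = 0); the equilibrium ",
         "response is R_max at any positive concentration", call. = FALSE)
  }
  x <- concentration / system$K_D
  system$R_max * x / (1 + x)
}
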