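## Two-ligand, one-site competitive binding.
##
## Both ligands compete for the same receptor sites with mutual exclusion:
##   d theta_A/dt = ka_A C_A (1 - theta_A - theta_C) - kd_A theta_A
##   d theta_C/dt = ka_C C_C (1 - theta_A - theta_C) - kd_C theta_C
## With constant concentrations within a phase this is a linear
## constant-coefficient system, solved here in closed form by
## eigendecomposition (a fixed-step RK4 backs up the rare defective case),
## so the trajectories are exact rather than integrator-tolerance-limited.

#' Define a pre-saturation competition protocol
#'
#' The receptor surface is first equilibrated with a competitor for
#' `presaturation_time` seconds; the analyte is then added (with the
#' competitor still in solution, as in a cuvette-based assay) and the
#' response is followed for `observation_time` seconds.
#'
#' @param analyte A [binding_system()] for the analyte.
#' @param analyte_concentration Analyte concentration in the observation
#'   phase, M.
#' @param competitor A [binding_system()] for the competitor.
#' @param competitor_concentration Competitor concentration, M (0 turns
#'   the protocol into a plain association experiment).
#' @param analyte_mass,competitor_mass Molecular masses, kDa; the
#'   instrument signal is proportional to bound mass, so the competitor
#'   contributes `competitor_mass / analyte_mass` arcsec per occupied site
#'   relative to the analyte.
#' @param presaturation_time,observation_time Phase durations, s (> 0).
#' @return An object of class `competition_protocol`.
#' @export
competition_protocol <- function(analyte, analyte_concentration,
                                 competitor, competitor_concentration,
                                 analyte_mass = 16,
                                 competitor_mass = 1.1,
                                 presaturation_time = 600,
                                 observation_time = 360) {
  stopifnot(inherits(analyte, "binding_system"),
            inherits(competitor, "binding_system"))
  check_scalar(analyte_concentration, "analyte_concentration", lower = 0)
  check_scalar(competitor_concentration, "competitor_concentration",
               lower = 0)
  check_scalar(analyte_mass, "analyte_mass")
  check_scalar(competitor_mass, "competitor_mass")
  check_scalar(presaturation_time, "presaturation_time")
  check_scalar(observation_time, "observation_time")
  if (presaturation_time <= 0 || observation_time <= 0) {
    stop("phase durations must be > 0", call. = FALSE)
  }
  if (analyte_mass <= 0 || competitor_mass <= 0) {
    stop("molecular masses must be > 0", call. = FALSE)
  }
  structure(
    list(analyte = analyte,
         analyte_concentration = analyte_concentration,
         competitor = competitor,
         competitor_concentration = competitor_concentration,
         analyte_mass = analyte_mass, competitor_mass = competitor_mass,
         presaturation_time = presaturation_time,
         observation_time = observation_time),
    class = "competition_protocol"
  )
}

## Closed-form trajectory of the two-species occupancy system.
## theta0: length-2 start occupancies; a = ka*C per species; kd per species.
## Returns a 2 x length(times) matrix.
occupancy_trajectory <- function(theta0, a, kd, times) {
  b <- a
  M <- rbind(c(a[1] + kd[1], a[1]),
             c(a[2], a[2] + kd[2]))
  row_zero <- rowSums(abs(M)) == 0
  if (any(row_zero)) {
    ## a species with zero on-flux and zero off-rate stays frozen;
    ## the other reduces to a scalar linear ODE
    out <- matrix(0, 2, length(times))
    frozen <- which(row_zero)
    live <- setdiff(1:2, frozen)
    out[frozen, ] <- theta0[frozen]
    if (length(live) == 2L || length(live) == 0L) {
      out[1, ] <- theta0[1]; out[2, ] <- theta0[2]
      return(out)
    }
    k <- a[live] + kd[live]
    if (k == 0) {
      out[live, ] <- theta0[live]
    } else {
      frozen_occ <- sum(theta0[frozen])
      inf_occ <- a[live] * (1 - frozen_occ) / k
      out[live, ] <- inf_occ + (theta0[live] - inf_occ) * exp(-k * times)
    }
    return(out)
  }
  ev <- eigen(M)
  V <- ev$vectors
  usable <- all(abs(Im(ev$values)) < 1e-12) &&
    abs(det(V)) > 1e-10 * max(abs(V))^2
  if (usable) {
    lam <- Re(ev$values)
    V <- Re(V)
    theta_inf <- solve(M, b)
    c0 <- solve(V, theta0 - theta_inf)
    decay <- exp(outer(-lam, times))       # 2 x nt
    return(theta_inf + V %*% (c0 * decay))
  }
  occupancy_trajectory_rk4(theta0, a, kd, times)
}

## Fixed-step RK4 fallback for the (defective-eigensystem) corner case.
occupancy_trajectory_rk4 <- function(theta0, a, kd, times) {
  deriv <- function(th) {
    free <- 1 - th[1] - th[2]
    c(a[1] * free - kd[1] * th[1], a[2] * free - kd[2] * th[2])
  }
  rate_scale <- max(a + kd, 1e-6)
  h <- min(0.05 / rate_scale, if (length(times) > 1) min(diff(times)) else 1)
  out <- matrix(NA_real_, 2, length(times))
  th <- theta0
  t_now <- times[1]
  out[, 1] <- th
  for (i in seq_along(times)[-1]) {
    while (t_now < times[i] - 1e-12) {
      step <- min(h, times[i] - t_now)
      k1 <- deriv(th)
      k2 <- deriv(th + step / 2 * k1)
      k3 <- deriv(th + step / 2 * k2)
      k4 <- deriv(th + step * k3)
      th <- th + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + step
    }
    out[, i] <- th
  }
  out
}

#' Simulate a competitive pre-saturation assay
#'
#' Runs the two-phase protocol twice — once with the competitor at its
#' stated concentration ("pre-saturated" arm) and once with the competitor
#' absent ("free receptor" arm) — and returns the analyte-phase
#' sensorgrams plus the equilibrium-response reduction. The response is
#' mass-proportional: `capacity * (m_A * theta_A + m_C * theta_C) / m_A`
#' arcsec, so `capacity` is the response at full occupancy by the analyte.
#' With competitor concentration 0 the analyte-phase trace is exactly the
#' simple mono-exponential association.
#'
#' @param protocol A [competition_protocol()].
#' @param receptor_capacity Response at full analyte occupancy, arcsec.
#' @param instrument An [instrument_config()]; `association_window` is
#'   ignored in favour of the protocol's `observation_time`.
#' @param condition Buffer metadata.
#' @param seed Integer seed, required when noise is on; the two arms use
#'   derived sub-seeds.
#' @return A list of class `competition_result` with elements `free` and
#'   `presaturated` (analyte-phase [sensorgram()]s, responses in absolute
#'   arcsec), `R_eq_free` and `R_eq_presaturated` (noiseless analyte-phase
#'   rises at the end of the observation window), `reduction` (their
#'   fractional difference) and `theta_presat` (competitor occupancy at
#'   the end of the pre-saturation phase).
#' @export
simulate_competition <- function(protocol, receptor_capacity = 100,
                                 instrument = instrument_config(),
                                 condition = buffer_condition(),
                                 seed = NULL) {
  stopifnot(inherits(protocol, "competition_protocol"),
            inherits(instrument, "instrument_config"))
  check_scalar(receptor_capacity, "receptor_capacity")
  if (receptor_capacity <= 0) {
    stop("`receptor_capacity` must be > 0", call. = FALSE)
  }
  p <- protocol
  mass_ratio <- p$competitor_mass / p$analyte_mass
  times <- sample_times(p$observation_time, instrument$sampling_interval)

  run_arm <- function(cc, arm_seed) {
    ## phase 1: competitor only
    th0 <- c(0, 0)
    if (cc > 0) {
      th0 <- occupancy_trajectory(
        c(0, 0),
        a = c(0, p$competitor$k_ass * cc),
        kd = c(p$analyte$k_diss, p$competitor$k_diss),
        times = c(0, p$presaturation_time))[, 2]
    }
    ## phase 2: analyte added, competitor still present
    th <- occupancy_trajectory(
      th0,
      a = c(p$analyte$k_ass * p$analyte_concentration,
            p$competitor$k_ass * cc),
      kd = c(p$analyte$k_diss, p$competitor$k_diss),
      times = times)
    clean <- receptor_capacity * (th[1, ] + mass_ratio * th[2, ])
    responses <- add_instrument_effects(clean, times, instrument, arm_seed)
    list(clean = clean,
         sg = sensorgram("association", times, responses,
                         analyte_concentration = p$analyte_concentration,
                         R0 = clean[1], condition = condition,
                         truth = p$analyte, seed = arm_seed),
         theta0 = th0)
  }

  sub_seed <- function(k) {
    if (is.null(seed)) NULL
    else as.integer((as.numeric(seed) * 100 + k) %% .Machine$integer.max)
  }
  free <- run_arm(0, sub_seed(1L))
  presat <- run_arm(p$competitor_concentration, sub_seed(2L))

  n <- length(times)
  R_eq_free <- free$clean[n] - free$clean[1]
  R_eq_presat <- presat$clean[n] - presat$clean[1]
  structure(
    list(free = free$sg, presaturated = presat$sg,
         R_eq_free = R_eq_free, R_eq_presaturated = R_eq_presat,
         reduction = if (R_eq_free > 0)
           competition_reduction(R_eq_free, R_eq_presat)$fraction
           else NA_real_,
         theta_presat = presat$theta0[2]),
    class = "competition_result"
  )
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf(paste0("competition assay: analyte-phase rise %.3g arcsec ",
                     "(free) vs %.3g arcsec (pre-saturated)\n"),
              x$R_eq_free, x$R_eq_presaturated))
  cat(sprintf("  equilibrium-response reduction: %.1f%%\n",
              100 * x$reduction))
  invisible(x)
}
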