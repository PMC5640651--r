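## Kinetic and equilibrium constant inference: observed-rate regression,
## K_D by the kinetic-ratio and isotherm routes, first-order error
## propagation, and surface-density / stoichiometry bookkeeping.

#' Collect observed rates from per-curve fits into a k_on series
#'
#' Pairs each titration concentration with the observed rate (and its
#' standard error) from the accepted mono-exponential fit of the matching
#' curve. Fits whose F-test verdict preferred the bi-exponential model
#' are excluded with a warning, since the single observed rate is then
#' ill-defined.
#'
#' @param series A [titration_series()].
#' @param fits A list, one element per series curve, each either an
#'   `exponential_fit` (mono association) or a `model_selection`.
#' @return A data frame of class `kon_series` with columns
#'   `concentration` (M), `k_on` (1/s), `se` (1/s), ordered by
#'   concentration.
#' @export
build_kon_series <- function(series, fits) {
  stopifnot(inherits(series, "titration_series"))
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  if (length(fits) != length(series$concentrations)) {
    stop("need exactly one fit per titration curve", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (inherits(f, "model_selection")) {
      if (f$chosen == "bi") {
        warning(sprintf(paste0("curve %d (C = %.3g M): bi-exponential ",
                               "selected; excluded from the k_on series"),
                        i, series$concentrations[i]), call. = FALSE)
        next
      }
      f <- f$fits$mono
    }
    if (!inherits(f, "exponential_fit") || f$model != "mono_assoc") {
      stop(sprintf("fit %d is not a mono-exponential association fit", i),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      concentration = series$concentrations[i],
      k_on = f$params[["kon"]],
      se = f$standard_errors[["kon"]])
  }
  if (length(rows) == 0L) {
    stop("no accepted mono-exponential fits in the series", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kon_series", "data.frame")
  out
}

#' Regress observed rates on concentration to recover rate constants
#'
#' Under pseudo-first-order kinetics the observed rate is affine in the
#' analyte concentration, `k_on = k_ass * C + k_diss`, so an ordinary
#' least-squares line through the (C, k_on) points has slope `k_ass` and
#' intercept `k_diss`. Weighted least squares (weights `1/se^2`) is
#' available but off by default. A negative fitted intercept is
#' physically impossible (`k_diss >= 0`) and is flagged, not clamped:
#' clamping would bias downstream K_D estimates.
#'
#' @param points A `kon_series` (or data frame with columns
#'   `concentration`, `k_on`, optionally `se`); >= 2 distinct
#'   concentrations, >= 3 for standard errors.
#' @param weighted Use `1/se^2` weights.
#' @return A list of class `kon_regression` with `k_ass`, `k_ass_se`,
#'   `k_diss`, `k_diss_se` and `flags`.
#' @export
regress_kon <- function(points, weighted = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "k_on") %in% names(points)))
  conc <- points$concentration
  if (length(unique(conc)) < 2L) {
    stop("need >= 2 distinct concentrations", call. = FALSE)
  }
  w <- NULL
  if (weighted) {
    if (is.null(points$se) || any(!is.finite(points$se)) ||
        any(points$se <= 0)) {
      stop("weighted regression needs finite positive `se`", call. = FALSE)
    }
    w <- 1 / points$se^2
  }
  fit <- stats::lm(k_on ~ concentration, data = points, weights = w)
  cf <- stats::coef(fit)
  se <- if (nrow(points) >= 3L) {
    ## exact input points trigger lm's "essentially perfect fit" warning;
    ## near-zero SEs are the correct answer there
    suppressWarnings(sqrt(diag(stats::vcov(fit))))
  } else {
    c(NA_real_, NA_real_)  # interpolating line: no residual dof
  }
  flags <- character()
  if (cf[[1]] < 0) flags <- c(flags, "negative_intercept")
  structure(
    list(k_ass = unname(cf[[2]]), k_ass_se = unname(se[[2]]),
         k_diss = unname(cf[[1]]), k_diss_se = unname(se[[1]]),
         n = nrow(points), flags = flags),
    class = "kon_regression"
  )
}

#' @export
print.kon_regression <- function(x, ...) {
  cat(sprintf("k_on vs concentration regression (%d points)\n", x$n))
  cat(sprintf("  k_ass  = %.4g +/- %.3g 1/(M s)\n", x$k_ass, x$k_ass_se))
  cat(sprintf("  k_diss = %.4g +/- %.3g 1/s\n", x$k_diss, x$k_diss_se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Equilibrium dissociation constant from the ratio of rate constants
#'
#' `K_D = k_diss / k_ass`, with the uncertainty propagated to first order
#' by relative-error quadrature:
#' \deqn{sd(K_D) = K_D \sqrt{(sd_{ass}/k_{ass})^2 + (sd_{diss}/k_{diss})^2}.}
#'
#' @param k_ass,k_diss Central values (> 0), in 1/(M s) and 1/s.
#' @param k_ass_sd,k_diss_sd Standard deviations (optional; NA gives an
#'   NA K_D uncertainty).
#' @return A list with `K_D` (M) and `K_D_sd` (M).
#' @examples
#' kd_from_kinetics(4.1e4, 2.5e-3, 0.6e4, 0.6e-3)  # 6.1e-8 +/- 1.7e-8 M
#' @export
kd_from_kinetics <- function(k_ass, k_diss, k_ass_sd = NA_real_,
                             k_diss_sd = NA_real_) {
  check_scalar(k_ass, "k_ass")
  check_scalar(k_diss, "k_diss")
  if (k_ass <= 0) stop("`k_ass` must be > 0", call. = FALSE)
  if (k_diss <= 0) stop("`k_diss` must be > 0", call. = FALSE)
  kd <- k_diss / k_ass
  sd <- if (is.na(k_ass_sd) || is.na(k_diss_sd)) NA_real_ else {
    kd * sqrt((k_ass_sd / k_ass)^2 + (k_diss_sd / k_diss)^2)
  }
  list(K_D = kd, K_D_sd = sd)
}

#' Fit the equilibrium binding isotherm
#'
#' Nonlinear least-squares fit of the extent-of-binding hyperbola
#' \deqn{R_{eq} = R_{max} \frac{C}{K_D + C}}
#' to (concentration, equilibrium response) pairs, yielding the
#' equilibrium-route estimate of K_D and the saturation response. With
#' all concentrations well below the fitted K_D only the initial slope
#' `R_max/K_D` is identified; such fits are flagged
#' `"poorly_constrained"`.
#'
#' @param extents Data frame with columns `concentration` (M) and `R_eq`
#'   (arcsec); optional `se` column for weighting. >= 3 distinct
#'   concentrations required.
#' @param weighted Use `1/se^2` weights.
#' @return A list of class `isotherm_fit` with `K_D`, `K_D_se`, `R_max`,
#'   `R_max_se`, `flags`.
#' @export
fit_isotherm <- function(extents, weighted = FALSE) {
  stopifnot(is.data.frame(extents),
            all(c("concentration", "R_eq") %in% names(extents)))
  if (length(unique(extents$concentration)) < 3L) {
    stop("underdetermined: need >= 3 distinct concentrations",
         call. = FALSE)
  }
  w <- NULL
  if (weighted) {
    stopifnot(!is.null(extents$se), all(extents$se > 0))
    w <- 1 / extents$se^2
  }
  rmax0 <- 1.2 * max(extents$R_eq)
  half <- extents$concentration[
    which.min(abs(extents$R_eq - max(extents$R_eq) / 2))]
  kd0 <- max(half, min(extents$concentration) / 10)
  fit <- tryCatch(
    stats::nls(R_eq ~ Rmax * concentration / (KD + concentration),
               data = extents, weights = w,
               start = list(Rmax = rmax0, KD = kd0),
               lower = c(Rmax = 0, KD = .Machine$double.xmin),
               algorithm = "port",
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) stop("isotherm fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- stats::coef(fit)
  se <- safe_se(fit, 2L)
  flags <- character()
  if (max(extents$concentration) < cf[["KD"]]) {
    flags <- c(flags, "poorly_constrained")
  }
  structure(
    list(K_D = unname(cf[["KD"]]), K_D_se = unname(se[2]),
         R_max = unname(cf[["Rmax"]]), R_max_se = unname(se[1]),
         n = nrow(extents), flags = flags),
    class = "isotherm_fit"
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("binding isotherm fit (%d extents)\n", x$n))
  cat(sprintf("  K_D   = %.3g +/- %.3g M\n", x$K_D, x$K_D_se))
  cat(sprintf("  R_max = %.4g +/- %.3g arcsec\n", x$R_max, x$R_max_se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Surface calibration for response-to-density conversions
#'
#' Defaults reproduce the standard pairing for this instrument class:
#' 700-800 arcsec of immobilisation shift corresponds to a surface
#' density of 1.20-1.30 ng/mm2, approximately 9-10 mg/mL within the
#' sensing layer. Both constants are explicit parameters, never
#' hard-coded downstream.
#'
#' @param response_per_density Instrument response per unit surface
#'   density, arcsec per (ng/mm2).
#' @param layer_thickness Effective sensing-layer thickness, nm.
#' @param receptor_mass Immobilised receptor molecular mass, kDa.
#' @return An object of class `surface_calibration`.
#' @export
surface_calibration <- function(response_per_density = 600,
                                layer_thickness = 132,
                                receptor_mass = 161) {
  check_scalar(response_per_density, "response_per_density")
  check_scalar(layer_thickness, "layer_thickness")
  check_scalar(receptor_mass, "receptor_mass")
  if (response_per_density <= 0 || layer_thickness <= 0 ||
      receptor_mass <= 0) {
    stop("all calibration constants must be > 0", call. = FALSE)
  }
  structure(
    list(response_per_density = response_per_density,
         layer_thickness = layer_thickness,
         receptor_mass = receptor_mass),
    class = "surface_calibration"
  )
}

#' Convert an immobilisation response shift to a surface density
#'
#' @param delta_R Baseline shift upon immobilisation, arcsec (>= 0).
#' @param cal A [surface_calibration()].
#' @return Surface density in ng/mm2.
#' @export
surface_density_from_shift <- function(delta_R,
                                       cal = surface_calibration()) {
  check_scalar(delta_R, "delta_R", lower = 0)
  stopifnot(inherits(cal, "surface_calibration"))
  delta_R / cal$response_per_density
}

#' Convert a surface density to a molar concentration in the sensing layer
#'
#' The surface density (ng/mm2) divided by the sensing-layer thickness
#' gives a mass concentration (mg/mL); dividing by the receptor molecular
#' mass gives the molar concentration. 1 ng/mm2 over 1 nm is 1000 mg/mL,
#' so `mass_conc = 1000 * density / thickness_nm`.
#'
#' @param density Surface density, ng/mm2 (>= 0).
#' @param cal A [surface_calibration()].
#' @return A list with `mass_concentration` (mg/mL) and
#'   `molar_concentration` (micromolar).
#' @export
molar_surface_concentration <- function(density,
                                        cal = surface_calibration()) {
  check_scalar(density, "density", lower = 0)
  stopifnot(inherits(cal, "surface_calibration"))
  mass_mg_ml <- 1000 * density / cal$layer_thickness
  ## mg/mL over kDa: (g/L) / (kg/mol) = mmol/L = 1000 uM
  molar_um <- 1000 * mass_mg_ml / cal$receptor_mass
  list(mass_concentration = mass_mg_ml, molar_concentration = molar_um)
}

#' Binding stoichiometry from molar surface concentrations
#'
#' Ratio of bound-analyte molar concentration at saturation to
#' immobilised-receptor molar concentration, reported both as a raw ratio
#' and rounded to the nearest small-integer ratio (denominator <= 4).
#'
#' @param surface_molar Immobilised receptor, micromolar (> 0).
#' @param extent_molar Bound analyte at saturation, micromolar (> 0).
#' @return A list of class `stoichiometry_result` with `surface_molar`,
#'   `extent_molar`, `ratio` and `rounded` (e.g. `"1:1"`).
#' @examples
#' determine_stoichiometry(59, 60)$rounded  # "1:1"
#' @export
determine_stoichiometry <- function(surface_molar, extent_molar) {
  check_scalar(surface_molar, "surface_molar")
  check_scalar(extent_molar, "extent_molar")
  if (surface_molar <= 0) stop("`surface_molar` must be > 0", call. = FALSE)
  if (extent_molar <= 0) stop("`extent_molar` must be > 0", call. = FALSE)
  ratio <- extent_molar / surface_molar
  structure(
    list(surface_molar = surface_molar, extent_molar = extent_molar,
         ratio = ratio, rounded = small_integer_ratio(ratio)),
    class = "stoichiometry_result"
  )
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("stoichiometry: %.3g uM bound / %.3g uM immobilised = %.3g -> %s\n",
              x$extent_molar, x$surface_molar, x$ratio, x$rounded))
  invisible(x)
}

#' Full kinetic analysis of a titration series
#'
#' Convenience pipeline: fit each association curve mono-exponentially
#' (optionally also bi-exponentially with F-test model selection), build
#' the k_on series, regress it on concentration, and form K_D by the
#' kinetic-ratio route; optionally fit the extent-of-binding isotherm for
#' the equilibrium-route K_D.
#'
#' @param series A [titration_series()].
#' @param confidence F-test confidence level; `NA` skips the bi fit and
#'   model selection (mono accepted throughout).
#' @param with_isotherm Also fit the binding isotherm to the fitted
#'   equilibrium responses.
#' @param weighted Weight the k_on regression by fit standard errors.
#' @return A list of class `kinetic_parameters` with `k_ass`, `k_ass_sd`,
#'   `k_diss`, `k_diss_sd`, `K_D_kin`, `K_D_kin_sd`, optionally
#'   `K_D_ext`, `K_D_ext_sd`, `R_max`, `R_max_sd`, plus `condition`,
#'   `n_concentrations`, `kon_series`, and `flags`.
#' @export
analyze_titration <- function(series, confidence = 0.95,
                              with_isotherm = TRUE, weighted = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  fits <- vector("list", length(series$sensorgrams))
  for (i in seq_along(series$sensorgrams)) {
    mono <- fit_mono_association(series$sensorgrams[[i]])
    fits[[i]] <- if (is.na(confidence)) mono else {
      bi <- fit_bi_association(series$sensorgrams[[i]])
      select_model_f_test(mono, bi, confidence)
    }
  }
  kon <- build_kon_series(series, fits)
  reg <- regress_kon(kon, weighted = weighted)
  if (reg$k_diss <= 0) {
    kd <- list(K_D = NA_real_, K_D_sd = NA_real_)
  } else {
    kd <- kd_from_kinetics(reg$k_ass, reg$k_diss,
                           reg$k_ass_se, reg$k_diss_se)
  }
  out <- list(k_ass = reg$k_ass, k_ass_sd = reg$k_ass_se,
              k_diss = reg$k_diss, k_diss_sd = reg$k_diss_se,
              K_D_kin = kd$K_D, K_D_kin_sd = kd$K_D_sd,
              K_D_ext = NA_real_, K_D_ext_sd = NA_real_,
              R_max = NA_real_, R_max_sd = NA_real_,
              condition = series$condition,
              n_concentrations = length(series$concentrations),
              kon_series = kon, fits = fits, flags = reg$flags)
  if (with_isotherm) {
    mono_of <- function(f) if (inherits(f, "model_selection"))
      f$fits$mono else f
    extents <- data.frame(
      concentration = series$concentrations,
      R_eq = vapply(fits, function(f) mono_of(f)$params[["Req"]],
                    numeric(1)),
      se = vapply(fits, function(f) mono_of(f)$standard_errors[["Req"]],
                  numeric(1)))
    iso <- tryCatch(fit_isotherm(extents, weighted = weighted),
                    error = function(e) NULL)
    if (!is.null(iso)) {
      out$K_D_ext <- iso$K_D; out$K_D_ext_sd <- iso$K_D_se
      out$R_max <- iso$R_max; out$R_max_sd <- iso$R_max_se
      out$flags <- c(out$flags, iso$flags)
    } else {
      out$flags <- c(out$flags, "isotherm_fit_failed")
    }
  }
  class(out) <- "kinetic_parameters"
  out
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf("kinetic parameters (%d concentrations%s)\n",
              x$n_concentrations,
              if (nzchar(x$condition$label))
                paste0(", ", x$condition$label) else ""))
  cat(sprintf("  k_ass   = %.3g +/- %.2g 1/(M s)\n", x$k_ass, x$k_ass_sd))
  cat(sprintf("  k_diss  = %.3g +/- %.2g 1/s\n", x$k_diss, x$k_diss_sd))
  cat(sprintf("  K_D,kin = %.3g +/- %.2g M\n", x$K_D_kin, x$K_D_kin_sd))
  if (is.finite(x$K_D_ext)) {
    cat(sprintf("  K_D,ext = %.3g +/- %.2g M (R_max %.4g +/- %.2g)\n",
                x$K_D_ext, x$K_D_ext_sd, x$R_max, x$R_max_sd))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
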