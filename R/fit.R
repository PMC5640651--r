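## Per-curve exponential fitting (mono and bi) and nested F-test model
## selection. Unweighted least squares by default: the instrument noise is
## homoscedastic by construction.

RATE_LOWER <- 1e-6
RATE_UPPER <- 10

## robust estimate of the per-point noise SD from first differences
noise_sd_estimate <- function(y) {
  if (length(y) < 3L) return(0)
  stats::mad(diff(y)) / sqrt(2)
}

## One bounded port-algorithm nls attempt. "False convergence" at the
## very tight tolerance means the optimiser stalled at the optimum's
## resolution; such fits are kept as fallback candidates.
nls_attempt <- function(formula, data, start, lower, upper) {
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(formula, data = data, start = start,
                 lower = lower, upper = upper, algorithm = "port",
                 control = stats::nls.control(
                   maxiter = 500, tol = 1e-10, minFactor = 1e-12,
                   warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  info <- fit$convInfo
  strict <- isTRUE(info$isConv)
  loose <- strict || grepl("false convergence|relative convergence",
                           info$stopMessage %||% "")
  if (!loose) return(NULL)
  list(fit = fit, ssr = sum(stats::resid(fit)^2), strict = strict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## bounded nls with deterministic jittered restarts
fit_nls_restart <- function(formula, data, start, lower, upper,
                            restarts = 3L) {
  jitters <- list(1, 0.4, 2.5, 0.1)
  best <- NULL
  for (j in seq_len(1L + restarts)) {
    st <- lapply(start, function(v) v * jitters[[j]])
    st <- mapply(function(v, lo, hi) min(max(v, lo), hi),
                 st, lower[names(st)], upper[names(st)],
                 SIMPLIFY = FALSE)
    cand <- nls_attempt(formula, data, st, lower, upper)
    if (!is.null(cand)) {
      better <- is.null(best) ||
        (cand$strict && !best$strict) ||
        (cand$strict == best$strict && cand$ssr < best$ssr - 1e-15)
      if (better) best <- cand
      if (j == 1L && cand$strict) break  # no need to jitter
    }
  }
  if (is.null(best)) {
    stop("fit failed to converge after jittered restarts", call. = FALSE)
  }
  best$fit
}

## standard errors from the fit covariance; NA-safe for boundary solutions
safe_se <- function(fit, n_params) {
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, n_params))
  se
}

new_exponential_fit <- function(model, params, se, residuals, fitted,
                                n_points, flags = character()) {
  ssr <- sum(residuals^2)
  dof <- n_points - length(params)
  n_tail <- max(3L, ceiling(0.1 * n_points))
  structure(
    list(model = model, params = params, standard_errors = se,
         ssr = ssr, n_points = n_points, n_params = length(params),
         dof = dof, residuals = residuals, fitted = fitted,
         diagnostics = list(
           rmse = sqrt(ssr / dof),
           tail_mean_residual = mean(utils::tail(residuals, n_tail))),
         flags = flags),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d points, ssr = %.4g, rmse = %.3g arcsec\n",
              x$model, x$n_points, x$ssr, x$diagnostics$rmse))
  est <- format(signif(x$params, 4))
  se <- format(signif(x$standard_errors, 3))
  for (i in seq_along(x$params)) {
    cat(sprintf("  %-8s %s +/- %s\n", names(x$params)[i], est[i], se[i]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a mono-exponential association model to a sensorgram
#'
#' Least-squares fit of
#' \deqn{R_t = R_0 + (R_{eq} - R_0)(1 - e^{-k_{on} t})}
#' with the amplitude constrained non-negative. Start values use the
#' first point for \eqn{R_0}, the mean of the last decile for
#' \eqn{R_{eq}}, and the reciprocal of the 63\%-amplitude crossing time
#' for \eqn{k_{on}}; up to three deterministic jittered restarts guard
#' against a poor basin.
#'
#' @param curve An association-phase [sensorgram()] with >= 5 points and a
#'   non-zero response range (a flat curve has no identifiable rate and
#'   raises an error).
#' @return An `exponential_fit` with parameters `R0`, `Req`, `kon`, their
#'   standard errors (from the fit covariance), the residual vector, sum
#'   of squared residuals and degrees of freedom.
#' @export
fit_mono_association <- function(curve) {
  stopifnot(inherits(curve, "sensorgram"))
  if (curve$phase != "association") {
    stop("expected an association-phase sensorgram", call. = FALSE)
  }
  t <- curve$times; y <- curve$responses
  n <- length(t)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)
  amp0 <- mean(utils::tail(y, max(3L, n %/% 10))) - y[1]
  noise <- noise_sd_estimate(y)
  if (abs(amp0) <= max(3 * noise, 1e-9 * max(abs(y), 1))) {
    stop("unidentifiable rate: response amplitude is zero within noise",
         call. = FALSE)
  }
  ## 63%-of-amplitude crossing gives 1/k_on without taking logs
  cross <- which(y - y[1] >= 0.63 * amp0)[1]
  k0 <- if (!is.na(cross) && t[cross] > 0) 1 / t[cross] else 1 / max(t)
  k0 <- min(max(k0, RATE_LOWER), RATE_UPPER)
  dat <- data.frame(t = t, y = y)
  fit <- fit_nls_restart(
    y ~ R0 + A * (1 - exp(-kon * t)), dat,
    start = list(R0 = y[1], A = max(amp0, 1e-6), kon = k0),
    lower = c(R0 = -Inf, A = 0, kon = RATE_LOWER),
    upper = c(R0 = Inf, A = Inf, kon = RATE_UPPER))
  cf <- stats::coef(fit)
  se <- safe_se(fit, 3L)
  V <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  req_se <- sqrt(V[1, 1] + V[2, 2] + 2 * V[1, 2])
  params <- c(R0 = unname(cf["R0"]), Req = unname(cf["R0"] + cf["A"]),
              kon = unname(cf["kon"]))
  ses <- c(R0 = unname(se[1]), Req = unname(req_se), kon = unname(se[3]))
  flags <- character()
  if (cf["kon"] <= RATE_LOWER * 1.01 || cf["kon"] >= RATE_UPPER * 0.99) {
    flags <- c(flags, "rate_at_bound")
  }
  new_exponential_fit("mono_assoc", params, ses,
                      residuals = y - stats::fitted(fit),
                      fitted = as.numeric(stats::fitted(fit)),
                      n_points = n, flags = flags)
}

#' Fit a bi-exponential association model
#'
#' Two-component fit
#' \deqn{R_t = R_0 + A_1 (1 - e^{-k_1 t}) + A_2 (1 - e^{-k_2 t}),}
#' components returned in canonical order \eqn{k_1 < k_2}. The fit is
#' seeded from the mono-exponential solution with the rate split by
#' factors 0.3 and 3. If the optimiser cannot beat the nested
#' mono-exponential solution, the mono solution itself (with one zero
#' amplitude) is returned so that nested dominance
#' (`ssr_bi <= ssr_mono`) holds by construction; near-equal rates or a
#' vanishing amplitude are flagged `"degenerate"`.
#'
#' @param curve An association-phase [sensorgram()] with >= 7 points.
#' @return An `exponential_fit` with parameters `R0`, `A1`, `k1`, `A2`,
#'   `k2` (ordered `k1 < k2`).
#' @export
fit_bi_association <- function(curve) {
  stopifnot(inherits(curve, "sensorgram"))
  if (curve$phase != "association") {
    stop("expected an association-phase sensorgram", call. = FALSE)
  }
  t <- curve$times; y <- curve$responses
  n <- length(t)
  if (n < 7L) stop("need at least 7 points", call. = FALSE)
  mono <- fit_mono_association(curve)
  A_tot <- mono$params[["Req"]] - mono$params[["R0"]]
  k_mono <- mono$params[["kon"]]
  dat <- data.frame(t = t, y = y)
  lower <- c(R0 = -Inf, A1 = 0, k1 = RATE_LOWER, A2 = 0, k2 = RATE_LOWER)
  upper <- c(R0 = Inf, A1 = Inf, k1 = RATE_UPPER, A2 = Inf, k2 = RATE_UPPER)
  starts <- list(
    list(R0 = mono$params[["R0"]], A1 = A_tot / 2,
         k1 = max(k_mono * 0.3, RATE_LOWER),
         A2 = A_tot / 2, k2 = min(k_mono * 3, RATE_UPPER)),
    list(R0 = mono$params[["R0"]], A1 = A_tot * 0.8,
         k1 = max(k_mono * 0.8, RATE_LOWER),
         A2 = A_tot * 0.2, k2 = min(k_mono * 8, RATE_UPPER)),
    list(R0 = mono$params[["R0"]], A1 = A_tot,
         k1 = k_mono, A2 = 0,
         k2 = min(k_mono * 3, RATE_UPPER)))
  best <- NULL
  for (st in starts) {
    cand <- nls_attempt(
      y ~ R0 + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)),
      dat, st, lower, upper)
    if (!is.null(cand) &&
        (is.null(best) || cand$ssr < best$ssr - 1e-15)) {
      best <- cand
    }
  }
  flags <- character()
  if (is.null(best) || best$ssr > mono$ssr * (1 + 1e-9)) {
    ## embed the mono solution: A2 = 0 at an arbitrary second rate
    params <- c(R0 = mono$params[["R0"]],
                A1 = A_tot, k1 = k_mono,
                A2 = 0, k2 = min(k_mono * 3, RATE_UPPER))
    ses <- c(R0 = mono$standard_errors[["R0"]], A1 = NA_real_,
             k1 = mono$standard_errors[["kon"]], A2 = NA_real_,
             k2 = NA_real_)
    return(new_exponential_fit("bi_assoc", params, ses,
                               residuals = mono$residuals,
                               fitted = mono$fitted, n_points = n,
                               flags = c("degenerate", "mono_embedded")))
  }
  cf <- stats::coef(best$fit)
  se <- safe_se(best$fit, 5L)
  names(se) <- names(cf)
  if (cf[["k1"]] > cf[["k2"]]) {    # canonical ordering k1 < k2
    cf <- cf[c("R0", "A2", "k2", "A1", "k1")]
    se <- se[c("R0", "A2", "k2", "A1", "k1")]
    names(cf) <- names(se) <- c("R0", "A1", "k1", "A2", "k2")
  }
  if (cf[["k2"]] / max(cf[["k1"]], RATE_LOWER) < 1.05 ||
      min(cf[["A1"]], cf[["A2"]]) < 1e-6 * (cf[["A1"]] + cf[["A2"]])) {
    flags <- c(flags, "degenerate")
  }
  new_exponential_fit("bi_assoc", cf, se,
                      residuals = y - stats::fitted(best$fit),
                      fitted = as.numeric(stats::fitted(best$fit)),
                      n_points = n, flags = flags)
}

#' Fit a mono-exponential dissociation model
#'
#' Least-squares fit of \eqn{R_t = A e^{-k_{diss} t}} or, with
#' `with_offset = TRUE`, \eqn{R_t = A e^{-k_{diss} t} + c} (incomplete
#' dissociation). An increasing trace is rejected as wrong-phase; a flat
#' trace has no identifiable rate. The `tail_mean_residual` diagnostic
#' (mean residual over the last 10\% of points) exposes the systematic
#' positive tail left by fitting offset-containing data without an
#' offset.
#'
#' @param curve A dissociation-phase [sensorgram()] with >= 5 points.
#' @param with_offset Include a constant offset term (default FALSE).
#' @return An `exponential_fit` with parameters `A`, `kdiss` (and
#'   `offset` when enabled).
#' @export
fit_dissociation <- function(curve, with_offset = FALSE) {
  stopifnot(inherits(curve, "sensorgram"))
  if (curve$phase != "dissociation") {
    stop("expected a dissociation-phase sensorgram", call. = FALSE)
  }
  t <- curve$times; y <- curve$responses
  n <- length(t)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)
  noise <- noise_sd_estimate(y)
  drop <- y[1] - mean(utils::tail(y, max(3L, n %/% 10)))
  if (drop < -max(3 * noise, 1e-9 * max(abs(y), 1))) {
    stop("wrong phase: trace increases; expected a decaying dissociation",
         call. = FALSE)
  }
  if (abs(drop) <= max(3 * noise, 1e-9 * max(abs(y), 1))) {
    stop("unidentifiable rate: trace is flat within noise", call. = FALSE)
  }
  tail_mean <- mean(utils::tail(y, max(3L, n %/% 10)))
  ## crude rate: time to lose 63% of the observed drop
  cross <- which(y[1] - y >= 0.63 * drop)[1]
  k0 <- if (!is.na(cross) && t[cross] > 0) 1 / t[cross] else 1 / max(t)
  k0 <- min(max(k0, RATE_LOWER), RATE_UPPER)
  dat <- data.frame(t = t, y = y)
  if (with_offset) {
    fit <- fit_nls_restart(
      y ~ A * exp(-kdiss * t) + offset, dat,
      start = list(A = max(drop, 1e-6), kdiss = k0, offset = tail_mean),
      lower = c(A = 0, kdiss = RATE_LOWER, offset = -Inf),
      upper = c(A = Inf, kdiss = RATE_UPPER, offset = Inf))
  } else {
    fit <- fit_nls_restart(
      y ~ A * exp(-kdiss * t), dat,
      start = list(A = max(y[1], 1e-6), kdiss = k0),
      lower = c(A = 0, kdiss = RATE_LOWER),
      upper = c(A = Inf, kdiss = RATE_UPPER))
  }
  cf <- stats::coef(fit)
  se <- safe_se(fit, length(cf))
  names(se) <- names(cf)
  model <- "mono_dissoc"
  new_exponential_fit(model, cf, se,
                      residuals = y - stats::fitted(fit),
                      fitted = as.numeric(stats::fitted(fit)),
                      n_points = n)
}

#' Nested F-test between mono- and bi-exponential fits
#'
#' For nested least-squares models fitted to the same curve,
#' \deqn{F = \frac{(SSR_{mono} - SSR_{bi})/(p_{bi} - p_{mono})}
#'            {SSR_{bi}/(n - p_{bi})},}
#' with the p-value from the F distribution on
#' \eqn{(p_{bi} - p_{mono},\; n - p_{bi})} degrees of freedom. The
#' bi-exponential model is accepted only when it improves the fit
#' significantly: `chosen = "bi"` iff `p_value < 1 - confidence`. A tie
#' at the threshold, or `ssr_bi >= ssr_mono` (F clamped at 0), keeps the
#' parsimonious mono model.
#'
#' @param mono,bi `exponential_fit` objects for the same curve.
#' @param confidence Confidence level, default 0.95.
#' @return An object of class `model_selection` with fields
#'   `f_statistic`, `p_value`, `confidence`, `chosen` ("mono"/"bi") and
#'   both fits.
#' @export
select_model_f_test <- function(mono, bi, confidence = 0.95) {
  stopifnot(inherits(mono, "exponential_fit"),
            inherits(bi, "exponential_fit"))
  if (mono$n_points != bi$n_points) {
    stop("fits are not of the same curve: point counts differ",
         call. = FALSE)
  }
  if (bi$n_params <= mono$n_params) {
    stop("`bi` must have more parameters than `mono`", call. = FALSE)
  }
  check_scalar(confidence, "confidence")
  if (confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  }
  n <- mono$n_points
  df1 <- bi$n_params - mono$n_params
  df2 <- n - bi$n_params
  f_stat <- ((mono$ssr - bi$ssr) / df1) / (bi$ssr / df2)
  f_stat <- max(f_stat, 0)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  chosen <- if (p < 1 - confidence) "bi" else "mono"
  structure(
    list(f_statistic = f_stat, p_value = p, confidence = confidence,
         df = c(df1, df2), chosen = chosen,
         fits = list(mono = mono, bi = bi)),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g -> %s-exponential at %g%% confidence\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value, x$chosen,
              100 * x$confidence))
  invisible(x)
}
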