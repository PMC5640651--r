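#' Construct a sensorgram (single-phase biosensor time course)
#'
#' A sensorgram is one association or dissociation time course: strictly
#' increasing times starting at 0 (seconds from phase start) and the
#' instrument response in arcsec, plus acquisition metadata.
#'
#' @param phase `"association"` or `"dissociation"`.
#' @param times Numeric vector, strictly increasing, first element 0.
#' @param responses Numeric vector, same length as `times`, arcsec.
#' @param analyte_concentration Analyte concentration in M. Required
#'   (>= 0) for association phases; ignored for dissociation.
#' @param R0 Initial response, arcsec.
#' @param condition A [buffer_condition()].
#' @param truth Optional [binding_system()] the curve was simulated from.
#' @param seed Optional integer seed used for the noise draw.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(phase, times, responses,
                       analyte_concentration = NULL, R0 = NULL,
                       condition = buffer_condition(), truth = NULL,
                       seed = NULL) {
  phase <- match.arg(phase, c("association", "dissociation"))
  times <- as.numeric(times)
  responses <- as.numeric(responses)
  if (length(times) != length(responses)) {
    stop("`times` and `responses` must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (times[1] != 0) stop("`times` must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(responses))) {
    stop("`responses` must be finite", call. = FALSE)
  }
  if (phase == "association") {
    check_scalar(analyte_concentration, "analyte_concentration", lower = 0)
  }
  if (!is.null(truth)) stopifnot(inherits(truth, "binding_system"))
  stopifnot(inherits(condition, "buffer_condition"))
  structure(
    list(phase = phase, times = times, responses = responses,
         analyte_concentration = analyte_concentration,
         R0 = if (is.null(R0)) responses[1] else R0,
         condition = condition, truth = truth, seed = seed),
    class = "sensorgram"
  )
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("sensorgram: %s phase, %d samples over %.4g s\n",
              x$phase, length(x$times), max(x$times)))
  if (!is.null(x$analyte_concentration)) {
    cat(sprintf("  analyte concentration: %.3g M\n",
                x$analyte_concentration))
  }
  cat(sprintf("  response range: %.4g to %.4g arcsec\n",
              min(x$responses), max(x$responses)))
  invisible(x)
}

#' Bundle association sensorgrams into a titration series
#'
#' @param sensorgrams List of association-phase [sensorgram()] objects at
#'   distinct analyte concentrations (>= 2 for downstream inference).
#' @param condition Shared [buffer_condition()].
#' @param dissociations Optional list of paired dissociation sensorgrams.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(sensorgrams, condition = buffer_condition(),
                             dissociations = NULL) {
  stopifnot(is.list(sensorgrams), length(sensorgrams) >= 2L)
  ok <- vapply(sensorgrams, function(s) {
    inherits(s, "sensorgram") && s$phase == "association"
  }, logical(1))
  if (!all(ok)) {
    stop("all members must be association-phase sensorgrams", call. = FALSE)
  }
  conc <- vapply(sensorgrams, `[[`, numeric(1), "analyte_concentration")
  if (anyDuplicated(conc)) {
    stop("analyte concentrations must be distinct", call. = FALSE)
  }
  ord <- order(conc)
  structure(
    list(sensorgrams = sensorgrams[ord],
         concentrations = conc[ord],
         condition = condition,
         dissociations = if (is.null(dissociations)) NULL
                         else dissociations[ord]),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration series: %d concentrations, %.3g to %.3g M\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations)))
  invisible(x)
}
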