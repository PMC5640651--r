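## Cross-condition and cross-ligand comparison: fold changes, the
## ionic-strength / ligand-variant parameter tables with internal
## consistency checks, salt-trend verdicts and competition quantification.

#' Fold change between two uncertain values
#'
#' Ratio `a/b` with first-order relative-error quadrature for the
#' uncertainty. `rounded` applies the usual reporting convention for
#' "nearly N-fold" statements: round to the nearest integer.
#'
#' @param a,b Central values (b > 0).
#' @param a_sd,b_sd Optional standard deviations.
#' @param numerator_label,denominator_label Labels for reports.
#' @param parameter Name of the compared parameter.
#' @return A list of class `fold_change` with `ratio`, `ratio_sd`,
#'   `rounded` and the labels.
#' @examples
#' fold_change(0.0025, 0.0001)$ratio  # 25
#' @export
fold_change <- function(a, b, a_sd = NA_real_, b_sd = NA_real_,
                        numerator_label = "a", denominator_label = "b",
                        parameter = "") {
  check_scalar(a, "a")
  check_scalar(b, "b")
  if (b <= 0) stop("denominator must be > 0", call. = FALSE)
  if (a <= 0) stop("numerator must be > 0", call. = FALSE)
  ratio <- a / b
  sd <- if (is.na(a_sd) || is.na(b_sd)) NA_real_ else {
    ratio * sqrt((a_sd / a)^2 + (b_sd / b)^2)
  }
  structure(
    list(ratio = ratio, ratio_sd = sd, rounded = round(ratio),
         numerator_label = numerator_label,
         denominator_label = denominator_label, parameter = parameter),
    class = "fold_change"
  )
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%s fold change %s / %s = %.3g", x$parameter,
              x$numerator_label, x$denominator_label, x$ratio))
  if (!is.na(x$ratio_sd)) cat(sprintf(" +/- %.2g", x$ratio_sd))
  cat(sprintf(" (~%d-fold)\n", x$rounded))
  invisible(x)
}

#' Assemble a kinetic-parameter comparison table with consistency checks
#'
#' Each entry pairs a label (a buffer condition or a ligand variant) with
#' kinetic parameters. Rows are ordered by NaCl concentration when every
#' entry carries a `buffer_condition`, otherwise in the given order.
#' Every row's printed K_D is recomputed from its `k_diss / k_ass` ratio
#' and compared at 2 significant figures; mismatches are flagged, not
#' dropped.
#'
#' @param entries A data frame with columns `label`, `k_ass`, `k_ass_sd`,
#'   `k_diss`, `k_diss_sd`, `KD`, `KD_sd` and optionally `nacl_mM`; or a
#'   list of such rows.
#' @return The data frame, ordered, with a logical `kd_consistent`
#'   column; class `condition_table`.
#' @export
build_condition_table <- function(entries) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- do.call(rbind, lapply(entries, as.data.frame))
  }
  stopifnot(is.data.frame(entries))
  if (nrow(entries) == 0L) stop("empty input", call. = FALSE)
  req <- c("label", "k_ass", "k_diss", "KD")
  if (!all(req %in% names(entries))) {
    stop("entries need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(entries$label)) {
    stop("row labels must be unique", call. = FALSE)
  }
  if ("nacl_mM" %in% names(entries) && !anyNA(entries$nacl_mM)) {
    entries <- entries[order(entries$nacl_mM), , drop = FALSE]
  }
  ratio <- entries$k_diss / entries$k_ass
  entries$kd_consistent <- signif(ratio, 2) == signif(entries$KD, 2)
  rownames(entries) <- NULL
  class(entries) <- c("condition_table", "data.frame")
  entries
}

#' Ionic-strength trend report over a condition table
#'
#' Checks the qualitative picture expected for an electrostatically
#' driven complex: `k_diss` and `K_D` increase with NaCl (destabilisation
#' at higher ionic strength) while `k_ass` stays constant within
#' experimental error. Monotonicity verdicts use strict ordering of the
#' central values; an error-aware verdict (allowing overlap of +/- 2 sd
#' intervals between neighbours) is reported alongside. `k_ass`
#' constancy means the largest pairwise difference is within the
#' combined 2-sd uncertainty of that pair.
#'
#' @param table A `condition_table` with a `nacl_mM` column and >= 3
#'   distinct salt conditions.
#' @return A list of class `salt_trend` with per-parameter verdicts.
#' @export
salt_trend <- function(table) {
  stopifnot(inherits(table, "condition_table"))
  if (!"nacl_mM" %in% names(table)) {
    stop("table has no `nacl_mM` column", call. = FALSE)
  }
  if (nrow(table) < 3L) {
    stop("need >= 3 salt conditions for a trend", call. = FALSE)
  }
  if (anyDuplicated(table$nacl_mM)) {
    stop("duplicate salt concentrations", call. = FALSE)
  }
  tab <- table[order(table$nacl_mM), , drop = FALSE]
  verdict <- function(x) {
    d <- diff(x)
    if (all(d > 0)) "increasing"
    else if (all(d < 0)) "decreasing"
    else if (all(d == 0)) "constant"
    else "no trend"
  }
  overlap_aware <- function(x, sd) {
    if (anyNA(sd)) return(NA)
    any(diff(x) < (sd[-length(sd)] + sd[-1]) * 2 & diff(x) > 0) == FALSE
  }
  ka <- tab$k_ass; ka_sd <- tab$k_ass_sd
  ka_const <- TRUE
  if (!anyNA(ka_sd)) {
    for (i in seq_along(ka)) for (j in seq_along(ka)) {
      if (i < j && abs(ka[i] - ka[j]) > 2 * (ka_sd[i] + ka_sd[j])) {
        ka_const <- FALSE
      }
    }
  } else {
    ka_const <- NA
  }
  structure(
    list(nacl_mM = tab$nacl_mM,
         k_diss_trend = verdict(tab$k_diss),
         KD_trend = verdict(tab$KD),
         k_ass_constant_within_error = ka_const,
         k_diss_strictly_resolved = overlap_aware(tab$k_diss,
                                                  tab$k_diss_sd)),
    class = "salt_trend"
  )
}

#' @export
print.salt_trend <- function(x, ...) {
  cat("ionic-strength trend over NaCl =",
      paste(x$nacl_mM, collapse = ", "), "mM\n")
  cat("  k_diss:", x$k_diss_trend, "\n")
  cat("  K_D:   ", x$KD_trend, "\n")
  cat("  k_ass constant within error:",
      x$k_ass_constant_within_error, "\n")
  invisible(x)
}

#' Fractional reduction of the equilibrium response under competition
#'
#' `(R_eq_free - R_eq_presaturated) / R_eq_free`, clamped to
#' `[-0.05, 1]`; values outside that band (a pre-saturated response
#' above the free response beyond noise, or below zero) are flagged
#' rather than silently truncated.
#'
#' @param R_eq_free Equilibrium analyte response on the free receptor,
#'   arcsec (> 0).
#' @param R_eq_presaturated Equilibrium analyte response after
#'   competitor pre-saturation, arcsec.
#' @return A list with `fraction` and `out_of_band` flag.
#' @examples
#' competition_reduction(100, 50)$fraction  # 0.5
#' @export
competition_reduction <- function(R_eq_free, R_eq_presaturated) {
  check_scalar(R_eq_free, "R_eq_free")
  check_scalar(R_eq_presaturated, "R_eq_presaturated")
  if (R_eq_free <= 0) {
    stop("`R_eq_free` must be > 0", call. = FALSE)
  }
  raw <- (R_eq_free - R_eq_presaturated) / R_eq_free
  clamped <- min(max(raw, -0.05), 1)
  list(fraction = clamped, out_of_band = raw < -0.05 || raw > 1)
}
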