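## File formats: the sensorgram CSV dialect, titration manifests, fit
## JSON records and results tables.
##
## Sensorgram CSV dialect: comment-prefixed `# key=value` header lines
## (phase, concentration_M, pH, nacl_mM, R0_arcsec, seed, label), then a
## two-column body `time_s,response_arcsec`.

#' Write a sensorgram to the package CSV dialect
#'
#' @param sg A [sensorgram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensorgram <- function(sg, path) {
  stopifnot(inherits(sg, "sensorgram"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# phase=%s", sg$phase))
  if (!is.null(sg$analyte_concentration)) {
    hdr <- c(hdr, sprintf("# concentration_M=%.17g",
                          sg$analyte_concentration))
  }
  hdr <- c(hdr,
           sprintf("# pH=%.17g", sg$condition$pH),
           sprintf("# nacl_mM=%.17g", sg$condition$nacl),
           sprintf("# R0_arcsec=%.17g", sg$R0))
  if (!is.null(sg$seed)) hdr <- c(hdr, sprintf("# seed=%d",
                                               as.integer(sg$seed)))
  if (nzchar(sg$condition$label)) {
    hdr <- c(hdr, sprintf("# label=%s", sg$condition$label))
  }
  writeLines(c(hdr, "time_s,response_arcsec"), con)
  utils::write.table(
    data.frame(t = sprintf("%.17g", sg$times),
               r = sprintf("%.17g", sg$responses)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read a sensorgram from the package CSV dialect
#'
#' Validates the dialect strictly: the `phase` header key is mandatory
#' (and `concentration_M` for association phases), the column header must
#' be `time_s,response_arcsec`, and times must be strictly increasing
#' from 0.
#'
#' @param path Path to a sensorgram CSV.
#' @return A [sensorgram()].
#' @export
read_sensorgram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- parse_header(lines[is_hdr])
  body <- lines[!is_hdr]
  if (length(body) < 2L || body[1] != "time_s,response_arcsec") {
    stop("format error: expected a `time_s,response_arcsec` column header",
         call. = FALSE)
  }
  if (is.null(hdr$phase)) {
    stop("format error: missing `# phase=` header", call. = FALSE)
  }
  phase <- hdr$phase
  if (!phase %in% c("association", "dissociation")) {
    stop("format error: phase must be association or dissociation",
         call. = FALSE)
  }
  conc <- NULL
  if (phase == "association") {
    if (is.null(hdr$concentration_M)) {
      stop("format error: association curve missing `# concentration_M=`",
           call. = FALSE)
    }
    conc <- as.numeric(hdr$concentration_M)
  }
  dat <- utils::read.csv(text = body, header = TRUE)
  if (any(diff(dat$time_s) <= 0) || dat$time_s[1] != 0) {
    stop("format error: times must be strictly increasing from 0",
         call. = FALSE)
  }
  cond <- buffer_condition(
    pH = if (is.null(hdr$pH)) 7.4 else as.numeric(hdr$pH),
    nacl = if (is.null(hdr$nacl_mM)) 0 else as.numeric(hdr$nacl_mM),
    label = if (is.null(hdr$label)) "" else hdr$label)
  sensorgram(phase, dat$time_s, dat$response_arcsec,
             analyte_concentration = conc,
             R0 = if (is.null(hdr$R0_arcsec)) NULL
                  else as.numeric(hdr$R0_arcsec),
             condition = cond,
             seed = if (is.null(hdr$seed)) NULL else as.integer(hdr$seed))
}

#' Write a titration series as member CSVs plus a JSON manifest
#'
#' @param series A [titration_series()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for member curves.
#' @return The manifest path, invisibly.
#' @export
write_titration <- function(series, dir, prefix = "curve") {
  stopifnot(inherits(series, "titration_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(series$sensorgrams))
  for (i in seq_along(series$sensorgrams)) {
    files[i] <- sprintf("%s_%02d.csv", prefix, i)
    write_sensorgram(series$sensorgrams[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    format = "bindkin-titration",
    version = as.character(utils::packageVersion("bindkin")),
    condition = list(pH = series$condition$pH,
                     nacl_mM = series$condition$nacl,
                     label = series$condition$label),
    files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a titration series from a manifest
#'
#' @param manifest_path Path to a manifest JSON written by
#'   [write_titration()].
#' @return A [titration_series()].
#' @export
read_titration <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(m$files) || length(m$files) == 0L) {
    stop("manifest lists no member files", call. = FALSE)
  }
  dir <- dirname(manifest_path)
  curves <- lapply(file.path(dir, m$files), read_sensorgram)
  cond <- buffer_condition(pH = m$condition$pH, nacl = m$condition$nacl_mM,
                           label = m$condition$label)
  titration_series(curves, condition = cond)
}

fit_record <- function(fit) {
  list(model = fit$model,
       params = as.list(fit$params),
       standard_errors = as.list(fit$standard_errors),
       ssr = fit$ssr, n_points = fit$n_points, dof = fit$dof,
       flags = as.list(fit$flags))
}

#' Serialise per-curve fit results (and F-test verdicts) to JSON
#'
#' @param fits Named list of `exponential_fit` or `model_selection`
#'   objects, keyed by curve identifier (e.g. input path).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  stopifnot(is.list(fits), length(fits) > 0)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    stop("`fits` must be a fully named list", call. = FALSE)
  }
  recs <- lapply(fits, function(f) {
    if (inherits(f, "model_selection")) {
      list(selection = list(f_statistic = f$f_statistic,
                            p_value = f$p_value,
                            confidence = f$confidence, chosen = f$chosen),
           mono = fit_record(f$fits$mono), bi = fit_record(f$fits$bi))
    } else {
      fit_record(f)
    }
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a kinetic-parameters results table as TSV
#'
#' Stable column order (the machine-readable twin of a published
#' kinetic-parameter table), a version-stamp comment header, and a
#' closure guarantee: [read_results()] reproduces the records.
#'
#' @param records Data frame with a `condition` column (unique labels)
#'   and the parameter columns `k_ass`, `k_ass_sd`, `k_diss`,
#'   `k_diss_sd`, `KD_kin`, `KD_kin_sd`, `KD_ext`, `KD_ext_sd` (missing
#'   ones are filled with NA); or a list of `kinetic_parameters`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  cols <- c("condition", "k_ass", "k_ass_sd", "k_diss", "k_diss_sd",
            "KD_kin", "KD_kin_sd", "KD_ext", "KD_ext_sd")
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, logical(1), "kinetic_parameters"))) {
    records <- do.call(rbind, lapply(records, function(p) {
      data.frame(condition = p$condition$label,
                 k_ass = p$k_ass, k_ass_sd = p$k_ass_sd,
                 k_diss = p$k_diss, k_diss_sd = p$k_diss_sd,
                 KD_kin = p$K_D_kin, KD_kin_sd = p$K_D_kin_sd,
                 KD_ext = p$K_D_ext, KD_ext_sd = p$K_D_ext_sd)
    }))
  }
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0) {
    if (!"condition" %in% names(records)) {
      stop("records need a `condition` column", call. = FALSE)
    }
    if (anyDuplicated(records$condition)) {
      stop("duplicate condition labels", call. = FALSE)
    }
  }
  for (c0 in setdiff(cols, names(records))) records[[c0]] <- NA_real_
  records <- records[, cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bindkin %s kinetic parameters",
                     utils::packageVersion("bindkin")), con)
  utils::write.table(records, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A data frame with the stable column set.
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
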