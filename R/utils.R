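## Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Seeds are always explicit arguments in this package; no function touches
#' the global random state without restoring it afterwards.
#'
#' @param seed Integer seed, or NULL for "use the current RNG stream".
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

## scalar validation: finite numeric of length 1
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("`%s` must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x),
         call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

## round to n significant figures, guarding zero
signif_pos <- function(x, digits = 2L) signif(x, digits)

#' Nearest small-integer ratio label
#'
#' Maps a positive real ratio to the closest p:q string with q <= max_den,
#' e.g. 1.02 -> "1:1", 2.05 -> "2:1", 0.52 -> "1:2".
#' @noRd
small_integer_ratio <- function(ratio, max_den = 4L) {
  stopifnot(ratio > 0)
  best <- c(1L, 1L)
  best_err <- Inf
  for (q in seq_len(max_den)) {
    p <- max(1L, round(ratio * q))
    err <- abs(ratio - p / q)
    if (err < best_err - 1e-12) {
      best <- c(p, q)
      best_err <- err
    }
  }
  g <- gcd_int(best[1], best[2])
  sprintf("%d:%d", best[1] %/% g, best[2] %/% g)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)
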