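#' Round half away from zero
#'
#' Rounds to `digits` decimals with exact halves going up, the convention
#' used for printed register-table percentages (base [round()] uses
#' round-half-to-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.05, 0.15, 0.25), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # nudge by a relative epsilon so values that are exactly .5 after the
  # decimal scaling (but stored slightly below it in binary) still go up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Format a count with its percentage
#'
#' @param n numerator count.
#' @param total denominator count.
#' @return character `"n (pct)"` with the percentage half-up rounded to one
#'   decimal, matching printed register tables.
#' @export
format_count_pct <- function(n, total) {
  sprintf("%d (%.1f)", n, round_half_up(100 * n / total, 1))
}

as_day_number <- function(x, origin) {
  if (inherits(x, "Date")) as.numeric(x - origin) else as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_prob <- function(value, field) {
  if (!is.numeric(value) || anyNA(value) || any(value < 0) || any(value > 1))
    stop_cfg(field, "must be a probability in [0, 1]")
  invisible(value)
}

check_nonneg <- function(value, field) {
  if (!is.numeric(value) || anyNA(value) || any(value < 0))
    stop_cfg(field, "must be a non-negative number")
  invisible(value)
}

check_pos <- function(value, field) {
  if (!is.numeric(value) || anyNA(value) || any(value <= 0))
    stop_cfg(field, "must be a positive number")
  invisible(value)
}
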