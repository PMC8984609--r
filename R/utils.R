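`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so `round_half_away(0.125,
#' 2)` is `0.13`), matching the printed style of most bioinformatics reports
#' rather than base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(50.415, 2)
#' round(50.415, 2) # base R differs on ties
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-12) / f
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_vector = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x))
    stop_field(field, "must be numeric and non-missing")
  if (!allow_vector && length(x) != 1L)
    stop_field(field, "must be a single number")
  if (any(x < lower) || any(x > upper))
    stop_field(field, sprintf("must lie in [%s, %s]", lower, upper))
  invisible(x)
}

#' @keywords internal
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
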