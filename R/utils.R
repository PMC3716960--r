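#' Round to fixed decimals, halves away from zero
#'
#' Formats a non-negative value the way spectral-count reports print it:
#' rounded to a fixed number of decimal places with ties going away from
#' zero (so `0.25` at one decimal prints `"0.3"`, unlike [base::round()]'s
#' banker's rounding). Display rounding is for reporting only; all
#' classification in this package operates on unrounded values.
#'
#' @param x Numeric vector, values `>= 0` (NA passed through).
#' @param decimals Integer, number of decimal places (default 3).
#' @return Character vector of formatted values.
#' @examples
#' display_round(497 / 3434, 3) # "0.145"
#' display_round(0.5412, 1)     # "0.5"
#' display_round(0.25, 1)       # "0.3"
#' @export
display_round <- function(x, decimals = 3) {
  stopifnot(is.numeric(x), length(decimals) == 1, decimals >= 0)
  if (any(x < 0, na.rm = TRUE)) {
    abort("display_round() expects non-negative values.", class = "scquant_error_validation")
  }
  p <- 10^decimals
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf(paste0("%.", decimals, "f"), floor(x[ok] * p + 0.5) / p)
  out
}

# numeric value of the display rounding (used by the acceptance script)
round_half_up <- function(x, decimals) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_config <- function(msg) abort(msg, class = "scquant_error_config")
stop_validation <- function(msg) abort(msg, class = "scquant_error_validation")
stop_parse <- function(msg) abort(msg, class = "scquant_error_parse")

check_count_col <- function(x, name) {
  if (any(is.na(x))) stop_parse(paste0("Non-numeric or missing value in column '", name, "'."))
  if (any(x < 0)) stop_validation(paste0("Negative spectral count in column '", name, "'."))
  if (any(x != floor(x))) stop_validation(paste0("Non-integer spectral count in column '", name, "'."))
  invisible(x)
}
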