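#' Round half away from zero
#'
#' Commercial rounding as used when converting scaled regression
#' coefficients to integer points: ties go away from zero, so 1.5 becomes 2
#' and -1.5 becomes -2 (unlike [base::round()], which rounds halves to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(1.5, -1.5, 2.5, 0.44))
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # 1e-9 guard: decimal constants (e.g. 0.092 * 7.5 / 0.46) can land a
  # hair below an exact half through binary representation error alone
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting; call. = FALSE everywhere so error
# messages read as validation diagnostics, not tracebacks
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
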