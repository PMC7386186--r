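#' Round half away from zero
#'
#' Spreadsheet-style rounding: halves round up in magnitude, unlike base
#' [round()] which rounds halves to even. Used everywhere a printed or
#' deliverable value is produced (integer MU, percentages to one decimal),
#' so results match hand-calculation worksheets digit for digit.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(0.5)      # 1, not 0
#' round_half_up(2.345, 2) # 2.35
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Single abort helper so every error in the package carries a class that
# tests and the CLI can dispatch on.
tbi_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "tbiplanr_error"), ...)
}

# Stable content checksum over an R object (canonical JSON serialization so
# the value is independent of in-memory attribute order).
content_checksum <- function(x) {
  digest::digest(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), force = TRUE),
    algo = "sha256", serialize = FALSE
  )
}

`%||%` <- rlang::`%||%`
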