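#' Round half away from zero
#'
#' Decimal rounding in which ties are resolved away from zero, the convention
#' of most spreadsheet and prism-style software (0.5625 -> 0.563 at three
#' decimals), as opposed to the IEEE banker's rounding used by [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(0.5625, 3)  # 0.563, where round() gives 0.562
#' @export
round_half_away <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## stop()/warning() without the "Error in f(...)" call prefix
abort <- function(..., class = "surfrank_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

warn <- function(...) warning(paste0(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## full-precision numeric -> text, so TSV round-trips are exact
num_to_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}
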