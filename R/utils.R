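# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even, which turns 78.125 into 78.12;
#' diagnostic accuracies are conventionally reported with halves rounded up
#' (78.125 -> 78.13).  A tiny epsilon guards against values such as 84.375
#' sitting a binary ulp below the true half.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stop() with a message assembled from sprintf-style parts
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# format a vector for error listings, truncated
.listing <- function(x, max = 10) {
  x <- as.character(x)
  if (length(x) > max) {
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
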