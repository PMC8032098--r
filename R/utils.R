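## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.QUANT_COLS <- c("specimen", "direction", "fraction", "protein", "area")
.DENSITY_COLS <- c("specimen", "direction", "fraction", "density")
.DIRECTIONS <- c("downward", "upward")

#' Truncate densities to a fixed number of decimals
#'
#' Equilibrium is decided by comparing the measured densities of the two peak
#' fractions at a finite precision (default 0.01 g/ml, the resolution at which
#' fraction densities are reported).  Truncation (floor at `10^-digits`) is
#' used rather than round-half rounding because it nests across precisions:
#' two values that agree at a fine precision always agree at any coarser one,
#' so coarsening the comparison can only create equilibrium calls, never
#' destroy them.  A `1e-9` guard absorbs floating-point deficit (e.g.
#' `1.13 * 100` evaluating just below 113).
#'
#' @param x numeric vector of densities (g/ml).
#' @param digits non-negative integer, decimal places kept.
#' @return numeric vector truncated to `digits` decimals.
#' @examples
#' trunc_density(c(1.1203, 1.1297, 1.13), 2)
#' @export
trunc_density <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  floor(x * scale + 1e-9) / scale
}

## Canonicalize direction labels; accepts common abbreviations.
normalize_direction <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("downward", "down", "d")] <- "downward"
  out[key %in% c("upward", "up", "u")] <- "upward"
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unrecognized direction value(s): ", paste(bad, collapse = ", "),
         " (expected 'downward' or 'upward')", call. = FALSE)
  }
  out
}

## Row-wise key for (specimen, direction, fraction, protein)-like frames.
record_key <- function(df, cols) {
  do.call(paste, c(unname(df[cols]), list(sep = "\r")))
}

fmt_density <- function(x, digits) {
  ifelse(is.na(x), NA_character_, sprintf(paste0("%.", digits, "f"), x))
}

detected_mask <- function(area) !is.na(area) & area > 0
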