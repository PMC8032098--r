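## The core computation: per-unit normalization, peak search, and the
## peak-fraction-density (PFD) / equilibrium statistic.
##
## A "unit" is one specimen x one direction: the 10-fraction set over which a
## protein's quantities are compared.  Quantified areas are log10-transformed
## and normalized by the per-protein maximum within the unit; the peak
## fraction is the argmax of the raw area (equivalently of the normalized
## value, since log10 is monotone), and its measured density is the candidate
## buoyant density.  A protein attains equilibrium in a specimen when the
## peak densities of the downward and upward separations agree at the
## configured precision; that shared density is the PFD.

#' Base-10 logarithm of quantified areas with a detection convention
#'
#' Areas of 0 (and absent values) mean "not detected" and map to `NA`;
#' negative areas are a domain error.
#'
#' @param area numeric vector of non-negative MS total areas.
#' @return numeric vector of log10 areas, `NA` where undetected.
#' @export
log10_area <- function(area) {
  stopifnot(is.numeric(area))
  if (any(!is.na(area) & area < 0)) {
    stop("negative area is not a valid quantified value", call. = FALSE)
  }
  out <- rep(NA_real_, length(area))
  ok <- detected_mask(area)
  out[ok] <- log10(area[ok])
  out
}

#' Normalize abundance profiles within each unit
#'
#' For every detected record, computes the log10 area and the normalized
#' value: log10 area divided by the maximum log10 area of the same protein in
#' the same unit, so the peak fraction maps to exactly 1.  Profiles whose
#' maximum log10 area is not positive (all areas at or below 1, a degenerate
#' case for real MS data) cannot be rescaled meaningfully: their log10 values
#' are kept unscaled and flagged with `normalizable = FALSE`.
#'
#' @param quant validated quantification data frame.
#' @return data frame of the detected records with added columns
#'   `log10_area`, `normalized` and `normalizable`.
#' @export
normalize_units <- function(quant) {
  quant <- validate_quant(quant)
  det <- quant[detected_mask(quant$area), , drop = FALSE]
  if (!nrow(det)) {
    stop("no detected records to normalize", call. = FALSE)
  }
  det$log10_area <- log10_area(det$area)
  key <- paste(det$specimen, det$direction, det$protein, sep = "\r")
  max_log <- stats::ave(det$log10_area, key, FUN = max)
  det$normalizable <- max_log > 0
  det$normalized <- ifelse(det$normalizable, det$log10_area / max_log,
                           det$log10_area)
  rownames(det) <- NULL
  det
}

#' Locate the peak fraction of every protein in every unit
#'
#' For each (specimen, direction, protein), returns the fraction with the
#' maximal raw area and its measured density.  Ties in area are broken
#' deterministically toward the lower fraction number (nearer the top of the
#' tube); tied peaks are reported with a message.
#'
#' @param quant validated quantification data frame.
#' @param densities validated fraction-density data frame covering every
#'   (specimen, direction, fraction) with a detected record.
#' @param precision decimal places at which peak densities are reported for
#'   comparison (default 2, i.e. 0.01 g/ml).
#' @return data frame with one row per (specimen, direction, protein):
#'   `fraction`, `area`, `density` (as measured) and `peak_density`
#'   (truncated to `precision`).
#' @export
peak_fractions <- function(quant, densities, precision = 2) {
  quant <- validate_quant(quant)
  densities <- validate_densities(densities)
  det <- quant[detected_mask(quant$area), , drop = FALSE]
  if (!nrow(det)) stop("no detected records", call. = FALSE)
  ord <- order(det$specimen, det$direction, det$protein,
               -det$area, det$fraction)
  det <- det[ord, , drop = FALSE]
  key <- paste(det$specimen, det$direction, det$protein, sep = "\r")
  is_peak <- !duplicated(key)
  max_area <- stats::ave(det$area, key, FUN = max)
  n_tied_units <- sum(tapply(det$area == max_area, key, sum) > 1)
  if (n_tied_units > 0) {
    message("peak ties in ", n_tied_units,
            " unit-protein profile(s); lower fraction number chosen")
  }
  peaks <- det[is_peak, c("specimen", "direction", "protein",
                          "fraction", "area")]
  m <- merge(peaks, densities, by = c("specimen", "direction", "fraction"),
             all.x = TRUE, sort = FALSE)
  if (anyNA(m$density)) {
    bad <- m[is.na(m$density), ]
    stop("no measured density for fraction ", bad$fraction[1], " of tube ",
         bad$specimen[1], " ", bad$direction[1], call. = FALSE)
  }
  m$peak_density <- trunc_density(m$density, precision)
  m <- m[order(m$specimen, m$direction, m$protein), ]
  rownames(m) <- NULL
  m
}

#' Compute peak fraction densities and the equilibrium flag
#'
#' For every protein x specimen, compares the peak densities of the downward
#' and upward separations, both truncated to `precision` decimals.  Densities
#' are compared, not fraction indices: different fraction numbers in the two
#' tubes can carry the same measured density and still evidence equilibrium.
#' A protein not detected in one or both directions of a specimen carries the
#' status `"X"`; detected in both but with disagreeing peak densities,
#' `"NE"` (not at equilibrium); otherwise `"PFD"` with the shared density as
#' its PFD.
#'
#' @inheritParams peak_fractions
#' @param specimens optional character vector fixing specimen order; defaults
#'   to the sorted specimens present in `quant`.
#' @return data frame with one row per protein x specimen: peak fraction and
#'   density for each direction, `at_equilibrium`, `pfd` (NA unless at
#'   equilibrium), `status` and `identified` (detected in at least one of the
#'   specimen's 20 fractions).
#' @examples
#' quant <- data.frame(
#'   specimen = "S1",
#'   direction = rep(c("downward", "upward"), each = 2),
#'   fraction = c(6, 7, 5, 7),
#'   protein = "CD63",
#'   area = c(1e5, 1e6, 2e4, 9e5))
#' dens <- expand.grid(specimen = "S1",
#'                     direction = c("downward", "upward"),
#'                     fraction = 1:10)
#' dens$density <- 1.02 + 0.02 * dens$fraction
#' compute_pfd(quant, dens)
#' @export
compute_pfd <- function(quant, densities, specimens = NULL, precision = 2) {
  quant <- validate_quant(quant)
  densities <- validate_densities(densities)
  peaks <- peak_fractions(quant, densities, precision)
  specimens <- specimens %||% sort(unique(quant$specimen))
  pfd_from_peaks(peaks, quant, specimens, precision)
}

## Internal assembly from precomputed peaks; `quant` only supplies the
## per-specimen identification flag.
pfd_from_peaks <- function(peaks, quant, specimens, precision) {
  proteins <- sort(unique(peaks$protein))
  grid <- expand.grid(protein = proteins, specimen = specimens,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  take <- function(dir) {
    p <- peaks[peaks$direction == dir, ]
    i <- match(paste(grid$protein, grid$specimen),
               paste(p$protein, p$specimen))
    list(fraction = p$fraction[i], density = p$density[i],
         peak = p$peak_density[i])
  }
  dn <- take("downward")
  up <- take("upward")
  at_eq <- !is.na(dn$peak) & !is.na(up$peak) & dn$peak == up$peak
  status <- ifelse(is.na(dn$peak) | is.na(up$peak), "X",
                   ifelse(at_eq, "PFD", "NE"))
  det <- quant[detected_mask(quant$area), ]
  ident_key <- unique(paste(det$protein, det$specimen))
  out <- data.frame(
    protein = grid$protein,
    specimen = grid$specimen,
    peak_fraction_down = dn$fraction,
    peak_fraction_up = up$fraction,
    peak_density_down = dn$peak,
    peak_density_up = up$peak,
    at_equilibrium = at_eq,
    pfd = ifelse(at_eq, dn$peak, NA_real_),
    status = status,
    identified = paste(grid$protein, grid$specimen) %in% ident_key,
    stringsAsFactors = FALSE)
  out[order(out$protein, out$specimen), ]
}
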