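## Mapping fractions onto a common measured-density axis and rendering
## per-protein heat maps as SVG.
##
## Each tube's 10 fractions have their own measured densities, so the same
## fraction number sits at different densities in different units.  Plotting
## against a common density axis (the sorted distinct truncated densities, or
## a regular grid) aligns units physically; bins a unit never reaches, and
## bins where the protein was not detected, are drawn gray.

#' Build a common density axis
#'
#' @param densities validated fraction-density data frame.
#' @param precision decimal places defining the bin width (`10^-precision`
#'   g/ml).
#' @param mode `"observed"` (default): bins are the sorted distinct truncated
#'   densities; `"grid"`: a regular grid at `10^-precision` covering the
#'   observed range.
#' @return object of class `"density_axis"`: `bins` (strictly increasing
#'   density values) and `map` (one row per (specimen, direction, fraction)
#'   with its bin index).
#' @export
build_density_axis <- function(densities, precision = 2,
                               mode = c("observed", "grid")) {
  mode <- match.arg(mode)
  densities <- validate_densities(densities)
  if (!nrow(densities)) stop("empty density table", call. = FALSE)
  vals <- trunc_density(densities$density, precision)
  scale <- 10^precision
  if (mode == "observed") {
    bins <- sort(unique(vals))
    bin_idx <- match(vals, bins)
  } else {
    ticks <- seq(round(min(vals) * scale), round(max(vals) * scale))
    bins <- ticks / scale
    bin_idx <- round(vals * scale) - ticks[1] + 1L
  }
  map <- data.frame(specimen = densities$specimen,
                    direction = densities$direction,
                    fraction = densities$fraction,
                    density = densities$density,
                    bin = bin_idx, stringsAsFactors = FALSE)
  structure(list(bins = bins, precision = precision, mode = mode, map = map),
            class = "density_axis")
}

#' @export
print.density_axis <- function(x, ...) {
  cat("Density axis:", length(x$bins), "bins (", x$mode, ") from",
      sprintf("%.3f", min(x$bins)), "to", sprintf("%.3f", max(x$bins)),
      "g/ml\n")
  invisible(x)
}

#' The 256-step red-to-green heat ramp
#'
#' Linear RGB interpolation from green `(0,255,0)` at step 0 (minimum) to red
#' `(255,0,0)` at step 255 (maximum), the orientation used for abundance heat
#' maps: the peak fraction is pure red.
#'
#' @return character vector of 256 hex colors ordered by increasing value.
#' @export
ev_heat_ramp <- function() {
  steps <- 0:255
  sprintf("#%02X%02X00", steps, 255L - steps)
}

## value in [0,1] -> ramp step 0..255
heat_step <- function(v) {
  pmax(0L, pmin(255L, as.integer(floor(v * 255))))
}

#' Render a protein's abundance heat map as SVG
#'
#' One row per unit (specimen x direction), one 12x12 px cell per density
#' bin.  Cell color is the 256-step red-to-green ramp applied to the unit-
#' normalized log10 abundance, rescaled from the minimum detected value
#' (across the protein's rows with `anchor = "protein"`, per unit with
#' `anchor = "unit"`) to the maximum; the peak cell of each unit is pure red.
#' Bins with no fraction in a unit, and fractions where the protein was not
#' detected, are gray.  Output is deterministic: identical inputs give
#' byte-identical SVG.
#'
#' @param fit an [ev_pfd()] fit.
#' @param protein protein ID to render.
#' @param path optional output path; when given the SVG is written there.
#' @param anchor low-end anchor of the color rescaling (see above).
#' @param cell_size cell edge in px.
#' @param axis optional precomputed [build_density_axis()]; defaults to the
#'   fit's densities at the fit's precision.
#' @return the SVG document as a single character string, invisibly.
#' @export
render_heatmap <- function(fit, protein, path = NULL,
                           anchor = c("protein", "unit"), cell_size = 12,
                           axis = NULL) {
  stopifnot(inherits(fit, "ev_pfd"))
  anchor <- match.arg(anchor)
  axis <- axis %||% build_density_axis(fit$densities, fit$precision)
  prof <- fit$profiles[fit$profiles$protein == protein, ]
  if (!nrow(prof)) stop("protein '", protein, "' has no detected records",
                        call. = FALSE)
  units <- expand.grid(direction = .DIRECTIONS, specimen = fit$specimens,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units <- units[c("specimen", "direction")]
  n_units <- nrow(units)
  n_bins <- length(axis$bins)

  ## unit x bin value matrix (max normalized value if several fractions of a
  ## unit share a bin); NA = gray
  val <- matrix(NA_real_, n_units, n_bins)
  ukey <- paste(units$specimen, units$direction)
  mkey <- paste(axis$map$specimen, axis$map$direction)
  pkey <- paste(prof$specimen, prof$direction)
  bin_of <- axis$map$bin[match(paste(pkey, prof$fraction),
                               paste(mkey, axis$map$fraction))]
  for (r in which(!is.na(bin_of))) {
    u <- match(pkey[r], ukey)
    b <- bin_of[r]
    val[u, b] <- max(val[u, b], prof$normalized[r], na.rm = TRUE)
  }

  rescaled <- val
  if (anchor == "protein") {
    vmin <- suppressWarnings(min(val, na.rm = TRUE))
    vmax <- suppressWarnings(max(val, na.rm = TRUE))
    rng <- vmax - vmin
    rescaled[] <- if (rng > 0) (val - vmin) / rng else 1
  } else {
    for (u in seq_len(n_units)) {
      v <- val[u, ]
      if (all(is.na(v))) next
      vmin <- min(v, na.rm = TRUE); vmax <- max(v, na.rm = TRUE)
      rescaled[u, ] <- if (vmax > vmin) (v - vmin) / (vmax - vmin) else 1
    }
  }
  ramp <- ev_heat_ramp()
  left <- 70L; top <- 26L
  w <- left + n_bins * cell_size + 10L
  h <- top + n_units * cell_size + 34L
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">"),
            w, h, w, h),
    sprintf("<title>%s</title>", protein),
    sprintf(paste0("<text x=\"%d\" y=\"16\" font-family=\"sans-serif\" ",
                   "font-size=\"12\">%s</text>"), left, protein))
  for (u in seq_len(n_units)) {
    y <- top + (u - 1L) * cell_size
    lab <- sprintf("%s %s", units$specimen[u],
                   ifelse(units$direction[u] == "downward", "D", "U"))
    lines <- c(lines,
               sprintf(paste0("<text x=\"4\" y=\"%d\" font-family=",
                              "\"sans-serif\" font-size=\"10\">%s</text>"),
                       y + cell_size - 3L, lab))
    for (b in seq_len(n_bins)) {
      fill <- if (is.na(rescaled[u, b])) "#808080" else
        ramp[heat_step(rescaled[u, b]) + 1L]
      lines <- c(lines,
                 sprintf(paste0("<rect x=\"%d\" y=\"%d\" width=\"%d\" ",
                                "height=\"%d\" fill=\"%s\"/>"),
                         left + (b - 1L) * cell_size, y,
                         cell_size, cell_size, fill))
    }
  }
  tick_every <- max(1L, n_bins %/% 8L)
  for (b in seq(1L, n_bins, by = tick_every)) {
    lines <- c(lines,
               sprintf(paste0("<text x=\"%d\" y=\"%d\" font-family=",
                              "\"sans-serif\" font-size=\"8\">%s</text>"),
                       left + (b - 1L) * cell_size,
                       top + n_units * cell_size + 12L,
                       fmt_density(axis$bins[b], axis$precision)))
  }
  lines <- c(lines, "</svg>")
  svg <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(svg, path, useBytes = TRUE)
  invisible(svg)
}

#' Dot plot of fraction densities
#'
#' Plots every measured fraction density, one horizontal row per unit
#' (specimen x direction), downward separations as circles and upward as
#' squares; fractions listed in `peaks` (e.g. the peak fractions of a
#' protein) are drawn filled.
#'
#' @param densities validated fraction-density data frame.
#' @param peaks optional data frame with columns `specimen`, `direction`,
#'   `fraction`: the fractions to fill.
#' @param highlight label used in the plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, a data frame of the plotted points (`density`, `y`,
#'   `pch`), one row per fraction record.
#' @export
plot_density_dots <- function(densities, peaks = NULL, highlight = NULL,
                              ...) {
  densities <- validate_densities(densities)
  specimens <- sort(unique(densities$specimen))
  units <- expand.grid(direction = .DIRECTIONS, specimen = specimens,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ukey <- paste(units$specimen, units$direction)
  y <- match(paste(densities$specimen, densities$direction), ukey)
  open_pch <- ifelse(densities$direction == "downward", 1, 0)
  filled_pch <- ifelse(densities$direction == "downward", 16, 15)
  is_peak <- rep(FALSE, nrow(densities))
  if (!is.null(peaks) && nrow(peaks)) {
    is_peak <- record_key(densities, .DENSITY_COLS[1:3]) %in%
      record_key(peaks, .DENSITY_COLS[1:3])
  }
  pch <- ifelse(is_peak, filled_pch, open_pch)
  col <- match(densities$specimen, specimens)
  graphics::plot(densities$density, y, pch = pch, col = col,
                 xlab = "density (g/ml)", ylab = "", yaxt = "n",
                 main = if (is.null(highlight)) "fraction densities" else
                   paste0("fraction densities (", highlight, " peaks filled)"),
                 ...)
  graphics::axis(2, at = seq_along(ukey), labels = sub(" downward", " D",
                 sub(" upward", " U", ukey)), las = 1, cex.axis = 0.7)
  invisible(data.frame(density = densities$density, y = y, pch = pch))
}
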