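## The user-facing fit: ingest -> normalize -> peak search -> PFD ->
## classification, returned as one classed object.

#' Fit peak fraction densities and drift-pattern classes
#'
#' The main entry point.  Takes a per-fraction quantification table and the
#' measured density ladder of every tube, normalizes log10 abundances within
#' each unit (specimen x direction), locates each protein's peak fraction,
#' decides equilibrium by agreement of the downward and upward peak densities
#' at `precision` decimals, and partitions proteins into drift-pattern
#' subgroups.
#'
#' @param quant quantification table: a data frame or a path to a TSV read
#'   with [read_quant_table()].
#' @param densities fraction-density table: a data frame or a TSV path.
#' @param specimens optional character vector fixing specimen order (defaults
#'   to sorted specimens present in `quant`).
#' @param precision decimal places (g/ml) at which peak densities are
#'   compared; default 2, i.e. 0.01 g/ml resolution.
#' @param reference_marker protein anchoring the IA-1 subgroup label;
#'   default `"CD63"`.
#' @return an object of class `"ev_pfd"`: a list with components
#'   \describe{
#'     \item{pfd}{per protein x specimen peak fractions/densities,
#'       equilibrium flag and PFD (see [compute_pfd()]).}
#'     \item{assignments}{per-protein group label and PFD pattern
#'       (see [assign_groups()]), with the `"subgroups"` attribute.}
#'     \item{overlap}{detection-overlap summary (see [detection_overlap()]).}
#'     \item{profiles}{detected records with log10 and unit-normalized
#'       abundances (see [normalize_units()]).}
#'     \item{peaks, densities, specimens, precision, reference_marker,
#'       call}{inputs and settings.}
#'   }
#' @examples
#' sim <- simulate_ev_dataset(ev_sim_config(noise = list(log10_sd = 0,
#'   dropout_prob = 0), density_jitter_sd = 0, seed = 1))
#' fit <- ev_pfd(sim$quant, sim$densities)
#' fit
#' coef(fit)["CD63", ]
#' @export
ev_pfd <- function(quant, densities, specimens = NULL, precision = 2,
                   reference_marker = "CD63") {
  cl <- match.call()
  if (is.character(quant)) quant <- read_quant_table(quant)
  if (is.character(densities)) densities <- read_density_table(densities)
  quant <- validate_quant(quant)
  densities <- validate_densities(densities)
  stopifnot(length(precision) == 1L, precision >= 0)

  det <- quant[detected_mask(quant$area), ]
  if (!nrow(det)) stop("no detected records in quant table", call. = FALSE)
  need <- unique(det[c("specimen", "direction", "fraction")])
  have <- record_key(densities, .DENSITY_COLS[1:3])
  miss <- !record_key(need, .DENSITY_COLS[1:3]) %in% have
  if (any(miss)) {
    b <- need[miss, ][1, ]
    stop("no density entry for (", b$specimen, ", ", b$direction,
         ", F", b$fraction, ")", call. = FALSE)
  }
  specimens <- specimens %||% sort(unique(quant$specimen))

  profiles <- normalize_units(quant)
  peaks <- peak_fractions(quant, densities, precision)
  pfd <- pfd_from_peaks(peaks, quant, specimens, precision)
  overlap <- detection_overlap(quant, specimens)
  assignments <- assign_groups(pfd, reference_marker, precision, specimens)

  structure(list(pfd = pfd,
                 assignments = assignments,
                 overlap = overlap,
                 profiles = profiles,
                 peaks = peaks,
                 densities = densities,
                 specimens = specimens,
                 precision = precision,
                 reference_marker = reference_marker,
                 call = cl),
            class = "ev_pfd")
}

## Shared count summary used by print/summary/pipeline.
ev_counts <- function(fit) {
  a <- fit$assignments
  sub <- attr(a, "subgroups")
  group_I <- sum(!is.na(a$group) & a$group != "II" & a$group != "unclassified")
  list(n_distinct = fit$overlap$n_distinct,
       n_identifications = fit$overlap$n_identifications,
       per_specimen = as.list(fit$overlap$per_specimen),
       n_common_all = fit$overlap$n_common_all,
       group_I = group_I,
       group_II = sum(!is.na(a$group) & a$group == "II"),
       unclassified = sum(!is.na(a$group) & a$group == "unclassified"),
       not_determined = sum(is.na(a$group)),
       subgroups = stats::setNames(as.list(sub$n), sub$label))
}

#' @export
print.ev_pfd <- function(x, ...) {
  cts <- ev_counts(x)
  cat("Peak-fraction-density fit (", length(x$specimens), " specimens: ",
      paste(x$specimens, collapse = ", "), ")\n", sep = "")
  cat("  distinct proteins:     ", cts$n_distinct, "\n")
  cat("  identifications:       ", cts$n_identifications, "\n")
  cat("  common to all:         ", cts$n_common_all, "\n")
  cat("  Group I (equilibrium): ", cts$group_I, "\n")
  cat("  Group II (never eq.):  ", cts$group_II, "\n")
  cat("  partial equilibrium:   ", cts$unclassified, "\n")
  sub <- attr(x$assignments, "subgroups")
  if (nrow(sub)) {
    cat("  subgroups:\n")
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-5s n = %3d  PFD %s\n",
                  sub$label[i], sub$n[i], sub$pattern[i]))
    }
  }
  invisible(x)
}

#' Summarize a PFD fit
#'
#' @param object an `"ev_pfd"` fit.
#' @param ... unused.
#' @return a `"summary.ev_pfd"` list: counts, the subgroup table, and the
#'   detection-overlap regions.
#' @export
summary.ev_pfd <- function(object, ...) {
  structure(list(counts = ev_counts(object),
                 subgroups = attr(object$assignments, "subgroups"),
                 overlap = object$overlap,
                 specimens = object$specimens,
                 precision = object$precision),
            class = "summary.ev_pfd")
}

#' @export
print.summary.ev_pfd <- function(x, ...) {
  cts <- x$counts
  cat("Specimens:", paste(x$specimens, collapse = ", "),
      sprintf(" (precision %g g/ml)\n", 10^-x$precision))
  cat("Identifications:", cts$n_identifications, "records,",
      cts$n_distinct, "distinct proteins\n")
  cat("Per specimen:",
      paste(sprintf("%s=%d", names(cts$per_specimen),
                    unlist(cts$per_specimen)), collapse = ", "), "\n")
  cat("Venn regions (exclusive):\n")
  print(x$overlap$regions)
  cat("Group I:", cts$group_I, " Group II:", cts$group_II,
      " partial:", cts$unclassified, " undetermined:", cts$not_determined,
      "\n")
  if (nrow(x$subgroups)) {
    cat("Subgroups:\n")
    print(x$subgroups, row.names = FALSE)
  }
  invisible(x)
}

#' Extract the PFD matrix
#'
#' @param object an `"ev_pfd"` fit.
#' @param ... unused.
#' @return numeric matrix, proteins x specimens, of peak fraction densities
#'   (g/ml); NA where the protein did not attain equilibrium or was not
#'   detected in both directions.
#' @export
coef.ev_pfd <- function(object, ...) {
  pfd <- object$pfd
  proteins <- sort(unique(pfd$protein))
  m <- matrix(NA_real_, length(proteins), length(object$specimens),
              dimnames = list(proteins, object$specimens))
  m[cbind(match(pfd$protein, proteins),
          match(pfd$specimen, object$specimens))] <- pfd$pfd
  m
}

#' Plot fraction densities on a common axis
#'
#' Scatter of every tube's measured fraction densities, one row per unit,
#' with the peak fractions of a highlighted protein drawn as filled markers
#' (circles for the downward, squares for the upward separation).
#'
#' @param x an `"ev_pfd"` fit.
#' @param highlight protein ID whose peak fractions are filled; defaults to
#'   the fit's reference marker, `NULL` for no highlight.
#' @param ... passed to [plot_density_dots()].
#' @return invisibly, the plotted point table.
#' @export
plot.ev_pfd <- function(x, highlight = x$reference_marker, ...) {
  peaks <- NULL
  if (!is.null(highlight) && highlight %in% x$peaks$protein) {
    peaks <- x$peaks[x$peaks$protein == highlight, ]
  }
  plot_density_dots(x$densities, peaks = peaks, highlight = highlight, ...)
}

#' Simulate datasets with the fitted drift structure
#'
#' Builds a simulation configuration whose planted classes reproduce the
#' fitted subgroup PFD tuples and sizes (plus a never-equilibrating class the
#' size of fitted Group II) and draws new datasets from it.  This gives a
#' parametric-bootstrap-style check: refitting a simulated dataset should
#' recover the fitted partition when the fit is informative.
#'
#' @param object an `"ev_pfd"` fit.
#' @param nsim number of datasets.
#' @param seed integer seed for the first dataset; dataset `i` uses
#'   `seed + i - 1`.
#' @param ... overrides passed to [ev_sim_config()] (e.g. `noise`).
#' @return a list of `nsim` simulated datasets (see [simulate_ev_dataset()]).
#' @export
simulate.ev_pfd <- function(object, nsim = 1, seed = 1, ...) {
  sub <- attr(object$assignments, "subgroups")
  if (!nrow(sub)) stop("no Group I subgroups to simulate from", call. = FALSE)
  classes <- lapply(seq_len(nrow(sub)), function(i) {
    vals <- as.numeric(strsplit(sub$pattern[i], "/", fixed = TRUE)[[1]])
    list(name = sub$label[i], base_density = vals[1],
         drift = vals - vals[1], n_proteins = sub$n[i])
  })
  n2 <- sum(!is.na(object$assignments$group) & object$assignments$group == "II")
  lapply(seq_len(nsim), function(i) {
    cfg <- ev_sim_config(classes = classes,
                         nonequilibrium = list(n_proteins = n2),
                         seed = seed + i - 1, ...)
    simulate_ev_dataset(cfg)
  })
}
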