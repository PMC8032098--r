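## Deterministic generator of a dataset with a prescribed detection-overlap
## and group structure.  Unlike simulate_ev_dataset() this draws nothing: it
## is a synthetic stand-in for a deposited three-specimen salivary-EV
## quantification table, planting exact marginal totals (per-specimen
## identifications, Venn regions, per-fraction identification count) and an
## exact Group I / Group II partition so that the pipeline's reported counts
## can be checked against known values.

#' Simulate a dataset with exact overlap and group counts
#'
#' Builds a quantification + density table pair in which every count the
#' pipeline reports is planted exactly:
#' \itemize{
#'   \item `classes` proteins (equilibrating drift classes, as in
#'     [ev_sim_config()]) are detected in both directions of every specimen
#'     and attain equilibrium everywhere;
#'   \item `n_partial` proteins equilibrate in specimen 1 only (detected in
#'     both directions everywhere);
#'   \item `n_nonequilibrium` proteins are detected everywhere but
#'     equilibrate nowhere (their downward and upward peaks sit at different
#'     densities);
#'   \item `singles` and `pairs` proteins are detected only in the named
#'     specimen subset, padding the Venn regions.
#' }
#' Extra low-abundance neighbour-fraction records are added deterministically
#' until the table holds exactly `n_identifications` detected records.
#'
#' All six tubes share the base density ladder, so planted densities are
#' recovered exactly.  The generator is fully deterministic (no RNG).
#'
#' @param classes equilibrating class list (see [ev_sim_config()]); default
#'   the package's default drift classes (16 + 59 + 29 + 7 proteins).
#' @param n_nonequilibrium never-equilibrating protein count (default 21).
#' @param n_partial partial-equilibrium protein count (default 344).
#' @param singles named integer vector: proteins detected in exactly one
#'   specimen (default `c(S1 = 361, S2 = 196, S3 = 88)`).
#' @param pairs named integer vector, names like `"S1&S2"`: proteins detected
#'   in exactly two specimens (default `c(200, 60, 48)` for
#'   S1&S2, S1&S3, S2&S3).
#' @param n_identifications total detected records to emit (default 11749).
#' @param gradient_profile shared base density ladder.
#' @return list of class `"ev_overlap_sim"` with `quant`, `densities`,
#'   `specimens` and `expected` (the planted counts).
#' @export
simulate_overlap_dataset <- function(classes = .default_classes(),
                                     n_nonequilibrium = 21,
                                     n_partial = 344,
                                     singles = c(S1 = 361, S2 = 196, S3 = 88),
                                     pairs = c("S1&S2" = 200, "S1&S3" = 60,
                                               "S2&S3" = 48),
                                     n_identifications = 11749,
                                     gradient_profile = .DEFAULT_LADDER) {
  specimens <- c("S1", "S2", "S3")
  ladder <- gradient_profile
  stopifnot(all(diff(ladder) > 0), length(ladder) == 10)
  snap <- function(x) vapply(x, function(v) which.min(abs(ladder - v)),
                             integer(1))

  densities <- do.call(rbind, lapply(specimens, function(s) {
    do.call(rbind, lapply(.DIRECTIONS, function(d) {
      data.frame(specimen = s, direction = d, fraction = 1:10,
                 density = ladder, stringsAsFactors = FALSE)
    }))
  }))

  ## unit table: one row per (protein, specimen, direction) with its peak
  units <- list()
  add_units <- function(protein, specimen, f_down, f_up) {
    units[[length(units) + 1L]] <<- data.frame(
      protein = protein, specimen = specimen,
      direction = rep(.DIRECTIONS, each = length(protein)),
      peak = c(f_down, f_up), stringsAsFactors = FALSE)
  }
  for (cls in classes) {
    ids <- sprintf("%s.%03d", toupper(gsub("[^A-Za-z0-9]", "", cls$name)),
                   seq_len(cls$n_proteins))
    if (!is.null(cls$marker)) ids[1] <- cls$marker
    for (k in seq_along(specimens)) {
      f <- snap(cls$base_density + cls$drift[k])
      add_units(ids, specimens[k], rep(f, length(ids)), rep(f, length(ids)))
    }
  }
  if (n_partial > 0) {
    ids <- sprintf("PART.%04d", seq_len(n_partial))
    part_peaks <- list(S1 = c(snap(1.12), snap(1.12)),
                       S2 = c(snap(1.12), snap(1.13)),
                       S3 = c(snap(1.09), snap(1.10)))
    for (s in specimens) {
      p <- part_peaks[[s]]
      add_units(ids, s, rep(p[1], n_partial), rep(p[2], n_partial))
    }
  }
  if (n_nonequilibrium > 0) {
    ids <- sprintf("NE.%03d", seq_len(n_nonequilibrium))
    ids[1] <- "AMY1"
    for (s in specimens) {
      add_units(ids, s, rep(snap(1.16), n_nonequilibrium),
                rep(snap(1.09), n_nonequilibrium))
    }
  }
  for (s in names(singles)) {
    if (singles[[s]] > 0) {
      ids <- sprintf("ONLY.%s.%04d", s, seq_len(singles[[s]]))
      add_units(ids, s, rep(5L, length(ids)), rep(5L, length(ids)))
    }
  }
  for (pp in names(pairs)) {
    if (pairs[[pp]] > 0) {
      both <- strsplit(pp, "&", fixed = TRUE)[[1]]
      ids <- sprintf("PAIR.%s.%04d", gsub("&", "", pp), seq_len(pairs[[pp]]))
      for (s in both) add_units(ids, s, rep(5L, length(ids)),
                                rep(5L, length(ids)))
    }
  }
  units <- do.call(rbind, units)
  units <- units[order(units$protein, units$specimen, units$direction), ]
  rownames(units) <- NULL

  ## base records: the peak of every unit, with a deterministic abundance
  i <- seq_len(nrow(units))
  base <- data.frame(specimen = units$specimen, direction = units$direction,
                     fraction = units$peak, protein = units$protein,
                     area = 10^(5 + (i %% 7) / 10), stringsAsFactors = FALSE)
  n_extra <- n_identifications - nrow(base)
  if (n_extra < 0) {
    stop("n_identifications smaller than the number of peak records (",
         nrow(base), ")", call. = FALSE)
  }
  ## allocate extras round-robin: first `leftover` units get k+1 neighbours
  k <- n_extra %/% nrow(units)
  leftover <- n_extra %% nrow(units)
  n_per_unit <- rep(k, nrow(units))
  if (leftover > 0) n_per_unit[seq_len(leftover)] <- k + 1L
  extras <- vector("list", nrow(units))
  for (u in which(n_per_unit > 0)) {
    cand <- units$peak[u] + c(-1L, 1L, -2L, 2L, -3L, 3L)
    cand <- cand[cand >= 1 & cand <= 10]
    if (n_per_unit[u] > length(cand)) {
      stop("cannot place ", n_per_unit[u], " extra records around fraction ",
           units$peak[u], call. = FALSE)
    }
    extras[[u]] <- data.frame(
      specimen = units$specimen[u], direction = units$direction[u],
      fraction = cand[seq_len(n_per_unit[u])], protein = units$protein[u],
      area = 10^(3 + (u %% 5) / 10), stringsAsFactors = FALSE)
  }
  quant <- rbind(base, do.call(rbind, extras))
  quant <- quant[order(quant$specimen, quant$direction, quant$protein,
                       quant$fraction), ]
  rownames(quant) <- NULL
  quant <- validate_quant(quant)
  stopifnot(nrow(quant) == n_identifications)

  n_classes <- sum(vapply(classes, `[[`, numeric(1), "n_proteins"))
  expected <- list(
    n_distinct = length(unique(units$protein)),
    n_identifications = n_identifications,
    group_I = n_classes,
    group_II = n_nonequilibrium,
    unclassified = n_partial,
    n_common_all = n_classes + n_nonequilibrium + n_partial)
  structure(list(quant = quant, densities = validate_densities(densities),
                 specimens = specimens, expected = expected),
            class = "ev_overlap_sim")
}
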