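## Partitioning proteins by detection pattern and PFD drift pattern.
##
## Group I   = at equilibrium in every specimen; partitioned by exact equality
##             of the per-specimen PFD tuple:
##   IA-k    = non-constant tuples ("specimen-specific density drift"); the
##             tuple containing the reference marker (CD63 by default) is
##             IA-1, the rest are numbered by descending size;
##   IB      = constant tuples (same density in every specimen).
## Group II  = detected in both directions in every specimen, at equilibrium
##             in none.
## unclassified = detected in both directions everywhere, equilibrium in some
##             but not all specimens.
## Proteins not detected in both directions of every specimen fall outside
## this partition (group NA; "X" entries in the results sheet).

#' Detection-overlap summary across specimens
#'
#' A protein counts as identified in a specimen when it is detected
#' (area > 0) in at least one of that specimen's 20 fractions (2 directions x
#' 10 fractions).  Returns the exclusive region counts of the specimen Venn
#' diagram, per-specimen identification totals, the distinct-protein total,
#' and the total number of per-fraction identifications (detected records).
#'
#' @param quant validated quantification data frame.
#' @param specimens optional character vector fixing specimen order.
#' @return list with elements `regions` (named exclusive counts, names like
#'   `"S1&S2"`), `per_specimen`, `n_common_all` (proteins identified in every
#'   specimen), `n_distinct` and `n_identifications`.
#' @export
detection_overlap <- function(quant, specimens = NULL) {
  quant <- validate_quant(quant)
  specimens <- specimens %||% sort(unique(quant$specimen))
  det <- quant[detected_mask(quant$area), ]
  sets <- lapply(split(det$specimen, det$protein), unique)
  membership <- vapply(sets, function(s) {
    paste(specimens[specimens %in% s], collapse = "&")
  }, character(1))
  subsets <- unlist(lapply(seq_along(specimens), function(k) {
    combn(specimens, k, paste, collapse = "&", simplify = FALSE)
  }))
  regions <- stats::setNames(integer(length(subsets)), subsets)
  tab <- table(membership)
  regions[names(tab)] <- as.integer(tab)
  per_specimen <- vapply(specimens, function(s) {
    sum(vapply(sets, function(x) s %in% x, logical(1)))
  }, integer(1))
  list(regions = regions,
       per_specimen = per_specimen,
       n_common_all = unname(regions[paste(specimens, collapse = "&")]),
       n_distinct = length(sets),
       n_identifications = nrow(det))
}

#' Assign drift-pattern groups from PFD results
#'
#' Partitions proteins using the per-specimen equilibrium calls of
#' [compute_pfd()].  Subgroup equivalence is exact equality of the PFD tuple
#' at the fit's precision; constant tuples are labelled `IB` (grouped by
#' their shared value, so distinct constant densities are not silently
#' merged), and non-constant tuples are labelled `IA-1` (the tuple containing
#' `reference_marker`), then `IA-2`, `IA-3`, ... in descending order of
#' membership, ties broken by tuple lexicographic order.  If the reference
#' marker is not in Group I a warning is issued and IA numbering starts at
#' the largest subgroup.
#'
#' @param pfd data frame from [compute_pfd()].
#' @param reference_marker protein ID anchoring the IA-1 label (default
#'   `"CD63"`, the classical exosome marker).
#' @param precision decimal places used to print PFD tuples.
#' @param specimens optional character vector fixing specimen order.
#' @return data frame with one row per protein: `group` (`"IA-k"`, `"IB"`,
#'   `"II"`, `"unclassified"` or NA) and `pattern` (the PFD tuple string for
#'   Group I proteins).  The attribute `"subgroups"` tabulates each Group I
#'   subgroup: label, pattern, size and whether the tuple is constant.
#' @export
assign_groups <- function(pfd, reference_marker = "CD63", precision = 2,
                          specimens = NULL) {
  stopifnot(is.data.frame(pfd))
  specimens <- specimens %||% sort(unique(pfd$specimen))
  proteins <- sort(unique(pfd$protein))
  idx <- matrix(match(paste(rep(proteins, length(specimens)),
                            rep(specimens, each = length(proteins))),
                      paste(pfd$protein, pfd$specimen)),
                nrow = length(proteins),
                dimnames = list(proteins, specimens))
  status <- matrix(pfd$status[idx], nrow = length(proteins),
                   dimnames = dimnames(idx))
  status[is.na(status)] <- "X"
  at_eq <- matrix(pfd$at_equilibrium[idx], nrow = length(proteins))
  at_eq[is.na(at_eq)] <- FALSE
  pfd_m <- matrix(pfd$pfd[idx], nrow = length(proteins))
  eligible <- apply(status != "X", 1, all)
  eq_all <- eligible & apply(at_eq, 1, all)
  eq_none <- eligible & apply(!at_eq, 1, all)

  group <- rep(NA_character_, length(proteins))
  pattern <- rep(NA_character_, length(proteins))
  group[eligible] <- "unclassified"
  group[eq_none] <- "II"

  sub_tab <- data.frame(label = character(0), pattern = character(0),
                        n = integer(0), constant = logical(0),
                        stringsAsFactors = FALSE)
  if (any(eq_all)) {
    tuples <- apply(pfd_m[eq_all, , drop = FALSE], 1, function(v) {
      paste(fmt_density(v, precision), collapse = "/")
    })
    constant <- apply(pfd_m[eq_all, , drop = FALSE], 1, function(v) {
      length(unique(v)) == 1L
    })
    pattern[eq_all] <- tuples
    tup_info <- unique(data.frame(pattern = tuples, constant = constant,
                                  stringsAsFactors = FALSE))
    tup_info$n <- as.integer(table(tuples)[tup_info$pattern])

    marker_tuple <- NA_character_
    gI_proteins <- proteins[eq_all]
    if (reference_marker %in% gI_proteins) {
      marker_tuple <- tuples[match(reference_marker, gI_proteins)]
      if (tup_info$constant[tup_info$pattern == marker_tuple]) {
        ## the marker sits in a constant tuple: it anchors nothing
        marker_tuple <- NA_character_
      }
    } else {
      warning("reference marker '", reference_marker,
              "' is not in Group I; IA numbering starts at the largest",
              " subgroup", call. = FALSE)
    }
    ia <- tup_info[!tup_info$constant, , drop = FALSE]
    ia <- ia[order(-ia$n, ia$pattern), , drop = FALSE]
    if (!is.na(marker_tuple)) {
      ia <- rbind(ia[ia$pattern == marker_tuple, , drop = FALSE],
                  ia[ia$pattern != marker_tuple, , drop = FALSE])
    }
    ia$label <- if (nrow(ia)) paste0("IA-", seq_len(nrow(ia))) else character(0)
    ib <- tup_info[tup_info$constant, , drop = FALSE]
    ib <- ib[order(ib$pattern), , drop = FALSE]
    ib$label <- rep("IB", nrow(ib))
    sub_tab <- rbind(ia[c("label", "pattern", "n", "constant")],
                     ib[c("label", "pattern", "n", "constant")])
    rownames(sub_tab) <- NULL
    group[eq_all] <- sub_tab$label[match(tuples, sub_tab$pattern)]
  }

  out <- data.frame(protein = proteins, group = group, pattern = pattern,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "subgroups") <- sub_tab
  out
}

#' Group-I membership
#'
#' Convenience accessor: the proteins at equilibrium in every specimen.
#'
#' @param pfd data frame from [compute_pfd()].
#' @return character vector of protein IDs.
#' @export
group_I_proteins <- function(pfd) {
  eq <- tapply(pfd$at_equilibrium, pfd$protein, all)
  sort(names(eq)[eq])
}

#' Group-II membership
#'
#' The proteins detected in both directions in every specimen that attained
#' equilibrium in none.
#'
#' @param pfd data frame from [compute_pfd()].
#' @return character vector of protein IDs.
#' @export
group_II_proteins <- function(pfd) {
  both <- tapply(pfd$status != "X", pfd$protein, all)
  none_eq <- tapply(!pfd$at_equilibrium, pfd$protein, all)
  sort(names(both)[both & none_eq])
}
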