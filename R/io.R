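## Tabular I/O with strict validation.
##
## Two input tables drive the analysis:
##   * quant table:   specimen, direction, fraction (1-10), protein, area
##                    (the label-free MS "total area"; 0/absent = not detected)
##   * density table: specimen, direction, fraction, density (g/ml, measured
##                    with a refractometer for every tube separately)
## Output mirrors a per-protein results sheet: one row per protein with a
## subgroup label and one PFD column per specimen ("X" when the protein was
## not detected in either or both directions, "N. E." when detected in both
## but not at equilibrium).

#' Validate a quantification table
#'
#' Checks the invariants of a per-fraction protein quantification table:
#' required columns, fractions in 1..10, non-negative areas, canonical
#' direction labels, and uniqueness of (specimen, direction, fraction,
#' protein) keys.  Returns the table with canonicalized columns.
#'
#' @param quant data frame with columns `specimen`, `direction`, `fraction`,
#'   `protein`, `area`.
#' @return the validated data frame (directions canonicalized, fraction
#'   integer), invisibly usable in place of the input.
#' @seealso [read_quant_table()]
#' @export
validate_quant <- function(quant) {
  stopifnot(is.data.frame(quant))
  missing <- setdiff(.QUANT_COLS, names(quant))
  if (length(missing)) {
    stop("quant table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  quant <- as.data.frame(quant)[.QUANT_COLS]
  quant$specimen <- as.character(quant$specimen)
  quant$protein <- as.character(quant$protein)
  quant$direction <- normalize_direction(quant$direction)
  frac <- suppressWarnings(as.numeric(quant$fraction))
  bad <- which(is.na(frac) | frac != as.integer(frac) | frac < 1 | frac > 10)
  if (length(bad)) {
    stop("fraction outside 1-10 (or non-integer) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  quant$fraction <- as.integer(frac)
  area <- suppressWarnings(as.numeric(quant$area))
  bad <- which(!is.na(quant$area) & is.na(area))
  if (length(bad)) {
    stop("non-numeric area at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  neg <- which(!is.na(area) & area < 0)
  if (length(neg)) {
    stop("negative area at row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  quant$area <- area
  key <- record_key(quant, .QUANT_COLS[1:4])
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (specimen, direction, fraction, protein) key at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  rownames(quant) <- NULL
  quant
}

#' Read a per-fraction protein quantification table
#'
#' Reads a UTF-8 tab-delimited table with a header row.  The five standard
#' fields are `specimen`, `direction`, `fraction`, `protein` and `area`;
#' `col_map` renames non-standard headers (names = standard field, values =
#' header in the file), so raw exports with e.g. an `total_area` column can be
#' ingested without editing the file.  Rows with area 0 or NA are kept and
#' treated as "not detected" downstream; undetected protein x fraction pairs
#' need no row at all (sparse representation).
#'
#' @param path path to a TSV file.
#' @param col_map optional named character vector mapping standard field names
#'   to the file's column headers.
#' @return validated data frame of quantification records, row order
#'   preserved.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("specimen\tdirection\tfraction\tprotein\tarea",
#'              "S1\tdownward\t7\tCD63\t1e6"), f)
#' read_quant_table(f)
#' @export
read_quant_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- apply_col_map(df, col_map)
  validate_quant(df)
}

#' Write a quantification table
#'
#' Inverse of [read_quant_table()]; writes the standard five-column TSV.
#'
#' @param quant validated quantification data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  quant <- validate_quant(quant)
  utils::write.table(quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  for (std in names(col_map)) {
    src <- col_map[[std]]
    if (!src %in% names(df)) {
      stop("mapped column '", src, "' (for field '", std,
           "') not found in table", call. = FALSE)
    }
    names(df)[names(df) == src] <- std
  }
  df
}

#' Validate a fraction-density table
#'
#' Each tube (specimen x direction) contributes 10 fractions, F1 at the top of
#' the tube; measured densities must strictly increase with fraction number
#' within a tube.  Densities outside the plausible iodixanol range
#' \[1.00, 1.30\] g/ml are kept but trigger a warning.
#'
#' @param densities data frame with columns `specimen`, `direction`,
#'   `fraction`, `density` (accepts `density_g_per_ml` as an alias).
#' @return the validated, canonicalized data frame.
#' @export
validate_densities <- function(densities) {
  stopifnot(is.data.frame(densities))
  densities <- as.data.frame(densities)
  if (!"density" %in% names(densities) && "density_g_per_ml" %in% names(densities)) {
    names(densities)[names(densities) == "density_g_per_ml"] <- "density"
  }
  missing <- setdiff(.DENSITY_COLS, names(densities))
  if (length(missing)) {
    stop("density table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  densities <- densities[.DENSITY_COLS]
  densities$specimen <- as.character(densities$specimen)
  densities$direction <- normalize_direction(densities$direction)
  frac <- suppressWarnings(as.numeric(densities$fraction))
  if (any(is.na(frac) | frac != as.integer(frac) | frac < 1 | frac > 10)) {
    stop("density table fractions must be integers in 1-10", call. = FALSE)
  }
  densities$fraction <- as.integer(frac)
  densities$density <- as.numeric(densities$density)
  if (anyNA(densities$density)) {
    stop("missing density value(s)", call. = FALSE)
  }
  key <- record_key(densities, .DENSITY_COLS[1:3])
  if (anyDuplicated(key)) {
    stop("duplicate (specimen, direction, fraction) in density table",
         call. = FALSE)
  }
  out_of_range <- densities$density < 1.00 | densities$density > 1.30
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " density value(s) outside the plausible iodixanol range",
            " [1.00, 1.30] g/ml; kept", call. = FALSE)
  }
  tubes <- split(densities, paste(densities$specimen, densities$direction))
  for (tb in tubes) {
    tb <- tb[order(tb$fraction), ]
    if (any(diff(tb$density) <= 0)) {
      stop("densities not strictly increasing with fraction in tube ",
           tb$specimen[1], " ", tb$direction[1], call. = FALSE)
    }
  }
  rownames(densities) <- NULL
  densities
}

#' Read a fraction-density table
#'
#' @inheritParams read_quant_table
#' @return validated data frame with columns `specimen`, `direction`,
#'   `fraction`, `density`.
#' @export
read_density_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- apply_col_map(df, col_map)
  validate_densities(df)
}

#' Write a fraction-density table
#'
#' @param densities validated density data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(densities, path) {
  densities <- validate_densities(densities)
  utils::write.table(densities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the per-protein results sheet
#'
#' One row per protein: the specimens it was identified in (at least one of
#' the 20 fractions), its subgroup label, and one PFD column per specimen.  A
#' PFD column holds the density (at the fit's precision), the token `"X"` if
#' the protein was not detected in either or both directions of that
#' specimen, or `"N. E."` if it was detected in both directions but did not
#' attain equilibrium.
#'
#' @param fit an [ev_pfd()] fit, or a list with elements `pfd`,
#'   `assignments`, `specimens`, `precision` of the same shape.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(fit, path) {
  pfd <- fit$pfd
  assignments <- fit$assignments
  specimens <- fit$specimens
  digits <- fit$precision
  stopifnot(is.data.frame(pfd), is.data.frame(assignments))
  orphan <- setdiff(unique(pfd$protein), assignments$protein)
  if (length(orphan)) {
    stop("protein(s) present in PFD results but not in assignments: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  proteins <- assignments$protein
  res <- data.frame(protein = proteins, stringsAsFactors = FALSE)
  det <- pfd$status != "X"
  det_by_prot <- split(pfd$specimen[det], pfd$protein[det])
  ident <- split(pfd$specimen[pfd$identified], pfd$protein[pfd$identified])
  res$detected_in <- vapply(proteins, function(p) {
    s <- ident[[p]] %||% character(0)
    paste(specimens[specimens %in% s], collapse = ";")
  }, character(1))
  res$group <- ifelse(is.na(assignments$group), "", assignments$group)
  for (s in specimens) {
    rows <- pfd[pfd$specimen == s, ]
    rows <- rows[match(proteins, rows$protein), ]
    token <- ifelse(rows$status == "X", "X",
                    ifelse(rows$status == "NE", "N. E.",
                           fmt_density(rows$pfd, digits)))
    res[[paste0("PFD_", s)]] <- token
  }
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a results sheet
#'
#' Parses a TSV written by [write_results()] back into per-protein group
#' labels and per-specimen PFD values / status tokens, for downstream reuse
#' and round-trip checks.
#'
#' @param path path to a results TSV.
#' @return data frame with one row per protein: `protein`, `detected_in`,
#'   `group`, and for every specimen `<S>` two columns `PFD_<S>` (numeric, NA
#'   unless at equilibrium) and `status_<S>` (`"PFD"`, `"NE"` or `"X"`).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  pfd_cols <- grep("^PFD_", names(df), value = TRUE)
  if (!length(pfd_cols) || !all(c("protein", "group") %in% names(df))) {
    stop("not a results sheet: expected protein, group and PFD_* columns",
         call. = FALSE)
  }
  out <- data.frame(protein = df$protein,
                    detected_in = df$detected_in,
                    group = ifelse(df$group == "", NA_character_, df$group),
                    stringsAsFactors = FALSE)
  for (cc in pfd_cols) {
    tok <- df[[cc]]
    status <- ifelse(tok == "X", "X", ifelse(tok == "N. E.", "NE", "PFD"))
    val <- suppressWarnings(as.numeric(tok))
    val[status != "PFD"] <- NA_real_
    out[[cc]] <- val
    out[[sub("^PFD_", "status_", cc)]] <- status
  }
  out
}
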