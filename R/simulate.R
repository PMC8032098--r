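## Seeded synthetic-data generator with planted ground truth.
##
## The generator emulates the structure the analysis assumes: a few EV
## classes whose buoyant densities drift between specimens, a constant-
## density class, proteins that never equilibrate (their apparent peak is
## offset in opposite senses in the two separation directions), log-scale MS
## abundance noise, and detection dropout.  Every simulated protein carries a
## truth record, so recovery can be scored exactly.

## Default base density ladder of a tube.  Real iodixanol gradients are
## sigmoid after the run: coarse near the ends, ~0.01 g/ml steps in the
## mid-gradient region where EVs band.  This ladder spans [1.03, 1.27] g/ml
## and resolves 0.01 g/ml drifts between 1.09 and 1.16.
.DEFAULT_LADDER <- c(1.03, 1.05, 1.07, 1.09, 1.10, 1.12, 1.13, 1.16, 1.20, 1.27)

.default_classes <- function() {
  list(
    list(name = "classA", base_density = 1.09, drift = c(0.03, 0.01, 0.00),
         n_proteins = 16, marker = "CD63"),
    list(name = "classB", base_density = 1.09, drift = c(0.03, 0.04, 0.00),
         n_proteins = 59),
    list(name = "constant", base_density = 1.16, drift = c(0, 0, 0),
         n_proteins = 29),
    list(name = "minor1", base_density = 1.10, drift = c(0.03, 0.02, 0.00),
         n_proteins = 2),
    list(name = "minor2", base_density = 1.09, drift = c(0.00, 0.03, 0.04),
         n_proteins = 2),
    list(name = "minor3", base_density = 1.09, drift = c(0.01, 0.00, 0.03),
         n_proteins = 1),
    list(name = "minor4", base_density = 1.13, drift = c(0.07, 0.03, 0.00),
         n_proteins = 1),
    list(name = "minor5", base_density = 1.07, drift = c(0.00, 0.02, 0.03),
         n_proteins = 1))
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults emulate the study design the analysis targets: 3 specimens x
#' 2 directions x 10 fractions; two major drifting classes of 16 and 59
#' proteins with patterns (1.12, 1.10, 1.09) and (1.12, 1.13, 1.09) g/ml, a
#' constant class of 29 proteins at 1.16 g/ml, five minor drift patterns
#' totalling 7 proteins, and 21 never-equilibrating proteins with a 0.04 g/ml
#' direction lag.
#'
#' @param n_specimens number of specimens (default 3).
#' @param n_fractions fractions per tube (default 10).
#' @param density_range plausible span of the gradient, g/ml.
#' @param gradient_profile base density ladder of a tube (length
#'   `n_fractions`, strictly increasing); jitter is added per tube.
#' @param classes list of equilibrating classes; each a list with `name`,
#'   `base_density` (g/ml), `drift` (per-specimen offsets, g/ml),
#'   `n_proteins`, and optionally `marker` (ID given to the class's first
#'   protein).
#' @param nonequilibrium list with `n_proteins`, `direction_lag` (g/ml;
#'   apparent peak density offset `+lag` in the downward and `-lag` in the
#'   upward separation), `base_densities` (recycled over proteins) and
#'   optional `marker`.
#' @param noise list with `log10_sd` (s.d. added to log10 areas) and
#'   `dropout_prob` (independent per-record detection dropout).
#' @param abundance list with `log10_mean`, `log10_sd` of per-protein peak
#'   log10 areas.
#' @param density_jitter_sd per-fraction s.d. (g/ml) of tube-specific density
#'   jitter; distinct tubes always draw distinct jitter.
#' @param profile_sd s.d. (g/ml) of the unimodal abundance profile in density
#'   space (~ one mid-gradient fraction).
#' @param min_log10_detect detection floor: log10 areas below it are
#'   unobserved (MS detection limit).
#' @param seed integer; the single source of randomness.
#' @return validated list of class `"ev_sim_config"`.
#' @export
ev_sim_config <- function(n_specimens = 3,
                          n_fractions = 10,
                          density_range = c(1.03, 1.27),
                          gradient_profile = .DEFAULT_LADDER,
                          classes = .default_classes(),
                          nonequilibrium = list(),
                          noise = list(),
                          abundance = list(),
                          density_jitter_sd = 0.005,
                          profile_sd = 0.015,
                          min_log10_detect = 1,
                          seed = 1) {
  nonequilibrium <- utils::modifyList(
    list(n_proteins = 21, direction_lag = 0.04,
         base_densities = c(1.09, 1.10, 1.12, 1.13, 1.16), marker = "AMY1"),
    nonequilibrium)
  noise <- utils::modifyList(list(log10_sd = 0.2, dropout_prob = 0.05), noise)
  abundance <- utils::modifyList(list(log10_mean = 6, log10_sd = 1), abundance)

  stopifnot(n_specimens >= 1, n_fractions >= 2,
            length(density_range) == 2, diff(density_range) > 0,
            length(gradient_profile) == n_fractions,
            all(diff(gradient_profile) > 0),
            noise$log10_sd >= 0,
            noise$dropout_prob >= 0, noise$dropout_prob <= 1,
            abundance$log10_sd >= 0,
            density_jitter_sd >= 0, profile_sd > 0,
            nonequilibrium$n_proteins >= 0,
            length(seed) == 1, is.finite(seed))
  for (cls in classes) {
    stopifnot(is.character(cls$name), cls$n_proteins >= 1,
              length(cls$drift) == n_specimens)
    dens <- cls$base_density + cls$drift
    if (any(dens < density_range[1] | dens > density_range[2])) {
      stop("class '", cls$name, "' densities fall outside density_range",
           call. = FALSE)
    }
  }
  if (anyDuplicated(vapply(classes, `[[`, character(1), "name"))) {
    stop("class names must be unique", call. = FALSE)
  }
  structure(list(n_specimens = n_specimens, n_fractions = n_fractions,
                 density_range = density_range,
                 gradient_profile = gradient_profile,
                 classes = classes, nonequilibrium = nonequilibrium,
                 noise = noise, abundance = abundance,
                 density_jitter_sd = density_jitter_sd,
                 profile_sd = profile_sd,
                 min_log10_detect = min_log10_detect,
                 seed = as.integer(seed)),
            class = "ev_sim_config")
}

#' Simulate one tube's density ladder
#'
#' The base gradient profile plus per-fraction Gaussian jitter, re-sorted so
#' densities stay strictly increasing with fraction number.  Uses the current
#' RNG state; [simulate_ev_dataset()] seeds it from the config.
#'
#' @param config an [ev_sim_config()].
#' @param specimen,direction labels for the returned records.
#' @return data frame with columns `specimen`, `direction`, `fraction`,
#'   `density`.
#' @export
simulate_gradient <- function(config, specimen, direction) {
  d <- config$gradient_profile +
    stats::rnorm(config$n_fractions, 0, config$density_jitter_sd)
  d <- sort(d)
  ## a.s. strictly increasing; nudge exact ties for safety
  while (any(diff(d) <= 0)) {
    i <- which(diff(d) <= 0)[1] + 1L
    d[i] <- d[i] + 1e-9
  }
  data.frame(specimen = specimen, direction = direction,
             fraction = seq_len(config$n_fractions), density = d,
             stringsAsFactors = FALSE)
}

## Protein id table + per-specimen target densities (truth).
build_truth <- function(config) {
  specimens <- sprintf("S%d", seq_len(config$n_specimens))
  rows <- list()
  for (cls in config$classes) {
    ids <- sprintf("%s.%03d", toupper(gsub("[^A-Za-z0-9]", "", cls$name)),
                   seq_len(cls$n_proteins))
    if (!is.null(cls$marker)) ids[1] <- cls$marker
    tg <- cls$base_density + cls$drift
    rows[[length(rows) + 1L]] <- data.frame(
      protein = ids, class = cls$name, equilibrating = TRUE,
      matrix(rep(tg, each = length(ids)), nrow = length(ids),
             dimnames = list(NULL, paste0("target_", specimens))),
      stringsAsFactors = FALSE)
  }
  ne <- config$nonequilibrium
  if (ne$n_proteins > 0) {
    ids <- sprintf("NE.%03d", seq_len(ne$n_proteins))
    if (!is.null(ne$marker)) ids[1] <- ne$marker
    base <- rep_len(ne$base_densities, ne$n_proteins)
    rows[[length(rows) + 1L]] <- data.frame(
      protein = ids, class = "nonequilibrium", equilibrating = FALSE,
      matrix(rep(base, config$n_specimens), nrow = length(ids),
             dimnames = list(NULL, paste0("target_", specimens))),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  if (anyDuplicated(truth$protein)) {
    stop("duplicate protein IDs across simulated classes", call. = FALSE)
  }
  rownames(truth) <- NULL
  truth
}

#' Simulate a complete dataset with ground truth
#'
#' Draws the per-tube density ladders, then for every protein and unit
#' centres a unimodal (Gaussian in density space) abundance profile on the
#' fraction whose density is nearest the protein's target density -- the
#' class base density plus the specimen drift; for never-equilibrating
#' proteins, offset by `+direction_lag` (downward) or `-direction_lag`
#' (upward).  Log10 areas are the per-protein abundance times the profile
#' plus Gaussian noise; records below the detection floor or hit by dropout
#' are omitted (sparse table), and areas are emitted on the linear scale.
#'
#' All randomness flows from `config$seed`; the caller's RNG state is
#' restored on exit.
#'
#' @param config an [ev_sim_config()].
#' @return a list of class `"ev_sim"`: `quant`, `densities`, `truth` (one row
#'   per protein: class, equilibrating flag, per-specimen target densities),
#'   `specimens` and the `config` used.
#' @examples
#' sim <- simulate_ev_dataset(ev_sim_config(seed = 7))
#' head(sim$quant)
#' @export
simulate_ev_dataset <- function(config = ev_sim_config()) {
  stopifnot(inherits(config, "ev_sim_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  specimens <- sprintf("S%d", seq_len(config$n_specimens))
  truth <- build_truth(config)
  n_prot <- nrow(truth)

  ## per-protein peak log10 abundance, clamped above the detection floor so
  ## every planted protein is observable
  A <- stats::rnorm(n_prot, config$abundance$log10_mean,
                    config$abundance$log10_sd)
  A <- pmax(A, config$min_log10_detect + 1)

  dens_list <- list()
  quant_list <- list()
  for (s in specimens) {
    for (dir in .DIRECTIONS) {
      ladder <- simulate_gradient(config, s, dir)
      dens_list[[length(dens_list) + 1L]] <- ladder

      target <- truth[[paste0("target_", s)]]
      lag <- ifelse(truth$equilibrating, 0,
                    ifelse(dir == "downward", 1, -1) *
                      config$nonequilibrium$direction_lag)
      tg <- target + lag
      ## proteins x fractions profile, peak normalized to 1
      dist2 <- outer(tg, ladder$density, function(a, b) (b - a)^2)
      g <- exp(-dist2 / (2 * config$profile_sd^2))
      gmax <- apply(g, 1, max)
      zero <- gmax <= 0
      if (any(zero)) { # target far outside the ladder: spike at nearest
        nearest <- apply(dist2[zero, , drop = FALSE], 1, which.min)
        g[zero, ] <- 0
        g[cbind(which(zero), nearest)] <- 1
        gmax[zero] <- 1
      }
      g <- g / gmax
      l10 <- A * g
      if (config$noise$log10_sd > 0) {
        l10 <- l10 + stats::rnorm(length(l10), 0, config$noise$log10_sd)
      }
      keep <- l10 >= config$min_log10_detect
      if (config$noise$dropout_prob > 0) {
        keep <- keep & stats::runif(length(l10)) >= config$noise$dropout_prob
      }
      idx <- which(keep, arr.ind = TRUE)
      quant_list[[length(quant_list) + 1L]] <- data.frame(
        specimen = s, direction = dir,
        fraction = idx[, 2],
        protein = truth$protein[idx[, 1]],
        area = 10^l10[idx],
        stringsAsFactors = FALSE)
    }
  }
  densities <- do.call(rbind, dens_list)
  quant <- do.call(rbind, quant_list)
  quant <- quant[order(quant$specimen, quant$direction, quant$protein,
                       quant$fraction), ]
  rownames(quant) <- rownames(densities) <- NULL
  structure(list(quant = quant, densities = densities, truth = truth,
                 specimens = specimens, config = config),
            class = "ev_sim")
}

#' @export
print.ev_sim <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$truth), "proteins,",
      length(x$specimens), "specimens,", nrow(x$quant),
      "detected records (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Score recovery of the planted structure
#'
#' Compares a fit against the generator's ground truth.  A member of an
#' equilibrating class is recovered when the fit places it in Group I with
#' exactly the planted PFD tuple (at the fit's precision); a member of the
#' never-equilibrating class is recovered when the fit places it in Group II.
#' The PFD error is the mean absolute difference between fitted PFDs and the
#' planted target densities.
#'
#' Proteins present in the truth but absent from the fit (lost to dropout)
#' count as not recovered; proteins in the fit that the truth does not know
#' are an error.
#'
#' @param truth truth data frame from a simulated dataset (or the `"ev_sim"`
#'   object itself).
#' @param fit an [ev_pfd()] fit of the simulated data.
#' @return data frame with one row per planted class: `class`, `n`,
#'   `n_recovered`, `recall`, `mean_abs_pfd_error`; the attribute
#'   `"overall"` holds the pooled recall and error.
#' @export
recovery_report <- function(truth, fit) {
  if (inherits(truth, "ev_sim")) truth <- truth$truth
  stopifnot(is.data.frame(truth), inherits(fit, "ev_pfd"))
  a <- fit$assignments
  extra <- setdiff(a$protein, truth$protein)
  if (length(extra)) {
    stop("fit contains protein(s) unknown to the truth: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  digits <- fit$precision
  tcols <- grep("^target_", names(truth), value = TRUE)
  planted_pattern <- apply(truth[tcols], 1, function(v) {
    paste(fmt_density(trunc_density(v, digits), digits), collapse = "/")
  })
  i <- match(truth$protein, a$protein)
  fitted_group <- a$group[i]
  fitted_pattern <- a$pattern[i]
  recovered <- ifelse(truth$equilibrating,
                      !is.na(fitted_pattern) & fitted_pattern == planted_pattern,
                      !is.na(fitted_group) & fitted_group == "II")

  pfd_m <- coef(fit)
  err <- abs(pfd_m[match(truth$protein, rownames(pfd_m)), , drop = FALSE] -
               as.matrix(truth[tcols]))
  per_prot_err <- rowMeans(err, na.rm = TRUE)

  cls <- unique(truth$class)
  out <- do.call(rbind, lapply(cls, function(cc) {
    m <- truth$class == cc
    data.frame(class = cc, n = sum(m), n_recovered = sum(recovered[m]),
               recall = mean(recovered[m]),
               mean_abs_pfd_error =
                 if (all(is.nan(per_prot_err[m]) | is.na(per_prot_err[m])))
                   NA_real_ else mean(per_prot_err[m], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "overall") <- list(
    recall = mean(recovered),
    mean_abs_pfd_error =
      if (all(is.na(per_prot_err) | is.nan(per_prot_err))) NA_real_
      else mean(per_prot_err, na.rm = TRUE))
  out
}
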