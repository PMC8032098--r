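# Fixtures built in code: a worked CD63 dataset reproducing the published
# peak fractions/densities, and small random tables for round-trip checks.

# Ladders chosen so the CD63-carrying fractions sit at the published
# densities: S1 F7 (both directions) at 1.12, S2 F6 at 1.10, S3 F6 downward /
# F5 upward both at 1.09 g/ml.
cd63_ladders <- function() {
  list(
    "S1 downward" = c(1.03, 1.045, 1.06, 1.08, 1.095, 1.105, 1.12, 1.15, 1.19, 1.24),
    "S1 upward"   = c(1.03, 1.046, 1.061, 1.081, 1.096, 1.106, 1.12, 1.151, 1.191, 1.241),
    "S2 downward" = c(1.03, 1.045, 1.06, 1.075, 1.09, 1.10, 1.13, 1.16, 1.20, 1.25),
    "S2 upward"   = c(1.03, 1.044, 1.059, 1.074, 1.089, 1.10, 1.131, 1.161, 1.201, 1.251),
    "S3 downward" = c(1.02, 1.04, 1.055, 1.07, 1.08, 1.09, 1.115, 1.14, 1.18, 1.23),
    "S3 upward"   = c(1.02, 1.04, 1.06, 1.075, 1.09, 1.11, 1.13, 1.15, 1.19, 1.24))
}

cd63_fixture <- function() {
  lad <- cd63_ladders()
  dens <- do.call(rbind, lapply(names(lad), function(k) {
    parts <- strsplit(k, " ")[[1]]
    data.frame(specimen = parts[1], direction = parts[2], fraction = 1:10,
               density = lad[[k]], stringsAsFactors = FALSE)
  }))
  peak <- c("S1 downward" = 7, "S1 upward" = 7,
            "S2 downward" = 6, "S2 upward" = 6,
            "S3 downward" = 6, "S3 upward" = 5)
  quant <- do.call(rbind, lapply(names(peak), function(k) {
    parts <- strsplit(k, " ")[[1]]
    f <- peak[[k]]
    data.frame(specimen = parts[1], direction = parts[2],
               fraction = c(f - 1, f, f + 1), protein = "CD63",
               area = c(2e5, 3e6, 1e5), stringsAsFactors = FALSE)
  }))
  list(quant = quant, densities = dens)
}

# Random valid quantification table (no duplicate keys) for round trips.
random_quant <- function(n = 100, seed = 42) {
  set.seed(seed)
  grid <- expand.grid(specimen = c("S1", "S2"),
                      direction = c("downward", "upward"),
                      fraction = 1:10,
                      protein = sprintf("P%02d", 1:10),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), n), ]
  grid$area <- round(10^runif(n, 2, 7), 3)
  rownames(grid) <- NULL
  grid
}

# Small fast simulation config for property tests.
small_sim_config <- function(log10_sd = 0, dropout = 0, jitter = 0,
                             seed = 1, n_per_class = 6) {
  classes <- list(
    list(name = "classA", base_density = 1.09, drift = c(0.03, 0.01, 0),
         n_proteins = n_per_class, marker = "CD63"),
    list(name = "classB", base_density = 1.09, drift = c(0.03, 0.04, 0),
         n_proteins = n_per_class),
    list(name = "constant", base_density = 1.16, drift = c(0, 0, 0),
         n_proteins = n_per_class))
  ev_sim_config(classes = classes,
                nonequilibrium = list(n_proteins = n_per_class),
                noise = list(log10_sd = log10_sd, dropout_prob = dropout),
                density_jitter_sd = jitter, seed = seed)
}

# Swap direction labels everywhere (downward <-> upward).
swap_directions <- function(df) {
  df$direction <- ifelse(df$direction == "downward", "upward", "downward")
  df
}
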