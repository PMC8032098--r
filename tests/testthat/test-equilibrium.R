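test_that("log10 transform follows the detection convention", {
  expect_equal(log10_area(c(1e4, 1, 0, NA)), c(4, 0, NA, NA))
  expect_error(log10_area(-1), "negative")
})

test_that("unit normalization divides by the per-unit per-protein max", {
  quant <- data.frame(specimen = "S1", direction = "downward",
                      fraction = c(3, 6), protein = "P1",
                      area = c(1e2, 1e4))
  norm <- normalize_units(quant)
  expect_equal(norm$normalized[order(norm$fraction)], c(0.5, 1.0))

  # all detected fractions equal -> all normalized exactly 1
  eq <- data.frame(specimen = "S1", direction = "downward", fraction = 1:5,
                   protein = "P1", area = rep(1e3, 5))
  expect_true(all(normalize_units(eq)$normalized == 1))

  # degenerate profile (max log10 <= 0) is kept unscaled and flagged
  tiny <- data.frame(specimen = "S1", direction = "downward",
                     fraction = c(1, 2), protein = "P1", area = c(0.1, 0.5))
  nt <- normalize_units(tiny)
  expect_false(any(nt$normalizable))
  expect_equal(sort(nt$normalized), sort(log10(c(0.1, 0.5))))
})

test_that("normalized argmax equals raw argmax over random profiles", {
  set.seed(11)
  for (i in 1:1000) {
    n_det <- sample(1:10, 1)
    fr <- sort(sample(1:10, n_det))
    area <- 10^runif(n_det, 0.5, 8)
    quant <- data.frame(specimen = "S1", direction = "downward",
                        fraction = fr, protein = "P", area = area)
    norm <- normalize_units(quant)
    expect_equal(norm$fraction[which.max(norm$normalized)],
                 fr[which.max(area)])
  }
})

test_that("peak search is invariant under strictly increasing transforms", {
  dens <- data.frame(specimen = "S1", direction = "downward", fraction = 1:10,
                     density = seq(1.04, 1.25, length.out = 10))
  transforms <- list(function(x) x^3,
                     function(x) 2 * x + 5,
                     function(x) sqrt(x),
                     function(x) log1p(x))
  set.seed(12)
  for (i in 1:250) {
    fr <- sort(sample(1:10, sample(2:10, 1)))
    area <- 10^runif(length(fr), 0, 7)
    quant <- data.frame(specimen = "S1", direction = "downward",
                        fraction = fr, protein = "P", area = area)
    base_peak <- peak_fractions(quant, dens)$fraction
    tr <- transforms[[1 + (i %% length(transforms))]]
    quant$area <- tr(quant$area)
    expect_identical(peak_fractions(quant, dens)$fraction, base_peak)
  }
})

test_that("peak ties break toward the lower fraction and are reported", {
  dens <- data.frame(specimen = "S1", direction = "downward", fraction = 1:10,
                     density = seq(1.04, 1.25, length.out = 10))
  quant <- data.frame(specimen = "S1", direction = "downward",
                      fraction = c(3, 7), protein = "P", area = c(5, 5))
  expect_message(p <- peak_fractions(quant, dens), "tie")
  expect_identical(p$fraction, 3L)
})

test_that("single detected fraction is its own peak", {
  dens <- data.frame(specimen = "S1", direction = "downward", fraction = 1:10,
                     density = seq(1.04, 1.25, length.out = 10))
  quant <- data.frame(specimen = "S1", direction = "downward", fraction = 5,
                      protein = "P", area = 42)
  p <- peak_fractions(quant, dens)
  expect_identical(p$fraction, 5L)
  expect_equal(p$density, dens$density[5])
})

test_that("equilibrium compares densities, not fraction indices", {
  fx <- cd63_fixture()
  pfd <- compute_pfd(fx$quant, fx$densities)
  s3 <- pfd[pfd$specimen == "S3", ]
  # F6 downward vs F5 upward, both 1.09 g/ml -> equilibrium
  expect_identical(s3$peak_fraction_down, 6L)
  expect_identical(s3$peak_fraction_up, 5L)
  expect_true(s3$at_equilibrium)
  expect_equal(s3$pfd, 1.09)
})

test_that("identical profiles in both directions imply equilibrium", {
  dens <- do.call(rbind, lapply(c("downward", "upward"), function(d) {
    data.frame(specimen = "S1", direction = d, fraction = 1:10,
               density = seq(1.04, 1.25, length.out = 10))
  }))
  quant <- do.call(rbind, lapply(c("downward", "upward"), function(d) {
    data.frame(specimen = "S1", direction = d, fraction = c(4, 8),
               protein = "P", area = c(10, 1e6))
  }))
  pfd <- compute_pfd(quant, dens)
  expect_true(pfd$at_equilibrium)
  expect_equal(pfd$pfd, trunc_density(dens$density[8], 2))
})

test_that("a protein detected in only one direction gets status X, never NE", {
  dens <- do.call(rbind, lapply(c("downward", "upward"), function(d) {
    data.frame(specimen = "S1", direction = d, fraction = 1:10,
               density = seq(1.04, 1.25, length.out = 10))
  }))
  quant <- data.frame(specimen = "S1", direction = "downward", fraction = 5,
                      protein = "P", area = 10)
  pfd <- compute_pfd(quant, dens)
  expect_identical(pfd$status, "X")
  expect_false(pfd$at_equilibrium)
  expect_true(is.na(pfd$pfd))
})

test_that("compute_pfd is symmetric in the two directions", {
  set.seed(13)
  for (i in 1:25) {
    sim <- simulate_ev_dataset(small_sim_config(log10_sd = 0.4,
                                                dropout = 0.1,
                                                jitter = 0.004, seed = i))
    a <- compute_pfd(sim$quant, sim$densities)
    b <- compute_pfd(swap_directions(sim$quant), swap_directions(sim$densities))
    expect_equal(a$at_equilibrium, b$at_equilibrium)
    expect_equal(a$pfd, b$pfd)
    expect_equal(a$status, b$status)
  }
})

test_that("coarsening the comparison precision never destroys equilibrium", {
  set.seed(14)
  for (i in 1:400) {
    d_down <- sort(runif(10, 1.03, 1.27))
    d_up <- sort(runif(10, 1.03, 1.27))
    dens <- rbind(data.frame(specimen = "S1", direction = "downward",
                             fraction = 1:10, density = d_down),
                  data.frame(specimen = "S1", direction = "upward",
                             fraction = 1:10, density = d_up))
    quant <- do.call(rbind, lapply(c("downward", "upward"), function(d) {
      data.frame(specimen = "S1", direction = d, fraction = sample(1:10, 3),
                 protein = "P", area = 10^runif(3, 1, 7))
    }))
    eq <- vapply(c(3, 2, 1, 0), function(p) {
      compute_pfd(quant, dens, precision = p)$at_equilibrium
    }, logical(1))
    # once at equilibrium at a fine precision, every coarser one agrees
    expect_true(all(diff(eq) >= 0))
  }
})

test_that("density truncation is exact on representative values", {
  expect_equal(trunc_density(c(1.12, 1.13, 1.1297, 1.0999), 2),
               c(1.12, 1.13, 1.12, 1.09))
  expect_equal(trunc_density(1.156, 1), 1.1)
  expect_equal(trunc_density(1.156, 0), 1)
})
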