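test_that("simulated gradients are monotone, span the range, and differ by tube", {
  cfg <- ev_sim_config(seed = 1)
  set.seed(1)
  # no jitter -> identical ladders for all tubes
  cfg0 <- ev_sim_config(density_jitter_sd = 0, seed = 1)
  g1 <- simulate_gradient(cfg0, "S1", "downward")
  g2 <- simulate_gradient(cfg0, "S2", "upward")
  expect_equal(g1$density, g2$density)

  # with jitter: strictly increasing for any seed; endpoints near the range
  ends <- matrix(NA_real_, 100, 2)
  for (i in 1:100) {
    set.seed(i)
    g <- simulate_gradient(cfg, "S1", "downward")
    expect_true(all(diff(g$density) > 0))
    ends[i, ] <- range(g$density)
  }
  jit <- cfg$density_jitter_sd
  expect_true(all(abs(ends[, 1] - cfg$density_range[1]) < 3 * jit))
  expect_true(all(abs(ends[, 2] - cfg$density_range[2]) < 3 * jit))
  # distinct tubes get distinct jitter within one dataset
  sim <- simulate_ev_dataset(cfg)
  tubes <- split(sim$densities$density,
                 paste(sim$densities$specimen, sim$densities$direction))
  expect_gt(length(unique(vapply(tubes, paste, character(1),
                                 collapse = ","))), 1)
})

test_that("the same seed reproduces the dataset exactly and leaves the RNG alone", {
  cfg <- ev_sim_config(seed = 99)
  a <- simulate_ev_dataset(cfg)
  set.seed(123)
  before <- .Random.seed
  b <- simulate_ev_dataset(cfg)
  expect_identical(before, .Random.seed)
  expect_identical(a$quant, b$quant)
  expect_identical(a$densities, b$densities)
  expect_identical(a$truth, b$truth)
  # a different seed gives a different dataset
  c <- simulate_ev_dataset(ev_sim_config(seed = 100))
  expect_false(identical(a$quant, c$quant))
})

test_that("zero-noise datasets are identified exactly (full circle)", {
  cfg <- small_sim_config(seed = 21)
  sim <- simulate_ev_dataset(cfg)
  fit <- ev_pfd(sim$quant, sim$densities)
  rr <- recovery_report(sim, fit)
  expect_true(all(rr$recall == 1))
  eqcls <- rr$class != "nonequilibrium"
  expect_true(all(rr$mean_abs_pfd_error[eqcls] < 1e-9))
  # planted never-equilibrating proteins all land in Group II
  expect_setequal(group_II_proteins(fit$pfd),
                  sim$truth$protein[!sim$truth$equilibrating])
})

test_that("recovery_report matches an independent brute-force tally", {
  cfg <- small_sim_config(log10_sd = 0.3, dropout = 0.1, seed = 8,
                          n_per_class = 25)
  sim <- simulate_ev_dataset(cfg)
  fit <- suppressWarnings(ev_pfd(sim$quant, sim$densities))
  rr <- recovery_report(sim, fit)

  # brute force: walk the truth table row by row
  a <- fit$assignments
  digits <- fit$precision
  tally <- list()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    j <- which(a$protein == tr$protein)
    hit <- FALSE
    if (length(j) == 1) {
      if (tr$equilibrating) {
        want <- paste(sprintf(paste0("%.", digits, "f"),
                              trunc_density(unlist(tr[paste0("target_",
                                                             sim$specimens)]),
                                            digits)),
                      collapse = "/")
        hit <- !is.na(a$pattern[j]) && a$pattern[j] == want
      } else {
        hit <- !is.na(a$group[j]) && a$group[j] == "II"
      }
    }
    tally[[tr$class]] <- c(tally[[tr$class]], hit)
  }
  for (k in seq_len(nrow(rr))) {
    expect_equal(rr$recall[k], mean(tally[[rr$class[k]]]),
                 info = rr$class[k])
  }
})

test_that("recovery degrades monotonically with abundance noise", {
  levels <- c(0, 0.6, 1.4)
  seeds <- 1:5
  mean_recall <- sapply(levels, function(sd_) {
    mean(sapply(seeds, function(s) {
      sim <- simulate_ev_dataset(small_sim_config(log10_sd = sd_, seed = s))
      fit <- suppressWarnings(ev_pfd(sim$quant, sim$densities))
      rr <- recovery_report(sim, fit)
      mean(rr$recall[rr$class != "nonequilibrium"])
    }))
  })
  expect_true(all(diff(mean_recall) <= 0))
  expect_lt(mean_recall[3], mean_recall[1])
})

test_that("proteins unknown to the truth are a scoring error", {
  sim <- simulate_ev_dataset(small_sim_config(seed = 2))
  other <- simulate_ev_dataset(small_sim_config(seed = 2))
  other$truth <- other$truth[1:3, ]
  fit <- ev_pfd(sim$quant, sim$densities)
  expect_error(recovery_report(other$truth, fit), "unknown to the truth")
})

test_that("config validation rejects impossible settings", {
  expect_error(ev_sim_config(noise = list(dropout_prob = 1.5)))
  expect_error(ev_sim_config(density_jitter_sd = -1))
  expect_error(ev_sim_config(classes = list(
    list(name = "bad", base_density = 1.40, drift = c(0, 0, 0),
         n_proteins = 1))), "density_range")
})
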