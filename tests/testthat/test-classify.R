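make_det_quant <- function(sets) {
  # sets: named list protein -> character vector of specimens
  do.call(rbind, lapply(names(sets), function(p) {
    do.call(rbind, lapply(sets[[p]], function(s) {
      data.frame(specimen = s, direction = "downward", fraction = 5,
                 protein = p, area = 10, stringsAsFactors = FALSE)
    }))
  }))
}

test_that("detection overlap handles identity and disjointness", {
  specs <- c("S1", "S2", "S3")
  # identical sets -> everything in the 3-way intersection
  sets <- setNames(rep(list(specs), 4), sprintf("P%d", 1:4))
  ov <- detection_overlap(make_det_quant(sets), specs)
  expect_equal(unname(ov$regions["S1&S2&S3"]), 4L)
  expect_true(all(ov$regions[setdiff(names(ov$regions), "S1&S2&S3")] == 0))
  expect_equal(unname(ov$per_specimen), c(4L, 4L, 4L))

  # pairwise-disjoint sets -> all intersection regions 0
  sets <- list(A = "S1", B = "S1", C = "S2", D = "S3")
  ov <- detection_overlap(make_det_quant(sets), specs)
  expect_equal(unname(ov$regions[c("S1", "S2", "S3")]), c(2L, 1L, 1L))
  expect_true(all(ov$regions[grepl("&", names(ov$regions))] == 0))
  expect_equal(ov$n_distinct, 4L)
  expect_equal(ov$n_identifications, 4L)
})

test_that("group assignment reproduces the drift-pattern partition", {
  sim <- simulate_ev_dataset(small_sim_config(seed = 3))
  fit <- ev_pfd(sim$quant, sim$densities)
  a <- fit$assignments
  sub <- attr(a, "subgroups")

  # IA-1 is the tuple containing the reference marker
  expect_identical(a$group[a$protein == "CD63"], "IA-1")
  expect_identical(sub$pattern[sub$label == "IA-1"], "1.12/1.10/1.09")
  # constant tuples go to IB
  expect_identical(sub$pattern[sub$label == "IB"], "1.16/1.16/1.16")
  # never-equilibrating proteins form Group II
  expect_identical(unique(a$group[grepl("^NE\\.|^AMY1$", a$protein)]), "II")
})

test_that("Group I requires equilibrium in every specimen", {
  fx <- cd63_fixture()
  # a protein at equilibrium in S1 and S2 but not S3 (different peak densities)
  partial <- do.call(rbind, lapply(c("S1", "S2", "S3"), function(s) {
    f_up <- if (s == "S3") 9 else 4
    rbind(data.frame(specimen = s, direction = "downward", fraction = 4,
                     protein = "PART", area = 1e5),
          data.frame(specimen = s, direction = "upward", fraction = f_up,
                     protein = "PART", area = 1e5))
  }))
  # S1/S2 tubes in the fixture have near-identical ladders at F4 after
  # truncation; S3 down F4 vs up F9 differ
  fit <- ev_pfd(rbind(fx$quant, partial), fx$densities)
  a <- fit$assignments
  expect_identical(a$group[a$protein == "CD63"], "IA-1")
  expect_identical(a$group[a$protein == "PART"], "unclassified")
  expect_identical(group_I_proteins(fit$pfd), "CD63")
})

test_that("partition identities hold on noisy data", {
  sim <- simulate_ev_dataset(small_sim_config(log10_sd = 0.6, dropout = 0.15,
                                              jitter = 0.004, seed = 9))
  fit <- suppressWarnings(ev_pfd(sim$quant, sim$densities))
  a <- fit$assignments
  sub <- attr(a, "subgroups")
  in_subgroup <- !is.na(a$group) & !a$group %in% c("II", "unclassified")
  # subgroup sizes sum to |Group I| and every Group-I protein has one label
  expect_equal(sum(sub$n), sum(in_subgroup))
  expect_equal(sort(group_I_proteins(fit$pfd)), sort(a$protein[in_subgroup]))
  # Group I and Group II are disjoint and, with unclassified, cover exactly
  # the proteins detected in both directions in all specimens
  gI <- group_I_proteins(fit$pfd)
  gII <- group_II_proteins(fit$pfd)
  expect_length(intersect(gI, gII), 0)
  both_all <- tapply(fit$pfd$status != "X", fit$pfd$protein, all)
  expect_setequal(c(gI, gII, a$protein[!is.na(a$group) &
                                         a$group == "unclassified"]),
                  names(both_all)[both_all])
})

test_that("subgroup labels are stable under row permutation and specimen relabeling", {
  sim <- simulate_ev_dataset(small_sim_config(seed = 5))
  fit1 <- ev_pfd(sim$quant, sim$densities)
  set.seed(1)
  fit2 <- ev_pfd(sim$quant[sample(nrow(sim$quant)), ],
                 sim$densities[sample(nrow(sim$densities)), ])
  expect_equal(fit1$assignments, fit2$assignments)

  # relabeling specimens permutes tuples but preserves the partition
  relab <- c(S1 = "S3", S2 = "S1", S3 = "S2")
  q <- sim$quant; q$specimen <- unname(relab[q$specimen])
  d <- sim$densities; d$specimen <- unname(relab[d$specimen])
  fit3 <- ev_pfd(q, d)
  canon <- function(fit) {
    grp <- split(fit$assignments$protein, fit$assignments$pattern)
    unname(sort(vapply(grp, function(g) paste(sort(g), collapse = ","),
                       character(1))))
  }
  expect_setequal(canon(fit1), canon(fit3))
})

test_that("a missing reference marker triggers a warning and size-ordered labels", {
  sim <- simulate_ev_dataset(small_sim_config(seed = 4))
  expect_warning(fit <- ev_pfd(sim$quant, sim$densities,
                               reference_marker = "NOSUCH"),
                 "not in Group I")
  sub <- attr(fit$assignments, "subgroups")
  ia <- sub[grepl("^IA-", sub$label), ]
  expect_true(all(diff(ia$n) <= 0))
})
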