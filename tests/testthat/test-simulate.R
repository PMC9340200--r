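test_that("zero divergence gives identical population frequencies", {
  pm <- pop_model(3, fst = c(0, 0, 0), n_variants = 200,
                  ancestral_freq_range = c(0.5, 0.5))
  g <- simulate_genotypes(pm, n_per_pop = c(10, 10, 10), seed = 1)
  expect_true(all(g$freq == 0.5))
  expect_equal(max(apply(g$freq, 1, var)), 0)
})

test_that("population frequencies follow the Balding-Nichols Beta variance", {
  pm <- pop_model(1, fst = 0.01, n_variants = 10000,
                  ancestral_freq_range = c(0.5, 0.5))
  g <- simulate_genotypes(pm, n_per_pop = 5, seed = 2)
  v <- var(g$freq[, 1])
  expect_gt(v, 0.0025 * 0.9)
  expect_lt(v, 0.0025 * 1.1)
})

test_that("realised differentiation matches the Hudson FST estimator", {
  g <- sim_two_pop(n_per_pop = 500, m = 5000, fst = 0.05, seed = 3)
  in1 <- g$samples$population == "POP1"
  p1 <- colMeans(g$dosage[in1, ]) / 2
  p2 <- colMeans(g$dosage[!in1, ]) / 2
  n1 <- sum(in1)
  n2 <- sum(!in1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_hat <- sum(num) / sum(den)
  expect_gt(fst_hat, 0.04)
  expect_lt(fst_hat, 0.06)
})

test_that("expected heterozygosity matches the model frequencies", {
  g <- sim_two_pop(n_per_pop = 400, m = 2000, fst = 0.02, seed = 31)
  in1 <- g$samples$population == "POP1"
  het_obs <- mean(g$dosage[in1, ] == 1)
  het_exp <- mean(2 * g$freq[, "POP1"] * (1 - g$freq[, "POP1"]))
  expect_lt(abs(het_obs - het_exp), 0.01)
})

test_that("a pairwise FST matrix is converted to per-population divergences", {
  fm <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  pm <- pop_model(2, fst = fm, n_variants = 10)
  expect_equal(unname(pm$divergence), c(0.05, 0.05), tolerance = 1e-8)
  expect_error(pop_model(2, fst = matrix(c(0, 0.2, 0.3, 0), 2, 2),
                         n_variants = 10), "symmetric")
})

test_that("genotype simulation is deterministic under a fixed seed", {
  pm <- pop_model(2, fst = c(0.01, 0.01), n_variants = 300)
  g1 <- simulate_genotypes(pm, c(50, 50), seed = 7, missing_rate = 0.02)
  g2 <- simulate_genotypes(pm, c(50, 50), seed = 7, missing_rate = 0.02)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)
})

test_that("variant positions are 1-based within their chromosome span", {
  pm <- pop_model(1, fst = 0, n_variants = 500,
                  chrom_lengths = c(`1` = 5e4, `2` = 1e5))
  g <- simulate_genotypes(pm, 10, seed = 8)
  for (ch in c("1", "2")) {
    p <- g$variants$pos[g$variants$chrom == ch]
    expect_true(all(p >= 1 & p <= pm$chrom_lengths[[ch]]))
    expect_false(is.unsorted(p))
  }
})

test_that("block-LD mode induces correlation between adjacent variants", {
  g <- sim_two_pop(n_per_pop = 400, m = 200, fst = 0, seed = 9,
                   ld = list(rho = 0.9, block_size = 10))
  X <- g$dosage[, 1:10]
  r_adj <- mean(abs(diag(cor(X[, -10], X[, -1]))))
  expect_gt(r_adj, 0.4)
  g0 <- sim_two_pop(n_per_pop = 400, m = 200, fst = 0, seed = 9)
  r0 <- mean(abs(diag(cor(g0$dosage[, 1:9], g0$dosage[, 2:10]))))
  expect_lt(r0, 0.1)
})

test_that("a pure-noise trait is independent of structure", {
  g <- sim_two_pop(n_per_pop = 300, m = 100, fst = 0.05, seed = 10)
  s <- make_samples(g, seed = 11)
  tm <- trait_model(heritability = 0, n_causal = 0, structure_effect = 0,
                    noise_sd = 1)
  y <- simulate_trait(g, s, tm, seed = 12)
  expect_lt(abs(cor(y, s$ancestry_score)), 0.1)
  expect_lt(abs(mean(y[s$population == "POP1"]) -
                  mean(y[s$population == "POP2"])), 0.15)
  expect_equal(sd(y), 1, tolerance = 0.1)
})

test_that("heritability is realised as regression R2 on the true score", {
  pm <- pop_model(1, fst = 0, n_variants = 800)
  g <- simulate_genotypes(pm, 10000, seed = 13)
  s <- make_samples(g, seed = 14)
  tm <- trait_model(heritability = 0.5, n_causal = 200)
  y <- simulate_trait(g, s, tm, seed = 15)
  ce <- attr(y, "causal_effects")
  G <- as.numeric(g$dosage[, ce$variant_id] %*% ce$beta)
  expect_lt(abs(cor(as.numeric(y), G)^2 - 0.5), 0.03)
})

test_that("the structure share is realised as R2 on the ancestry score", {
  g <- sim_two_pop(n_per_pop = 2500, m = 50, fst = 0.01, seed = 16)
  s <- make_samples(g, seed = 17)
  tm <- trait_model(heritability = 0, n_causal = 0, structure_effect = 0.05)
  y <- simulate_trait(g, s, tm, seed = 18)
  expect_lt(abs(cor(as.numeric(y), s$ancestry_score)^2 - 0.05), 0.01)
})

test_that("trait models reject variance shares above one", {
  expect_error(trait_model(heritability = 0.8, n_causal = 10,
                           structure_effect = 0.3),
               "variance shares exceed 1")
  expect_error(trait_model(heritability = 0.5, n_causal = 0), "n_causal")
})

test_that("cohort splits are disjoint, reproducible, and exhaustive on demand", {
  g <- sim_two_pop(n_per_pop = 60, m = 20, fst = 0, seed = 19)
  s <- make_samples(g, seed = 20)
  sizes <- list(a = 40, b = 50, c = 30)
  sp1 <- split_cohorts(s, sizes, seed = 21)
  sp2 <- split_cohorts(s, sizes, seed = 21)
  expect_identical(sp1, sp2)
  all_ids <- unlist(sp1)
  expect_equal(length(all_ids), length(unique(all_ids)))
  expect_setequal(all_ids, s$sample_id)
  expect_error(split_cohorts(s, list(a = 200), seed = 1), "available")
  sp3 <- split_cohorts(s, list(a = list(n = 10, populations = "POP2")),
                       seed = 22)
  expect_true(all(grepl("^POP2", sp3$a)))
})

test_that("the emulation preset keeps the study's role proportions", {
  sz <- cohort_preset(scale = 0.1)
  expect_equal(unname(sz[c("panel_all", "panel_eur", "panel_neur")]),
               c(250L, 50L, 200L))
  expect_equal(sz[["discovery"]], 35074L)
  full <- cohort_preset(1)
  expect_equal(unname(full[c("target_same", "target_other", "panel_same")]),
               c(7100L, 7070L, 5000L))
})
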