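test_that("panel scores are centred and eigenvalues preserve the trace", {
  set.seed(1)
  g <- make_toy_geno(matrix(rbinom(40 * 120, 2, 0.4), 40, 120))
  sp <- build_pc_space(g, K = 39, prune = FALSE)
  expect_equal(sp$K, 39L)
  scores <- project_samples(sp, g)
  expect_lt(max(abs(colMeans(scores))), 1e-10)
  ## with K = n-1 the eigenvalues carry all standardised variance
  expect_equal(sum(sp$eigenvalues), length(sp$variant_ids), tolerance = 1e-8)
  ## non-increasing, non-negative
  expect_true(all(diff(sp$eigenvalues) <= 1e-10))
  expect_true(all(sp$eigenvalues >= 0))
})

test_that("loadings are orthonormal", {
  g <- sim_two_pop(n_per_pop = 80, m = 300, fst = 0.03, seed = 2)
  sp <- build_pc_space(g, K = 20)
  G <- crossprod(sp$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("PC1 of a structured panel separates the populations", {
  g <- sim_two_pop(n_per_pop = 250, m = 2000, fst = 0.05, seed = 3)
  sp <- build_pc_space(filter_variants(g)$genotypes, K = 10)
  sc <- project_samples(sp, g)
  lab <- as.numeric(g$samples$population == "POP2")
  expect_gt(abs(cor(sc[, 1], lab)), 0.9)
})

test_that("projection reproduces the panel's own eigendecomposition scores", {
  set.seed(4)
  g <- make_toy_geno(matrix(rbinom(60 * 200, 2, 0.35), 60, 200))
  sp <- build_pc_space(g, K = 10, prune = FALSE)
  sc <- project_samples(sp, g)
  ## independent oracle: svd of the standardised dosage matrix
  X <- scale(g$dosage)
  sv <- svd(X)
  oracle <- sv$u[, 1:10] %*% diag(sv$d[1:10])
  for (k in 1:10) {
    s <- sign(cor(oracle[, k], sc[, k]))
    expect_equal(unname(sc[, k]), s * oracle[, k], tolerance = 1e-8)
  }
})

test_that("a duplicated sample projects to identical coordinates", {
  g <- sim_two_pop(n_per_pop = 50, m = 150, fst = 0.02, seed = 5)
  panel <- subset_geno(g, samples = 1:60)
  other <- subset_geno(g, samples = c(61, 61, 62))
  sp <- build_pc_space(panel, K = 5)
  sc <- project_samples(sp, other)
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-12)
})

test_that("projection is linear in the genotype vector", {
  g <- sim_two_pop(n_per_pop = 60, m = 180, fst = 0.02, seed = 6)
  panel <- subset_geno(g, samples = 1:80)
  sp <- build_pc_space(panel, K = 5)
  a <- subset_geno(g, samples = 81)
  b <- subset_geno(g, samples = 82)
  mix <- a
  mix$dosage <- 0.25 * a$dosage + 0.75 * b$dosage
  sc <- rbind(project_samples(sp, a), project_samples(sp, b),
              project_samples(sp, mix))
  expect_equal(unname(sc[3, ]), unname(0.25 * sc[1, ] + 0.75 * sc[2, ]),
               tolerance = 1e-10)
})

test_that("swapped alleles are flipped during projection; mismatches error", {
  g <- sim_two_pop(n_per_pop = 60, m = 100, fst = 0.02, seed = 7)
  panel <- subset_geno(g, samples = 1:60)
  cohort <- subset_geno(g, samples = 61:120)
  sp <- build_pc_space(panel, K = 5)
  base <- project_samples(sp, cohort)
  flipped <- cohort
  j <- match(sp$variant_ids[1], flipped$variants$variant_id)
  flipped$variants[j, c("a1", "a2")] <- flipped$variants[j, c("a2", "a1")]
  flipped$dosage[, j] <- 2L - flipped$dosage[, j]
  expect_equal(project_samples(sp, flipped), base, tolerance = 1e-12)
  bad <- cohort
  bad$variants$a2[j] <- setdiff(c("A", "C", "G", "T"),
                                unlist(cohort$variants[j, c("a1", "a2")]))[1]
  expect_error(project_samples(sp, bad), "allele mismatch")
  small <- subset_geno(cohort, variants = 2:ncol(cohort$dosage))
  expect_error(project_samples(sp, small), "missing space variants")
})

test_that("structure-free panels yield no population separation after projection", {
  pm <- pop_model(2, fst = c(0, 0), n_variants = 800)
  g <- simulate_genotypes(pm, c(500, 500), seed = 8)
  panel <- subset_geno(g, samples = c(1:150, 501:650))
  cohort <- subset_geno(g, samples = c(151:500, 651:1000))
  sp <- build_pc_space(panel, K = 10)
  sc <- project_samples(sp, cohort)
  lab <- as.numeric(cohort$samples$population == "POP2")
  expect_true(all(abs(cor(sc[, 1:10], lab)) < 0.1))
})

test_that("gross outliers are removed within the iteration budget", {
  set.seed(9)
  D <- matrix(rbinom(100 * 400, 2, 0.5), 100, 400)
  D[1, ] <- rbinom(400, 2, 0.98)  # one extreme sample
  g <- make_toy_geno(D)
  sp <- build_pc_space(g, K = 10, prune = FALSE)
  expect_true(g$samples$sample_id[1] %in% sp$removed_ids)
  expect_false(g$samples$sample_id[1] %in% sp$panel_ids)
  expect_lte(sp$n_iterations, 5)
  expect_gte(sp$n_iterations, 2)
})

test_that("K is capped at panel size minus one with a warning", {
  set.seed(10)
  g <- make_toy_geno(matrix(rbinom(10 * 100, 2, 0.5), 10, 100))
  expect_warning(sp <- build_pc_space(g, K = 20, prune = FALSE), "K reduced")
  expect_equal(sp$K, 9L)
})

test_that("requesting shrinkage correction is an explicit error", {
  g <- sim_two_pop(n_per_pop = 30, m = 50, seed = 11)
  expect_error(build_pc_space(g, shrinkage = TRUE), "not implemented")
})

test_that("make_pc_sets yields one coordinate set per panel plus a control", {
  g <- sim_two_pop(n_per_pop = 200, m = 300, fst = 0.03, seed = 12)
  panels <- list(p1 = subset_geno(g, samples = 1:50),
                 p2 = subset_geno(g, samples = 51:100))
  cohorts <- list(c1 = subset_geno(g, samples = 101:200),
                  c2 = subset_geno(g, samples = 201:300))
  res <- make_pc_sets(cohorts, panels, K = 5)
  expect_named(res$coords, c("c1", "c2"))
  expect_named(res$coords$c1, c("p1", "p2", "none"))
  expect_null(res$coords$c1$none)
  expect_s3_class(res$coords$c2$p1, "pc_coords")
  ## overlap between panel and projected cohort violates independence
  bad <- list(c1 = subset_geno(g, samples = 40:140))
  expect_error(make_pc_sets(bad, panels, K = 5), "shares")
})
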