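test_that("mutually uncorrelated variants each become their own index", {
  set.seed(1)
  g <- make_toy_geno(matrix(rbinom(500 * 30, 2, 0.5), 500, 30))
  st <- make_toy_stats(g, beta = rnorm(30), p = runif(30, 0, 0.9))
  idx <- clump_variants(st, g, r2_max = 0.5, window_kb = 1000)
  expect_setequal(idx, g$variants$variant_id)
  ## and the first index is the smallest p
  expect_equal(idx[1], g$variants$variant_id[which.min(st$p)])
})

test_that("a correlated nearby pair is clumped to the more significant member", {
  set.seed(2)
  x <- rbinom(400, 2, 0.5)
  flip <- sample(400, 8)
  x2 <- x
  x2[flip] <- 2 - x2[flip]  # r2 about 0.9
  g <- make_toy_geno(cbind(x, x2), pos = c(100000L, 110000L))
  expect_gt(cor(x, x2)^2, 0.8)
  st <- make_toy_stats(g, beta = c(0.2, 0.2), p = c(1e-8, 1e-4))
  expect_equal(clump_variants(st, g), "v001")
  ## outside the window both survive
  g2 <- make_toy_geno(cbind(x, x2), pos = c(100000L, 2e6 + 200000L))
  st2 <- make_toy_stats(g2, beta = c(0.2, 0.2), p = c(1e-8, 1e-4))
  expect_setequal(clump_variants(st2, g2), c("v001", "v002"))
})

test_that("clumping equals the brute-force greedy oracle on a block-LD fixture", {
  g <- sim_two_pop(n_per_pop = 200, m = 100, fst = 0.02, seed = 3,
                   ld = list(rho = 0.9, block_size = 5))
  set.seed(4)
  st <- make_toy_stats(g, beta = rnorm(100), p = runif(100)^2)
  got <- clump_variants(st, g, r2_max = 0.05, window_kb = 1000)
  expect_identical(got, clump_oracle(st, g))
})

test_that("clump output does not depend on the input row order", {
  g <- sim_two_pop(n_per_pop = 150, m = 60, fst = 0.02, seed = 5,
                   ld = list(rho = 0.8, block_size = 6))
  set.seed(6)
  st <- make_toy_stats(g, beta = rnorm(60), p = runif(60))
  shuffled <- st[sample(nrow(st)), ]
  attributes(shuffled)[c("pc_set_label", "lambda", "n")] <-
    attributes(st)[c("pc_set_label", "lambda", "n")]
  expect_identical(clump_variants(st, g), clump_variants(shuffled, g))
})

test_that("scores are the dosage-weighted sums of effect sizes", {
  g <- make_toy_geno(matrix(c(0L, 1L, 2L), 3, 1))
  st <- make_toy_stats(g, beta = 0.5, p = 0.01)
  s <- prs_score(g, st, "v001")
  expect_equal(as.numeric(s), c(0, 0.5, 1.0))
  ## zero betas give zero scores
  st0 <- make_toy_stats(g, beta = 0, p = 0.01)
  expect_true(all(prs_score(g, st0, "v001") == 0))
})

test_that("a 20-variant score equals the independent dot-product oracle", {
  set.seed(7)
  g <- make_toy_geno(matrix(rbinom(50 * 20, 2, 0.4), 50, 20))
  beta <- rnorm(20)
  st <- make_toy_stats(g, beta = beta, p = runif(20))
  s <- prs_score(g, st, g$variants$variant_id)
  oracle <- numeric(50)
  for (i in 1:50) {
    for (j in 1:20) oracle[i] <- oracle[i] + g$dosage[i, j] * beta[j]
  }
  expect_equal(as.numeric(s), oracle, tolerance = 1e-12)
})

test_that("swapped alleles flip the dosage; inconsistent alleles error", {
  set.seed(8)
  D <- matrix(rbinom(40 * 2, 2, 0.5), 40, 2)
  g <- make_toy_geno(D)
  st <- make_toy_stats(g, beta = c(1, 1), p = c(0.01, 0.01))
  base <- prs_score(g, st, c("v001", "v002"))
  gsw <- g
  gsw$variants[1, c("a1", "a2")] <- gsw$variants[1, c("a2", "a1")]
  gsw$dosage[, 1] <- 2L - gsw$dosage[, 1]
  expect_equal(prs_score(gsw, st, c("v001", "v002")), base)
  gbad <- g
  gbad$variants$a1[1] <- "C"
  expect_error(prs_score(gbad, st, c("v001", "v002")), "inconsistent alleles")
})

test_that("missing dosages contribute the variant's mean dosage", {
  D <- matrix(c(0L, 2L, NA, 1L), 4, 1)
  g <- make_toy_geno(D)
  st <- make_toy_stats(g, beta = 1, p = 0.01)
  s <- prs_score(g, st, "v001")
  expect_equal(unname(s[3]), 1)  # mean of 0, 2, 1
})

test_that("threshold selection finds the grid value admitting the signal", {
  set.seed(9)
  n <- 600
  m <- 40
  g <- make_toy_geno(matrix(rbinom(n * m, 2, 0.5), n, m))
  samp <- make_toy_samples(g)
  causal <- 1:5
  y <- rowSums(g$dosage[, causal]) * 1.0 + rnorm(n, 0, 1)
  st <- run_gwas(g, y, samp)
  expect_true(all(st$p[causal] < 5e-5))
  clumped <- clump_variants(st, g)
  prof <- select_best_threshold(g, y, samp, st, clumped)
  expect_equal(prof$chosen_threshold, 5e-5)
  expect_true(all(g$variants$variant_id[causal] %in% prof$variants$variant_id))
  ## standardisation contract
  expect_lt(abs(mean(prof$score)), 1e-10)
  expect_lt(abs(sd(prof$score) - 1), 1e-10)
  ## a degenerate one-threshold grid returns that threshold
  prof1 <- select_best_threshold(g, y, samp, st, clumped, thresholds = 0.05)
  expect_equal(prof1$chosen_threshold, 0.05)
})

test_that("doubling all betas leaves the standardised score unchanged", {
  set.seed(10)
  g <- make_toy_geno(matrix(rbinom(300 * 25, 2, 0.4), 300, 25))
  samp <- make_toy_samples(g)
  y <- rnorm(300) + 0.3 * g$dosage[, 2]
  st <- run_gwas(g, y, samp)
  st2 <- st
  st2$beta <- st$beta * 2
  clumped <- clump_variants(st, g)
  p1 <- select_best_threshold(g, y, samp, st, clumped)
  p2 <- select_best_threshold(g, y, samp, st2, clumped)
  expect_equal(p1$score, p2$score, tolerance = 1e-10)
  expect_equal(p1$chosen_threshold, p2$chosen_threshold)
})

test_that("variants absent from the LD reference are excluded with a count", {
  set.seed(11)
  g <- make_toy_geno(matrix(rbinom(200 * 10, 2, 0.5), 200, 10))
  st <- make_toy_stats(g, beta = rnorm(10), p = runif(10))
  gsub <- subset_geno(g, variants = 1:8)
  expect_message(idx <- clump_variants(st, gsub), "2 .*absent")
  expect_true(all(idx %in% gsub$variants$variant_id))
})
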