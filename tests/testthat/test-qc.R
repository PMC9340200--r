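test_that("each QC rule fires once on the six-variant toy table", {
  n <- 100
  set.seed(1)
  base <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  base[1:6, 5] <- NA            # 6% missing
  base[, 6] <- 0L
  base[1, 6] <- 1L              # maf 0.005
  g <- make_toy_geno(base,
                     pos = c(1000L, 1000L, 3000L, 4000L, 5000L, 6000L),
                     a1 = c("A", "A", "A", "C", "A", "A"),
                     a2 = c("G", "G", "T", "G", "G", "G"))
  out <- filter_variants(g)
  expect_equal(out$report$variants_out, 1L)
  expect_equal(out$genotypes$variants$variant_id, "v001")
  expect_equal(unname(out$report$removed),
               c(1L, 0L, 2L, 1L, 1L))  # dup, indel, palindromic, miss, maf
  expect_equal(sum(out$report$removed),
               out$report$variants_in - out$report$variants_out)
})

test_that("indels are removed and counted before the palindromic rule", {
  set.seed(2)
  g <- make_toy_geno(matrix(rbinom(200, 2, 0.5), 50, 4),
                     a1 = c("A", "AT", "A", "T"),
                     a2 = c("G", "T", "C", "A"))
  out <- filter_variants(g)
  expect_equal(unname(out$report$removed[c("indel", "palindromic")]),
               c(1L, 1L))
})

test_that("clean input passes QC unchanged", {
  set.seed(3)
  g <- make_toy_geno(matrix(rbinom(2000, 2, 0.5), 100, 20))
  out <- filter_variants(g)
  expect_identical(out$genotypes$dosage, g$dosage)
  expect_true(all(out$report$removed == 0))
})

test_that("QC matches a rule-by-rule brute-force oracle on a random fixture", {
  set.seed(4)
  n <- 120
  m <- 60
  D <- matrix(rbinom(n * m, 2, runif(m, 0.02, 0.5)[rep(1:m, each = n)]), n, m)
  pos <- sample(1:5e5, m)
  pos[8] <- pos[3]                      # duplicate position
  alleles <- cbind(rep("A", m), rep("G", m))
  alleles[12, ] <- c("T", "A")          # palindromic
  alleles[15, ] <- c("C", "G")
  alleles[20, ] <- c("ACGT", "A")       # indel
  D[sample(n, 9), 25] <- NA             # 7.5% missing
  g <- make_toy_geno(D, pos = pos, a1 = alleles[, 1], a2 = alleles[, 2])

  ## independent oracle: apply the five rules one by one on the metadata
  keep <- rep(TRUE, m)
  keep[duplicated(paste(g$variants$chrom, g$variants$pos))] <- FALSE
  keep[nchar(g$variants$a1) > 1 | nchar(g$variants$a2) > 1] <- FALSE
  set_of <- function(i) sort(c(g$variants$a1[i], g$variants$a2[i]))
  for (i in 1:m) {
    if (nchar(g$variants$a1[i]) == 1 && nchar(g$variants$a2[i]) == 1 &&
        (identical(set_of(i), c("A", "T")) ||
         identical(set_of(i), c("C", "G")))) keep[i] <- FALSE
  }
  keep[colMeans(is.na(D)) > 0.05] <- FALSE
  p <- colMeans(D, na.rm = TRUE) / 2
  keep[pmin(p, 1 - p) < 0.01] <- FALSE

  out <- filter_variants(g)
  expect_equal(out$genotypes$variants$variant_id,
               g$variants$variant_id[keep])
})

test_that("variant QC is idempotent", {
  set.seed(5)
  D <- matrix(rbinom(3000, 2, 0.3), 100, 30)
  D[sample(length(D), 150)] <- NA
  g <- make_toy_geno(D, pos = c(1000L, 1000L, seq(3, 30) * 1000L))
  once <- filter_variants(g)
  twice <- filter_variants(once$genotypes)
  expect_identical(once$genotypes$dosage, twice$genotypes$dosage)
  expect_true(all(twice$report$removed == 0))
})

test_that("independent variants survive LD pruning untouched", {
  set.seed(6)
  g <- make_toy_geno(matrix(rbinom(60000, 2, 0.5), 600, 100))
  expect_identical(ld_prune(g), 1:100)
})

test_that("one member of a perfectly correlated pair is pruned", {
  set.seed(7)
  x <- rbinom(300, 2, 0.5)
  D <- cbind(x, x, rbinom(300, 2, 0.5))
  g <- make_toy_geno(D)
  kept <- ld_prune(g)
  expect_equal(kept, c(1L, 3L))  # later-positioned duplicate dropped
})

test_that("monomorphic variants are dropped before pruning", {
  set.seed(8)
  D <- cbind(matrix(rbinom(600, 2, 0.5), 100, 6), 0L)
  g <- make_toy_geno(D)
  expect_message(kept <- ld_prune(g), "monomorphic")
  expect_false(7L %in% kept)
})

test_that("windowed pruning equals the brute-force greedy oracle", {
  set.seed(9)
  g <- sim_two_pop(n_per_pop = 150, m = 200, fst = 0.02, seed = 123,
                   ld = list(rho = 0.85, block_size = 8))
  kept <- ld_prune(g, window = 20, step = 5, r2_max = 0.1)
  oracle <- prune_oracle(g$dosage, g$variants$chrom, window = 20, step = 5,
                         r2_max = 0.1)
  expect_identical(kept, oracle)
  ## default parameters as well
  kept50 <- ld_prune(g)
  oracle50 <- prune_oracle(g$dosage, g$variants$chrom, 50, 10, 0.1)
  expect_identical(kept50, oracle50)
})

test_that("no scanned window retains a pair above the r2 threshold", {
  g <- sim_two_pop(n_per_pop = 200, m = 150, fst = 0.02, seed = 10,
                   ld = list(rho = 0.9, block_size = 10))
  kept <- ld_prune(g, window = 25, step = 5, r2_max = 0.1)
  X <- scale(g$dosage[, kept])
  for (s in seq(1, length(kept), by = 5)) {
    win <- s:min(s + 24, length(kept))
    if (length(win) < 2) next
    R2 <- cor(X[, win])^2
    diag(R2) <- 0
    expect_lt(max(R2), 0.1 + 1e-12)
  }
})
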