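# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# A geno_matrix built by hand from a dosage matrix and optional metadata.
make_toy_geno <- function(dosage, chrom = NULL, pos = NULL, a1 = NULL,
                          a2 = NULL, populations = NULL) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  if (is.null(populations)) populations <- rep("POP1", n)
  ids <- sprintf("v%03d", seq_len(m))
  dimnames(dosage) <- list(sprintf("S%04d", seq_len(n)), ids)
  structure(list(
    dosage = dosage,
    variants = data.frame(variant_id = ids, chrom = chrom, pos = pos,
                          a1 = a1, a2 = a2, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = rownames(dosage),
                         population = populations, stringsAsFactors = FALSE),
    freq = NULL
  ), class = "geno_matrix")
}

# A hand-built gwas_stats table (for clumping/scoring tests).
make_toy_stats <- function(geno, beta, p, label = "none") {
  v <- geno$variants
  structure(data.frame(
    variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$a1, other_allele = v$a2,
    beta = beta, se = abs(beta) / 2 + 0.1, t = NA_real_, p = p,
    n_used = nrow(geno$dosage), reason = NA_character_,
    stringsAsFactors = FALSE
  ), class = c("gwas_stats", "data.frame"),
  pc_set_label = label, lambda = NA_real_, n = nrow(geno$dosage))
}

# A minimal covariate table with null covariates.
make_toy_samples <- function(geno, seed = 99) {
  set.seed(seed)
  n <- nrow(geno$dosage)
  data.frame(sample_id = geno$samples$sample_id,
             population = geno$samples$population,
             age = sample(40:70, n, replace = TRUE),
             sex = rbinom(n, 1, 0.5),
             batch = sample(c("batchA", "batchB"), n, replace = TRUE),
             ancestry_score = 0,
             stringsAsFactors = FALSE)
}

# Two-population structured genotypes with a block-LD option.
sim_two_pop <- function(n_per_pop = 200, m = 500, fst = 0.05, seed = 42,
                        ld = NULL) {
  pm <- pop_model(2, fst = c(fst, fst), n_variants = m)
  simulate_genotypes(pm, n_per_pop = c(n_per_pop, n_per_pop), seed = seed,
                     ld = ld)
}

# Independent per-variant OLS via the normal equations (oracle for GWAS and
# validation fits).
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tv <- b / se
  list(beta = as.numeric(b), se = as.numeric(se), t = as.numeric(tv),
       p = as.numeric(2 * pt(-abs(tv), df)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}
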