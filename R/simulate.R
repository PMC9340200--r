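# Synthetic structured cohorts: Balding-Nichols genotypes, covariates and
# quantitative traits with a configurable ancestry confounder.

#' Define a multi-population allele-frequency model
#'
#' Populations diverge from a shared ancestral population under the
#' Balding-Nichols model: for a variant with ancestral frequency \eqn{p}, the
#' frequency in population \eqn{k} is Beta-distributed with mean \eqn{p} and
#' variance \eqn{c_k p (1 - p)}, where \eqn{c_k} is that population's
#' divergence. Under this star-shaped model the expected pairwise Hudson
#' FST between populations \eqn{i} and \eqn{j} is \eqn{(c_i + c_j) / 2}.
#'
#' @param n_populations Number of populations.
#' @param fst Either a length-`n_populations` vector of per-population
#'   divergences \eqn{c_k} in `[0, 1)`, or a symmetric pairwise FST matrix with
#'   zero diagonal and entries in `[0, 1)`; a matrix is converted to
#'   per-population divergences by least squares on
#'   \eqn{F_{ij} = (c_i + c_j)/2}.
#' @param n_variants Number of variants to simulate.
#' @param ancestral_freq_range Interval from which ancestral allele frequencies
#'   are drawn uniformly.
#' @param chrom_lengths Named numeric vector of chromosome lengths in base
#'   pairs; variants are assigned uniformly at random 1-based positions.
#' @param pop_labels Optional character labels, defaults to `POP1..POPn`.
#' @return An object of class `pop_model`.
#' @examples
#' m <- pop_model(2, fst = c(0.05, 0.05), n_variants = 100)
#' m
#' @export
pop_model <- function(n_populations, fst, n_variants,
                      ancestral_freq_range = c(0.05, 0.95),
                      chrom_lengths = c(`1` = 1.2e8, `2` = 1.2e8),
                      pop_labels = NULL) {
  stopifnot(n_populations >= 1, n_variants >= 1)
  if (is.matrix(fst)) {
    if (!isTRUE(all.equal(fst, t(fst))) ||
        any(abs(diag(fst)) > 1e-12) ||
        any(fst < 0) || any(fst >= 1)) {
      stop("fst matrix must be symmetric with zero diagonal and entries in [0, 1)")
    }
    if (nrow(fst) != n_populations) stop("fst matrix dimension != n_populations")
    divergence <- fst_matrix_to_divergence(fst)
  } else {
    if (length(fst) != n_populations) stop("fst vector length != n_populations")
    if (any(fst < 0) || any(fst >= 1)) stop("divergences must lie in [0, 1)")
    divergence <- as.numeric(fst)
  }
  if (is.null(pop_labels)) pop_labels <- paste0("POP", seq_len(n_populations))
  stopifnot(length(pop_labels) == n_populations)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  if (ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] > ancestral_freq_range[2]) {
    stop("ancestral_freq_range must be an interval inside (0, 1)")
  }
  structure(list(
    n_populations = as.integer(n_populations),
    divergence = stats::setNames(divergence, pop_labels),
    n_variants = as.integer(n_variants),
    ancestral_freq_range = ancestral_freq_range,
    chrom_lengths = chrom_lengths,
    pop_labels = pop_labels
  ), class = "pop_model")
}

# Least-squares fit of per-population divergences to a pairwise FST matrix
# under F_ij = (c_i + c_j)/2; minimum-norm solution, clamped into [0, 1).
fst_matrix_to_divergence <- function(fst) {
  K <- nrow(fst)
  if (K == 1) return(0)
  pairs <- utils::combn(K, 2)
  A <- matrix(0, ncol(pairs), K)
  b <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    A[q, pairs[, q]] <- 0.5
    b[q] <- fst[pairs[1, q], pairs[2, q]]
  }
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-10
  c_hat <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  pmin(pmax(as.numeric(c_hat), 0), 1 - 1e-8)
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Balding-Nichols population model\n")
  cat("  populations:", paste(x$pop_labels, collapse = ", "), "\n")
  cat("  divergences:", paste(signif(x$divergence, 3), collapse = ", "), "\n")
  cat("  variants:", x$n_variants, "on", length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

#' Simulate additive genotype dosages under the Balding-Nichols model
#'
#' For each variant an ancestral frequency is drawn uniformly from the model's
#' range; each population's frequency is drawn from a Beta distribution with
#' mean \eqn{p} and variance \eqn{c\,p(1-p)} (populations with divergence 0 use
#' \eqn{p} exactly); genotypes are the sum of two Binomial(1, p_pop) allele
#' draws. Variants are independent unless a block-LD mode is requested, in
#' which case allele draws within blocks of consecutive variants share a
#' latent AR(1) Gaussian with lag-1 correlation `ld$rho` (Gaussian copula, so
#' the realised dosage correlation is somewhat below `rho`).
#'
#' @param model A [pop_model()].
#' @param n_per_pop Integer vector of samples per population (recycled names
#'   from the model's labels).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param missing_rate Per-variant probability that any given dosage is set
#'   missing (`NA`); default 0.
#' @param ld Optional list `list(rho=, block_size=)` switching on block LD.
#' @return An object of class `geno_matrix`: a list with `dosage`
#'   (samples x variants integer matrix, counts of allele `a1`), `variants`
#'   (variant_id, chrom, pos, a1, a2), `samples` (sample_id, population) and
#'   `freq` (variants x populations matrix of realised population frequencies).
#' @examples
#' m <- pop_model(2, fst = c(0.05, 0.05), n_variants = 50)
#' g <- simulate_genotypes(m, n_per_pop = c(20, 20), seed = 1)
#' g
#' @export
simulate_genotypes <- function(model, n_per_pop, seed, missing_rate = 0,
                               ld = NULL) {
  stopifnot(inherits(model, "pop_model"))
  K <- model$n_populations
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, K)
  stopifnot(length(n_per_pop) == K, all(n_per_pop > 0))
  stopifnot(missing_rate >= 0, missing_rate < 1)
  set.seed(as.integer(seed))
  m <- model$n_variants

  ## variant metadata: positions uniform within chromosome spans, sorted
  props <- model$chrom_lengths / sum(model$chrom_lengths)
  n_chr <- diff(round(cumsum(c(0, props)) * m))
  chrom <- rep(names(model$chrom_lengths), n_chr)
  pos <- unlist(lapply(seq_along(n_chr), function(i) {
    sort(sample.int(model$chrom_lengths[i], n_chr[i]))
  }), use.names = FALSE)
  allele_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  ap <- allele_pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
  variants <- data.frame(
    variant_id = sprintf("v%06d", seq_len(m)),
    chrom = chrom, pos = pos, a1 = ap[, 1], a2 = ap[, 2],
    stringsAsFactors = FALSE
  )

  ## ancestral and per-population frequencies
  p_anc <- stats::runif(m, model$ancestral_freq_range[1],
                        model$ancestral_freq_range[2])
  freq <- matrix(NA_real_, m, K, dimnames = list(variants$variant_id,
                                                 model$pop_labels))
  for (k in seq_len(K)) {
    c_k <- model$divergence[k]
    if (c_k == 0) {
      freq[, k] <- p_anc  # degenerate Beta: frequency equals p exactly
    } else {
      freq[, k] <- stats::rbeta(m, p_anc * (1 - c_k) / c_k,
                                (1 - p_anc) * (1 - c_k) / c_k)
    }
  }

  n_total <- sum(n_per_pop)
  dosage <- matrix(NA_integer_, n_total, m)
  pop_of <- rep(model$pop_labels, n_per_pop)
  row0 <- cumsum(c(0, n_per_pop))
  for (k in seq_len(K)) {
    rows <- (row0[k] + 1):row0[k + 1]
    nk <- n_per_pop[k]
    if (is.null(ld)) {
      dosage[rows, ] <- matrix(
        stats::rbinom(nk * m, 2L, rep(freq[, k], each = nk)), nk, m)
    } else {
      dosage[rows, ] <- simulate_ld_block_genotypes(freq[, k], variants$chrom,
                                                    nk, ld)
    }
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(dosage)) < missing_rate
    dosage[drop] <- NA_integer_
  }
  sample_id <- sprintf("%s_S%05d", pop_of, seq_len(n_total))
  dimnames(dosage) <- list(sample_id, variants$variant_id)
  structure(list(
    dosage = dosage,
    variants = variants,
    samples = data.frame(sample_id = sample_id, population = pop_of,
                         stringsAsFactors = FALSE),
    freq = freq
  ), class = "geno_matrix")
}

# Gaussian-copula haplotypes: latent AR(1) within blocks of consecutive
# variants, blocks never span a chromosome boundary.
simulate_ld_block_genotypes <- function(p, chrom, n, ld) {
  stopifnot(is.list(ld), !is.null(ld$rho), !is.null(ld$block_size))
  rho <- ld$rho
  m <- length(p)
  thr <- stats::qnorm(p)
  hap <- function() {
    z <- matrix(NA_real_, n, m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      for (b in split(idx, (seq_along(idx) - 1) %/% ld$block_size)) {
        z[, b[1]] <- stats::rnorm(n)
        for (j in b[-1]) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
        }
      }
    }
    sweep(z, 2, thr, "<") * 1L
  }
  h <- hap() + hap()
  storage.mode(h) <- "integer"
  h
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "variants\n")
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  if (miss > 0) cat("  missingness:", signif(miss, 3), "\n")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or variants
#'
#' @param geno A `geno_matrix`.
#' @param samples Character vector of sample ids or logical/integer index.
#' @param variants Character vector of variant ids or logical/integer index.
#' @return A `geno_matrix` restricted to the requested rows/columns.
#' @export
subset_geno <- function(geno, samples = NULL, variants = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(geno$dosage)) else {
    if (is.character(samples)) match(samples, geno$samples$sample_id) else samples
  }
  vi <- if (is.null(variants)) seq_len(ncol(geno$dosage)) else {
    if (is.character(variants)) match(variants, geno$variants$variant_id) else variants
  }
  if (is.numeric(si) && anyNA(si)) stop("unknown sample id in subset")
  if (is.numeric(vi) && anyNA(vi)) stop("unknown variant id in subset")
  structure(list(
    dosage = geno$dosage[si, vi, drop = FALSE],
    variants = geno$variants[vi, , drop = FALSE],
    samples = geno$samples[si, , drop = FALSE],
    freq = if (!is.null(geno$freq)) geno$freq[vi, , drop = FALSE]
  ), class = "geno_matrix")
}

#' Build the sample covariate table
#'
#' Attaches the non-genetic covariates used throughout the analysis (age,
#' sex, genotyping batch) and the latent ancestry score: each population is
#' assigned a scalar shift (by default its index along a cline), standardised
#' across the table. Structured traits load on this score.
#'
#' @param geno A `geno_matrix`.
#' @param seed Integer seed.
#' @param ancestry_shifts Optional named numeric vector of per-population
#'   shifts; defaults to `0, 1, 2, ...` in population order.
#' @return A data.frame with columns sample_id, population, age, sex, batch,
#'   ancestry_score (one row per sample, no duplicates).
#' @export
make_samples <- function(geno, seed, ancestry_shifts = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  set.seed(as.integer(seed))
  n <- nrow(geno$samples)
  pops <- unique(geno$samples$population)
  if (is.null(ancestry_shifts)) {
    ancestry_shifts <- stats::setNames(seq_along(pops) - 1, pops)
  }
  if (!all(pops %in% names(ancestry_shifts))) {
    stop("ancestry_shifts must name every population")
  }
  raw <- ancestry_shifts[geno$samples$population]
  anc <- if (stats::sd(raw) > 0) as.numeric(scale(raw)) else raw * 0
  data.frame(
    sample_id = geno$samples$sample_id,
    population = geno$samples$population,
    age = sample(40:70, n, replace = TRUE),
    sex = stats::rbinom(n, 1L, 0.5),
    batch = sample(c("batchA", "batchB"), n, replace = TRUE),
    ancestry_score = anc,
    stringsAsFactors = FALSE
  )
}

#' Define a quantitative trait model
#'
#' The trait is built on a unit-variance scale as
#' \deqn{y = \sqrt{h^2}\,\tilde G + \sqrt{s}\,\tilde a + \sum_c \beta_c \tilde x_c + \epsilon,}
#' where \eqn{\tilde G} is the standardised additive score over `n_causal`
#' variants with Gaussian effects, \eqn{\tilde a} the standardised ancestry
#' score (structure share `s`), covariates enter standardised, and
#' \eqn{\epsilon} is Gaussian noise. When `noise_sd` is `NULL` it defaults to
#' the square root of the unexplained variance share, so the trait has total
#' variance close to 1.
#'
#' @param heritability Variance share of the additive genetic score, in `[0,1]`.
#' @param n_causal Number of causal variants.
#' @param structure_effect Variance share of the ancestry score (0 for a
#'   non-structured, BMI-like trait; >0 for a structured, height-like trait).
#' @param covariate_effects Named coefficients for the standardised age, sex
#'   and batch covariates.
#' @param noise_sd Residual standard deviation; `NULL` for the complement.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(heritability, n_causal, structure_effect = 0,
                        covariate_effects = c(age = 0, sex = 0, batch = 0),
                        noise_sd = NULL) {
  stopifnot(heritability >= 0, heritability <= 1,
            structure_effect >= 0, structure_effect <= 1,
            n_causal >= 0)
  cov_share <- sum(covariate_effects^2)
  total <- heritability + structure_effect + cov_share
  if (total > 1 + 1e-12) {
    stop(sprintf(paste0("variance shares exceed 1: heritability=%.3f + ",
                        "structure=%.3f + covariates=%.3f = %.3f"),
                 heritability, structure_effect, cov_share, total))
  }
  if (heritability > 0 && n_causal == 0) {
    stop("heritability > 0 requires n_causal > 0")
  }
  if (is.null(noise_sd)) noise_sd <- sqrt(max(0, 1 - total))
  structure(list(
    heritability = heritability, n_causal = as.integer(n_causal),
    structure_effect = structure_effect,
    covariate_effects = covariate_effects, noise_sd = noise_sd
  ), class = "trait_model")
}

#' Simulate a quantitative trait over a genotyped sample
#'
#' @param geno A `geno_matrix`; causal variants must be completely observed.
#' @param samples Covariate table from [make_samples()], aligned to `geno`.
#' @param model A [trait_model()].
#' @param seed Integer seed.
#' @details The causal score is centred within each population before
#'   scaling, so the trait's correlation with ancestry is exactly the
#'   configured `structure_effect` share: without this, allele-frequency
#'   drift of the causal variants would add a random, seed-dependent
#'   population shift that can dominate or cancel the configured one.
#'   Polygenic differentiation of true effects is therefore deliberately
#'   not simulated.
#' @return Numeric trait vector named by sample id, with attributes
#'   `causal_effects` (data.frame variant_id, beta on the trait scale) and
#'   `realized_shares` (realised variance shares of each component).
#' @export
simulate_trait <- function(geno, samples, model, seed) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(model, "trait_model"))
  stopifnot(identical(samples$sample_id, geno$samples$sample_id))
  set.seed(as.integer(seed))
  n <- nrow(geno$dosage)
  m <- ncol(geno$dosage)
  if (model$n_causal > m) stop("n_causal exceeds the number of variants")

  g_term <- 0
  causal <- data.frame(variant_id = character(0), beta = numeric(0))
  if (model$heritability > 0) {
    idx <- sort(sample.int(m, model$n_causal))
    G_cols <- geno$dosage[, idx, drop = FALSE]
    if (anyNA(G_cols)) {
      stop("causal variants must be completely observed (missing dosages found)")
    }
    beta_raw <- stats::rnorm(model$n_causal)
    G <- as.numeric(G_cols %*% beta_raw)
    ## remove the population-mean component of the causal score: allele
    ## frequency drift would otherwise add a random trait-ancestry
    ## correlation on top of (or cancelling) the configured structure share,
    ## making the trait's structuredness a coin flip instead of a parameter
    G <- G - stats::ave(G, samples$population)
    s <- stats::sd(G)
    scale_fac <- if (s > 0) sqrt(model$heritability) / s else 0
    g_term <- (G - mean(G)) * scale_fac
    causal <- data.frame(variant_id = geno$variants$variant_id[idx],
                         beta = beta_raw * scale_fac,
                         stringsAsFactors = FALSE)
  }

  s_term <- 0
  if (model$structure_effect > 0) {
    a <- samples$ancestry_score
    if (stats::sd(a) == 0) stop("structure_effect > 0 but ancestry_score is constant")
    s_term <- as.numeric(scale(a)) * sqrt(model$structure_effect)
  }

  std <- function(x) if (stats::sd(x) > 0) as.numeric(scale(x)) else x * 0
  ce <- model$covariate_effects
  c_term <- ce[["age"]] * std(samples$age) +
    ce[["sex"]] * std(samples$sex) +
    ce[["batch"]] * std(as.numeric(factor(samples$batch)))

  eps <- stats::rnorm(n, 0, model$noise_sd)
  y <- g_term + s_term + c_term + eps
  names(y) <- samples$sample_id
  vt <- stats::var(y)
  attr(y, "causal_effects") <- causal
  attr(y, "realized_shares") <- c(
    genetic = if (length(g_term) > 1) stats::var(g_term) / vt else 0,
    structure = if (length(s_term) > 1) stats::var(s_term) / vt else 0,
    covariates = if (length(c_term) > 1) stats::var(c_term) / vt else 0,
    noise = stats::var(eps) / vt
  )
  y
}

#' Randomly split samples into disjoint analysis roles
#'
#' @param samples Sample table (needs sample_id and population columns).
#' @param sizes Named list; each element is either a count (drawn from all
#'   remaining samples) or a list `list(n=, populations=)` restricting the draw
#'   to given populations. Roles are filled in list order without replacement.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return Object of class `cohort_split`: named list of sample-id vectors.
#' @export
split_cohorts <- function(samples, sizes, seed) {
  stopifnot(is.list(sizes), length(names(sizes)) == length(sizes))
  set.seed(as.integer(seed))
  available <- samples$sample_id
  out <- list()
  for (role in names(sizes)) {
    spec <- sizes[[role]]
    if (is.list(spec)) {
      pool <- samples$sample_id[samples$population %in% spec$populations]
      pool <- intersect(pool, available)
      n_req <- spec$n
    } else {
      pool <- available
      n_req <- spec
    }
    if (n_req > length(pool)) {
      stop(sprintf("role '%s' requests %d samples but only %d are available",
                   role, n_req, length(pool)))
    }
    take <- sample(pool, n_req)
    out[[role]] <- sort(take)
    available <- setdiff(available, take)
  }
  structure(out, class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("cohort_split:\n")
  for (r in names(x)) cat(sprintf("  %-16s %d samples\n", r, length(x[[r]])))
  invisible(x)
}

#' Role sizes in the proportions of the emulated biobank design
#'
#' Returns discovery/target/panel sizes proportional to the emulated study
#' (discovery 350745, same-cohort target 7100, other-cohort target 7070,
#' cohort panels 5000, all-reference 2504, European-like 503,
#' non-European-like 2001), multiplied by `scale` and rounded (minimum 2).
#'
#' @param scale Scaling factor applied to every role size.
#' @return Named integer vector of role sizes.
#' @export
cohort_preset <- function(scale = 1) {
  base <- c(discovery = 350745, target_same = 7100, target_other = 7070,
            panel_same = 5000, panel_other = 5000,
            panel_all = 2504, panel_eur = 503, panel_neur = 2001)
  stats::setNames(pmax(2L, as.integer(round(base * scale))), names(base))
}
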