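# Polygenic score construction: greedy LD clumping, scoring, and
# best-p-value-threshold selection.

#' The p-value threshold grid used for score construction
#' @export
prs_threshold_grid <- function() {
  c(0.00005, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5)
}

#' Greedy LD clumping of summary statistics
#'
#' Variants are sorted by ascending p-value (ties by chromosome then
#' position); the best remaining variant becomes an index variant and every
#' unclaimed variant on the same chromosome within `window_kb` kilobases with
#' squared correlation above `r2_max` against it (in the LD reference) is
#' claimed and discarded. Summary-statistic variants absent from the LD
#' reference are excluded (count reported by message). Correlations use
#' mean-imputed standardised dosages.
#'
#' @param stats A `gwas_stats` data.frame.
#' @param ld_reference A `geno_matrix` supplying LD (typically the target
#'   cohort's genotypes).
#' @param r2_max Squared-correlation threshold.
#' @param p_max Maximum p-value for index variants.
#' @param window_kb Clumping window half-width in kb.
#' @param X Optional precomputed `standardize_dosage(ld_reference$dosage)`,
#'   reused across repeated calls against the same reference.
#' @return Character vector of index variant ids in selection order.
#' @export
clump_variants <- function(stats, ld_reference, r2_max = 0.05, p_max = 1,
                           window_kb = 1000, X = NULL) {
  stopifnot(inherits(ld_reference, "geno_matrix"), r2_max < 1, r2_max > 0,
            window_kb > 0)
  df <- as.data.frame(stats)
  df <- df[!is.na(df$p), ]
  pos_in_ref <- match(df$variant_id, ld_reference$variants$variant_id)
  if (anyNA(pos_in_ref)) {
    message(sum(is.na(pos_in_ref)),
            " summary-statistic variant(s) absent from LD reference, excluded")
    df <- df[!is.na(pos_in_ref), ]
    pos_in_ref <- pos_in_ref[!is.na(pos_in_ref)]
  }
  if (nrow(df) == 0) return(character(0))
  if (is.null(X)) X <- standardize_dosage(ld_reference$dosage)
  stopifnot(ncol(X) == ncol(ld_reference$dosage))
  n1 <- nrow(X) - 1
  ord <- order(df$p, df$chrom, df$pos)
  claimed <- rep(FALSE, nrow(df))
  index <- integer(0)
  win_bp <- window_kb * 1000
  for (i in ord) {
    if (claimed[i] || df$p[i] > p_max) next
    claimed[i] <- TRUE
    index <- c(index, i)
    nbr <- which(!claimed & df$chrom == df$chrom[i] &
                   abs(df$pos - df$pos[i]) <= win_bp)
    if (length(nbr) == 0) next
    r <- crossprod(X[, pos_in_ref[i]],
                   X[, pos_in_ref[nbr], drop = FALSE]) / n1
    claimed[nbr[as.numeric(r)^2 > r2_max]] <- TRUE
  }
  df$variant_id[index]
}

#' Compute raw polygenic scores
#'
#' Per sample, the sum over included variants of effect-allele dosage times
#' the GWAS beta. Variants whose effect allele matches the genotype's second
#' allele are flipped (dosage 2 - g); inconsistent alleles raise an error.
#' Missing dosages contribute the variant's mean dosage.
#'
#' @param geno Target `geno_matrix`.
#' @param stats A `gwas_stats` data.frame (effect sizes and alleles).
#' @param variants Character vector of variant ids to include.
#' @return Numeric raw score vector named by sample id, with attribute
#'   `n_snps`.
#' @export
prs_score <- function(geno, stats, variants) {
  df <- as.data.frame(stats)
  df <- df[match(variants, df$variant_id), , drop = FALSE]
  if (anyNA(df$variant_id)) stop("variants missing from summary statistics")
  gi <- match(variants, geno$variants$variant_id)
  if (anyNA(gi)) stop("variants missing from target genotypes")
  if (length(variants) == 0) {
    return(structure(stats::setNames(rep(0, nrow(geno$dosage)),
                                     geno$samples$sample_id), n_snps = 0L))
  }
  ga <- geno$variants[gi, ]
  same <- df$effect_allele == ga$a1 & df$other_allele == ga$a2
  swapped <- df$effect_allele == ga$a2 & df$other_allele == ga$a1
  if (any(!same & !swapped)) {
    stop("inconsistent alleles between summary statistics and genotypes for: ",
         paste(utils::head(variants[!same & !swapped], 5), collapse = ", "))
  }
  D <- geno$dosage[, gi, drop = FALSE]
  storage.mode(D) <- "double"
  if (any(swapped)) D[, swapped] <- 2 - D[, swapped]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- mu[na_idx[, 2]]
  }
  s <- as.numeric(D %*% df$beta)
  structure(stats::setNames(s, geno$samples$sample_id),
            n_snps = length(variants))
}

#' Select the best-performing p-value threshold
#'
#' For each threshold in the grid, the clumped variants passing it are scored,
#' the score standardised in the target set, and the validation regression
#' (trait on score plus age, sex, batch and optionally PCs) fitted; the
#' threshold maximising the model R-squared wins, ties broken toward the
#' smaller threshold (hence fewer SNPs). With `objective = "prs_only"` the
#' R-squared of trait on the score alone is maximised instead.
#'
#' @param geno Target `geno_matrix`.
#' @param trait Trait vector aligned to the target samples.
#' @param samples Covariate table aligned to the target samples.
#' @param stats A `gwas_stats` data.frame.
#' @param clumped Character vector of clumped index variant ids.
#' @param pcs Optional `pc_coords` used as validation covariates.
#' @param thresholds Numeric threshold grid.
#' @param objective `"total"` (validation-model R-squared, default) or
#'   `"prs_only"`.
#' @param n_pcs PCs used when `pcs` is supplied.
#' @return Object of class `prs_profile`: standardised `score` (mean 0, sd 1
#'   in the target set), `chosen_threshold`, `n_snps`, `variants` (id, effect
#'   allele, beta), `label`, `r2_by_threshold`.
#' @export
select_best_threshold <- function(geno, trait, samples, stats, clumped,
                                  pcs = NULL,
                                  thresholds = prs_threshold_grid(),
                                  objective = c("total", "prs_only"),
                                  n_pcs = 20) {
  objective <- match.arg(objective)
  df <- as.data.frame(stats)
  pmap <- df$p[match(clumped, df$variant_id)]
  W <- covariate_matrix(samples, c("age", "sex", "batch"))
  if (!is.null(pcs)) W <- cbind(W, as.matrix(pcs)[, seq_len(n_pcs), drop = FALSE])
  best <- NULL
  r2s <- stats::setNames(rep(NA_real_, length(thresholds)),
                         format(thresholds, scientific = FALSE))
  ## threshold sets are nested, so raw scores accumulate incrementally
  acc <- rep(0, nrow(geno$dosage))
  used <- rep(FALSE, length(clumped))
  for (ti in order(thresholds)) {
    thr <- thresholds[ti]
    keep <- !is.na(pmap) & pmap <= thr
    vs <- clumped[keep]
    if (length(vs) == 0) {
      message(sprintf("threshold %g admits no variants, skipped", thr))
      next
    }
    delta <- keep & !used
    if (any(delta)) {
      acc <- acc + as.numeric(prs_score(geno, stats, clumped[delta]))
      used <- used | delta
    }
    raw <- acc
    if (stats::sd(raw) == 0) {
      message(sprintf("threshold %g yields a constant score, skipped", thr))
      next
    }
    z <- as.numeric(scale(raw))
    X <- if (objective == "total") cbind(W, prs = z)
         else cbind(`(Intercept)` = 1, prs = z)
    fit <- stats::lm.fit(X, trait)
    r2 <- 1 - sum(fit$residuals^2) / sum((trait - mean(trait))^2)
    r2s[ti] <- r2
    if (is.null(best) || r2 > best$r2) {
      best <- list(r2 = r2, thr = thr, vs = vs, z = z)
    }
  }
  if (is.null(best)) stop("no threshold admitted any variants")
  vinfo <- df[match(best$vs, df$variant_id),
              c("variant_id", "effect_allele", "other_allele", "beta")]
  structure(list(
    score = stats::setNames(best$z, geno$samples$sample_id),
    chosen_threshold = best$thr,
    n_snps = length(best$vs),
    variants = vinfo,
    label = attr(stats, "pc_set_label") %||% "unknown",
    r2_by_threshold = r2s
  ), class = "prs_profile")
}

#' Write a PRS profile as TSV plus a JSON sidecar
#'
#' Writes `<prefix>.tsv` (sample_id, prs_standardized), the included-variant
#' list `<prefix>_variants.tsv`, and `<prefix>.json` with the chosen
#' threshold, SNP count and source summary-statistics label.
#'
#' @param profile A `prs_profile`.
#' @param prefix Output path prefix.
#' @export
write_prs_profile <- function(profile, prefix) {
  stopifnot(inherits(profile, "prs_profile"))
  utils::write.table(
    data.frame(sample_id = names(profile$score),
               prs_standardized = as.numeric(profile$score)),
    paste0(prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profile$variants, paste0(prefix, "_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(chosen_threshold = profile$chosen_threshold,
         n_snps = profile$n_snps, source = profile$label),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("prs_profile (%s): %d SNPs at p<=%g, standardized over %d samples\n",
              x$label, x$n_snps, x$chosen_threshold, length(x$score)))
  invisible(x)
}
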