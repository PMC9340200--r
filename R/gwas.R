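# Per-variant additive linear-model association with configurable PC
# adjustment, and the genomic inflation factor.

#' Run a per-variant additive GWAS
#'
#' For each variant, ordinary least squares of the trait on
#' `[1, age, sex, batch, dosage, PC1..PCk]`; the dosage coefficient, its
#' standard error, t statistic and two-sided p-value (t distribution with
#' residual degrees of freedom) are reported. Samples with a missing dosage at
#' a variant are excluded from that variant's fit. For complete dosage columns
#' the fit is computed by residualising the trait and all dosages on the
#' shared covariates once and regressing residual on residual, which is
#' algebraically identical to the per-variant fit; variants with any missing
#' dosage fall back to an explicit per-variant regression.
#'
#' @param geno A `geno_matrix`.
#' @param trait Numeric trait vector aligned to the genotype rows.
#' @param samples Covariate table aligned to the genotype rows (columns age,
#'   sex, batch used; batch is dummy-coded, reference level lexicographically
#'   first).
#' @param pcs Optional `pc_coords` (or plain matrix); `NULL` runs the
#'   control GWAS without PC adjustment.
#' @param n_pcs Number of PC columns used when `pcs` is supplied.
#' @param covariates Character vector of covariate column names to use from
#'   `samples` (empty vector fits an intercept-plus-dosage model).
#' @return Object of class `gwas_stats`, a data.frame with one row per variant
#'   (variant_id, chrom, pos, effect_allele, other_allele, beta, se, t, p,
#'   n_used, reason) and attributes `pc_set_label`, `lambda`, `n`.
#'   Variants monomorphic among their complete cases get an `NA` row with a
#'   reason code.
#' @export
run_gwas <- function(geno, trait, samples, pcs = NULL, n_pcs = 20,
                     covariates = c("age", "sex", "batch")) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- nrow(geno$dosage)
  stopifnot(length(trait) == n, nrow(samples) == n)
  label <- if (is.null(pcs)) "none" else attr(pcs, "source_space") %||% "pcs"

  W <- covariate_matrix(samples, covariates)
  if (!is.null(pcs)) {
    P <- as.matrix(pcs)
    if (ncol(P) < n_pcs) {
      stop(sprintf("pcs has %d columns but n_pcs=%d requested", ncol(P), n_pcs))
    }
    W <- cbind(W, P[, seq_len(n_pcs), drop = FALSE])
  }
  check_full_rank(W)

  m <- ncol(geno$dosage)
  beta <- se <- tval <- pval <- rep(NA_real_, m)
  n_used <- rep(NA_integer_, m)
  reason <- rep(NA_character_, m)

  qrW <- qr(W)
  Q <- qr.Q(qrW)
  ry <- trait - Q %*% crossprod(Q, trait)
  df <- n - ncol(W) - 1
  has_na <- colSums(is.na(geno$dosage)) > 0

  ## batched residualisation pass over complete columns, in memory-safe chunks
  complete_idx <- which(!has_na)
  chunk <- 2000L
  for (start in seq(1, length(complete_idx), by = chunk)) {
    cols <- complete_idx[start:min(start + chunk - 1, length(complete_idx))]
    D <- geno$dosage[, cols, drop = FALSE]
    storage.mode(D) <- "double"
    RD <- D - Q %*% crossprod(Q, D)
    css <- colSums(RD^2)
    ok <- css > 1e-10
    b <- rep(NA_real_, length(cols))
    b[ok] <- colSums(RD[, ok, drop = FALSE] * as.numeric(ry)) / css[ok]
    sse <- sum(ry^2) - b^2 * css
    sse <- pmax(sse, 0)
    s2 <- sse / df
    beta[cols] <- b
    se[cols] <- sqrt(s2 / css)
    n_used[cols] <- n
    reason[cols][!ok] <- "monomorphic"
    se[cols][!ok] <- NA_real_
  }

  ## per-variant reference path for variants with missing dosages
  for (j in which(has_na)) {
    g <- geno$dosage[, j]
    cc <- !is.na(g)
    gj <- as.numeric(g[cc])
    n_used[j] <- sum(cc)
    if (stats::var(gj) < 1e-12 || sum(cc) <= ncol(W) + 1) {
      reason[j] <- "monomorphic"
      next
    }
    X <- cbind(W[cc, , drop = FALSE], dosage = gj)
    fit <- stats::lm.fit(X, trait[cc])
    dfj <- sum(cc) - ncol(X)
    s2 <- sum(fit$residuals^2) / dfj
    XtXinv_gg <- chol2inv(chol(crossprod(X)))[ncol(X), ncol(X)]
    beta[j] <- fit$coefficients[["dosage"]]
    se[j] <- sqrt(s2 * XtXinv_gg)
  }

  ok <- !is.na(beta) & !is.na(se)
  dfs <- ifelse(has_na, n_used - ncol(W) - 1, df)
  tval[ok] <- beta[ok] / se[ok]
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), dfs[ok])

  out <- data.frame(
    variant_id = geno$variants$variant_id,
    chrom = geno$variants$chrom,
    pos = geno$variants$pos,
    effect_allele = geno$variants$a1,
    other_allele = geno$variants$a2,
    beta = beta, se = se, t = tval, p = pval,
    n_used = n_used, reason = reason,
    stringsAsFactors = FALSE
  )
  lam <- if (sum(ok) > 0) genomic_inflation(pval[ok]) else NA_real_
  structure(out, class = c("gwas_stats", "data.frame"),
            pc_set_label = label, lambda = lam, n = n)
}

# Dummy-coded covariate matrix with intercept; factors get lexicographic
# reference levels through factor()'s default ordering.
covariate_matrix <- function(samples, covariates) {
  if (length(covariates) == 0) {
    return(matrix(1, nrow(samples), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- samples[, covariates, drop = FALSE]
  for (cl in names(df)) if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  stats::model.matrix(stats::reformulate(covariates), data = df)
}

check_full_rank <- function(W) {
  qd <- qr(W)
  if (qd$rank < ncol(W)) {
    dropped <- colnames(W)[qd$pivot[(qd$rank + 1):ncol(W)]]
    stop("collinear covariates: ", paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.gwas_stats <- function(x, ...) {
  cat(sprintf("gwas_stats: %d variants, n=%d, PC set '%s', lambda=%.4f\n",
              nrow(x), attr(x, "n"), attr(x, "pc_set_label"),
              attr(x, "lambda")))
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} is the median of the 1-df chi-square statistics implied by
#' the p-values, divided by the null chi-square median (0.4549364). Zero
#' p-values are clamped to the smallest positive representable double with a
#' warning.
#'
#' @param p Numeric vector of p-values.
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) {
    warning("fewer than 100 p-values; lambda estimate is unstable")
  }
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to smallest representable positive value")
    p[p <= 0] <- .Machine$double.xmin
  }
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Write GWAS summary statistics as TSV
#'
#' Header comment lines record the PC-set label and genomic inflation.
#'
#' @param stats A `gwas_stats` object.
#' @param path Output file path.
#' @export
write_gwas <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pc_set_label=%s", attr(stats, "pc_set_label")), con)
  writeLines(sprintf("# lambda=%.6f", attr(stats, "lambda")), con)
  utils::write.table(as.data.frame(stats), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
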