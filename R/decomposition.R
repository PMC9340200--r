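# Residual-regression decomposition of trait, polygenic score, and PCs.

#' Residualise a vector on a covariate design
#'
#' Returns `y` minus its ordinary-least-squares projection on the design
#' (which must have full rank and should include an intercept); the residual
#' is orthogonal to every design column.
#'
#' @param y Numeric response vector.
#' @param design Numeric matrix (or data.frame) of covariates.
#' @return Numeric residual vector.
#' @export
residualize <- function(y, design) {
  X <- as.matrix(design)
  stopifnot(length(y) == nrow(X))
  check_full_rank(X)
  qx <- qr(X)
  as.numeric(y - qr.fitted(qx, y))
}

# Upper-tail F-test of an OLS model (with intercept) against intercept-only.
f_test_vs_intercept <- function(y, X) {
  n <- length(y)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  d <- ncol(as.matrix(X))
  fstat <- (r2 / d) / ((1 - r2) / (n - d - 1))
  p <- stats::pf(fstat, d, n - d - 1, lower.tail = FALSE)
  list(r2 = r2, f = fstat, p = p, df1 = d, df2 = n - d - 1)
}

#' Residual-regression decomposition of trait, PRS and PCs
#'
#' After regressing the non-genetic covariates (age, sex, genotyping batch)
#' out of the trait, six regressions quantify the variance shared among the
#' residual trait, the standardised polygenic score, and the principal
#' components:
#' (1) `trait_res ~ PCs`, (2) `PRS ~ PCs`, (3) `trait_res ~ PRS`,
#' (4) `trait_res ~ PCs + PRS`, (5) `trait_res_PRS ~ PCs`,
#' (6) `trait_res_PCs ~ PRS`, where `trait_res_PRS` and `trait_res_PCs` are
#' the residual trait additionally residualised on the score or the PCs.
#' Each model is tested against the intercept-only model with the upper-tail
#' F-test; significance uses a Bonferroni-corrected one-sided cut-off
#' (0.05 divided by `n_tests`, the study-design family of PRS-by-trait
#' combinations, 10 by default giving 0.005).
#'
#' @param trait Trait vector.
#' @param prs A `prs_profile` or numeric score vector (standardised
#'   internally, with a warning, if it is not).
#' @param pcs A `pc_coords` matrix (cohort-specific PCs in the default
#'   design).
#' @param samples Covariate table.
#' @param n_pcs Number of PC columns used.
#' @param n_tests Size of the Bonferroni family.
#' @return Object of class `decomposition_result`, a data.frame with one row
#'   per model: model, formula, r2, f, p, significant.
#' @export
run_decomposition <- function(trait, prs, pcs, samples, n_pcs = 20,
                              n_tests = 10) {
  z <- if (inherits(prs, "prs_profile")) prs$score else as.numeric(prs)
  if (abs(mean(z)) > 1e-8 || abs(stats::sd(z) - 1) > 1e-6) {
    warning("PRS was not standardised; standardising internally")
    z <- as.numeric(scale(z))
  }
  P <- as.matrix(pcs)[, seq_len(n_pcs), drop = FALSE]
  W <- covariate_matrix(samples, c("age", "sex", "batch"))
  trait_res <- residualize(trait, W)
  trait_res_prs <- residualize(trait_res, cbind(1, z))
  trait_res_pcs <- residualize(trait_res, cbind(1, P))

  models <- list(
    list(label = "trait_res ~ PCs",       y = trait_res,     X = P),
    list(label = "PRS ~ PCs",             y = z,             X = P),
    list(label = "trait_res ~ PRS",       y = trait_res,     X = cbind(prs = z)),
    list(label = "trait_res ~ PCs + PRS", y = trait_res,     X = cbind(P, prs = z)),
    list(label = "trait_res_PRS ~ PCs",   y = trait_res_prs, X = P),
    list(label = "trait_res_PCs ~ PRS",   y = trait_res_pcs, X = cbind(prs = z))
  )
  cutoff <- 0.05 / n_tests
  rows <- lapply(seq_along(models), function(i) {
    ft <- f_test_vs_intercept(models[[i]]$y, models[[i]]$X)
    data.frame(model = i, formula = models[[i]]$label, r2 = ft$r2, f = ft$f,
               p = ft$p, significant = ft$p < cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cutoff") <- cutoff
  attr(out, "prs_label") <- if (inherits(prs, "prs_profile")) prs$label else "prs"
  class(out) <- c("decomposition_result", "data.frame")
  out
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("decomposition_result (PRS %s, cut-off %.4g):\n",
              attr(x, "prs_label"), attr(x, "cutoff")))
  df <- as.data.frame(x)
  df$r2 <- round(df$r2, 4)
  df$f <- round(df$f, 2)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
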