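# Validation-model fits, BIC / delta-BIC model comparison, and the
# 5 x 5 PRS-by-PC grid.

#' Fit one validation model
#'
#' Ordinary least squares of the trait on
#' `[1, PRS, age, sex, batch, (PC1..PCk)]`, with the Gaussian log-likelihood
#' at the maximum-likelihood variance estimate and
#' `BIC = -2 loglik + k log(n)`, where `k` counts every regression
#' coefficient plus the residual variance. The added R-squared of the score
#' is the total R-squared minus that of the matched model without the score
#' term.
#'
#' @param trait Trait vector.
#' @param prs A `prs_profile` (or standardised numeric score vector).
#' @param samples Covariate table aligned to the trait.
#' @param pcs Optional `pc_coords`; `NULL` is the no-PC control.
#' @param n_pcs PCs used when `pcs` is supplied.
#' @return Object of class `validation_fit`: prs_label, pc_label,
#'   log_likelihood, k, n, bic, total_r2, added_r2_prs, prs_beta, prs_p.
#' @export
fit_validation_model <- function(trait, prs, samples, pcs = NULL, n_pcs = 20) {
  z <- if (inherits(prs, "prs_profile")) prs$score else prs
  stopifnot(length(z) == length(trait))
  W <- covariate_matrix(samples, c("age", "sex", "batch"))
  pc_label <- if (is.null(pcs)) "none" else attr(pcs, "source_space") %||% "pcs"
  if (!is.null(pcs)) {
    W <- cbind(W, as.matrix(pcs)[, seq_len(n_pcs), drop = FALSE])
  }
  X <- cbind(W, prs = as.numeric(z))
  check_full_rank(X)
  n <- length(trait)

  fit_ols <- function(X) {
    f <- stats::lm.fit(X, trait)
    rss <- sum(f$residuals^2)
    sigma2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
    r2 <- 1 - rss / sum((trait - mean(trait))^2)
    list(fit = f, rss = rss, ll = ll, r2 = r2, k = ncol(X) + 1)
  }
  full <- fit_ols(X)
  null_prs <- fit_ols(W)

  ## t test on the score coefficient from the full fit
  s2 <- full$rss / (n - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_prs <- sqrt(s2 * XtXinv[ncol(X), ncol(X)])
  b_prs <- full$fit$coefficients[["prs"]]
  p_prs <- 2 * stats::pt(-abs(b_prs / se_prs), n - ncol(X))

  structure(list(
    prs_label = if (inherits(prs, "prs_profile")) prs$label else "prs",
    pc_label = pc_label,
    log_likelihood = full$ll,
    k = full$k,
    n = n,
    bic = -2 * full$ll + full$k * log(n),
    total_r2 = full$r2,
    added_r2_prs = full$r2 - null_prs$r2,
    prs_beta = b_prs,
    prs_p = p_prs
  ), class = "validation_fit")
}

#' @export
print.validation_fit <- function(x, ...) {
  cat(sprintf("validation_fit [PRS %s | PC %s]\n", x$prs_label, x$pc_label))
  cat(sprintf("  n=%d k=%d  logLik=%.2f  BIC=%.2f\n",
              x$n, x$k, x$log_likelihood, x$bic))
  cat(sprintf("  total R2=%.4f  added R2 (PRS)=%.4f  (beta=%.3f, p=%.3g)\n",
              x$total_r2, x$added_r2_prs, x$prs_beta, x$prs_p))
  invisible(x)
}

#' Fit the full PRS-by-PC validation grid
#'
#' Every supplied score (rows, including the PC-free-GWAS control) is fitted
#' against every PC option (columns, including the no-PC control), giving the
#' grid of validation models; delta-BIC is each cell's BIC minus the grid
#' minimum.
#'
#' @param trait Trait vector.
#' @param prs_list Named list of `prs_profile`s (rows).
#' @param samples Covariate table.
#' @param pcs_list Named list of `pc_coords` (columns); a `none` control
#'   column is appended automatically if absent.
#' @param n_pcs PCs used per column.
#' @return Object of class `validation_grid`: `fits` (row x column list),
#'   `bic`, `delta_bic`, `total_r2`, `added_r2` matrices, and `best_cell`
#'   (row/column labels of the minimum-BIC cell).
#' @export
run_grid <- function(trait, prs_list, samples, pcs_list, n_pcs = 20) {
  stopifnot(is.list(prs_list), is.list(pcs_list))
  if (!"none" %in% names(pcs_list)) pcs_list <- c(pcs_list, list(none = NULL))
  rn <- names(prs_list)
  cn <- names(pcs_list)
  fits <- vector("list", length(rn) * length(cn))
  dim(fits) <- c(length(rn), length(cn))
  dimnames(fits) <- list(rn, cn)
  num <- function(f) matrix(vapply(fits, function(x) x[[f]], 0),
                            length(rn), length(cn), dimnames = list(rn, cn))
  for (r in rn) {
    for (cc in cn) {
      fits[[r, cc]] <- fit_validation_model(trait, prs_list[[r]], samples,
                                            pcs = pcs_list[[cc]], n_pcs = n_pcs)
    }
  }
  bic <- num("bic")
  delta <- bic - min(bic)
  best <- arrayInd(which.min(bic), dim(bic))
  structure(list(
    fits = fits,
    bic = bic,
    delta_bic = delta,
    total_r2 = num("total_r2"),
    added_r2 = num("added_r2_prs"),
    best_cell = c(prs = rn[best[1]], pc = cn[best[2]])
  ), class = "validation_grid")
}

#' @export
print.validation_grid <- function(x, ...) {
  cat(sprintf("validation_grid (%d x %d); best cell: PRS %s | PC %s\n",
              nrow(x$bic), ncol(x$bic), x$best_cell[["prs"]],
              x$best_cell[["pc"]]))
  cat("\ndelta BIC:\n")
  print(round(x$delta_bic, 1))
  cat("\nadded R2 by PRS:\n")
  print(round(x$added_r2, 4))
  invisible(x)
}

#' Classify delta-BIC values into evidence bins
#'
#' Less than 6 units is a weak difference in model performance, 6 to 10
#' (inclusive) strong, above 10 very strong.
#'
#' @param delta Non-negative delta-BIC value(s).
#' @return Character vector of bins (`weak`, `strong`, `very strong`).
#' @export
classify_delta_bic <- function(delta) {
  if (any(delta < 0)) stop("delta BIC must be non-negative")
  ifelse(delta < 6, "weak", ifelse(delta <= 10, "strong", "very strong"))
}

#' Write the grid's delta-BIC and added-R2 tables as TSV
#'
#' @param grid A `validation_grid`.
#' @param prefix Output path prefix; writes `<prefix>_delta_bic.tsv`,
#'   `<prefix>_added_r2.tsv` and `<prefix>_best_cell.json`.
#' @export
write_grid <- function(grid, prefix) {
  write_matrix_tsv(grid$delta_bic, paste0(prefix, "_delta_bic.tsv"))
  write_matrix_tsv(grid$added_r2, paste0(prefix, "_added_r2.tsv"))
  jsonlite::write_json(as.list(grid$best_cell),
                       paste0(prefix, "_best_cell.json"), auto_unbox = TRUE)
  invisible(prefix)
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(label = rownames(mat),
                   formatC(mat, format = "g", digits = 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
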