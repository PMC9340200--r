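# Principal component spaces from reference panels, with iterative outlier
# removal, and least-squares projection of other cohorts onto them.

#' Build a PC space from a reference panel
#'
#' The panel is LD-pruned, its dosages standardised per variant
#' ((g - mean)/sd, missing contributing 0 after centering), and the sample
#' covariance eigendecomposed. For up to `n_outlier_iters` iterations, panel
#' samples lying more than `outlier_sd` standard deviations from the panel
#' mean on any of the top `top_pcs_checked` PCs are removed and the analysis
#' (including LD pruning and the standardisation constants) recomputed on the
#' remaining samples; iteration stops early when no outlier is found. SNP
#' loadings are orthonormal; each loading column is oriented so that its
#' largest-absolute-value entry is positive, which fixes the arbitrary
#' eigenvector sign.
#'
#' @param panel A `geno_matrix` of the reference panel (post-QC).
#' @param K Number of components to retain (reduced with a warning if it
#'   exceeds the final panel size minus one).
#' @param n_outlier_iters Maximum outlier-removal iterations.
#' @param outlier_sd Outlier threshold in per-PC standard deviations.
#' @param top_pcs_checked Number of leading PCs screened for outliers.
#' @param prune Logical; LD-prune the panel each iteration (default TRUE).
#' @param prune_window,prune_step,prune_r2 LD pruning parameters.
#' @param shrinkage Must be FALSE; projected-score shrinkage correction is not
#'   implemented and requesting it is an error.
#' @return Object of class `pc_space`: `loadings` (variants x K, orthonormal
#'   columns, rownames variant ids), `eigenvalues` (non-increasing,
#'   variance-explained scale), `snp_means`, `snp_sds`, `alleles`
#'   (a1/a2 per retained variant), `variant_ids`, `panel_ids` (final panel),
#'   `removed_ids`, `K`, `n_iterations`.
#' @export
build_pc_space <- function(panel, K = 20, n_outlier_iters = 5, outlier_sd = 6,
                           top_pcs_checked = 10, prune = TRUE,
                           prune_window = 50, prune_step = 10, prune_r2 = 0.1,
                           shrinkage = FALSE) {
  stopifnot(inherits(panel, "geno_matrix"))
  if (isTRUE(shrinkage)) {
    stop("shrinkage-corrected projection is not implemented")
  }
  current <- panel
  removed <- character(0)
  iter_done <- 0
  repeat {
    iter_done <- iter_done + 1
    work <- current
    if (prune) {
      kept <- ld_prune(work, window = prune_window, step = prune_step,
                       r2_max = prune_r2)
      work <- subset_geno(work, variants = kept)
    }
    dec <- panel_eigen(work, K)
    n_pc <- ncol(dec$scores)
    check <- seq_len(min(top_pcs_checked, n_pc))
    ctr <- colMeans(dec$scores[, check, drop = FALSE])
    sds <- apply(dec$scores[, check, drop = FALSE], 2, stats::sd)
    sds[sds == 0] <- Inf
    dev <- abs(sweep(dec$scores[, check, drop = FALSE], 2, ctr, "-"))
    out <- rowSums(sweep(dev, 2, sds, "/") > outlier_sd) > 0
    if (!any(out) || iter_done >= n_outlier_iters) {
      space <- structure(list(
        loadings = dec$loadings,
        eigenvalues = dec$eigenvalues,
        snp_means = dec$snp_means,
        snp_sds = dec$snp_sds,
        alleles = work$variants[, c("variant_id", "a1", "a2")],
        variant_ids = work$variants$variant_id,
        panel_ids = work$samples$sample_id,
        removed_ids = removed,
        K = ncol(dec$loadings),
        n_iterations = iter_done
      ), class = "pc_space")
      return(space)
    }
    removed <- c(removed, work$samples$sample_id[out])
    current <- subset_geno(current, samples = which(
      !current$samples$sample_id %in% removed))
  }
}

# Eigendecomposition of the standardised panel via the n x n Gram matrix.
# Eigenvalues are on the variance-explained scale d^2/(n-1), so with K = n-1
# they sum to the number of (polymorphic) variants.
panel_eigen <- function(geno, K) {
  X <- standardize_dosage(geno$dosage)
  sds <- attr(X, "sds")
  poly <- sds > 0
  if (!all(poly)) X <- X[, poly, drop = FALSE]
  n <- nrow(X)
  m <- ncol(X)
  K_eff <- min(K, n - 1, m)
  if (K_eff < K) {
    warning(sprintf("K reduced from %d to %d (panel size/variant limit)",
                    K, K_eff))
  }
  eg <- eigen(tcrossprod(X), symmetric = TRUE)
  d2 <- pmax(eg$values[seq_len(K_eff)], 0)
  d <- sqrt(d2)
  U <- eg$vectors[, seq_len(K_eff), drop = FALSE]
  V <- crossprod(X, U)
  V <- sweep(V, 2, ifelse(d > 0, d, 1), "/")
  ## sign convention: largest-|entry| of each loading column is positive
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))])) < 0
  V[, flip] <- -V[, flip]
  scores <- X %*% V
  mu <- colMeans(geno$dosage, na.rm = TRUE)[poly]
  rownames(V) <- geno$variants$variant_id[poly]
  colnames(V) <- paste0("PC", seq_len(K_eff))
  dimnames(scores) <- list(geno$samples$sample_id, colnames(V))
  list(loadings = V,
       eigenvalues = d2 / (n - 1),
       scores = scores,
       snp_means = stats::setNames(mu, rownames(V)),
       snp_sds = stats::setNames(attr(X, "sds")[poly], rownames(V)))
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("pc_space: %d PCs over %d variants, panel n=%d (%d iteration%s",
              x$K, length(x$variant_ids), length(x$panel_ids),
              x$n_iterations, if (x$n_iterations == 1) ")" else "s)"))
  cat(sprintf("\n  outliers removed: %d\n", length(x$removed_ids)))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project samples onto a reference PC space
#'
#' Cohort dosages at the space's variants are standardised with the panel's
#' means and standard deviations (never the cohort's own), missing dosages
#' contributing zero after centering; scores are the product with the
#' orthonormal SNP loadings, which is the least-squares solution. Variants with
#' swapped alleles relative to the panel are flipped (dosage 2 - g); variants
#' with inconsistent alleles, or absent from the cohort, raise an error naming
#' them.
#'
#' @param space A `pc_space`.
#' @param cohort A `geno_matrix` containing all of the space's variants.
#' @param label Optional source-space label stored on the result.
#' @return Object of class `pc_coords`: samples x K score matrix with a
#'   `source_space` attribute.
#' @export
project_samples <- function(space, cohort, label = NULL) {
  stopifnot(inherits(space, "pc_space"), inherits(cohort, "geno_matrix"))
  vid <- space$variant_ids
  pos <- match(vid, cohort$variants$variant_id)
  if (anyNA(pos)) {
    miss <- vid[is.na(pos)]
    stop("cohort is missing space variants: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  }
  ca <- cohort$variants[pos, ]
  same <- ca$a1 == space$alleles$a1 & ca$a2 == space$alleles$a2
  swapped <- ca$a1 == space$alleles$a2 & ca$a2 == space$alleles$a1
  if (any(!same & !swapped)) {
    bad <- vid[!same & !swapped]
    stop("allele mismatch between cohort and panel for: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  D <- cohort$dosage[, pos, drop = FALSE]
  storage.mode(D) <- "double"
  if (any(swapped)) D[, swapped] <- 2 - D[, swapped]
  D <- sweep(D, 2, space$snp_means, "-")
  D[is.na(D)] <- 0  # mean imputation after centering
  D <- sweep(D, 2, space$snp_sds, "/")
  scores <- D %*% space$loadings
  rownames(scores) <- cohort$samples$sample_id
  structure(scores, class = c("pc_coords", "matrix"),
            source_space = label %||% "unnamed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pc_coords <- function(x, ...) {
  cat(sprintf("pc_coords: %d samples x %d PCs (source: %s)\n",
              nrow(x), ncol(x), attr(x, "source_space")))
  invisible(x)
}

#' Serialize a PC space as a TSV pair
#'
#' Writes `<prefix>_loadings.tsv` (variant_id, a1, a2, PC1..PCK) and
#' `<prefix>_meta.tsv` (variant_id, snp_mean, snp_sd plus one `#eigenvalues`
#' header comment). [read_pc_space()] restores an equivalent `pc_space`
#' (panel sample ids are not preserved).
#'
#' @param space A `pc_space`.
#' @param prefix Output path prefix.
#' @export
write_pc_space <- function(space, prefix) {
  stopifnot(inherits(space, "pc_space"))
  lo <- data.frame(variant_id = space$variant_ids,
                   a1 = space$alleles$a1, a2 = space$alleles$a2,
                   space$loadings, check.names = FALSE)
  utils::write.table(lo, paste0(prefix, "_loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, "_meta.tsv"), "w")
  on.exit(close(con))
  writeLines(paste0("#eigenvalues\t",
                    paste(format(space$eigenvalues, digits = 15),
                          collapse = "\t")), con)
  utils::write.table(
    data.frame(variant_id = space$variant_ids,
               snp_mean = space$snp_means, snp_sd = space$snp_sds),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_pc_space
#' @export
read_pc_space <- function(prefix) {
  lo <- utils::read.table(paste0(prefix, "_loadings.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  first <- readLines(paste0(prefix, "_meta.tsv"), n = 1)
  ev <- as.numeric(strsplit(first, "\t")[[1]][-1])
  meta <- utils::read.table(paste0(prefix, "_meta.tsv"), header = TRUE,
                            sep = "\t", comment.char = "#")
  L <- as.matrix(lo[, -(1:3), drop = FALSE])
  rownames(L) <- lo$variant_id
  structure(list(
    loadings = L, eigenvalues = ev,
    snp_means = stats::setNames(meta$snp_mean, meta$variant_id),
    snp_sds = stats::setNames(meta$snp_sd, meta$variant_id),
    alleles = data.frame(variant_id = lo$variant_id, a1 = lo$a1, a2 = lo$a2,
                         stringsAsFactors = FALSE),
    variant_ids = lo$variant_id,
    panel_ids = character(0), removed_ids = character(0),
    K = ncol(L), n_iterations = NA_integer_
  ), class = "pc_space")
}

#' Write PC coordinates as TSV (sample_id, PC1..PCK)
#'
#' @param coords A `pc_coords` matrix.
#' @param path Output file path.
#' @export
write_pc_coords <- function(coords, path) {
  df <- data.frame(sample_id = rownames(coords), unclass(coords),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build every PC space and project every cohort onto each
#'
#' Convenience wrapper around [build_pc_space()] and [project_samples()]: one
#' space per panel, every cohort projected onto every space, plus a `none`
#' entry per cohort standing for the no-PC control. Panels sharing samples
#' with a projected cohort violate the independence requirement and raise an
#' error.
#'
#' @param cohorts Named list of `geno_matrix` cohorts.
#' @param panels Named list of `geno_matrix` reference panels.
#' @param K,... Passed to [build_pc_space()].
#' @return List with `spaces` (named `pc_space` list) and `coords`: per cohort
#'   a named list of `pc_coords` (one per panel) plus `none = NULL`.
#' @export
make_pc_sets <- function(cohorts, panels, K = 20, ...) {
  stopifnot(is.list(cohorts), is.list(panels))
  spaces <- lapply(names(panels), function(pn) {
    build_pc_space(panels[[pn]], K = K, ...)
  })
  names(spaces) <- names(panels)
  coords <- lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    per <- lapply(names(spaces), function(pn) {
      ov <- intersect(co$samples$sample_id, spaces[[pn]]$panel_ids)
      if (length(ov) > 0) {
        stop(sprintf("cohort '%s' shares %d sample(s) with panel '%s'",
                     cn, length(ov), pn))
      }
      project_samples(spaces[[pn]], co, label = pn)
    })
    names(per) <- names(spaces)
    c(per, list(none = NULL))
  })
  names(coords) <- names(cohorts)
  list(spaces = spaces, coords = coords)
}
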