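# Variant-level quality control and LD pruning.

#' Apply variant quality-control filters
#'
#' Filters are applied in a fixed order, and each removed variant is counted
#' once, at the first filter that removes it: (1) duplicated positions (same
#' chrom:pos; the first occurrence is kept), (2) indels (any allele longer
#' than one base), (3) palindromic SNPs (allele set A/T or C/G, strand-naive),
#' (4) missingness above `max_missing`, (5) minor allele frequency below
#' `min_maf` (computed from complete cases). The order of surviving variants
#' is preserved, and the operation is idempotent.
#'
#' @param geno A `geno_matrix`.
#' @param max_missing Maximum tolerated per-variant missing fraction.
#' @param min_maf Minimum minor allele frequency.
#' @return A list with `genotypes` (filtered `geno_matrix`) and `report`
#'   (class `qc_report`: per-filter removal counts, variants in/out).
#' @export
filter_variants <- function(geno, max_missing = 0.05, min_maf = 0.01) {
  stopifnot(inherits(geno, "geno_matrix"))
  v <- geno$variants
  m <- nrow(v)
  removed_by <- rep(NA_character_, m)

  key <- paste(v$chrom, v$pos, sep = ":")
  dup <- duplicated(key)
  removed_by[dup] <- "duplicate"

  indel <- nchar(v$a1) != 1L | nchar(v$a2) != 1L
  hit <- is.na(removed_by) & indel
  removed_by[hit] <- "indel"

  pair <- paste(pmin(v$a1, v$a2), pmax(v$a1, v$a2), sep = "/")
  palin <- pair %in% c("A/T", "C/G")
  hit <- is.na(removed_by) & palin & !indel
  removed_by[hit] <- "palindromic"

  miss <- colMeans(is.na(geno$dosage))
  hit <- is.na(removed_by) & miss > max_missing
  removed_by[hit] <- "missingness"

  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # fully missing variant
  hit <- is.na(removed_by) & maf < min_maf
  removed_by[hit] <- "maf"

  keep <- is.na(removed_by)
  filters <- c("duplicate", "indel", "palindromic", "missingness", "maf")
  counts <- stats::setNames(
    vapply(filters, function(f) sum(removed_by == f, na.rm = TRUE), 0L),
    filters)
  report <- structure(list(removed = counts, variants_in = m,
                           variants_out = sum(keep)), class = "qc_report")
  if (!any(keep)) warning("no variants survived quality control")
  list(genotypes = subset_geno(geno, variants = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Variant QC report\n")
  cat(sprintf("  in: %d   out: %d\n", x$variants_in, x$variants_out))
  for (f in names(x$removed)) {
    cat(sprintf("  removed (%s): %d\n", f, x$removed[[f]]))
  }
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(filter = c(names(x$removed), "variants_in", "variants_out"),
             count = c(unname(x$removed), x$variants_in, x$variants_out),
             stringsAsFactors = FALSE)
}

# Mean-imputed, column-standardised dosage matrix (sd with denominator n-1).
# Zero-variance columns come back as all-zero columns.
standardize_dosage <- function(D) {
  D <- as.matrix(D)
  storage.mode(D) <- "double"
  mu <- colMeans(D, na.rm = TRUE)
  if (anyNA(D)) {
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- mu[na_idx[, 2]]
  }
  D <- sweep(D, 2, mu, "-")
  sds <- sqrt(colSums(D^2) / max(1, nrow(D) - 1))
  nz <- sds > 0
  D[, nz] <- sweep(D[, nz, drop = FALSE], 2, sds[nz], "/")
  attr(D, "sds") <- sds
  D
}

#' Sliding-window greedy LD pruning
#'
#' Windows of `window` consecutive variants (per chromosome, in position
#' order) advance by `step`. Within each window, while any still-kept pair has
#' squared Pearson correlation above `r2_max`, the pair with the largest
#' r-squared is located (ties to the first found) and its later-positioned
#' member is dropped. Correlations are computed on mean-imputed standardised
#' dosages. Monomorphic variants are dropped before pruning.
#'
#' @param geno A `geno_matrix` (or plain dosage matrix).
#' @param window Window size in variants.
#' @param step Window increment in variants.
#' @param r2_max Maximum tolerated squared correlation.
#' @return Sorted integer vector of kept variant column indices.
#' @export
ld_prune <- function(geno, window = 50, step = 10, r2_max = 0.1) {
  D <- if (inherits(geno, "geno_matrix")) geno$dosage else geno
  if (ncol(D) < 2) return(seq_len(ncol(D)))
  chrom <- if (inherits(geno, "geno_matrix")) geno$variants$chrom
           else rep("1", ncol(D))
  X <- standardize_dosage(D)
  sds <- attr(X, "sds")
  mono <- sds == 0
  if (any(mono)) {
    message(sum(mono), " monomorphic variant(s) dropped before LD pruning")
  }
  keep <- !mono
  n1 <- nrow(X) - 1
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & keep)
    if (length(idx) < 2) next
    starts <- seq(1, length(idx), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1, length(idx))]
      active <- win[keep[win]]
      if (length(active) < 2) next
      R2 <- (crossprod(X[, active, drop = FALSE]) / n1)^2
      diag(R2) <- 0
      while (TRUE) {
        mx <- which.max(R2)
        if (R2[mx] <= r2_max) break
        ij <- arrayInd(mx, dim(R2))
        drop_local <- max(ij)  # later-positioned member of the pair
        keep[active[drop_local]] <- FALSE
        R2[drop_local, ] <- 0
        R2[, drop_local] <- 0
      }
    }
  }
  sort(unname(which(keep)))
}
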