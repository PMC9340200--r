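# Minimal PLINK .bed/.bim/.fam writer and reader (variant-major layout).

#' Write a genotype matrix as a PLINK fileset
#'
#' Variant-major `.bed` (magic bytes 0x6c 0x1b 0x01; two-bit codes 00 =
#' homozygous a1, 10 = heterozygous, 11 = homozygous a2, 01 = missing),
#' `.bim` (chrom, id, cM = 0, bp, a1, a2) and `.fam` (family = population,
#' id, 0, 0, 0, -9).
#'
#' @param geno A `geno_matrix`.
#' @param prefix Output path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "geno_matrix"))
  D <- geno$dosage
  n <- nrow(D)
  m <- ncol(D)
  ## per-genotype 2-bit codes, dosage of a1: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[!is.na(D) & D == 2L] <- 0L
  code[!is.na(D) & D == 1L] <- 2L
  code[is.na(D)] <- 1L
  bytes_per_var <- ceiling(n / 4)
  pad <- bytes_per_var * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  shifts <- c(1L, 4L, 16L, 64L)
  packed <- vapply(seq_len(bytes_per_var), function(b) {
    rows <- (b - 1) * 4 + 1:4
    colSums(code[rows, , drop = FALSE] * shifts)
  }, numeric(m))
  ## packed is m x bytes_per_var; write variant-major
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(t(packed)), con)
  close(con)

  bim <- data.frame(geno$variants$chrom, geno$variants$variant_id, 0,
                    geno$variants$pos, geno$variants$a1, geno$variants$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(geno$samples$population, geno$samples$sample_id,
                    0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK fileset into a genotype matrix
#'
#' @param prefix Path prefix of a `.bed`/`.bim`/`.fam` triple.
#' @return A `geno_matrix`.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chrom", "variant_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           col.names = c("population", "sample_id", "pid",
                                         "mid", "sex", "pheno"),
                           colClasses = c("character", "character", rep(NA, 4)))
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_var <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    close(con)
    stop("not a variant-major PLINK .bed file")
  }
  raw <- readBin(con, "raw", bytes_per_var * m)
  close(con)
  v <- as.integer(raw)
  ## unpack 2-bit codes, sample-fastest within each variant's byte block
  codes <- cbind(v %% 4, (v %/% 4) %% 4, (v %/% 16) %% 4, (v %/% 64) %% 4)
  dos_lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  D <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    block <- codes[((j - 1) * bytes_per_var + 1):(j * bytes_per_var), ,
                   drop = FALSE]
    cj <- as.integer(t(block))[seq_len(n)]
    D[, j] <- dos_lut[cj + 1]
  }
  dimnames(D) <- list(fam$sample_id, bim$variant_id)
  structure(list(
    dosage = D,
    variants = bim[, c("variant_id", "chrom", "pos", "a1", "a2")],
    samples = fam[, c("sample_id", "population")],
    freq = NULL
  ), class = "geno_matrix")
}

#' Write the phenotype/covariate table as TSV
#'
#' @param samples Covariate table.
#' @param traits Named list of trait vectors aligned to the samples.
#' @param path Output file path.
#' @export
write_pheno <- function(samples, traits, path) {
  df <- samples
  for (tn in names(traits)) df[[tn]] <- as.numeric(traits[[tn]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
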