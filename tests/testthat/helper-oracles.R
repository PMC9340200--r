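# Independent brute-force oracles for the greedy LD operations. These follow
# the operation definitions directly (full pairwise r2 matrices, explicit
# loops) and stay independent of the package's incremental implementations.

# Windowed greedy LD pruning over mean-imputed standardised dosages.
prune_oracle <- function(D, chrom, window, step, r2_max) {
  X <- scale(apply(D, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  }))
  keep <- apply(D, 2, function(col) sd(col, na.rm = TRUE) > 0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & keep)
    if (length(idx) < 2) next
    for (s in seq(1, length(idx), by = step)) {
      win <- idx[s:min(s + window - 1, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        best <- c(NA, NA, r2_max)
        for (a in seq_along(act)) {
          for (b in seq_along(act)) {
            if (b <= a) next
            r2 <- cor(X[, act[a]], X[, act[b]])^2
            if (r2 > best[3]) best <- c(a, b, r2)
          }
        }
        if (is.na(best[1])) break
        keep[act[max(best[1:2])]] <- FALSE
      }
    }
  }
  sort(unname(which(keep)))
}

# Greedy p-value-ordered clumping over the full pairwise r2 matrix.
clump_oracle <- function(st, g, r2_max = 0.05, p_max = 1, window_kb = 1000) {
  X <- scale(g$dosage)
  R2 <- cor(X)^2
  df <- as.data.frame(st)
  ord <- order(df$p, df$chrom, df$pos)
  claimed <- rep(FALSE, nrow(df))
  out <- character(0)
  for (i in ord) {
    if (claimed[i] || df$p[i] > p_max) next
    claimed[i] <- TRUE
    out <- c(out, df$variant_id[i])
    for (j in seq_len(nrow(df))) {
      if (!claimed[j] && df$chrom[j] == df$chrom[i] &&
          abs(df$pos[j] - df$pos[i]) <= window_kb * 1000 &&
          R2[i, j] > r2_max) claimed[j] <- TRUE
    }
  }
  out
}
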