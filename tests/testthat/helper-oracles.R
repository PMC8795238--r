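# Independent brute-force oracles used across test files. These re-derive
# expected results by direct definition, never through the package's own
# computational path.

# Four QC rules evaluated cell by cell on a dense matrix, straight from
# their definitions.
qc_oracle_keep <- function(dense, mito_hb, stddev_floor = 1,
                           zero_ceiling = 0.9, mito_ceiling = 0.1,
                           umi_floor = 100, umi_ceiling = 20000) {
  apply(seq_len(nrow(dense)) |> as.matrix(), 1, function(i) {
    x <- dense[i, ]
    total <- sum(x)
    r1 <- sd(x) < stddev_floor
    r2 <- mean(x == 0) >= zero_ceiling
    r3 <- (if (total > 0) sum(x[mito_hb]) / total else 0) >= mito_ceiling
    r4 <- total < umi_floor || total > umi_ceiling
    !(r1 || r2 || r3 || r4)
  })
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over the
# fixed margins (probability-mass criterion).
fisher_oracle_p <- function(tb) {
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, 0)
  p_obs <- probs[ks == tb[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties assumed).
wilcox_oracle_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(m)])
  combs <- utils::combn(n, m)
  w_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- m * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(r_obs - mu) - 1e-9)
}

# Adjusted Rand index between two labelings, from the contingency-table
# definition.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# AUROC by the rank-sum definition.
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
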