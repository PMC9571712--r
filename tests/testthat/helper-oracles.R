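# Independent oracles, deliberately written along different routes than
# the package implementations.

# brute-force MI: explicit double loop over the joint histogram
mi_bruteforce <- function(x, y, n_bins, base = 2) {
  ix <- fbcfuse:::discretize_series(x, n_bins)
  iy <- fbcfuse:::discretize_series(y, n_bins)
  n <- length(x)
  mi <- 0
  for (a in seq_len(n_bins)) {
    for (b in seq_len(n_bins)) {
      pxy <- sum(ix == a & iy == b) / n
      if (pxy == 0) next
      px <- sum(ix == a) / n
      py <- sum(iy == b) / n
      mi <- mi + pxy * log(pxy / (px * py), base)
    }
  }
  mi
}

# one-way F by explicit sum-of-squares decomposition
anova_oracle <- function(x, g) {
  g <- factor(g)
  grand <- mean(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    v <- x[g == lev]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- nlevels(g) - 1; df2 <- length(x) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# AUC as the Mann-Whitney pairwise-comparison statistic
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
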