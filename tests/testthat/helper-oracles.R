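# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-sided exact Wilcoxon rank-sum p by full enumeration of all
# choose(m+n, m) group assignments (no ties assumed).
wilcox_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  w_all <- apply(idx, 2, function(ii) sum(ranks[ii]) - m * (m + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Hypergeometric right-tail by direct summation over the 2x2 table.
hyper_right_tail <- function(n11, n12, n21, n22) {
  m <- n11 + n12          # row 1 total
  n <- n21 + n22          # row 2 total
  k <- n11 + n21          # column 1 total
  ks <- n11:min(m, k)
  sum(exp(lchoose(m, ks) + lchoose(n, k - ks) - lchoose(m + n, k)))
}

# Log multivariate-normal density via determinant()/solve(), independent of
# the package's Cholesky path.
dmvnorm_log <- function(y, mean, V) {
  n <- length(y)
  res <- y - mean
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + as.numeric(t(res) %*% solve(V) %*% res))
}

# Brute-force Jaccard distance between two logical vectors.
jaccard_brute <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 0 else 1 - sum(a & b) / u
}

# Chi-square distances between row profiles of the complete disjunctive
# coding of a Boolean matrix (the metric MCA coordinates must reproduce).
chi2_row_dists <- function(B) {
  Z <- cbind(B, 1 - B)
  P <- Z / sum(Z)
  r <- rowSums(P); cc <- colSums(P)
  prof <- P / r
  n <- nrow(B)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sqrt(sum((prof[i, ] - prof[j, ])^2 / cc))
  }
  d
}

# All 24 permutations of 1:4, one per row.
gtools_permutations4 <- function() {
  out <- NULL
  for (a in 1:4) for (b in setdiff(1:4, a)) for (c in setdiff(1:4, c(a, b)))
    out <- rbind(out, c(a, b, c, setdiff(1:4, c(a, b, c))))
  out
}

# Simple interval data frame constructor for fixtures.
iv <- function(start, end, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end, stringsAsFactors = FALSE)
}

# A constant-rate map: SNPs every `spacing` bp over [0, L].
const_map <- function(L = 2e5, spacing = 200, rho = 4e-3, pop = "p") {
  pos <- seq(0, L, by = spacing)
  rate_map("chr1", pos, rep(rho, length(pos) - 1), pop)
}
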