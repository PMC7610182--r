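# Independent oracles and small fixture builders used across the suite.

# generic weighted least squares through the origin (lm is the oracle,
# never the implementation)
wls_origin_oracle <- function(g, G, w) {
  unname(coef(lm(G ~ 0 + g, weights = w)))
}

# generic weighted least squares with intercept: c(intercept, slope)
wls_intercept_oracle <- function(g, G, w) {
  unname(coef(lm(G ~ g, weights = w)))
}

# exhaustive cumulative-weight scan for the weighted median: walk the
# sorted ratios accumulating normalised weight; the median sits where the
# mid-point mass passes one half, solved linearly between neighbours
weighted_median_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  acc <- 0
  prev_mid <- -Inf
  prev_r <- r[1]
  for (i in seq_along(r)) {
    mid <- acc + w[i] / 2       # mass strictly below the i-th ratio + half
    if (mid >= 0.5) {
      if (i == 1 || prev_mid == mid) return(r[i])
      frac <- (0.5 - prev_mid) / (mid - prev_mid)
      return(prev_r + frac * (r[i] - prev_r))
    }
    acc <- acc + w[i]
    prev_mid <- mid
    prev_r <- r[i]
  }
  r[length(r)]
}

# random harmonised dataset with heterogeneous precisions
rand_dataset <- function(J, seed, theta = 0.5) {
  set.seed(seed)
  g <- rnorm(J, 0.1, 0.05)
  sg <- runif(J, 0.005, 0.02)
  sG <- runif(J, 0.01, 0.05)
  G <- theta * g + rnorm(J, 0, sG)
  harmonisedDataset(g, sg, G, sG)
}

# minimal well-formed summary-stat data.frame
mk_stats <- function(snp, ea, oa, beta, se, pval, chrom = "1",
                     pos = seq_along(snp) * 1e6, eaf = 0.2,
                     n = 1e5) {
  data.frame(snp = snp, chrom = chrom, pos = pos, ea = ea, oa = oa,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}
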