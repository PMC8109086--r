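# Fixture builders and independent oracles used across test files.
# Oracles are deliberately written as straightforward loops/sums so they
# share no code path with the package implementations they check.

make_instruments <- function(beta_exp, beta_out, se_out,
                             se_exp = rep(1e-3, length(beta_exp)),
                             eaf = rep(0.3, length(beta_exp))) {
  n <- length(beta_exp)
  harmonized_instruments(tibble::tibble(
    rsid = paste0("rs", seq_len(n)),
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf,
    beta_out = beta_out, se_out = se_out, eaf_out = eaf,
    flipped = FALSE, palindromic = FALSE, frequency_aligned = FALSE))
}

make_variant <- function(rsid, ea, oa, beta, se = 0.01, eaf = 0.3,
                         chrom = "1", pos = 1000L, pval = 1e-9) {
  tibble::tibble(rsid = rsid, chrom = chrom, pos = as.integer(pos),
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se, pval = pval)
}

make_dataset <- function(...) summary_dataset(rbind(...))

# Closed-form zero-intercept WLS oracle for the IVW estimator: explicit
# sums, first-order ratio weights.
oracle_ivw <- function(beta_exp, beta_out, se_out) {
  r <- beta_out / beta_exp
  s <- se_out / abs(beta_exp)
  w <- 1 / s^2
  b <- sum(w * r) / sum(w)
  q <- sum(w * (r - b)^2)
  list(beta = b, se_fixed = 1 / sqrt(sum(w)), Q = q,
       se_mre = max(1, sqrt(q / (length(r) - 1))) / sqrt(sum(w)))
}

# Loop-based weighted-median oracle: sort, walk breakpoints p_j = S_j - w_j/2,
# interpolate at 0.5 by hand.
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- numeric(length(w))
  s <- 0
  for (j in seq_along(w)) {
    s <- s + w[j]
    p[j] <- s - w[j] / 2
  }
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  j <- max(which(p <= 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# Brute-force greedy clumping oracle on a full pairwise r2 matrix.
oracle_clump <- function(df, r2mat, r2_threshold, window_bp) {
  remaining <- df[order(df$pval, df$chrom, df$pos, df$rsid), , drop = FALSE]
  kept <- character()
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$rsid)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (k in seq_len(nrow(remaining))) {
      cand <- remaining[k, ]
      if (cand$chrom == idx$chrom && abs(cand$pos - idx$pos) <= window_bp) {
        r2 <- r2mat[idx$rsid, cand$rsid]
        drop[k] <- is.na(r2) || r2 >= r2_threshold
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# Harmonized instruments straight from a generated scenario (shared
# convenience for simulation-driven tests).
scenario_instruments <- function(...) {
  g <- generate_scenario(scenario_config(...))
  harmonize_datasets(g$exposure, g$outcome)$instruments
}
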