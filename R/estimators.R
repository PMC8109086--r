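# Causal-effect estimators on harmonized instruments: Wald ratios,
# multiplicative random-effects IVW, MR-Egger, simple/weighted median, RAPS,
# and heterogeneity statistics.
#
# Throughout, gamma (beta_exp) is the per-allele log-odds effect on the
# exposure and Gamma (beta_out) the per-allele log-odds effect on the
# outcome; the causal effect beta is the change in log-odds of the outcome
# per unit increase in log-odds of the exposure.

#' Assemble a causal-estimate row
#'
#' @param method Method label.
#' @param n_snps Number of instruments used.
#' @param beta,se Estimate and standard error on the log-odds-ratio scale.
#' @param pval Two-sided p-value.
#' @param ci_mult Half-width multiplier for the 95% CI (1.96 for the normal
#'   reference; a t quantile for MR-Egger).
#' @return One-row tibble: `method`, `n_snps`, `beta`, `se`, `pval`, `or`,
#'   `or_ci_low`, `or_ci_high`.
#' @export
mr_estimate <- function(method, n_snps, beta, se, pval,
                        ci_mult = stats::qnorm(0.975)) {
  tibble::tibble(method = method, n_snps = as.integer(n_snps),
                 beta = beta, se = se, pval = pval,
                 or = exp(beta),
                 or_ci_low = exp(beta - ci_mult * se),
                 or_ci_high = exp(beta + ci_mult * se))
}

#' Per-variant Wald ratio estimates
#'
#' For each instrument, the causal-effect estimate from that variant alone:
#' `ratio = beta_out / beta_exp`, with first-order standard error
#' `se = se_out / |beta_exp|` (exposure-side sampling error ignored, the
#' usual approximation for genome-wide-significant instruments).
#'
#' @param instruments A [harmonized_instruments()] table.
#' @return Tibble with `rsid`, `ratio`, `se`.
#' @export
wald_ratios <- function(instruments) {
  zero <- instruments$rsid[instruments$beta_exp == 0]
  if (length(zero) > 0) {
    mr_abort(paste0("zero exposure effect for: ",
                    paste(zero, collapse = ", ")),
             class = "mrsuite_validation_error")
  }
  tibble::tibble(rsid = instruments$rsid,
                 ratio = instruments$beta_out / instruments$beta_exp,
                 se = instruments$se_out / abs(instruments$beta_exp))
}

#' Cochran's Q heterogeneity of the ratio estimates
#'
#' `Q = sum w_j (r_j - b)^2` with inverse-variance weights
#' `w_j = 1/se_j^2` about the IVW mean `b`; p-value from the chi-square
#' upper tail on `n - 1` degrees of freedom; `I2 = max(0, (Q - df)/Q)`.
#'
#' @param instruments A [harmonized_instruments()] table with at least 2 rows.
#' @return One-row tibble: `Q`, `df`, `pval`, `i2`.
#' @export
heterogeneity <- function(instruments) {
  r <- wald_ratios(instruments)
  w <- 1 / r$se^2
  b <- sum(w * r$ratio) / sum(w)
  Q <- sum(w * (r$ratio - b)^2)
  df <- nrow(r) - 1L
  tibble::tibble(Q = Q, df = df,
                 pval = stats::pchisq(Q, df, lower.tail = FALSE),
                 i2 = if (Q > 0) max(0, (Q - df) / Q) else 0)
}

#' Multiplicative random-effects inverse-variance weighted estimator
#'
#' The IVW estimate is the inverse-variance weighted mean of the per-variant
#' Wald ratios with first-order weights `w_j = 1/se_ratio_j^2` (equivalent
#' to zero-intercept weighted regression of the outcome effects on the
#' exposure effects with weights `1/se_out^2`). The fixed-effect standard
#' error `(sum w_j)^{-1/2}` is inflated by the multiplicative
#' random-effects scale `max(1, sqrt(Q/(n-1)))`, so that between-variant
#' heterogeneity widens -- and can never narrow -- the interval. The
#' p-value uses the standard normal reference.
#'
#' @param instruments A [harmonized_instruments()] table with >= 2 rows.
#' @return List with `estimate` (an [mr_estimate()] row, method
#'   `"IVW (multiplicative random effects)"`) and `heterogeneity` (a
#'   [heterogeneity()] row).
#' @export
mr_ivw <- function(instruments) {
  n <- nrow(instruments)
  if (n < 2) {
    mr_abort("IVW requires at least 2 instruments",
             class = "mrsuite_validation_error")
  }
  r <- wald_ratios(instruments)
  w <- 1 / r$se^2
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  het <- heterogeneity(instruments)
  scale <- max(1, sqrt(het$Q / (n - 1)))
  se <- se_fixed * scale
  pval <- 2 * stats::pnorm(-abs(beta / se))
  est <- mr_estimate("IVW (multiplicative random effects)", n, beta, se, pval)
  est$se_fixed <- se_fixed
  list(estimate = est, heterogeneity = het)
}

#' Internal fixed-effect IVW slope (zero-intercept WLS, weights 1/se_out^2)
#' @noRd
ivw_beta <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(w * bx * by) / sum(w * bx^2)
}

#' MR-Egger regression with intercept test
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1/se_out^2`, after orienting every
#' instrument so its exposure effect is positive (Egger regression is not
#' invariant to allele orientation; the convention is the
#' exposure-increasing allele). The slope estimates the causal effect under
#' the weaker InSIDE assumption; a nonzero intercept indicates directional
#' pleiotropy. Both standard errors are inflated by the residual
#' overdispersion scale `max(1, sqrt(RSS_w/(n-2)))`; p-values and 95% CIs
#' use the t distribution with `n - 2` degrees of freedom.
#'
#' @param instruments A [harmonized_instruments()] table with >= 3 rows.
#' @return List of class `mr_egger_result`: `estimate` (slope as an
#'   [mr_estimate()] row, method `"MR-Egger"`) and `intercept` (one-row
#'   tibble: `value`, `se`, `ci_low`, `ci_high`, `pval`, `df`).
#' @export
mr_egger <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3) {
    mr_abort("MR-Egger requires at least 3 instruments",
             class = "mrsuite_validation_error")
  }
  sgn <- ifelse(instruments$beta_exp < 0, -1, 1)
  bx <- sgn * instruments$beta_exp
  by <- sgn * instruments$beta_out
  w <- 1 / instruments$se_out^2
  fit <- stats::lm.wfit(x = cbind(intercept = 1, slope = bx), y = by, w = w)
  coefs <- fit$coefficients
  rss_w <- sum(w * fit$residuals^2)
  scale <- max(1, sqrt(rss_w / (n - 2)))
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
  se_unscaled <- sqrt(diag(xtx_inv))
  se <- se_unscaled * scale
  df <- n - 2
  tq <- stats::qt(0.975, df)
  pvals <- 2 * stats::pt(-abs(coefs / se), df)
  est <- mr_estimate("MR-Egger", n, coefs[["slope"]], se[[2]],
                     pvals[[2]], ci_mult = tq)
  intercept <- tibble::tibble(value = coefs[["intercept"]], se = se[[1]],
                              ci_low = coefs[["intercept"]] - tq * se[[1]],
                              ci_high = coefs[["intercept"]] + tq * se[[1]],
                              pval = pvals[[1]], df = df)
  structure(list(estimate = est, intercept = intercept),
            class = "mr_egger_result")
}

#' Weighted median by breakpoint interpolation
#'
#' With weights normalized to sum 1 and ratios sorted ascending, the
#' cumulative weight `S_j` defines breakpoints `p_j = S_j - w_j/2`; the
#' weighted median linearly interpolates the ratio at `p = 0.5`. Under
#' equal weights this reduces to the ordinary sample median.
#'
#' @param x Numeric values.
#' @param w Positive weights (any scale; normalized internally).
#' @return The weighted median.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Simple and weighted median causal estimators
#'
#' The simple median is the unweighted median of the per-variant Wald
#' ratios; the weighted median uses normalized inverse-variance weights
#' `se_ratio^{-2}` with breakpoint interpolation ([weighted_median()]).
#' The median estimators remain consistent when up to half of the
#' instruments (by count for the simple median, by weight for the weighted
#' median) are invalid. The standard error comes from a parametric
#' bootstrap: each replicate redraws every `beta_exp` and `beta_out` from
#' normal distributions centred at the observed values with the observed
#' standard errors, recomputes the median estimator, and the SE is the
#' standard deviation across replicates.
#'
#' @param instruments A [harmonized_instruments()] table with >= 3 rows.
#' @param kind `"weighted"` (default) or `"simple"`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return An [mr_estimate()] row (method `"Simple median"` or
#'   `"Weighted median"`).
#' @export
mr_median <- function(instruments, kind = c("weighted", "simple"),
                      n_boot = 1000, seed = NULL) {
  kind <- match.arg(kind)
  n <- nrow(instruments)
  if (n < 3) {
    mr_abort("median estimators require at least 3 instruments",
             class = "mrsuite_validation_error")
  }
  point_fun <- function(bx, by, sy) {
    r <- by / bx
    if (kind == "simple") stats::median(r)
    else weighted_median(r, abs(bx)^2 / sy^2)  # w = 1/se_ratio^2
  }
  beta <- point_fun(instruments$beta_exp, instruments$beta_out,
                    instruments$se_out)
  boots <- with_seed(seed, {
    bx_mat <- matrix(stats::rnorm(n * n_boot, instruments$beta_exp,
                                  instruments$se_exp), nrow = n)
    by_mat <- matrix(stats::rnorm(n * n_boot, instruments$beta_out,
                                  instruments$se_out), nrow = n)
    vapply(seq_len(n_boot), function(b) {
      point_fun(bx_mat[, b], by_mat[, b], instruments$se_out)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate(if (kind == "simple") "Simple median" else "Weighted median",
              n, beta, se, pval)
}
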