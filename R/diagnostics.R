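# Sensitivity diagnostics: leave-one-out analysis, funnel/scatter exports
# and binary-outcome power calculation.

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the multiplicative random-effects IVW estimate with each
#' instrument omitted in turn, plus the all-instrument estimate, to expose
#' single variants that drive the pooled result. An omission is flagged
#' `influential` when it moves the estimate by more than one fixed-effect
#' standard error of the full analysis.
#'
#' @param instruments A [harmonized_instruments()] table with >= 3 rows.
#' @return Tibble with `n_snps + 1` rows: column `omitted` (`rsid`, or
#'   `"(none)"` for the full set), the [mr_estimate()] columns, and
#'   `influential`.
#' @export
leave_one_out <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3) {
    mr_abort("leave-one-out requires at least 3 instruments",
             class = "mrsuite_validation_error")
  }
  full <- mr_ivw(instruments)
  rows <- lapply(seq_len(n), function(j) {
    est <- mr_ivw(instruments[-j, , drop = FALSE])$estimate
    est$omitted <- instruments$rsid[j]
    est
  })
  all_row <- full$estimate
  all_row$omitted <- "(none)"
  out <- do.call(rbind, c(rows, list(all_row)))
  out$influential <- abs(out$beta - full$estimate$beta) >
    full$estimate$se_fixed
  out[c("omitted", setdiff(names(out), "omitted"))]
}

#' Funnel-plot data
#'
#' Per-variant Wald ratio estimates against their precision (1/se), the
#' standard asymmetry diagnostic: under balanced pleiotropy the points
#' scatter symmetrically about the pooled estimate.
#'
#' @param instruments A [harmonized_instruments()] table.
#' @return List with `points` (tibble `rsid`, `ratio`, `precision`),
#'   `ivw_beta` and `egger_beta` (reference verticals; `egger_beta` is `NA`
#'   with fewer than 3 instruments).
#' @export
funnel_data <- function(instruments) {
  r <- wald_ratios(instruments)
  list(points = tibble::tibble(rsid = r$rsid, ratio = r$ratio,
                               precision = 1 / r$se),
       ivw_beta = if (nrow(instruments) >= 2) {
         mr_ivw(instruments)$estimate$beta
       } else NA_real_,
       egger_beta = if (nrow(instruments) >= 3) {
         mr_egger(instruments)$estimate$beta
       } else NA_real_)
}

#' Scatter-plot data
#'
#' Outcome effects against exposure effects with error bars, plus fitted
#' lines for the IVW (through the origin) and MR-Egger (free intercept)
#' fits. Points are oriented to a positive exposure effect, the
#' orientation under which the Egger intercept is defined.
#'
#' @param instruments A [harmonized_instruments()] table with >= 3 rows.
#' @return List with `points` (tibble `rsid`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`) and `lines` (tibble `method`, `intercept`,
#'   `slope`).
#' @export
scatter_data <- function(instruments) {
  sgn <- ifelse(instruments$beta_exp < 0, -1, 1)
  egger <- mr_egger(instruments)
  lines <- tibble::tibble(
    method = c("IVW (multiplicative random effects)", "MR-Egger"),
    intercept = c(0, egger$intercept$value),
    slope = c(mr_ivw(instruments)$estimate$beta, egger$estimate$beta))
  list(points = tibble::tibble(rsid = instruments$rsid,
                               beta_exp = sgn * instruments$beta_exp,
                               se_exp = instruments$se_exp,
                               beta_out = sgn * instruments$beta_out,
                               se_out = instruments$se_out),
       lines = lines)
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Non-centrality-parameter approximation: with outcome-study sample size
#' `n_sample`, instrument strength `r2_xz` (variance in exposure liability
#' explained by the instrument), case fraction `k_cases` and true odds
#' ratio `or_alt` per unit exposure,
#' `NCP = n_sample * r2_xz * log(or_alt)^2 * k_cases * (1 - k_cases)` and
#' `power = Phi(sqrt(NCP) - z_(1 - alpha/2))` for a two-sided test at
#' level `alpha`.
#'
#' @param n_sample Total sample size (cases + controls).
#' @param r2_xz Variance explained by the instrument, in \[0, 1\].
#' @param k_cases Case fraction, in (0, 1).
#' @param or_alt Odds ratio under the alternative (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1). `r2_xz = 0` (or `or_alt = 1`) leaves only the
#'   null rejection mass `Phi(-z_(1-alpha/2))`; this degenerate case is
#'   flagged with a warning.
#' @export
mr_power_binary <- function(n_sample, r2_xz, k_cases, or_alt, alpha = 0.05) {
  stopifnot(n_sample > 0, r2_xz >= 0, r2_xz <= 1,
            k_cases > 0, k_cases < 1, or_alt > 0, alpha > 0, alpha < 1)
  ncp <- n_sample * r2_xz * log(or_alt)^2 * k_cases * (1 - k_cases)
  if (ncp == 0) {
    warning("zero non-centrality (r2_xz = 0 or OR = 1): power is the ",
            "one-tail null rejection rate alpha/2")
  }
  stats::pnorm(sqrt(ncp) - stats::qnorm(1 - alpha / 2))
}

#' Smallest detectable odds ratio at a given power
#'
#' Inverts [mr_power_binary()] for the odds ratio: returns the OR > 1 whose
#' detection power equals `power` at the given design.
#'
#' @inheritParams mr_power_binary
#' @param power Target power, in (alpha/2, 1).
#' @return Odds ratio > 1.
#' @export
mr_detectable_or <- function(n_sample, r2_xz, k_cases, power = 0.80,
                             alpha = 0.05) {
  stopifnot(n_sample > 0, r2_xz > 0, r2_xz <= 1,
            k_cases > 0, k_cases < 1, alpha > 0, alpha < 1,
            power > alpha / 2, power < 1)
  log_or <- (stats::qnorm(power) + stats::qnorm(1 - alpha / 2)) /
    sqrt(n_sample * r2_xz * k_cases * (1 - k_cases))
  exp(log_or)
}
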