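# Synthetic two-sample GWAS summary-statistic generator.
#
# Generative model (per variant j):
#   gamma_j  ~ N(0, gamma_scale^2)          true exposure effect (log-odds)
#   alpha_j  per pleiotropy model            direct (pleiotropic) effect
#   Gamma_j  = true_beta * gamma_j + alpha_j true outcome effect
# Observed effects add sampling noise with SE = 1/sqrt(2 n eaf (1-eaf))
# for the respective study (case-control scaling optional); the two studies
# are drawn independently (two-sample design, no overlap).  LD blocks emit
# correlated tag SNPs of block-index variants; a configurable fraction of
# variants is palindromic, and the outcome dataset re-expresses variants
# with swapped allele labels and strand flips so harmonization is exercised
# against known truth.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a realistic large two-sample setting for an
#' immune-mediated disease exposure and a cardiac outcome: 112 instrument
#' candidates, exposure study of 76,312 and outcome study of 1,030,836
#' individuals, per-variant true exposure effects with SD 0.1 on the
#' log-odds scale, and a null causal effect.
#'
#' @param n_snps Number of index variants (default 112).
#' @param true_beta Causal effect, log-odds of outcome per log-odds of
#'   exposure (default 0).
#' @param exposure_n,outcome_n Study sample sizes (defaults 76312 and
#'   1030836).
#' @param eaf_range Range of true effect-allele frequencies (default
#'   c(0.05, 0.95)).
#' @param gamma_scale SD of true exposure effects (default 0.1).
#' @param gamma_sign `"symmetric"` (default) leaves effect signs random;
#'   `"positive"` orients every true exposure effect to the
#'   exposure-increasing allele, the convention under which directional
#'   pleiotropy has a defined sign.
#' @param pleiotropy One of `"none"` (default), `"balanced"` (mean-zero
#'   direct effects), `"directional"` (nonzero-mean direct effects) or
#'   `"outliers"` (a few variants with large direct effects).
#' @param alpha_mean Mean direct effect under `"directional"`
#'   (default 0.002).
#' @param alpha_sd SD of direct effects under `"balanced"`/`"directional"`
#'   (default 0.002 and 0.001 respectively; pass explicitly to override).
#' @param outlier_count,outlier_size Under `"outliers"`: number of outlying
#'   variants (default 1) and direct-effect size in multiples of the
#'   variant's outcome SE (default 10).
#' @param inside_violation Correlation between direct effects and true
#'   exposure effects, in \[-1, 1\] (default 0 = InSIDE holds).
#' @param ld_blocks `NULL` (default, all variants independent) or
#'   `list(n_blocks, snps_per_block, r2)`: the first `n_blocks` index
#'   variants each gain `snps_per_block - 1` tag SNPs within 10 kb at
#'   pairwise r-squared `r2`.
#' @param palindrome_fraction Fraction of variants with A/T or C/G alleles
#'   (default 0.16, about what uniform allele-pair usage produces in real
#'   GWAS).
#' @param label_swap_fraction Fraction of outcome records expressed with
#'   effect/other alleles exchanged (default 0.5).
#' @param strand_flip_fraction Fraction of non-palindromic outcome records
#'   expressed on the opposite strand (default 0.2).
#' @param se_model `"quantitative"` (default; SE = 1/sqrt(2 n eaf(1-eaf)))
#'   or `"case_control"` (adds the case-fraction factor K(1-K)).
#' @param case_fraction_exp,case_fraction_out Case fractions used by the
#'   case-control SE model (defaults 38565/76312 and 60620/1030836).
#' @param seed RNG seed (required).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_snps = 112, true_beta = 0,
                            exposure_n = 76312, outcome_n = 1030836,
                            eaf_range = c(0.05, 0.95), gamma_scale = 0.1,
                            gamma_sign = c("symmetric", "positive"),
                            pleiotropy = c("none", "balanced", "directional",
                                           "outliers"),
                            alpha_mean = 0.002, alpha_sd = NULL,
                            outlier_count = 1, outlier_size = 10,
                            inside_violation = 0, ld_blocks = NULL,
                            palindrome_fraction = 0.16,
                            label_swap_fraction = 0.5,
                            strand_flip_fraction = 0.2,
                            se_model = c("quantitative", "case_control"),
                            case_fraction_exp = 38565 / 76312,
                            case_fraction_out = 60620 / 1030836,
                            seed) {
  pleiotropy <- match.arg(pleiotropy)
  gamma_sign <- match.arg(gamma_sign)
  se_model <- match.arg(se_model)
  if (is.null(alpha_sd)) {
    alpha_sd <- if (pleiotropy == "balanced") 0.002 else 0.001
  }
  stopifnot(n_snps >= 1, exposure_n > 0, outcome_n > 0,
            gamma_scale > 0, alpha_sd >= 0,
            abs(inside_violation) <= 1,
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2])
  if (missing(seed)) mr_abort("a seed is required",
                              class = "mrsuite_config_error")
  if (!is.null(ld_blocks)) {
    stopifnot(all(c("n_blocks", "snps_per_block", "r2") %in%
                    names(ld_blocks)),
              ld_blocks$n_blocks <= n_snps,
              ld_blocks$r2 >= 0, ld_blocks$r2 <= 1)
  }
  structure(list(n_snps = n_snps, true_beta = true_beta,
                 exposure_n = exposure_n, outcome_n = outcome_n,
                 eaf_range = eaf_range, gamma_scale = gamma_scale,
                 gamma_sign = gamma_sign, pleiotropy = pleiotropy,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 outlier_count = outlier_count, outlier_size = outlier_size,
                 inside_violation = inside_violation, ld_blocks = ld_blocks,
                 palindrome_fraction = palindrome_fraction,
                 label_swap_fraction = label_swap_fraction,
                 strand_flip_fraction = strand_flip_fraction,
                 se_model = se_model,
                 case_fraction_exp = case_fraction_exp,
                 case_fraction_out = case_fraction_out,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                 "G", "A", "G", "T", "T", "C", "T", "G"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Generate a synthetic two-sample GWAS scenario
#'
#' Draws exposure and outcome summary datasets, the pairwise LD source for
#' the planted LD blocks, and a truth record holding every latent quantity
#' (true effects, direct effects, block membership, palindromic status and
#' how each outcome record was re-expressed), so that selection,
#' harmonization and estimation can be verified against known truth.
#'
#' @param config A [scenario_config()].
#' @return List with `exposure` and `outcome` ([summary_dataset()]s), `ld`
#'   (an [ld_source()]), `truth` (tibble) and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(cfg$seed, {
    m <- cfg$n_snps
    blocks <- cfg$ld_blocks
    n_blocks <- if (is.null(blocks)) 0L else blocks$n_blocks
    spb <- if (is.null(blocks)) 1L else blocks$snps_per_block
    n_tags_per <- max(spb - 1L, 0L)

    # index variants spread across autosomes, 1 Mb apart within a chromosome
    chrom_idx <- rep(as.character(1:22), length.out = m)
    pos_idx <- 1000000L * (as.integer(seq_len(m) / 22) + 1L) +
      100000L * (seq_len(m) %% 22)
    block_id <- c(seq_len(m),
                  rep(seq_len(n_blocks), each = n_tags_per))
    is_tag <- c(rep(FALSE, m), rep(TRUE, n_blocks * n_tags_per))
    tag_rank <- c(rep(0L, m),
                  rep(seq_len(n_tags_per), times = n_blocks))
    N <- length(block_id)
    rsid <- paste0("rs", 1000000L + seq_len(N))
    chrom <- chrom_idx[block_id]
    pos <- as.integer(pos_idx[block_id] + tag_rank * 1000L)

    eaf_idx <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
    eaf <- eaf_idx[block_id]

    pal <- stats::runif(N) < cfg$palindrome_fraction
    a1 <- character(N); a2 <- character(N)
    pal_row <- sample.int(nrow(PALINDROMIC_PAIRS), sum(pal), replace = TRUE)
    a1[pal] <- PALINDROMIC_PAIRS[pal_row, 1]
    a2[pal] <- PALINDROMIC_PAIRS[pal_row, 2]
    np_row <- sample.int(nrow(NONPALINDROMIC_PAIRS), sum(!pal),
                         replace = TRUE)
    a1[!pal] <- NONPALINDROMIC_PAIRS[np_row, 1]
    a2[!pal] <- NONPALINDROMIC_PAIRS[np_row, 2]

    gamma_idx <- stats::rnorm(m, 0, cfg$gamma_scale)
    if (cfg$gamma_sign == "positive") gamma_idx <- abs(gamma_idx)
    r_attn <- ifelse(is_tag, sqrt(if (is.null(blocks)) 0 else blocks$r2), 1)
    gamma <- gamma_idx[block_id] * r_attn

    se_factor_exp <- if (cfg$se_model == "case_control") {
      cfg$case_fraction_exp * (1 - cfg$case_fraction_exp)
    } else 1
    se_factor_out <- if (cfg$se_model == "case_control") {
      cfg$case_fraction_out * (1 - cfg$case_fraction_out)
    } else 1
    se_exp <- 1 / sqrt(2 * cfg$exposure_n * se_factor_exp * eaf * (1 - eaf))
    se_out <- 1 / sqrt(2 * cfg$outcome_n * se_factor_out * eaf * (1 - eaf))

    rho <- cfg$inside_violation
    is_outlier <- rep(FALSE, N)
    alpha <- switch(cfg$pleiotropy,
      none = rep(0, N),
      balanced = ,
      directional = {
        mu <- if (cfg$pleiotropy == "balanced") 0 else cfg$alpha_mean
        mu + rho * (cfg$alpha_sd / cfg$gamma_scale) * gamma +
          sqrt(1 - rho^2) * stats::rnorm(N, 0, cfg$alpha_sd)
      },
      outliers = {
        a <- rep(0, N)
        k <- min(cfg$outlier_count, N)
        idx <- sample.int(N, k)
        is_outlier[idx] <- TRUE
        a[idx] <- cfg$outlier_size * se_out[idx] *
          sample(c(-1, 1), k, replace = TRUE)
        a
      })
    Gamma <- cfg$true_beta * gamma + alpha

    beta_exp <- stats::rnorm(N, gamma, se_exp)
    beta_out <- stats::rnorm(N, Gamma, se_out)
    eaf_exp <- pmin(pmax(
      stats::rnorm(N, eaf, sqrt(eaf * (1 - eaf) / (2 * cfg$exposure_n))),
      0.001), 0.999)
    eaf_out <- pmin(pmax(
      stats::rnorm(N, eaf, sqrt(eaf * (1 - eaf) / (2 * cfg$outcome_n))),
      0.001), 0.999)
    p_exp <- 2 * stats::pnorm(-abs(beta_exp / se_exp))
    p_out <- 2 * stats::pnorm(-abs(beta_out / se_out))

    exposure <- summary_dataset(tibble::tibble(
      rsid = rsid, chrom = chrom, pos = pos,
      effect_allele = a1, other_allele = a2,
      eaf = eaf_exp, beta = beta_exp, se = se_exp,
      pval = pmax(p_exp, .Machine$double.xmin)),
      trait = "simulated exposure", ancestry = "simulated",
      n_cases = NA_integer_, n_controls = NA_integer_)
    attr(exposure, "n_total") <- cfg$exposure_n

    # outcome re-expression: swapped allele labels and/or opposite strand
    swap <- stats::runif(N) < cfg$label_swap_fraction
    flip <- !pal & stats::runif(N) < cfg$strand_flip_fraction
    o_a1 <- ifelse(swap, a2, a1)
    o_a2 <- ifelse(swap, a1, a2)
    o_a1 <- ifelse(flip, complement_allele(o_a1), o_a1)
    o_a2 <- ifelse(flip, complement_allele(o_a2), o_a2)
    o_beta <- ifelse(swap, -beta_out, beta_out)
    o_eaf <- ifelse(swap, 1 - eaf_out, eaf_out)

    outcome <- summary_dataset(tibble::tibble(
      rsid = rsid, chrom = chrom, pos = pos,
      effect_allele = o_a1, other_allele = o_a2,
      eaf = o_eaf, beta = o_beta, se = se_out,
      pval = pmax(p_out, .Machine$double.xmin)),
      trait = "simulated outcome", ancestry = "simulated",
      n_cases = NA_integer_, n_controls = NA_integer_)
    attr(outcome, "n_total") <- cfg$outcome_n

    ld_pairs <- if (n_blocks > 0 && spb > 1) {
      do.call(rbind, lapply(seq_len(n_blocks), function(b) {
        members <- rsid[block_id == b]
        cmb <- utils::combn(members, 2)
        data.frame(rsid_a = cmb[1, ], rsid_b = cmb[2, ], r2 = blocks$r2)
      }))
    } else {
      data.frame(rsid_a = character(), rsid_b = character(), r2 = numeric())
    }

    truth <- tibble::tibble(rsid = rsid, chrom = chrom, pos = pos,
                            block = block_id, is_tag = is_tag,
                            eaf = eaf, gamma = gamma, alpha = alpha,
                            Gamma = Gamma, is_palindromic = pal,
                            out_label_swapped = swap,
                            out_strand_flipped = flip,
                            is_outlier = is_outlier)
    list(exposure = exposure, outcome = outcome, ld = ld_source(ld_pairs),
         truth = truth, config = cfg)
  })
}

CONFOUNDER_TRAITS <- c("body mass index", "fat-free mass", "heart rate",
                       "systolic blood pressure", "coronary artery disease",
                       "type 2 diabetes", "chronic kidney disease")

#' Build a synthetic SNP-to-trait catalog
#'
#' Assigns a named confounder trait, at genome-wide significance, to a
#' configured fraction of the dataset's variants -- a local stand-in for an
#' online SNP-trait lookup -- so that confounder-trait exclusion can be
#' verified exactly against the recorded assignment.
#'
#' @param dataset A `summary_dataset`.
#' @param confounder_fraction Fraction of variants to flag, in \[0, 1\].
#' @param seed RNG seed.
#' @return A [trait_catalog()] whose `excluded_traits` are the confounder
#'   trait names; the flagged rsids are attached as attribute
#'   `"confounder_rsids"`.
#' @export
make_trait_catalog <- function(dataset, confounder_fraction, seed) {
  stopifnot(confounder_fraction >= 0, confounder_fraction <= 1)
  n <- nrow(dataset)
  k <- round(confounder_fraction * n)
  with_seed(seed, {
    idx <- if (k > 0) sample.int(n, k) else integer()
    cat <- trait_catalog(
      data.frame(rsid = dataset$rsid[idx],
                 trait = rep_len(CONFOUNDER_TRAITS, k),
                 pval = 10^-stats::runif(k, 8.2, 15)),
      excluded_traits = CONFOUNDER_TRAITS)
    attr(cat, "confounder_rsids") <- dataset$rsid[idx]
    cat
  })
}
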