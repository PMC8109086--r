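# Allele harmonization: express exposure and outcome effects on a common
# effect allele, resolving label swaps, strand flips and palindromic SNPs.

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome association to the exposure's effect allele:
#'
#' * identical alleles: copied through;
#' * swapped labels (effect and other allele exchanged): outcome beta is
#'   negated and its frequency reflected (`eaf := 1 - eaf`), flag `flipped`;
#' * strand complement (or complement plus swap) for non-palindromic SNPs:
#'   the outcome alleles are complemented (A<->T, C<->G) and the two rules
#'   above applied;
#' * palindromic SNPs (A/T or C/G) carry no strand information in their
#'   alleles, so orientation is resolved by allele frequency: when the
#'   exposure minor-allele frequency is below `maf_threshold` the outcome
#'   effect is oriented so both frequencies fall on the same side of 0.5
#'   (flags `palindromic`, `frequency_aligned`); at or above the threshold
#'   the frequencies are uninformative and the pair is dropped
#'   (`"ambiguous palindrome"`);
#' * irreconcilable alleles are dropped (`"allele mismatch"`).
#'
#' The exposure effect and SE are never modified.
#'
#' @param exp,out Single-row variant records (as in a `summary_dataset`)
#'   for the same rsid.
#' @param maf_threshold Exposure minor-allele-frequency bound below which a
#'   palindromic SNP is considered frequency-resolvable (default 0.3).
#' @param palindrome_action `"align"` (default) frequency-aligns resolvable
#'   palindromes; `"drop"` discards every palindromic SNP.
#' @return List with either `instrument` (one-row [harmonized_instruments()]
#'   tibble) and `reason = NA`, or `instrument = NULL` and a drop `reason`.
#' @export
harmonize_pair <- function(exp, out, maf_threshold = 0.3,
                           palindrome_action = c("align", "drop")) {
  palindrome_action <- match.arg(palindrome_action)
  if (exp$rsid != out$rsid) {
    mr_abort(paste0("rsid mismatch: ", exp$rsid, " vs ", out$rsid),
             class = "mrsuite_usage_error")
  }
  dropped <- function(reason) list(instrument = NULL, reason = reason)
  kept <- function(beta_out, eaf_out, flipped, palindromic, freq_aligned) {
    list(instrument = harmonized_instruments(tibble::tibble(
      rsid = exp$rsid,
      beta_exp = exp$beta, se_exp = exp$se, eaf_exp = exp$eaf,
      beta_out = beta_out, se_out = out$se, eaf_out = eaf_out,
      flipped = flipped, palindromic = palindromic,
      frequency_aligned = freq_aligned)),
      reason = NA_character_)
  }
  ea <- exp$effect_allele; oa <- exp$other_allele
  if (is_palindromic_pair(ea, oa)) {
    # complement equals swap for palindromes: only the allele *set* can match
    if (!setequal(c(out$effect_allele, out$other_allele), c(ea, oa))) {
      return(dropped("allele mismatch"))
    }
    if (palindrome_action == "drop") return(dropped("palindromic SNP"))
    if (is.na(exp$eaf) || is.na(out$eaf)) {
      return(dropped("palindrome without EAF"))
    }
    if (min(exp$eaf, 1 - exp$eaf) >= maf_threshold) {
      return(dropped("ambiguous palindrome"))
    }
    # nominal label orientation first, then align frequencies across 0.5
    beta_out <- out$beta; eaf_out <- out$eaf
    if (out$effect_allele != ea) {
      beta_out <- -beta_out; eaf_out <- 1 - eaf_out
    }
    if ((exp$eaf - 0.5) * (eaf_out - 0.5) < 0) {
      beta_out <- -beta_out; eaf_out <- 1 - eaf_out
    }
    return(kept(beta_out, eaf_out, flipped = FALSE, palindromic = TRUE,
                freq_aligned = TRUE))
  }
  oea <- out$effect_allele; ooa <- out$other_allele
  if (!(oea == ea && ooa == oa) && !(oea == oa && ooa == ea)) {
    oea <- complement_allele(oea); ooa <- complement_allele(ooa)
  }
  if (oea == ea && ooa == oa) {
    kept(out$beta, out$eaf, flipped = FALSE, palindromic = FALSE,
         freq_aligned = FALSE)
  } else if (oea == oa && ooa == ea) {
    kept(-out$beta, if (is.na(out$eaf)) NA_real_ else 1 - out$eaf,
         flipped = TRUE, palindromic = FALSE, freq_aligned = FALSE)
  } else {
    dropped("allele mismatch")
  }
}

#' Harmonize two GWAS summary datasets
#'
#' Intersects the exposure and outcome datasets on rsid and harmonizes each
#' shared pair with [harmonize_pair()]. Every exposure record absent from
#' the returned instruments is accounted for in the drop log (reason
#' `"not in outcome"`, `"ambiguous palindrome"`, `"allele mismatch"`, ...).
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @inheritParams harmonize_pair
#' @return List with `instruments` (a [harmonized_instruments()] tibble,
#'   ordered as the exposure dataset) and `drops`, a tibble of
#'   `(rsid, reason)`.
#' @export
harmonize_datasets <- function(exposure, outcome, maf_threshold = 0.3,
                               palindrome_action = c("align", "drop")) {
  palindrome_action <- match.arg(palindrome_action)
  out_idx <- match(exposure$rsid, outcome$rsid)
  kept <- vector("list", nrow(exposure))
  drop_rsid <- character(); drop_reason <- character()
  for (i in seq_len(nrow(exposure))) {
    if (is.na(out_idx[i])) {
      drop_rsid <- c(drop_rsid, exposure$rsid[i])
      drop_reason <- c(drop_reason, "not in outcome")
      next
    }
    h <- harmonize_pair(exposure[i, ], outcome[out_idx[i], ],
                        maf_threshold = maf_threshold,
                        palindrome_action = palindrome_action)
    if (is.null(h$instrument)) {
      drop_rsid <- c(drop_rsid, exposure$rsid[i])
      drop_reason <- c(drop_reason, h$reason)
    } else {
      kept[[i]] <- h$instrument
    }
  }
  kept <- kept[!vapply(kept, is.null, logical(1))]
  instruments <- if (length(kept) > 0) {
    harmonized_instruments(do.call(rbind, kept))
  } else {
    harmonized_instruments(tibble::tibble(
      rsid = character(), beta_exp = numeric(), se_exp = numeric(),
      eaf_exp = numeric(), beta_out = numeric(), se_out = numeric(),
      eaf_out = numeric(), flipped = logical(), palindromic = logical(),
      frequency_aligned = logical()))
  }
  list(instruments = instruments,
       drops = tibble::tibble(rsid = drop_rsid, reason = drop_reason))
}
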