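# Reading, validating and writing GWAS summary-statistic tables and the
# harmonized-instrument table.

#' Default column mapping for GWAS summary-statistic files
#'
#' Maps the fields mrsuite needs to the most common GWAS summary header names
#' (PLINK-style `SNP/CHR/BP/A1/A2/EAF/BETA/SE/P`). Pass a modified copy to
#' [read_gwas_summary()] when your file uses different names.
#'
#' @return Named character vector: names are mrsuite field names, values the
#'   source column names.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  c(rsid = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P")
}

#' Construct a GWAS summary dataset
#'
#' A summary dataset is a tibble of per-variant association records (one row
#' per SNP) carrying study metadata as attributes. Each record holds the
#' variant identity (rsid, chromosome, 1-based position, effect and other
#' allele), the effect-allele frequency, the log-odds effect size, its
#' standard error and p-value.
#'
#' @param records Data frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`.
#' @param trait Trait name.
#' @param ancestry Ancestry label.
#' @param n_cases,n_controls Study composition (non-negative integers; `NA`
#'   when unknown or not case-control).
#' @param validate Check record invariants and rsid uniqueness (default TRUE).
#' @return A `summary_dataset`: tibble of records with metadata attributes.
#' @export
summary_dataset <- function(records, trait = NA_character_,
                            ancestry = NA_character_,
                            n_cases = NA_integer_, n_controls = NA_integer_,
                            validate = TRUE) {
  cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    mr_abort(paste0("records is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             class = "mrsuite_config_error")
  }
  x <- tibble::as_tibble(records[cols])
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  x$eaf <- as.numeric(x$eaf)
  x$beta <- as.numeric(x$beta)
  x$se <- as.numeric(x$se)
  x$pval <- as.numeric(x$pval)
  if (validate) {
    reasons <- validate_variant_records(x)
    bad <- which(!is.na(reasons))
    if (length(bad) > 0) {
      mr_abort(paste0("invalid record(s): ",
                      paste0(x$rsid[bad[seq_len(min(5, length(bad)))]], " (",
                             reasons[bad[seq_len(min(5, length(bad)))]], ")",
                             collapse = "; ")),
               class = "mrsuite_validation_error")
    }
    dup <- x$rsid[duplicated(x$rsid)]
    if (length(dup) > 0) {
      mr_abort(paste0("duplicate rsid(s): ",
                      paste(unique(dup), collapse = ", ")),
               class = "mrsuite_validation_error")
    }
  }
  structure(x,
            trait = trait, ancestry = ancestry,
            n_cases = n_cases, n_controls = n_controls,
            class = c("summary_dataset", class(tibble::tibble())))
}

#' Per-row invariant check for variant association records
#'
#' @param x Data frame of (typed) variant records.
#' @return Character vector, `NA` where the row is valid, else the first
#'   violated invariant as a short reason string.
#' @keywords internal
validate_variant_records <- function(x) {
  n <- nrow(x)
  reason <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- msg
  }
  flag(is.na(x$rsid) | x$rsid == "" | is.na(x$chrom) | is.na(x$pos),
       "missing identifier or position")
  flag(!(x$effect_allele %in% VALID_BASES) |
         !(x$other_allele %in% VALID_BASES),
       "allele not a single base (indel/multi-allelic rejected)")
  flag(x$effect_allele == x$other_allele, "identical alleles")
  flag(is.na(x$beta), "missing beta")
  flag(is.na(x$se) | x$se <= 0, "non-positive SE")
  flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "EAF outside [0, 1]")
  flag(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "p-value outside (0, 1]")
  reason
}

#' Read a GWAS summary-statistic table
#'
#' Parses a tab-separated summary-statistic file into a [summary_dataset()].
#' Rows violating the record invariants (non-base or identical alleles,
#' non-positive SE, frequency outside \[0, 1\], p-value outside (0, 1\]) are
#' rejected row-by-row with a reason; nothing is dropped silently --
#' accepted plus rejected rows always account for every input row. Alleles
#' are upper-cased on read. The effect-allele-frequency column may be absent
#' from `column_map` (all `eaf` set to `NA`), in which case palindromic SNPs
#' cannot be frequency-aligned downstream.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row and
#'   `.`-decimal numbers.
#' @param column_map Named character vector mapping mrsuite field names to
#'   source column names; see [default_column_map()].
#' @inheritParams summary_dataset
#' @param quiet Suppress the accepted/rejected count message.
#' @return A `summary_dataset`. Rejected rows are attached as attribute
#'   `"rejected"`, a tibble with columns `row`, `rsid`, `reason`.
#' @export
read_gwas_summary <- function(path, column_map = default_column_map(),
                              trait = NA_character_, ancestry = NA_character_,
                              n_cases = NA_integer_, n_controls = NA_integer_,
                              quiet = FALSE) {
  if (!file.exists(path)) {
    mr_abort(paste0("file not found: ", path), class = "mrsuite_io_error")
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  missing_fields <- setdiff(required, names(column_map))
  if (length(missing_fields) > 0) {
    mr_abort(paste0("column_map is missing required field(s): ",
                    paste(missing_fields, collapse = ", ")),
             class = "mrsuite_config_error")
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    mr_abort(paste0("required column(s) not in file: ",
                    paste(missing_cols, collapse = ", ")),
             class = "mrsuite_config_error")
  }
  x <- tibble::tibble(
    rsid = as.character(raw[[column_map[["rsid"]]]]),
    chrom = as.character(raw[[column_map[["chrom"]]]]),
    pos = suppressWarnings(as.integer(raw[[column_map[["pos"]]]])),
    effect_allele = toupper(raw[[column_map[["effect_allele"]]]]),
    other_allele = toupper(raw[[column_map[["other_allele"]]]]),
    eaf = if ("eaf" %in% names(column_map)) {
      suppressWarnings(as.numeric(raw[[column_map[["eaf"]]]]))
    } else NA_real_,
    beta = suppressWarnings(as.numeric(raw[[column_map[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[column_map[["se"]]]])),
    pval = suppressWarnings(as.numeric(raw[[column_map[["pval"]]]]))
  )
  reasons <- validate_variant_records(x)
  keep <- is.na(reasons)
  rejected <- tibble::tibble(row = which(!keep),
                             rsid = x$rsid[!keep],
                             reason = reasons[!keep])
  accepted <- x[keep, , drop = FALSE]
  dup <- accepted$rsid[duplicated(accepted$rsid)]
  if (length(dup) > 0) {
    mr_abort(paste0("duplicate rsid(s) in ", path, ": ",
                    paste(unique(dup), collapse = ", ")),
             class = "mrsuite_validation_error")
  }
  if (!quiet) {
    message(sprintf("read_gwas_summary: %d accepted, %d rejected (of %d rows)",
                    nrow(accepted), nrow(rejected), nrow(x)))
  }
  out <- summary_dataset(accepted, trait = trait, ancestry = ancestry,
                         n_cases = n_cases, n_controls = n_controls,
                         validate = FALSE)
  attr(out, "rejected") <- rejected
  out
}

#' Write a GWAS summary dataset to a tab-separated file
#'
#' Inverse of [read_gwas_summary()] under the default column map.
#'
#' @param dataset A `summary_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(dataset, path) {
  out <- data.frame(SNP = dataset$rsid, CHR = dataset$chrom, BP = dataset$pos,
                    A1 = dataset$effect_allele, A2 = dataset$other_allele,
                    EAF = dataset$eaf, BETA = dataset$beta, SE = dataset$se,
                    P = dataset$pval)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mr_abort(paste0("cannot write: ", path), class = "mrsuite_io_error")
  invisible(path)
}

HARMONIZED_COLS <- c("rsid", "beta_exp", "se_exp", "eaf_exp",
                     "beta_out", "se_out", "eaf_out",
                     "flipped", "palindromic", "frequency_aligned")

#' Assemble a harmonized-instrument table
#'
#' One row per instrument with exposure and outcome effects expressed on the
#' same effect allele, plus provenance flags set by harmonization:
#' `flipped` (outcome effect was re-signed to the exposure effect allele),
#' `palindromic` (A/T or C/G variant), `frequency_aligned` (orientation was
#' resolved by allele frequency).
#'
#' @param x Data frame with columns `rsid`, `beta_exp`, `se_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `eaf_out`, `flipped`, `palindromic`,
#'   `frequency_aligned`.
#' @return Tibble of class `harmonized_instruments`.
#' @export
harmonized_instruments <- function(x) {
  missing_cols <- setdiff(HARMONIZED_COLS, names(x))
  if (length(missing_cols) > 0) {
    mr_abort(paste0("missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             class = "mrsuite_config_error")
  }
  x <- tibble::as_tibble(x[HARMONIZED_COLS])
  if (nrow(x) > 0 && any(x$se_exp <= 0 | x$se_out <= 0)) {
    mr_abort("standard errors must be positive",
             class = "mrsuite_validation_error")
  }
  class(x) <- c("harmonized_instruments", class(tibble::tibble()))
  x
}

#' Write harmonized instruments to a tab-separated file
#'
#' The file has a header row, one data row per instrument, and serializes
#' the provenance flags as TRUE/FALSE so that [read_harmonized()] reproduces
#' the collection exactly.
#'
#' @param instruments A `harmonized_instruments` table (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(instruments, path) {
  if (nrow(instruments) == 0) {
    mr_abort("refusing to write an empty instrument table",
             class = "mrsuite_validation_error")
  }
  ok <- tryCatch({
    utils::write.table(as.data.frame(instruments)[HARMONIZED_COLS], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mr_abort(paste0("cannot write: ", path), class = "mrsuite_io_error")
  invisible(path)
}

#' Read a harmonized-instrument table written by [write_harmonized()]
#'
#' @param path Path to the tab-separated file.
#' @return A `harmonized_instruments` tibble.
#' @export
read_harmonized <- function(path) {
  if (!file.exists(path)) {
    mr_abort(paste0("file not found: ", path), class = "mrsuite_io_error")
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           fileEncoding = "UTF-8",
                           colClasses = c(rsid = "character"))
  harmonized_instruments(raw)
}
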