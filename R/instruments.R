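# Instrument selection: significance filtering, greedy LD clumping and
# confounder-trait exclusion.

#' Build a pairwise LD source from an r-squared pair table
#'
#' Wraps a long table of pairwise r-squared values (as produced, for
#' example, from a 1000 Genomes European reference panel, or by the
#' synthetic generator) behind a symmetric lookup. Self-LD is always 1;
#' pairs absent from the table return `NA` so the caller can decide how to
#' treat unknown LD.
#'
#' @param pairs Data frame with columns `rsid_a`, `rsid_b`, `r2`
#'   (r-squared in \[0, 1\]). May have zero rows.
#' @return An object of class `ld_source` with a vectorized `$r2(a, b)`
#'   lookup function.
#' @export
ld_source <- function(pairs = data.frame(rsid_a = character(),
                                         rsid_b = character(),
                                         r2 = numeric())) {
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)))
  if (nrow(pairs) > 0 && any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    mr_abort("r2 values must lie in [0, 1]",
             class = "mrsuite_validation_error")
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- new.env(parent = emptyenv(), size = max(nrow(pairs), 29L))
  if (nrow(pairs) > 0) {
    k <- key(as.character(pairs$rsid_a), as.character(pairs$rsid_b))
    for (i in seq_along(k)) assign(k[i], pairs$r2[i], envir = tab)
  }
  r2 <- function(a, b) {
    a <- as.character(a); b <- as.character(b)
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
    out <- numeric(n)
    k <- key(a, b)
    for (i in seq_len(n)) {
      out[i] <- if (a[i] == b[i]) 1 else
        if (exists(k[i], envir = tab, inherits = FALSE))
          get(k[i], envir = tab) else NA_real_
    }
    out
  }
  structure(list(r2 = r2, n_pairs = nrow(pairs)), class = "ld_source")
}

#' Read an LD pair table (rsid_a, rsid_b, r2) from a TSV file
#'
#' @param path Tab-separated file with header `rsid_a rsid_b r2`.
#' @return An [ld_source()].
#' @export
read_ld_pairs <- function(path) {
  if (!file.exists(path)) {
    mr_abort(paste0("file not found: ", path), class = "mrsuite_io_error")
  }
  ld_source(utils::read.delim(path, header = TRUE, sep = "\t",
                              colClasses = c("character", "character",
                                             "numeric")))
}

#' Filter a summary dataset at a significance threshold
#'
#' Retains exactly the records with `pval <` the threshold, in input order.
#' The conventional instrument-selection threshold is genome-wide
#' significance, 5e-8.
#'
#' @param dataset A `summary_dataset`.
#' @param p_threshold Strict upper bound on the p-value, in (0, 1).
#' @return The filtered `summary_dataset` (metadata preserved).
#' @export
filter_significant <- function(dataset, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold <= 1)
  subset_dataset(dataset, dataset$pval < p_threshold)
}

#' @noRd
subset_dataset <- function(dataset, keep) {
  out <- dataset[keep, , drop = FALSE]
  for (a in c("trait", "ancestry", "n_cases", "n_controls")) {
    attr(out, a) <- attr(dataset, a)
  }
  class(out) <- class(dataset)
  out
}

#' Greedy LD clumping
#'
#' Prunes the dataset to approximately independent index SNPs: repeatedly
#' take the remaining record with the smallest p-value as an index SNP
#' (ties broken by chromosome, position, then rsid, so the result does not
#' depend on input row order) and remove every remaining record on the same
#' chromosome within `window_bp` of it whose r-squared with the index is at
#' least `r2_threshold`. Pairs inside the window with unknown LD are, by
#' default, treated as correlated and removed (`missing_ld = "remove"`);
#' set `missing_ld = "keep"` to retain them instead.
#'
#' @param dataset A `summary_dataset` with chromosome and position.
#' @param ld An [ld_source()].
#' @param r2_threshold Records with r-squared at or above this value are
#'   clumped away (default 0.001).
#' @param window_bp Window in base pairs around the index SNP within which
#'   LD is checked (default 10000, i.e. 10 kb; conventional MR pipelines
#'   often use 10 Mb -- the window is a parameter, not a constant).
#' @param missing_ld `"remove"` (default) or `"keep"`: treatment of
#'   within-window pairs absent from the LD source.
#' @return The clumped `summary_dataset`, index SNPs in selection order
#'   (ascending p-value).
#' @export
clump <- function(dataset, ld, r2_threshold = 0.001, window_bp = 10000,
                  missing_ld = c("remove", "keep")) {
  missing_ld <- match.arg(missing_ld)
  stopifnot(r2_threshold > 0, window_bp > 0)
  if (nrow(dataset) <= 1) return(dataset)
  ord <- order(dataset$pval, dataset$chrom, dataset$pos, dataset$rsid)
  x <- dataset[ord, , drop = FALSE]
  n <- nrow(x)
  alive <- rep(TRUE, n)
  index <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    index[i] <- TRUE
    j <- which(alive & seq_len(n) > i & x$chrom == x$chrom[i] &
                 abs(x$pos - x$pos[i]) <= window_bp)
    if (length(j) == 0) next
    r2 <- tryCatch(ld$r2(rep(x$rsid[i], length(j)), x$rsid[j]),
                   error = function(e) {
                     mr_abort(paste0("LD lookup failed for pair (",
                                     x$rsid[i], ", ", x$rsid[j][1], "): ",
                                     conditionMessage(e)),
                              class = "mrsuite_ld_error")
                   })
    drop <- if (missing_ld == "remove") is.na(r2) | r2 >= r2_threshold
            else !is.na(r2) & r2 >= r2_threshold
    alive[j[drop]] <- FALSE
  }
  subset_dataset(x, index)
}

#' Build a SNP-to-trait association catalog
#'
#' A local catalog of known SNP-trait associations (the role an online
#' SNP-phenotype lookup service plays in a connected workflow) together
#' with the list of confounder
#' traits whose associated SNPs must be excluded from the instrument set.
#'
#' @param associations Data frame with columns `rsid`, `trait`, `pval`.
#' @param excluded_traits Character vector of trait names to screen against.
#' @return An object of class `trait_catalog`.
#' @export
trait_catalog <- function(associations = data.frame(rsid = character(),
                                                    trait = character(),
                                                    pval = numeric()),
                          excluded_traits = character()) {
  stopifnot(all(c("rsid", "trait", "pval") %in% names(associations)))
  if (nrow(associations) > 0 &&
      any(associations$pval <= 0 | associations$pval > 1, na.rm = TRUE)) {
    mr_abort("catalog p-values must lie in (0, 1]",
             class = "mrsuite_validation_error")
  }
  structure(list(associations = tibble::as_tibble(associations),
                 excluded_traits = as.character(excluded_traits)),
            class = "trait_catalog")
}

#' Read a trait catalog from a TSV file (rsid, trait, pval)
#'
#' @param path Tab-separated file with header `rsid trait pval`.
#' @param excluded_traits Traits to screen against; defaults to every trait
#'   present in the file.
#' @return A [trait_catalog()].
#' @export
read_trait_catalog <- function(path, excluded_traits = NULL) {
  if (!file.exists(path)) {
    mr_abort(paste0("file not found: ", path), class = "mrsuite_io_error")
  }
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "numeric"))
  trait_catalog(x, excluded_traits %||% unique(x$trait))
}

#' Exclude instruments associated with confounder traits
#'
#' Removes every record whose rsid is associated, in the catalog, with any
#' of the excluded (confounder) traits at `pval < p_threshold`. This screens
#' out variants that could act on the outcome through pathways other than
#' the exposure (e.g. body-composition, cardiovascular, diabetes or kidney
#' traits when the outcome is cardiac).
#'
#' @param dataset A `summary_dataset`.
#' @param catalog A [trait_catalog()].
#' @param p_threshold Association significance below which a catalog hit
#'   triggers exclusion (default 5e-8, genome-wide significance).
#' @return List with `dataset` (records retained) and `exclusions`, a
#'   tibble of `(rsid, trait, pval)` with one row per removal reason.
#' @export
exclude_pleiotropic_traits <- function(dataset, catalog, p_threshold = 5e-8) {
  stopifnot(inherits(catalog, "trait_catalog"))
  hits <- catalog$associations
  hits <- hits[hits$trait %in% catalog$excluded_traits &
                 hits$pval < p_threshold &
                 hits$rsid %in% dataset$rsid, , drop = FALSE]
  keep <- !(dataset$rsid %in% hits$rsid)
  list(dataset = subset_dataset(dataset, keep),
       exclusions = tibble::as_tibble(hits[order(match(hits$rsid,
                                                       dataset$rsid)), ,
                                           drop = FALSE]))
}
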