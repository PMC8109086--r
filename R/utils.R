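# Internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

VALID_BASES <- c("A", "C", "G", "T")

#' Strand complement of single-base alleles
#' @noRd
complement_allele <- function(x) chartr("ACGT", "TGCA", x)

#' Is an allele pair palindromic (A/T or C/G)?
#' @noRd
is_palindromic_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent error class
#' @noRd
mr_abort <- function(msg, class = "mrsuite_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
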