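# End-to-end pipeline: select -> harmonize -> estimate (+ PRESSO,
# diagnostics), with per-stage accounting and a human-readable report.

PIPELINE_METHODS <- c("ivw", "egger", "simple-median", "weighted-median",
                      "raps", "presso")

#' Run every requested causal estimator on a harmonized instrument table
#'
#' @param instruments A [harmonized_instruments()] table.
#' @param methods Subset of `c("ivw", "egger", "simple-median",
#'   "weighted-median", "raps", "presso")`.
#' @param seed RNG seed for the stochastic components (median bootstrap,
#'   MR-PRESSO).
#' @param n_boot Bootstrap replicates for the median estimators.
#' @param presso_nsim,presso_alpha MR-PRESSO simulation count and outlier
#'   significance level.
#' @param raps_loss,raps_overdispersed Options passed to [mr_raps()].
#' @return List with `results` (one [mr_estimate()] row per method,
#'   PRESSO reported as the outlier-corrected IVW), `heterogeneity`,
#'   `egger` (full [mr_egger()] result or NULL) and `presso` (full
#'   [mr_presso()] result or NULL).
#' @export
mr_all <- function(instruments, methods = PIPELINE_METHODS, seed = NULL,
                   n_boot = 1000, presso_nsim = 1000, presso_alpha = 0.05,
                   raps_loss = "quadratic", raps_overdispersed = FALSE) {
  unknown <- setdiff(methods, PIPELINE_METHODS)
  if (length(unknown) > 0) {
    mr_abort(paste0("unknown method(s): ", paste(unknown, collapse = ", ")),
             class = "mrsuite_config_error")
  }
  rows <- list()
  het <- NULL; egger <- NULL; presso <- NULL
  if ("ivw" %in% methods) {
    ivw <- mr_ivw(instruments)
    rows$ivw <- ivw$estimate[setdiff(names(ivw$estimate), "se_fixed")]
    het <- ivw$heterogeneity
  }
  if ("egger" %in% methods) {
    egger <- mr_egger(instruments)
    rows$egger <- egger$estimate
  }
  if ("simple-median" %in% methods) {
    rows$simple_median <- mr_median(instruments, "simple", n_boot = n_boot,
                                    seed = if (is.null(seed)) NULL
                                           else seed + 11L)
  }
  if ("weighted-median" %in% methods) {
    rows$weighted_median <- mr_median(instruments, "weighted",
                                      n_boot = n_boot,
                                      seed = if (is.null(seed)) NULL
                                             else seed + 12L)
  }
  if ("raps" %in% methods) {
    raps <- mr_raps(instruments, loss = raps_loss,
                    overdispersed = raps_overdispersed)
    rows$raps <- raps[setdiff(names(raps), c("tau2", "loss"))]
  }
  if ("presso" %in% methods) {
    presso <- mr_presso(instruments, n_sim = presso_nsim,
                        seed = if (is.null(seed)) NULL else seed + 13L,
                        outlier_alpha = presso_alpha)
    base <- presso$corrected %||% mr_ivw(instruments)
    row <- base$estimate[setdiff(names(base$estimate), "se_fixed")]
    row$method <- "MR-PRESSO (outlier-corrected)"
    rows$presso <- row
  }
  list(results = do.call(rbind, unname(rows)), heterogeneity = het,
       egger = egger, presso = presso)
}

#' Run the full two-sample MR pipeline
#'
#' Executes, in order: significance filtering, LD clumping,
#' confounder-trait exclusion (when a catalog is supplied), harmonization,
#' the requested estimators, MR-PRESSO outlier handling, and leave-one-out,
#' funnel and scatter diagnostics. Every stage's in/out counts and
#' drop/exclusion logs are collected, heterogeneity is reported both before
#' and after outlier removal, and every tunable parameter is echoed in the
#' report header so a run can be reproduced exactly. Any stage failure
#' aborts with the stage name; output files are only written once the whole
#' pipeline has succeeded.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `exposure`, `outcome` (a [summary_dataset()] or TSV path), `seed`
#'   (required), and optionally `ld` ([ld_source()] or LD-pair TSV path),
#'   `trait_catalog` ([trait_catalog()] or TSV path), `p_threshold` (5e-8),
#'   `clump_r2` (0.001), `clump_kb` (10), `missing_ld` ("remove"),
#'   `palindrome_maf` (0.3), `palindrome_action` ("align"), `methods` (all
#'   six), `n_boot` (1000), `presso_nsim` (1000), `presso_alpha` (0.05),
#'   `raps_loss` ("quadratic"), `raps_overdispersed` (FALSE), `out_dir`
#'   (NULL; when set, writes `results.tsv`, `heterogeneity.tsv`, `loo.tsv`,
#'   `funnel.tsv`, `scatter.tsv` and `report.md` there).
#' @return List with `results`, `heterogeneity` (pre/post outlier removal),
#'   `egger_intercept`, `presso`, `loo`, `funnel`, `scatter`,
#'   `instruments`, `logs` (per-stage accounting), `drops`, `exclusions`
#'   and the echoed `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      mr_abort("reading YAML configs requires the yaml package",
               class = "mrsuite_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10,
                   missing_ld = "remove", palindrome_maf = 0.3,
                   palindrome_action = "align", methods = PIPELINE_METHODS,
                   n_boot = 1000, presso_nsim = 1000, presso_alpha = 0.05,
                   raps_loss = "quadratic", raps_overdispersed = FALSE,
                   ld = NULL, trait_catalog = NULL, out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  for (field in c("exposure", "outcome", "seed")) {
    if (is.null(cfg[[field]])) {
      mr_abort(paste0("config is missing '", field, "'"),
               class = "mrsuite_config_error")
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      mr_abort(paste0("pipeline stage '", name, "' failed: ",
                      conditionMessage(e)),
               class = "mrsuite_pipeline_error")
    })
  }
  as_dataset <- function(x, what) {
    if (inherits(x, "summary_dataset")) x
    else stage(paste0("read_", what),
               read_gwas_summary(x, trait = what, quiet = TRUE))
  }
  exposure <- as_dataset(cfg$exposure, "exposure")
  outcome <- as_dataset(cfg$outcome, "outcome")
  ld <- if (is.null(cfg$ld)) ld_source()
        else if (inherits(cfg$ld, "ld_source")) cfg$ld
        else stage("read_ld", read_ld_pairs(cfg$ld))
  catalog <- if (is.null(cfg$trait_catalog)) NULL
             else if (inherits(cfg$trait_catalog, "trait_catalog"))
               cfg$trait_catalog
             else stage("read_trait_catalog",
                        read_trait_catalog(cfg$trait_catalog))

  logs <- list()
  log_stage <- function(name, n_in, n_out, detail = "") {
    logs[[length(logs) + 1]] <<- tibble::tibble(stage = name, n_in = n_in,
                                                n_out = n_out,
                                                detail = detail)
  }

  sig <- stage("filter_significant",
               filter_significant(exposure, cfg$p_threshold))
  log_stage("filter_significant", nrow(exposure), nrow(sig),
            sprintf("p < %g", cfg$p_threshold))
  clumped <- stage("clump",
                   clump(sig, ld, r2_threshold = cfg$clump_r2,
                         window_bp = cfg$clump_kb * 1000,
                         missing_ld = cfg$missing_ld))
  log_stage("clump", nrow(sig), nrow(clumped),
            sprintf("r2 < %g in %g kb", cfg$clump_r2, cfg$clump_kb))
  exclusions <- tibble::tibble(rsid = character(), trait = character(),
                               pval = numeric())
  screened <- clumped
  if (!is.null(catalog)) {
    scr <- stage("exclude_pleiotropic_traits",
                 exclude_pleiotropic_traits(clumped, catalog,
                                            cfg$p_threshold))
    screened <- scr$dataset
    exclusions <- scr$exclusions
    log_stage("trait_screen", nrow(clumped), nrow(screened),
              sprintf("%d confounder-trait exclusions",
                      length(unique(exclusions$rsid))))
  }
  harm <- stage("harmonize",
                harmonize_datasets(screened, outcome,
                                   maf_threshold = cfg$palindrome_maf,
                                   palindrome_action = cfg$palindrome_action))
  instruments <- harm$instruments
  log_stage("harmonize", nrow(screened), nrow(instruments),
            sprintf("%d dropped", nrow(harm$drops)))

  est <- stage("estimators",
               mr_all(instruments, methods = cfg$methods, seed = cfg$seed,
                      n_boot = cfg$n_boot, presso_nsim = cfg$presso_nsim,
                      presso_alpha = cfg$presso_alpha,
                      raps_loss = cfg$raps_loss,
                      raps_overdispersed = cfg$raps_overdispersed))
  presso <- est$presso
  het_pre <- if (nrow(instruments) >= 2) heterogeneity(instruments) else NULL
  het_post <- NULL
  final_instruments <- instruments
  if (!is.null(presso) && length(presso$outliers) > 0) {
    final_instruments <-
      instruments[!instruments$rsid %in% presso$outliers, , drop = FALSE]
    het_post <- heterogeneity(final_instruments)
    log_stage("presso_outliers", nrow(instruments), nrow(final_instruments),
              paste(presso$outliers, collapse = ", "))
  }
  het <- rbind(
    if (!is.null(het_pre)) cbind(tibble::tibble(stage = "pre-outlier"),
                                 het_pre),
    if (!is.null(het_post)) cbind(tibble::tibble(stage = "post-outlier"),
                                  het_post))

  loo <- if (nrow(final_instruments) >= 3) {
    stage("leave_one_out", leave_one_out(final_instruments))
  } else NULL
  funnel <- stage("funnel_data", funnel_data(final_instruments))
  scatter <- if (nrow(final_instruments) >= 3) {
    stage("scatter_data", scatter_data(final_instruments))
  } else NULL

  out <- list(results = est$results, heterogeneity = het,
              egger_intercept = if (!is.null(est$egger))
                est$egger$intercept else NULL,
              presso = presso, loo = loo, funnel = funnel,
              scatter = scatter, instruments = instruments,
              logs = do.call(rbind, logs), drops = harm$drops,
              exclusions = exclusions,
              config = cfg[setdiff(names(cfg),
                                   c("exposure", "outcome", "ld",
                                     "trait_catalog", "out_dir"))])
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' @noRd
write_tsv_plain <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' @noRd
write_pipeline_outputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_plain(out$results, file.path(dir, "results.tsv"))
  if (!is.null(out$heterogeneity)) {
    write_tsv_plain(out$heterogeneity, file.path(dir, "heterogeneity.tsv"))
  }
  if (!is.null(out$loo)) write_tsv_plain(out$loo, file.path(dir, "loo.tsv"))
  write_tsv_plain(out$funnel$points, file.path(dir, "funnel.tsv"))
  if (!is.null(out$scatter)) {
    write_tsv_plain(out$scatter$points, file.path(dir, "scatter.tsv"))
  }
  writeLines(render_report(out), file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a pipeline result as a markdown report
#'
#' @param out Value of [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(out) {
  fmt_or <- function(r) {
    sprintf("| %s | %d | %.4f | %.4f | %.4f (%.4f-%.4f) | %.2g |",
            r$method, r$n_snps, r$beta, r$se, r$or, r$or_ci_low,
            r$or_ci_high, r$pval)
  }
  lines <- c("# Two-sample Mendelian randomization report", "",
             "## Parameters", "")
  cfgv <- out$config
  lines <- c(lines, vapply(names(cfgv), function(k) {
    sprintf("- %s: %s", k, paste(format(cfgv[[k]]), collapse = ", "))
  }, character(1)), "")
  lines <- c(lines, "## Stage accounting", "",
             "| stage | in | out | detail |", "|---|---|---|---|",
             sprintf("| %s | %d | %d | %s |", out$logs$stage, out$logs$n_in,
                     out$logs$n_out, out$logs$detail), "")
  lines <- c(lines, "## Causal estimates", "",
             "| method | n SNPs | beta | SE | OR (95% CI) | p |",
             "|---|---|---|---|---|---|",
             vapply(seq_len(nrow(out$results)),
                    function(i) fmt_or(out$results[i, ]), character(1)), "")
  if (!is.null(out$heterogeneity) && nrow(out$heterogeneity) > 0) {
    h <- out$heterogeneity
    lines <- c(lines, "## Heterogeneity", "",
               "| stage | Q | df | p | I2 |", "|---|---|---|---|---|",
               sprintf("| %s | %.4f | %d | %.4g | %.4f |", h$stage, h$Q,
                       h$df, h$pval, h$i2), "")
  }
  if (!is.null(out$egger_intercept)) {
    ic <- out$egger_intercept
    lines <- c(lines, "## MR-Egger intercept", "",
               sprintf("intercept = %.4f (95%% CI %.4f to %.4f), p = %.2g",
                       ic$value, ic$ci_low, ic$ci_high, ic$pval), "")
  }
  if (!is.null(out$presso)) {
    p <- out$presso
    lines <- c(lines, "## MR-PRESSO", "",
               sprintf("global test p = %.4g (n_sim = %d)", p$global_p,
                       p$n_sim),
               if (length(p$outliers) > 0) {
                 c(sprintf("outliers: %s", paste(p$outliers,
                                                 collapse = ", ")),
                   sprintf("distortion: %.2f%% (p = %.4g)",
                           p$distortion$coefficient, p$distortion$pval))
               } else "no outliers detected", "")
  }
  if (!is.null(out$loo)) {
    lines <- c(lines, "## Leave-one-out (IVW)", "",
               "| omitted | beta | SE | OR | p | influential |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.4f | %.4f | %.4f | %.2g | %s |",
                       out$loo$omitted, out$loo$beta, out$loo$se,
                       out$loo$or, out$loo$pval, out$loo$influential), "")
  }
  if (nrow(out$drops) > 0) {
    lines <- c(lines, "## Harmonization drops", "",
               sprintf("- %s: %s", out$drops$rsid, out$drops$reason), "")
  }
  if (nrow(out$exclusions) > 0) {
    lines <- c(lines, "## Confounder-trait exclusions", "",
               sprintf("- %s: %s (p = %.2g)", out$exclusions$rsid,
                       out$exclusions$trait, out$exclusions$pval), "")
  }
  lines
}
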