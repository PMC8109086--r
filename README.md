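# mrsuite

Two-sample Mendelian randomization (MR) from GWAS summary statistics, for
epidemiologists and statistical geneticists who want the complete
summary-data workflow — instrument selection, allele harmonization, six
causal estimators, pleiotropy and heterogeneity diagnostics, sensitivity
analysis and power calculation — in one tested R package, together with a
seeded synthetic GWAS generator so every stage can be exercised and
verified without downloading any external data.

## The statistical core

For variant *j*, let γ̂ⱼ (SE σ<sub>γj</sub>) be its estimated log-odds
effect on the exposure and Γ̂ⱼ (SE σ<sub>Γj</sub>) on the outcome, from two
independent GWAS. Under the instrumental-variable assumptions the working
model is Γⱼ = β·γⱼ + αⱼ, with β the causal effect (log-OR of outcome per
log-OR of exposure) and αⱼ a direct pleiotropic effect. The package
implements:

| method | function | handles |
|---|---|---|
| IVW, multiplicative random effects | `mr_ivw()` | valid instruments; heterogeneity widens the CI via max{1, √(Q/(n−1))} |
| MR-Egger + intercept test | `mr_egger()` | directional pleiotropy under InSIDE |
| simple / weighted median | `mr_median()` | up to 50% invalid instruments; bootstrap SE |
| RAPS (robust adjusted profile score) | `mr_raps()` | exposure-side noise, overdispersion, idiosyncratic outliers |
| MR-PRESSO | `mr_presso()` | global heterogeneity test, per-SNP outlier detection, corrected estimate, distortion test |
| Cochran's Q / I² | `heterogeneity()` | between-variant heterogeneity of ratio estimates |

Around the estimators: `read_gwas_summary()` (validating TSV reader with
configurable column map), `filter_significant()` / `clump()` /
`exclude_pleiotropic_traits()` (instrument selection), `harmonize_datasets()`
(allele alignment with palindromic-SNP frequency resolution),
`leave_one_out()`, `funnel_data()`, `scatter_data()`, `mr_power_binary()` /
`mr_detectable_or()`, the one-call `run_pipeline()`, and the generator
`generate_scenario()` / `make_trait_catalog()`. A thin CLI lives at
`inst/cli/mrsuite.R` (`Rscript mrsuite.R run|simulate|power ...`).

## Worked example

Simulate a null scenario at realistic scale (112 candidate instruments,
exposure study n = 76,312, outcome study n = 1,030,836, no causal effect),
screen and harmonize, and run all six methods:

```r
library(mrsuite)

g <- generate_scenario(scenario_config(n_snps = 112, true_beta = 0,
                                       seed = 6))
catalog <- make_trait_catalog(g$exposure, confounder_fraction = 0.25,
                              seed = 7)
res <- run_pipeline(list(exposure = g$exposure, outcome = g$outcome,
                         ld = g$ld, trait_catalog = catalog, seed = 6))
res$logs
#>                stage n_in n_out                         detail
#> 1 filter_significant  112    76                      p < 5e-08
#> 2              clump   76    76            r2 < 0.001 in 10 kb
#> 3       trait_screen   76    61 15 confounder-trait exclusions
#> 4          harmonize   61    57                      4 dropped
res$results
#>                                method n_snps       beta       se   pval     or or_ci_low or_ci_high
#> 1 IVW (multiplicative random effects)     57 -3.533e-05 0.001733 0.9837 1.0000    0.9966      1.003
#> 2                            MR-Egger     57  4.170e-03 0.003473 0.2351 1.0042    0.9972      1.011
#> 3                       Simple median     57 -2.340e-03 0.003114 0.4524 0.9977    0.9916      1.004
#> 4                     Weighted median     57  8.312e-04 0.002662 0.7548 1.0008    0.9956      1.006
#> 5                                RAPS     57 -3.541e-05 0.001783 0.9842 1.0000    0.9965      1.003
#> 6       MR-PRESSO (outlier-corrected)     57 -3.533e-05 0.001733 0.9837 1.0000    0.9966      1.003
res$heterogeneity
#>         stage     Q df   pval      i2
#> 1 pre-outlier 56.84 56 0.4435 0.01481
res$egger_intercept
#>       value       se   ci_low  ci_high  pval df
#> 1 -0.000601 0.000431 -0.00147 0.000263 0.169 55
```

Reading this: of 112 candidates, 76 reach genome-wide significance, none
are clumped away (index variants are simulated 1 Mb apart), 15 fall to the
confounder-trait screen and 4 are dropped in harmonization (ambiguous
palindromes), leaving 57 instruments. All six estimators agree on an odds
ratio indistinguishable from 1 — correctly, since the scenario's true
causal effect is zero — with no heterogeneity (Q ≈ df) and a null Egger
intercept (no directional pleiotropy was simulated).

The power calculation behind a typical design of this size:

```r
mr_power_binary(n_sample = 76312, r2_xz = 0.090, k_cases = 38565/76312,
                or_alt = 1.07, alpha = 0.05)
#> [1] 0.8005094
```

i.e. 80% power to detect an odds ratio of 1.07 per log-odds of exposure at
α = 0.05, and `mr_detectable_or()` inverts it (→ 1.0700 at 80% power).
`run_pipeline(..., out_dir = "...")` additionally writes `results.tsv`,
`heterogeneity.tsv`, `loo.tsv`, `funnel.tsv`, `scatter.tsv` and a
`report.md` echoing every parameter and stage count; reruns with the same
config and seed are byte-identical.

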