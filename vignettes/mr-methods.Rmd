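---
title: "Methods: two-sample Mendelian randomization in mrsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsuite)
```

## The model

Two-sample Mendelian randomization (MR) uses genetic variants as
instrumental variables to estimate the causal effect of an exposure on an
outcome from two independent GWAS. For variant $j$, let $\hat\gamma_j$
(SE $\sigma_{\gamma j}$) be its estimated log-odds effect on the exposure
and $\hat\Gamma_j$ (SE $\sigma_{\Gamma j}$) its estimated log-odds effect
on the outcome. Under the instrumental-variable assumptions (relevance,
independence from confounders, exclusion restriction), the working model is

$$\Gamma_j = \beta\,\gamma_j + \alpha_j,$$

where $\beta$ is the causal effect — change in log-odds of the outcome per
unit increase in log-odds of the exposure — and $\alpha_j$ is variant
$j$'s direct (horizontally pleiotropic) effect, zero for a valid
instrument. Every estimator in the package is a different compromise about
the $\alpha_j$:

* **IVW (multiplicative random effects)**, `mr_ivw()`: the
  inverse-variance weighted mean of the per-variant Wald ratios
  $r_j = \hat\Gamma_j/\hat\gamma_j$ with first-order weights
  $w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$. Assumes all instruments
  valid (or balanced pleiotropy absorbed by the overdispersion scale).
  The fixed-effect SE $(\sum_j w_j)^{-1/2}$ is multiplied by
  $\max\{1, \sqrt{Q/(n-1)}\}$, so heterogeneity can widen but never
  narrow the interval.
* **MR-Egger**, `mr_egger()`: weighted regression of $\hat\Gamma_j$ on
  $\hat\gamma_j$ with a free intercept, after orienting each instrument
  to $\hat\gamma_j > 0$ (Egger regression is not orientation-invariant;
  the convention is the exposure-increasing allele). The slope is
  consistent under the weaker InSIDE assumption — instrument strength
  independent of direct effects — and a nonzero intercept estimates the
  mean directional pleiotropic effect. Inference uses the $t$
  distribution with $n-2$ degrees of freedom and the same
  overdispersion-scale floor as IVW (the floor is applied here for the
  same never-narrower rationale).
* **Simple and weighted median**, `mr_median()`: the (weighted) median of
  the Wald ratios, consistent while up to half of the information comes
  from invalid instruments. The weighted median interpolates the sorted
  ratios at cumulative weight 0.5 using breakpoints $p_j = S_j - w_j/2$.
  SEs come from a parametric bootstrap that redraws every
  $(\hat\gamma_j, \hat\Gamma_j)$ from normal distributions centred at the
  observed values with the observed SEs.
* **RAPS**, `mr_raps()`: maximizes the profile log-likelihood built from
  standardized residuals
  $t_j(\beta,\tau^2) = (\hat\Gamma_j - \beta\hat\gamma_j)/
  \sqrt{\sigma_{\Gamma j}^2 + \beta^2\sigma_{\gamma j}^2 + \tau^2}$,
  which — unlike first-order IVW — propagates exposure-side sampling
  error. `overdispersed = TRUE` estimates the systematic-pleiotropy
  variance $\tau^2$ from the adjusted profile score; `loss = "huber"`
  bounds the influence of idiosyncratically pleiotropic variants.
* **MR-PRESSO**, `mr_presso()`: a simulation-based global heterogeneity
  test on the leave-one-out residual sum of squares, per-variant outlier
  tests against each variant's own simulated residual distribution
  (Bonferroni-adjusted), an outlier-corrected IVW estimate, and a
  distortion test comparing the correction against removals of random
  subsets of the same size.

Heterogeneity is summarized by Cochran's $Q = \sum_j w_j(r_j - \hat\beta)^2$
with $df = n-1$ and $I^2 = \max\{0, (Q-df)/Q\}$, reported both before and
after outlier removal because the attribution of a published heterogeneity
statistic to one or the other stage is often ambiguous.

## Instrument selection and harmonization

Selection proceeds in the conventional order: keep variants with exposure
$p < 5\times10^{-8}$ (`filter_significant()`); greedily clump to
approximately independent index SNPs, smallest $p$ first, removing
within-window variants with $r^2$ at or above the threshold (`clump()`,
defaults $r^2 \ge 0.001$ within 10 kb); and drop variants associated with
confounder traits at genome-wide significance in a local SNP-trait catalog
(`exclude_pleiotropic_traits()`). Three non-obvious choices:

* **Clumping window.** The default is 10 kb. Common MR pipelines clump
  over 10 Mb; both are reachable through `window_bp`, and the window is
  deliberately a parameter rather than a constant because published
  analyses differ.
* **Missing LD.** A within-window pair absent from the LD source is
  treated as correlated and removed (`missing_ld = "remove"`). This is
  conservative: it can only cost instruments, never retain a correlated
  pair. `"keep"` is available when the panel is known to be complete.
* **Ties.** Equal p-values are broken by (chromosome, position, rsid), so
  clumping is invariant to input row order.

Harmonization (`harmonize_datasets()`) expresses both effects on the same
effect allele: label swaps negate the outcome beta and reflect its
frequency; non-palindromic strand flips are resolved by complementing
(A↔T, C↔G); palindromic SNPs (A/T, C/G) carry no strand information in
their alleles, so they are oriented by allele frequency when the exposure
minor-allele frequency is below 0.3 (both frequencies put on the same side
of 0.5) and dropped as ambiguous otherwise. The 0.3 threshold makes a
palindrome resolvable exactly when its frequency is informative; the
alternative convention of dropping every palindrome is available as
`palindrome_action = "drop"`. A palindromic variant missing a frequency on
either side is always dropped. Every input variant is accounted for: the
drop log plus the output partition the input.

## Power

`mr_power_binary()` implements the standard non-centrality approximation
for a binary outcome:
$NCP = n\,r^2_{xz}\,(\ln OR)^2\,K(1-K)$, power
$= \Phi(\sqrt{NCP} - z_{1-\alpha/2})$, with $n$ the sample size, $r^2_{xz}$
the variance in exposure liability explained by the instrument, $K$ the
case fraction and $OR$ the detectable odds ratio per unit log-odds of
exposure. For the motivating design — an exposure study of 76,312 with
38,565 cases and an instrument explaining 9.0% of liability variance — the
package computes 80.05% power to detect OR 1.07 at $\alpha = 0.05$, and
`mr_detectable_or()` inverts the formula (1.0700 at 80% power). The case
fraction of the *exposure* study is used in this worked example because it
is the only composition that reproduces that power/OR combination at
$r^2 = 0.090$; which study's composition enters such published
calculations is usually not stated.

## The synthetic generator

`generate_scenario()` draws both summary datasets from the working model:
true exposure effects $\gamma_j \sim N(0, 0.1^2)$ (SD on the log-odds
scale, typical of genome-wide-significant effects for common
immune-mediated disease loci), direct effects $\alpha_j$ per pleiotropy
model, outcome effects $\beta\gamma_j + \alpha_j$, and observed effects
with SE $1/\sqrt{2n\,\mathrm{eaf}(1-\mathrm{eaf})}$ — the
quantitative-trait approximation, adequate for exercising estimators; a
case-control-scaled variant ($K(1-K)$ factor) is a config option. Default
sample sizes are 76,312 (exposure) and 1,030,836 (outcome), and the
default candidate count is 112. Further defaults, chosen once as realistic
for this setting: balanced pleiotropy SD 0.002 and directional mean 0.002
(comparable to the per-variant outcome SE, i.e. detectable but not
dominant); 16% palindromic variants (about what uniform allele-pair usage
yields); allele frequencies uniform on (0.05, 0.95); half of outcome
records re-expressed with swapped allele labels and 20% of non-palindromic
ones strand-flipped, so harmonization always has real work with recorded
truth. LD blocks emit equicorrelated tag SNPs within 10 kb of their index
variant with effects attenuated by $r$ ($=\sqrt{r^2}$). The truth record
keeps every latent quantity.

What the generator does **not** emulate: realistic human LD maps (blocks
are idealized and equicorrelated), logistic-regression SEs, sample overlap
between the two studies, winner's curse beyond explicit significance
filtering, population stratification, or indels/multi-allelic variants.
Passing simulation tests therefore demonstrates correctness of the
estimators under their own statistical model, not robustness to every
artefact of real GWAS.

## Numerical choices

* IVW/median/RAPS p-values and CIs use the normal reference; Egger uses
  $t_{n-2}$. CI half-width multiplier is 1.96 except Egger's $t$ quantile.
* Overdispersion scales (IVW, Egger) are floored at 1.
* RAPS root-finds the profile score starting from the IVW estimate with an
  expanding bracket, tolerance $10^{-10}$ on the score; Huber constant
  1.345; SE from the per-variant-score sandwich with a numerical observed
  information; $\tau^2$ (when estimated) solves the moment equation
  $\sum_j(\psi(t_j)t_j - \delta)/s_j^2 = 0$ with
  $\delta = E[\psi(T)T] = 2\Phi(k)-1$ for Huber (1 for the quadratic
  loss), floored at 0.
* MR-PRESSO: the global empirical p uses the $(1+\#)/(1+n_{sim})$ form and
  so is never 0; per-variant outlier p-values use $\#/n_{sim}$ so that,
  after Bonferroni adjustment over $n$ variants, an extreme outlier can
  still fall below the 0.05 default — with the $+1$ form and the default
  $n_{sim} = 1000$, no outlier could ever be declared among ~50
  instruments. Residuals are unweighted in the RSS; the per-variant scales
  enter through the resampling.
* Bootstrap and simulation functions take explicit seeds and restore the
  caller's RNG state; identical seeds reproduce results exactly *within
  this package* (RNG streams are not portable across software).
* Degenerate inputs: zero exposure effects are refused by `wald_ratios()`
  with the offending rsid; estimators enforce their minimum instrument
  counts (2 for IVW, 3 for Egger/medians/RAPS, 4 for PRESSO); `Q = 0`
  forces $I^2 = 0$; `r2_xz = 0` in the power formula is flagged as
  degenerate.

## Validation scale and known limitations

The test suite validates parameter recovery over 500 replicates of an
80-instrument scenario with true $\beta = 0.1$ (bootstrap SEs at 400
replicates there; 1000 is the analysis default), type-I calibration over
1000 null replicates with balanced pleiotropy, Egger-intercept recovery
over 200 directional replicates on genome-wide-significant instruments,
and PRESSO detection of a 10-SD planted outlier over 100 runs. These sizes
give Monte-Carlo SEs well under the asserted tolerances while keeping the
suite runnable on a laptop in minutes.

Known limitations:

* The parametric bootstrap SE of the **simple** median is systematically
  conservative (~15% in the recovery scenario above): resampling around
  the observed, already-noisy effects spreads the cross-variant ratio
  distribution, flattening its density at the median and inflating the
  bootstrap variance of a sample median. Its CIs overcover (~0.975
  empirically). The weighted median is barely affected because
  inverse-variance weights concentrate on precise ratios.
* First-order IVW weights ignore exposure-side sampling error; with weak
  instruments this produces regression dilution. RAPS is the in-package
  remedy.
* Egger's intercept is only interpretable with sign-determinate
  instruments; the package orients by the *observed* exposure effect
  sign, which for near-null instruments (excluded by any sensible
  significance threshold) can flip orientation.
* The distortion-test p-value is a randomization test against
  equal-sized random removals, a pragmatic convention; it is not an
  exact test.

## A worked run

```{r, eval = FALSE}
g <- generate_scenario(scenario_config(n_snps = 112, true_beta = 0,
                                       seed = 6))
catalog <- make_trait_catalog(g$exposure, confounder_fraction = 0.25,
                              seed = 7)
res <- run_pipeline(list(exposure = g$exposure, outcome = g$outcome,
                         ld = g$ld, trait_catalog = catalog, seed = 6))
res$results
res$heterogeneity
cat(render_report(res), sep = "\n")
```
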