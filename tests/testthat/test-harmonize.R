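# Allele harmonization: label swaps, strand flips, palindromes.

pair_result <- function(exp, out, ...) harmonize_pair(exp, out, ...)

test_that("swapped allele labels negate the outcome beta and reflect EAF", {
  exp <- make_variant("rs1", "A", "G", 0.1, eaf = 0.3)
  out <- make_variant("rs1", "G", "A", -0.05, eaf = 0.7)
  h <- pair_result(exp, out)
  expect_equal(h$instrument$beta_out, 0.05)
  expect_equal(h$instrument$eaf_out, 0.3)
  expect_true(h$instrument$flipped)
  # exposure side untouched
  expect_equal(h$instrument$beta_exp, 0.1)
  expect_equal(h$instrument$se_exp, 0.01)
})

test_that("strand-complemented records are recognized, swapped or not", {
  exp <- make_variant("rs1", "A", "G", 0.1, eaf = 0.3)
  same_strand_comp <- make_variant("rs1", "T", "C", 0.07, eaf = 0.29)
  h <- pair_result(exp, same_strand_comp)
  expect_equal(h$instrument$beta_out, 0.07)
  expect_false(h$instrument$flipped)
  swapped_comp <- make_variant("rs1", "C", "T", 0.07, eaf = 0.71)
  h2 <- pair_result(exp, swapped_comp)
  expect_equal(h2$instrument$beta_out, -0.07)
  expect_equal(h2$instrument$eaf_out, 0.29)
  expect_true(h2$instrument$flipped)
})

test_that("palindromic SNPs are frequency-aligned below the MAF threshold", {
  exp <- make_variant("rs1", "A", "T", 0.1, eaf = 0.20)
  out <- make_variant("rs1", "A", "T", 0.04, eaf = 0.21)
  h <- pair_result(exp, out, maf_threshold = 0.3)
  expect_equal(h$instrument$beta_out, 0.04)
  expect_true(h$instrument$palindromic)
  expect_true(h$instrument$frequency_aligned)
  # frequencies on opposite sides of 0.5: outcome re-oriented
  out2 <- make_variant("rs1", "A", "T", 0.04, eaf = 0.79)
  h2 <- pair_result(exp, out2, maf_threshold = 0.3)
  expect_equal(h2$instrument$beta_out, -0.04)
  expect_equal(h2$instrument$eaf_out, 0.21)
})

test_that("ambiguous palindromes and missing frequencies are dropped", {
  exp <- make_variant("rs1", "C", "G", 0.1, eaf = 0.45)
  out <- make_variant("rs1", "C", "G", 0.04, eaf = 0.44)
  expect_equal(pair_result(exp, out, maf_threshold = 0.3)$reason,
               "ambiguous palindrome")
  exp2 <- make_variant("rs1", "C", "G", 0.1, eaf = NA_real_)
  out2 <- make_variant("rs1", "C", "G", 0.04, eaf = 0.2)
  expect_equal(pair_result(exp2, out2)$reason, "palindrome without EAF")
  # the drop-all switch discards even resolvable palindromes
  exp3 <- make_variant("rs1", "A", "T", 0.1, eaf = 0.2)
  out3 <- make_variant("rs1", "A", "T", 0.04, eaf = 0.2)
  expect_equal(pair_result(exp3, out3, palindrome_action = "drop")$reason,
               "palindromic SNP")
})

test_that("irreconcilable alleles are dropped and rsid mismatch errors", {
  exp <- make_variant("rs1", "A", "G", 0.1)
  out <- make_variant("rs1", "A", "C", 0.04)
  expect_equal(pair_result(exp, out)$reason, "allele mismatch")
  out2 <- make_variant("rs2", "A", "G", 0.04)
  expect_error(pair_result(exp, out2), class = "mrsuite_usage_error")
})

test_that("double flip is the identity on 200 random pairs", {
  set.seed(19)
  for (i in 1:200) {
    pal <- stats::runif(1) < 0.3
    alleles <- if (pal) sample(list(c("A", "T"), c("C", "G")), 1)[[1]]
    else sample(list(c("A", "G"), c("C", "T"), c("A", "C")), 1)[[1]]
    eafe <- stats::runif(1, 0.02, 0.28)
    exp <- make_variant("rsX", alleles[1], alleles[2],
                        stats::rnorm(1, 0, 0.1), eaf = eafe)
    out <- make_variant("rsX", alleles[1], alleles[2],
                        stats::rnorm(1, 0, 0.1),
                        eaf = eafe + stats::rnorm(1, 0, 0.005))
    out_swapped <- out
    out_swapped$effect_allele <- out$other_allele
    out_swapped$other_allele <- out$effect_allele
    out_swapped$beta <- -out$beta
    out_swapped$eaf <- 1 - out$eaf
    h1 <- pair_result(exp, out)
    h2 <- pair_result(exp, out_swapped)
    expect_equal(h2$instrument$beta_out, h1$instrument$beta_out)
    expect_equal(h2$instrument$eaf_out, h1$instrument$eaf_out)
    # |beta_out| preserved, exposure side untouched
    expect_equal(abs(h1$instrument$beta_out), abs(out$beta))
    expect_equal(h1$instrument$beta_exp, exp$beta)
  }
})

test_that("dataset harmonization intersects rsids and accounts for drops", {
  exposure <- make_dataset(
    make_variant("rs1", "A", "G", 0.1, eaf = 0.3),
    make_variant("rs2", "C", "T", 0.2, eaf = 0.4, chrom = "2"),
    make_variant("rs3", "A", "T", 0.1, eaf = 0.45, chrom = "3"))
  outcome <- make_dataset(
    make_variant("rs2", "C", "T", 0.05, eaf = 0.4, chrom = "2"),
    make_variant("rs3", "A", "T", 0.01, eaf = 0.44, chrom = "3"),
    make_variant("rs4", "G", "A", 0.02, eaf = 0.2, chrom = "4"))
  res <- harmonize_datasets(exposure, outcome)
  expect_equal(res$instruments$rsid, "rs2")
  # conservation: every exposure rsid in output or drop log
  expect_setequal(c(res$instruments$rsid, res$drops$rsid), exposure$rsid)
  expect_equal(res$drops$reason[res$drops$rsid == "rs1"], "not in outcome")
  expect_equal(res$drops$reason[res$drops$rsid == "rs3"],
               "ambiguous palindrome")
})

test_that("harmonizing a dataset with itself is the identity", {
  g <- generate_scenario(scenario_config(n_snps = 30, true_beta = 0.1,
                                         seed = 5))
  res <- harmonize_datasets(g$exposure, g$exposure)
  keep <- !g$truth$is_palindromic |
    pmin(g$exposure$eaf, 1 - g$exposure$eaf) < 0.3
  expect_equal(res$instruments$rsid, g$exposure$rsid[keep])
  expect_equal(res$instruments$beta_out, res$instruments$beta_exp)
  expect_false(any(res$instruments$flipped))
})
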