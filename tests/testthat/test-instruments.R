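# Instrument selection: significance filter, greedy LD clumping, trait screen.

test_that("significance filter keeps exactly the sub-threshold records", {
  d <- make_dataset(
    make_variant("rs1", "A", "G", 0.1, pval = 1e-9),
    make_variant("rs2", "C", "T", 0.1, pval = 4e-8, chrom = "2"),
    make_variant("rs3", "G", "A", 0.1, pval = 6e-8, chrom = "3"))
  f <- filter_significant(d, 5e-8)
  expect_equal(f$rsid, c("rs1", "rs2"))
  expect_equal(filter_significant(d, 1.0)$rsid, d$rsid)
  empty <- filter_significant(d, 1e-12)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "summary_dataset")
})

test_that("clumping removes correlated neighbours and keeps the lead SNP", {
  d <- make_dataset(
    make_variant("rsA", "A", "G", 0.1, pval = 1e-10, pos = 1000),
    make_variant("rsB", "C", "T", 0.1, pval = 1e-9, pos = 6000))
  ld <- ld_source(data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = 0.5))
  expect_equal(clump(d, ld, 0.001, 10000)$rsid, "rsA")
  # sub-threshold LD: both kept
  ld2 <- ld_source(data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = 0.0005))
  expect_setequal(clump(d, ld2, 0.001, 10000)$rsid, c("rsA", "rsB"))
  # single record passes through
  one <- make_dataset(make_variant("rsA", "A", "G", 0.1))
  expect_equal(clump(one, ld, 0.001, 10000)$rsid, "rsA")
})

test_that("missing LD within the window is conservative by default", {
  d <- make_dataset(
    make_variant("rsA", "A", "G", 0.1, pval = 1e-10, pos = 1000),
    make_variant("rsB", "C", "T", 0.1, pval = 1e-9, pos = 6000))
  no_ld <- ld_source()
  expect_equal(clump(d, no_ld, 0.001, 10000)$rsid, "rsA")
  expect_setequal(clump(d, no_ld, 0.001, 10000, missing_ld = "keep")$rsid,
                  c("rsA", "rsB"))
  # outside the window the pair is never tested
  far <- make_dataset(
    make_variant("rsA", "A", "G", 0.1, pval = 1e-10, pos = 1000),
    make_variant("rsB", "C", "T", 0.1, pval = 1e-9, pos = 60000))
  expect_setequal(clump(far, no_ld, 0.001, 10000)$rsid, c("rsA", "rsB"))
})

test_that("clumping is idempotent, order-invariant, and matches brute force", {
  set.seed(401)
  for (rep in 1:10) {
    n <- 12
    rsids <- paste0("rs", sample(100:999, n))
    df <- tibble::tibble(
      rsid = rsids, chrom = as.character(sample(1:2, n, TRUE)),
      pos = as.integer(sample(seq(1000, 40000, by = 1500), n)),
      effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = 0.1, se = 0.01, pval = stats::runif(n, 1e-12, 1e-6))
    # random sparse LD: ~half of all pairs known
    cmb <- utils::combn(rsids, 2)
    known <- stats::runif(ncol(cmb)) < 0.5
    pairs <- data.frame(rsid_a = cmb[1, known], rsid_b = cmb[2, known],
                        r2 = stats::runif(sum(known)))
    ld <- ld_source(pairs)
    r2mat <- matrix(NA_real_, n, n, dimnames = list(rsids, rsids))
    for (k in seq_len(nrow(pairs))) {
      r2mat[pairs$rsid_a[k], pairs$rsid_b[k]] <- pairs$r2[k]
      r2mat[pairs$rsid_b[k], pairs$rsid_a[k]] <- pairs$r2[k]
    }
    d <- summary_dataset(df)
    got <- clump(d, ld, 0.1, 10000)
    expect_equal(got$rsid, oracle_clump(df, r2mat, 0.1, 10000))
    # pairwise postcondition: no retained same-chrom pair in-window with known r2 >= threshold
    if (nrow(got) > 1) {
      gc <- utils::combn(seq_len(nrow(got)), 2)
      for (k in seq_len(ncol(gc))) {
        a <- got[gc[1, k], ]; b <- got[gc[2, k], ]
        if (a$chrom == b$chrom && abs(a$pos - b$pos) <= 10000) {
          # retained in-window pairs must have known, sub-threshold LD
          r2 <- r2mat[a$rsid, b$rsid]
          expect_false(is.na(r2))
          expect_lt(r2, 0.1)
        }
      }
    }
    # idempotence
    expect_equal(clump(got, ld, 0.1, 10000)$rsid, got$rsid)
    # row-order invariance
    perm <- sample(nrow(d))
    expect_equal(clump(summary_dataset(df[perm, ]), ld, 0.1, 10000)$rsid,
                 got$rsid)
  }
})

test_that("clumping a synthetic LD-block dataset keeps one SNP per block", {
  g <- generate_scenario(scenario_config(
    n_snps = 12, true_beta = 0, gamma_scale = 0.15, seed = 77,
    ld_blocks = list(n_blocks = 12, snps_per_block = 4, r2 = 0.8),
    palindrome_fraction = 0))
  sig <- filter_significant(g$exposure, 1.0)
  got <- clump(sig, g$ld, 0.001, 10000)
  expect_equal(nrow(got), 12)
  blocks <- g$truth$block[match(got$rsid, g$truth$rsid)]
  expect_setequal(blocks, 1:12)
  # the retained SNP is the lowest-p member of its block
  for (b in blocks) {
    members <- g$truth$rsid[g$truth$block == b]
    best <- members[which.min(g$exposure$pval[match(members,
                                                    g$exposure$rsid)])]
    expect_equal(got$rsid[blocks == b], best)
  }
})

test_that("confounder-trait screening excludes catalog hits below threshold", {
  d <- make_dataset(
    make_variant("rs1", "A", "G", 0.1),
    make_variant("rs2", "C", "T", 0.1, chrom = "2"),
    make_variant("rs3", "G", "A", 0.1, chrom = "3"))
  cat <- trait_catalog(
    data.frame(rsid = c("rs1", "rs2", "rs2"),
               trait = c("body mass index", "body mass index", "height"),
               pval = c(1e-9, 1e-6, 1e-20)),
    excluded_traits = "body mass index")
  res <- exclude_pleiotropic_traits(d, cat, 5e-8)
  expect_equal(res$dataset$rsid, c("rs2", "rs3"))  # rs2 hit above threshold,
  expect_equal(res$exclusions$rsid, "rs1")         # rs3 absent from catalog
  expect_equal(res$exclusions$trait, "body mass index")
  expect_equal(res$exclusions$pval, 1e-9)
})

test_that("LD source is symmetric with unit self-LD and validated input", {
  ld <- ld_source(data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = 0.4))
  expect_equal(ld$r2("rsA", "rsB"), 0.4)
  expect_equal(ld$r2("rsB", "rsA"), 0.4)
  expect_equal(ld$r2("rsA", "rsA"), 1)
  expect_true(is.na(ld$r2("rsA", "rsZ")))
  expect_error(ld_source(data.frame(rsid_a = "a", rsid_b = "b", r2 = 1.2)),
               class = "mrsuite_validation_error")
})
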