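# Causal estimators: closed-form oracles, equivariance, degenerate cases.

test_that("Wald ratios follow the first-order formulas", {
  h <- make_instruments(c(0.1, -0.1, 0.1), c(0.05, 0.05, 0),
                        c(0.02, 0.02, 0.02))
  r <- wald_ratios(h)
  expect_equal(r$ratio, c(0.5, -0.5, 0))
  expect_equal(r$se, c(0.2, 0.2, 0.2))
  h0 <- make_instruments(c(0.1, 0), c(0.05, 0.01), c(0.02, 0.02))
  expect_error(wald_ratios(h0), "rs2", class = "mrsuite_validation_error")
})

test_that("IVW matches the weighted-least-squares closed form", {
  h <- make_instruments(c(0.2, 0.1), c(0.02, 0.02), c(0.01, 0.02))
  res <- mr_ivw(h)
  expect_equal(res$estimate$beta, 45 / 425, tolerance = 1e-12)
  expect_equal(res$estimate$se_fixed, 425^-0.5, tolerance = 1e-12)
  expect_equal(res$heterogeneity$Q, 0.23529412, tolerance = 1e-7)
  # Q/(n-1) < 1 here: multiplicative random-effects scale floored at 1
  expect_equal(res$estimate$se, res$estimate$se_fixed)

  # random 2-5 SNP cases against the independent sum-based oracle
  set.seed(11)
  for (n in 2:5) {
    for (rep in 1:20) {
      bx <- stats::rnorm(n, 0, 0.15); bx[abs(bx) < 0.02] <- 0.05
      by <- stats::rnorm(n, 0.1 * bx, 0.01)
      sy <- stats::runif(n, 0.005, 0.03)
      o <- oracle_ivw(bx, by, sy)
      got <- mr_ivw(make_instruments(bx, by, sy))
      expect_equal(got$estimate$beta, o$beta, tolerance = 1e-12)
      expect_equal(got$estimate$se, o$se_mre, tolerance = 1e-12)
      expect_equal(got$heterogeneity$Q, o$Q, tolerance = 1e-10)
    }
  }
})

test_that("identical ratios give a degenerate homogeneous IVW fit", {
  h <- make_instruments(c(0.1, 0.2, 0.4), 0.3 * c(0.1, 0.2, 0.4),
                        c(0.01, 0.01, 0.02))
  res <- mr_ivw(h)
  expect_equal(res$estimate$beta, 0.3)
  expect_equal(res$heterogeneity$Q, 0, tolerance = 1e-20)
  expect_equal(res$heterogeneity$i2, 0)
  expect_error(mr_ivw(h[1, ]), class = "mrsuite_validation_error")
})

test_that("heterogeneity invariants hold on random data", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    h <- make_instruments(stats::runif(n, 0.05, 0.3),
                          stats::rnorm(n, 0, 0.05),
                          stats::runif(n, 0.005, 0.05))
    het <- heterogeneity(h)
    expect_gte(het$Q, 0)
    expect_equal(het$df, n - 1)
    expect_gte(het$i2, 0)
    expect_lt(het$i2, 1)
  }
})

test_that("Egger recovers an exact affine fit and defines the intercept", {
  bx <- c(0.1, 0.2, 0.3)
  h <- make_instruments(bx, 0.01 + 0.5 * bx, rep(0.01, 3))
  e <- mr_egger(h)
  expect_equal(e$estimate$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept$value, 0.01, tolerance = 1e-10)
  expect_equal(e$intercept$df, 1)
  expect_error(mr_egger(h[1:2, ]), class = "mrsuite_validation_error")
})

test_that("Egger is invariant to instrument allele orientation", {
  set.seed(31)
  n <- 10
  bx <- stats::rnorm(n, 0, 0.15)
  by <- 0.005 + 0.3 * bx + stats::rnorm(n, 0, 0.01)
  h <- make_instruments(bx, by, rep(0.01, n))
  e1 <- mr_egger(h)
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  h2 <- h
  h2$beta_exp <- ifelse(flip, -h$beta_exp, h$beta_exp)
  h2$beta_out <- ifelse(flip, -h$beta_out, h$beta_out)
  e2 <- mr_egger(h2)
  expect_equal(e2$estimate$beta, e1$estimate$beta, tolerance = 1e-12)
  expect_equal(e2$intercept$value, e1$intercept$value, tolerance = 1e-12)
})

test_that("weighted median interpolates breakpoints exactly", {
  expect_equal(weighted_median(c(0.1, 0.2, 0.3), c(0.25, 0.25, 0.5)),
               0.2 + 0.1 * (0.5 - 0.375) / (0.75 - 0.375), tolerance = 1e-12)
  # random cases against the loop-based oracle
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(3:25, 1)
    x <- stats::rnorm(n)
    w <- stats::runif(n, 0.1, 2)
    expect_equal(weighted_median(x, w), oracle_weighted_median(x, w),
                 tolerance = 1e-12)
  }
})

test_that("median estimators agree under equal weights", {
  h <- make_instruments(c(1, 1, 1), c(0.1, 0.2, 0.3), c(0.05, 0.05, 0.05))
  s <- mr_median(h, "simple", n_boot = 200, seed = 1)
  w <- mr_median(h, "weighted", n_boot = 200, seed = 1)
  expect_equal(s$beta, 0.2)
  expect_equal(w$beta, 0.2)
  # property: equal weights => weighted point estimate == simple, any data
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(c(3, 5, 9), 1)
    bx <- stats::runif(n, 0.1, 0.3)
    by <- stats::rnorm(n, 0, 0.05)
    h2 <- make_instruments(bx, by, se_out = 0.07 * bx)  # equal ratio SEs
    expect_equal(mr_median(h2, "weighted", n_boot = 100, seed = 2)$beta,
                 mr_median(h2, "simple", n_boot = 100, seed = 2)$beta,
                 tolerance = 1e-12)
  }
  expect_error(mr_median(h[1:2, ]), class = "mrsuite_validation_error")
})

test_that("median bootstrap SE is seed-reproducible", {
  h <- make_instruments(stats::runif(10, 0.1, 0.3),
                        stats::rnorm(10, 0.02, 0.02),
                        stats::runif(10, 0.005, 0.02))
  a <- mr_median(h, "weighted", n_boot = 300, seed = 99)
  b <- mr_median(h, "weighted", n_boot = 300, seed = 99)
  expect_identical(a, b)
  c <- mr_median(h, "weighted", n_boot = 300, seed = 100)
  expect_false(identical(a$se, c$se))
})

test_that("RAPS reduces to fixed-effect IVW as exposure error vanishes", {
  set.seed(51)
  n <- 20
  bx <- stats::rnorm(n, 0, 0.15); bx[abs(bx) < 0.02] <- 0.05
  by <- stats::rnorm(n, 0.1 * bx, 0.005)
  sy <- rep(0.005, n)
  h <- make_instruments(bx, by, sy, se_exp = rep(1e-8, n))
  raps <- mr_raps(h)
  expect_equal(raps$beta, oracle_ivw(bx, by, sy)$beta, tolerance = 1e-6)
  expect_error(mr_raps(h[1:2, ]), class = "mrsuite_validation_error")
})

test_that("RAPS huber and overdispersed variants behave sensibly", {
  h <- scenario_instruments(n_snps = 60, true_beta = 0.1,
                            pleiotropy = "balanced", alpha_sd = 0.003,
                            palindrome_fraction = 0, seed = 61)
  quad <- mr_raps(h)
  hub <- mr_raps(h, loss = "huber")
  over <- mr_raps(h, overdispersed = TRUE)
  expect_equal(hub$beta, quad$beta, tolerance = 0.05)
  expect_gt(over$tau2, 0)           # balanced pleiotropy inflates tau2
  expect_gt(over$se, 0)
  expect_lt(abs(over$beta - 0.1), 3 * over$se)
})

test_that("estimators are scale- and sign-equivariant", {
  h <- scenario_instruments(n_snps = 40, true_beta = 0.1,
                            palindrome_fraction = 0, seed = 71)
  ests <- function(h) {
    c(ivw = mr_ivw(h)$estimate$beta,
      egger = mr_egger(h)$estimate$beta,
      smed = mr_median(h, "simple", n_boot = 50, seed = 3)$beta,
      wmed = mr_median(h, "weighted", n_boot = 50, seed = 3)$beta,
      raps = mr_raps(h)$beta)
  }
  base <- ests(h)
  scl <- h
  scl$beta_exp <- 2.5 * h$beta_exp
  scl$se_exp <- 2.5 * h$se_exp
  expect_equal(ests(scl), base / 2.5, tolerance = 1e-6)
  neg <- h
  neg$beta_out <- -h$beta_out
  expect_equal(ests(neg), -base, tolerance = 1e-6)
})
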