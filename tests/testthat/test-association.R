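test_that("genotype coding follows the inheritance mode and risk allele", {
  calls <- c("C/C", "C/T", "T/T", "./.")
  expect_equal(code_genotypes(calls, "T", "additive"), c(0, 1, 2, NA))
  expect_equal(code_genotypes(calls, "T", "dominant"), c(0, 1, 1, NA))
  expect_equal(code_genotypes(calls, "T", "recessive"), c(0, 0, 1, NA))
  expect_equal(code_genotypes(calls, "C", "additive"), c(2, 1, 0, NA))
  expect_error(code_genotypes(calls, "G", "additive",
                              alleles = c("C", "T")), "risk allele")
  expect_error(code_genotypes(c("A/A"), "C", "additive",
                              alleles = c("C", "T")), "declared alleles")
})

test_that("additive coding equals dominant plus recessive coding per subject", {
  set.seed(21)
  calls <- sample(c("G/G", "G/T", "T/T", "./."), 200, replace = TRUE)
  add <- code_genotypes(calls, "T", "additive")
  dom <- code_genotypes(calls, "T", "dominant")
  rec <- code_genotypes(calls, "T", "recessive")
  expect_equal(add, dom + rec)
})

test_that("least-squares fits match hand-derived solutions", {
  x <- 1:10
  f <- fit_linear_model(2 * x + 1, cbind(1, x = x))
  expect_equal(f$coefficients$beta, c(1, 2), tolerance = 1e-10)
  expect_equal(f$r2, 1)

  f2 <- fit_linear_model(c(1, 2, 3, 4), cbind(1, x = c(0, 0, 1, 1)))
  expect_equal(f2$coefficients$beta, c(1.5, 2.0), tolerance = 1e-12)
  expect_equal(f2$r2, 0.8, tolerance = 1e-12)

  y <- c(3, 1, 4, 1, 5)
  f3 <- fit_linear_model(y, matrix(1, 5, 1,
                                   dimnames = list(NULL, "(Intercept)")))
  expect_equal(f3$coefficients$beta, mean(y))
  expect_equal(f3$r2, 0)
})

test_that("degenerate designs are rejected with informative errors", {
  x <- rnorm(10)
  expect_error(fit_linear_model(rep(1, 10), cbind(1, x = x)),
               "zero-variance response")
  X <- cbind(`(Intercept)` = 1, a = x, b = 2 * x)
  expect_error(fit_linear_model(rnorm(10), X), "b")
})

test_that("R-squared never decreases when a predictor is added", {
  set.seed(31)
  for (i in 1:20) {
    n <- 40
    X1 <- cbind(1, x1 = rnorm(n))
    X2 <- cbind(X1, x2 = rnorm(n))
    y <- rnorm(n)
    expect_gte(fit_linear_model(y, X2)$r2 - fit_linear_model(y, X1)$r2,
               -1e-12)
  }
})

test_that("coefficient inference agrees with stats::lm", {
  set.seed(41)
  n <- 60
  X <- cbind(1, a = rnorm(n), b = rnorm(n))
  y <- 1 + 0.5 * X[, "a"] + rnorm(n)
  f <- fit_linear_model(y, X)
  ref <- summary(lm(y ~ X[, "a"] + X[, "b"]))
  expect_equal(f$coefficients$beta, unname(ref$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(f$coefficients$se, unname(ref$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(f$coefficients$p, unname(ref$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(f$r2, ref$r.squared, tolerance = 1e-10)
})

test_that("associate_snp detects a simulated recessive effect and drops missing calls", {
  co <- simulate_cohort(one_snp_config(600, share = 0.06, seed = 13))
  res <- associate_snp(co$genotypes, co$phenotypes, co$snps[1, ], "total",
                       mode = "recessive", risk_allele = "T")
  expect_lt(res$p_unadjusted, 0.01)
  expect_gt(res$beta, 0)
  expect_equal(res$n, 600)

  gm <- inject_missingness(co$genotypes, 0.15, seed = 99)
  res_m <- associate_snp(gm, co$phenotypes, co$snps[1, ], "total",
                         mode = "recessive", risk_allele = "T")
  expect_equal(res_m$n, sum(gm[, "rs0001"] != "./."))
})

test_that("adjusted and unadjusted genotype effects agree when covariates are independent", {
  set.seed(17)
  diffs <- ses <- numeric(40)
  for (i in 1:40) {
    co <- simulate_cohort(one_snp_config(300, share = 0.03, seed = 1000 + i))
    r <- associate_snp(co$genotypes, co$phenotypes, co$snps[1, ], "total",
                       mode = "recessive", risk_allele = "T", adjust = TRUE)
    diffs[i] <- r$beta_adjusted - r$beta
    ses[i] <- r$se
  }
  # genotype orthogonal to covariates: expected difference is zero
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("stratified means report the per-genotype phenotype ladder", {
  gm <- geno(matrix(c("T/T", "T/T", "C/T", "C/C", "C/T"), ncol = 1),
             snp_ids = "rs9")
  ph <- pheno_stub(c(28, 32, 20, 25, 22))
  snp <- snp_info("rs9", "G", "C > T")
  sm <- stratified_means(gm, ph, snp, "total")
  expect_equal(sm$class, c("hom_major", "het", "hom_minor"))
  tt <- sm[sm$genotype == "TT", ]
  expect_equal(tt$n, 2)
  expect_equal(tt$mean, 30)
  expect_equal(tt$sd, 2.8284271, tolerance = 1e-6)

  # invariant to sample order
  perm <- c(3, 1, 5, 2, 4)
  gm2 <- geno(matrix(gm[perm, 1], ncol = 1),
              sample_ids = rownames(gm)[perm], snp_ids = "rs9")
  expect_equal(stratified_means(gm2, ph[perm, ], snp, "total"), sm)

  # empty class reported with n = 0
  gm3 <- geno(matrix(c("C/C", "C/C", "C/T"), ncol = 1), snp_ids = "rs9")
  sm3 <- stratified_means(gm3, pheno_stub(c(20, 22, 25)), snp, "total")
  expect_equal(sm3$n[sm3$class == "hom_minor"], 0)
  expect_true(is.na(sm3$mean[sm3$class == "hom_minor"]))
})

test_that("contingency chi-square reproduces the cohort characteristics test", {
  marital <- matrix(c(151, 54, 54, 39, 15, 13), nrow = 3)
  res <- contingency_chi_square(marital)
  expect_equal(res$p_value, 0.9447, tolerance = 2e-3)
  expect_equal(res$df, 2)

  # identical row proportions: no association at all
  flat <- matrix(c(10, 20, 30, 60), nrow = 2)
  res_flat <- contingency_chi_square(flat)
  expect_equal(res_flat$chi_square, 0, tolerance = 1e-12)
  expect_equal(res_flat$p_value, 1)

  res22 <- contingency_chi_square(matrix(c(10, 20, 20, 10), nrow = 2))
  expect_equal(res22$chi_square, 6.666667, tolerance = 1e-6)
  expect_equal(res22$df, 1)

  # transpose invariance
  expect_equal(contingency_chi_square(t(marital))$chi_square,
               res$chi_square)
  expect_error(contingency_chi_square(matrix(c(0, 0, 3, 4), nrow = 2)),
               "marginal")
})

test_that("pooled t test matches hand computation from raw data and summaries", {
  same <- two_sample_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742346, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0213115, tolerance = 1e-5)

  # summary entry point is identical to the raw entry point
  s <- two_sample_t(summary_x = c(3, 2, 1), summary_y = c(3, 5, 1))
  expect_equal(s$t, r$t, tolerance = 1e-12)
  expect_equal(s$p_value, r$p_value, tolerance = 1e-12)

  # published age contrast: strongly significant
  age <- two_sample_t(summary_x = c(259, 43.2, 7.2),
                      summary_y = c(67, 37.8, 6.3))
  expect_lt(age$p_value, 0.001)

  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_t(c(1), c(2, 3)), "n >= 2")
})
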