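test_that("item allocation preserves the target total within item bounds", {
  totals <- c(0, 1, 13, 14, 15, 27, 41, 55, 56)
  items <- allocate_items(totals)
  expect_equal(unname(rowSums(items)), totals)
  expect_true(all(items >= 0 & items <= 4))
  expect_error(allocate_items(57), "0..56")
  expect_error(allocate_items(-1), "0..56")
})

test_that("identical (config, seed) gives identical cohorts", {
  cfg <- one_snp_config(120, share = 0.04, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$latent, b$truth$latent)
  # a different seed changes the draw
  c2 <- simulate_cohort(one_snp_config(120, share = 0.04, seed = 78))
  expect_false(identical(unclass(a$genotypes), unclass(c2$genotypes)))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(prop_male = 1.2), "prop_male")
  expect_error(cohort_config(residual_sd = 0), "residual_sd")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(ascertainment = 1.5), "ascertainment")
  expect_error(snp_sim_spec("rs1", "A", "A", 0.3), "distinct")
  expect_error(snp_sim_spec("rs1", "A", "G", 0.6), "maf")
  expect_error(snp_sim_spec("rs1", "A", "G", 0.3, risk_allele = "T"),
               "risk_allele")
})

test_that("simulated genotypes match the configured allele frequency and HWE", {
  co <- simulate_cohort(one_snp_config(2000, maf = 0.3, share = 0, seed = 3))
  af <- allele_frequencies(co$genotypes, "rs0001")
  expect_lt(abs(af$maf - 0.3), 0.035)  # ~4.8 binomial SDs at n = 2000
  snp <- co$snps[1, ]
  al <- parse_alleles(snp$alleles)
  cts <- hucgrs:::genotype_counts(co$genotypes, "rs0001", al["major"],
                                  al["minor"])
  expect_gt(hwe_test(cts)$p_value, 1e-4)
})

test_that("covariate distributions follow the configured sex-specific parameters", {
  co <- simulate_cohort(cohort_config(n_subjects = 4000, seed = 15))
  ph <- co$phenotypes
  expect_equal(mean(ph$sex == "male"), 259 / 326, tolerance = 0.03)
  expect_equal(mean(ph$age[ph$sex == "male"]), 43.2, tolerance = 0.5)
  expect_equal(mean(ph$age[ph$sex == "female"]), 37.8, tolerance = 0.8)
  expect_equal(mean(ph$bmi[ph$sex == "male"]), 23.0, tolerance = 0.3)
  expect_true(all(ph$total >= 0 & ph$total <= 56))
  expect_equal(mean(ph$total), 27, tolerance = 1)
})

test_that("extreme sampling keeps the upper tail and is recorded in truth", {
  co <- simulate_cohort(one_snp_config(400, share = 0, seed = 19))
  cut <- apply_extreme_sampling(co, 0.5)
  n_kept <- nrow(cut$phenotypes)
  expect_gte(n_kept, 180)
  expect_lte(n_kept, 240)
  expect_true(all(cut$phenotypes$total >= min(cut$phenotypes$total)))
  expect_gte(min(cut$phenotypes$total), median(co$phenotypes$total) - 1)
  expect_equal(cut$truth$ascertainment, 0.5)
  expect_equal(nrow(cut$genotypes), n_kept)
  expect_error(apply_extreme_sampling(co, 0), "quantile")
  expect_error(apply_extreme_sampling(co, 1), "quantile")
})

test_that("phenotype truncation attenuates the fitted genotype effect", {
  betas_full <- betas_cut <- numeric(30)
  for (i in 1:30) {
    co <- simulate_cohort(one_snp_config(500, mode = "additive",
                                         share = 0.05, seed = 3000 + i))
    cut <- apply_extreme_sampling(co, 0.5)
    fit_f <- associate_snp(co$genotypes, co$phenotypes, co$snps[1, ],
                           "total", mode = "additive", risk_allele = "T",
                           adjust = FALSE)
    fit_c <- associate_snp(cut$genotypes, cut$phenotypes, co$snps[1, ],
                           "total", mode = "additive", risk_allele = "T",
                           adjust = FALSE)
    betas_full[i] <- fit_f$beta
    betas_cut[i] <- fit_c$beta
  }
  expect_lt(mean(betas_cut), mean(betas_full))
})

test_that("injected missingness hits the configured rate and is seed-stable", {
  co <- simulate_cohort(one_snp_config(200, share = 0, seed = 33))
  expect_identical(inject_missingness(co$genotypes, 0), co$genotypes)

  big <- geno(matrix("A/G", nrow = 100, ncol = 100))
  masked <- inject_missingness(big, 0.1, seed = 44)
  frac <- mean(masked == "./.")
  ci_half <- 2.576 * sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), ci_half)
  expect_identical(inject_missingness(big, 0.1, seed = 44), masked)
  expect_error(inject_missingness(big, 1), "rate")
})

test_that("configured effect sizes are recovered by the matching fit", {
  # additive effect, moderate n: mean fitted beta within Monte-Carlo error
  reps <- 100
  betas <- numeric(reps)
  eff <- effect_for_variance_share(0.3, "additive", 0.04, 9.5)
  for (i in seq_len(reps)) {
    cfg <- cohort_config(
      n_subjects = 1000,
      snp_specs = list(snp_sim_spec("rs0001", "C", "T", 0.3, "additive",
                                    effect_size = eff, gene = "G")),
      residual_sd = 9.5, seed = 5000 + i)
    co <- simulate_cohort(cfg)
    r <- associate_snp(co$genotypes, co$phenotypes, co$snps[1, ], "total",
                       mode = "additive", risk_allele = "T", adjust = FALSE)
    betas[i] <- r$beta
  }
  mc_se <- sd(betas) / sqrt(reps)
  expect_lt(abs(mean(betas) - eff), 3 * mc_se)
})
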