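# Cohorts whose genotype-stratified means mimic the published ladder
# patterns, for checking risk-allele assignment.
ladder_cohort <- function(means, calls_by_class, n_per = 40, jitter_sd = 1,
                          seed = 5) {
  set.seed(seed)
  calls <- rep(calls_by_class, each = n_per)
  total <- round(rep(means, each = n_per) +
                   rnorm(length(calls), 0, jitter_sd))
  list(gm = geno(matrix(calls, ncol = 1), snp_ids = "rsX"),
       ph = pheno_stub(total))
}

test_that("recessive risk assignment isolates the homozygote far from the heterozygotes", {
  snp <- snp_info("rsX", "GENE", "C > T")

  # high isolated homozygote (TT): recessive risk coding TT -> 1
  hi <- ladder_cohort(c(26.46, 25.37, 30.64), c("C/C", "C/T", "T/T"))
  rc_hi <- assign_risk_coding(hi$gm, hi$ph, snp, "total", "recessive")
  expect_equal(unname(rc_hi$map[c("C/C", "C/T", "T/T")]), c(0L, 0L, 1L))
  expect_equal(rc_hi$risk_allele, "T")

  # low isolated homozygote (TT): carriers of the other allele are risk
  lo <- ladder_cohort(c(26.97, 27.84, 17.14), c("C/C", "C/T", "T/T"))
  rc_lo <- assign_risk_coding(lo$gm, lo$ph, snp, "total", "recessive")
  expect_equal(unname(rc_lo$map[c("C/C", "C/T", "T/T")]), c(1L, 1L, 0L))
  expect_equal(rc_lo$risk_allele, "C")
})

test_that("additive risk assignment follows the monotone genotype ladder", {
  snp <- snp_info("rsX", "GENE", "C > T")
  mono <- ladder_cohort(c(25.35, 27.63, 30.00), c("C/C", "C/T", "T/T"))
  rc <- assign_risk_coding(mono$gm, mono$ph, snp, "total", "additive")
  expect_equal(rc$risk_allele, "T")
  expect_equal(unname(rc$map[c("C/C", "C/T", "T/T")]), c(0L, 1L, 2L))
})

test_that("exactly tied stratified means raise a tie error", {
  snp <- snp_info("rsX", "GENE", "C > T")
  gm <- geno(matrix(c("C/C", "C/C", "T/T", "T/T"), ncol = 1),
             snp_ids = "rsX")
  ph <- pheno_stub(c(20, 30, 20, 30))
  expect_error(assign_risk_coding(gm, ph, snp, "total", "additive"), "tie")
})

test_that("best_fit picks the mode with the smallest genotype p-value", {
  cfg <- one_snp_config(800, maf = 0.45, mode = "recessive", share = 0.08,
                        seed = 23)
  co <- simulate_cohort(cfg)
  rc <- assign_risk_coding(co$genotypes, co$phenotypes, co$snps[1, ],
                           "total", "best_fit")
  expect_equal(rc$mode, "recessive")
  expect_equal(unname(rc$map[c("C/C", "C/T", "T/T")]), c(0L, 0L, 1L))
})

test_that("published panel genotype combinations map to the printed scores", {
  model <- craving_risk_model()
  gm <- geno(rbind(
    c("T/T", "C/C", "C/C", "G/G", "T/T"),   # no risk components
    c("C/C", "T/T", "T/T", "T/T", "C/C"),   # every risk component
    c("C/T", "C/T", "C/T", "G/T", "C/T")),  # het everywhere
    snp_ids = names(model$codings))
  grs <- compute_grs(gm, model)
  expect_equal(grs$grs, c(0, 6, 2))
  expect_equal(model$max_score, 6)
})

test_that("GRS is monotone in per-SNP codes and invariant to SNP order", {
  model <- craving_risk_model()
  set.seed(61)
  lv <- list(c("C/C", "C/T", "T/T"), c("C/C", "C/T", "T/T"),
             c("C/C", "C/T", "T/T"), c("G/G", "G/T", "T/T"),
             c("C/C", "C/T", "T/T"))
  calls <- vapply(lv, sample, character(30), size = 30, replace = TRUE)
  gm <- geno(calls, snp_ids = names(model$codings))
  grs <- compute_grs(gm, model)

  # flipping one genotype to a higher-coded one never lowers the total
  for (i in 1:20) {
    s <- sample.int(30, 1); j <- sample.int(5, 1)
    rc <- model$codings[[j]]
    cur <- gm[s, j]
    higher <- names(rc$map)[rc$map > rc$map[[cur]]]
    if (!length(higher)) next
    gm2 <- unclass(gm)
    gm2[s, j] <- higher[1]
    gm2 <- geno(gm2, sample_ids = rownames(gm), snp_ids = colnames(gm))
    expect_gte(compute_grs(gm2, model)$grs[s], grs$grs[s])
  }

  perm <- c(4, 1, 5, 3, 2)
  model_perm <- risk_model(model$codings[perm])
  expect_equal(compute_grs(gm, model_perm)$grs, grs$grs)
})

test_that("missing component genotypes follow the missing policy", {
  model <- craving_risk_model()
  gm <- geno(rbind(c("C/C", "T/T", "T/T", "T/T", "C/C"),
                   c("./.", "T/T", "T/T", "T/T", "C/C")),
             snp_ids = names(model$codings))
  excl <- compute_grs(gm, model, missing_policy = "exclude")
  expect_equal(excl$grs, c(6, NA))
  expect_equal(excl$n_missing, c(0, 1))
  part <- compute_grs(gm, model, missing_policy = "partial")
  expect_equal(part$grs, c(6, 5))
  expect_error(compute_grs(geno(matrix("A/A", 1, 1), snp_ids = "rs2240158"),
                           risk_model(model$codings[1])), "not covered")
})

test_that("trend test recovers a simulated dose-response effect", {
  set.seed(71)
  n <- 500
  score <- sample(0:6, n, replace = TRUE)
  total <- pmin(pmax(round(20 + 2 * score + rnorm(n, 0, 5)), 0), 56)
  ph <- pheno_stub(total)
  grs <- data.frame(sample_id = ph$sample_id, grs = score, n_missing = 0)
  tr <- grs_trend_test(grs, ph, "total")
  expect_equal(tr$beta, 2, tolerance = 0.25)
  expect_lt(tr$p_trend, 1e-10)
  expect_equal(nrow(tr$levels), 7)

  expect_error(grs_trend_test(
    data.frame(sample_id = ph$sample_id, grs = 1, n_missing = 0), ph,
    "total"), "constant")
})

test_that("per-level mean ladder is monotone for a large positive simulated effect", {
  set.seed(73)
  n <- 5000
  score <- sample(0:6, n, replace = TRUE)
  total <- pmin(pmax(round(18 + 2.5 * score + rnorm(n, 0, 5)), 0), 56)
  ph <- pheno_stub(total)
  grs <- data.frame(sample_id = ph$sample_id, grs = score, n_missing = 0)
  tr <- grs_trend_test(grs, ph, "total")
  expect_true(all(diff(tr$levels$mean) > 0))
})

test_that("combined report has one row per SNP plus the combined-GRS row", {
  co <- simulate_cohort(hucgrs:::default_sim_config(n_subjects = 250,
                                                    seed = 29,
                                                    null_snps = FALSE))
  model <- craving_risk_model()
  rep4 <- combined_report(co$genotypes, co$phenotypes, model, co$snps)
  expect_equal(nrow(rep4), 6)
  expect_equal(rep4$term[6], "combined_grs")
  expect_true(all(paste0("r2_", c("total", "urge", "ability")) %in%
                    names(rep4)))
  # regenerating from the same inputs is identical
  expect_identical(rep4,
                   combined_report(co$genotypes, co$phenotypes, model,
                                   co$snps))
  # a single-SNP model's combined row equals that SNP's own row
  m1 <- risk_model(model$codings[2])
  r1 <- combined_report(co$genotypes, co$phenotypes, m1, co$snps)
  expect_equal(unlist(r1[1, grep("^(r2|p)_", names(r1))]),
               unlist(r1[2, grep("^(r2|p)_", names(r1))]),
               tolerance = 1e-12)
})

test_that("risk model TSV round-trips", {
  model <- craving_risk_model()
  path <- tempfile(fileext = ".tsv")
  write_risk_model(model, path)
  back <- read_risk_model(path)
  expect_equal(back$max_score, 6)
  for (id in names(model$codings)) {
    expect_equal(back$codings[[id]]$map, model$codings[[id]]$map)
    expect_equal(back$codings[[id]]$mode, model$codings[[id]]$mode)
  }
})
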