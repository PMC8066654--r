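## Synthetic genotype-phenotype cohorts with known truth.
##
## The generator emulates the statistical structure the association
## analysis assumes: biallelic genotypes drawn from Hardy-Weinberg
## proportions at a configured minor allele frequency, covariates (sex,
## age, BMI) with sex-specific Gaussian distributions matching a
## methadone-maintenance cohort, a latent craving phenotype that is
## linear in the mode-coded genotypes and covariates with Gaussian
## residual noise, and discretization of the latent total onto the 14
## questionnaire items. Optional extreme-phenotype ascertainment and
## genotype missingness mirror the study design.

#' Specification of one simulated SNP
#'
#' @param snp_id identifier.
#' @param major_allele,minor_allele distinct single-base alleles.
#' @param maf minor allele frequency, in (0, 0.5].
#' @param mode inheritance mode of the phenotype effect.
#' @param effect_size phenotype units per coded-genotype unit.
#' @param risk_allele allele whose coded dosage increases the phenotype;
#'   defaults to the minor allele.
#' @param gene,pathway optional annotation carried into the cohort's SNP
#'   table.
#' @return list of class \code{snp_sim_spec}.
#' @export
snp_sim_spec <- function(snp_id, major_allele, minor_allele, maf,
                         mode = c("additive", "dominant", "recessive"),
                         effect_size = 0, risk_allele = minor_allele,
                         gene = NA_character_, pathway = NA_character_) {
  mode <- match.arg(mode)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop("maf must be in (0, 0.5]", call. = FALSE)
  }
  if (!major_allele %in% VALID_ALLELES || !minor_allele %in% VALID_ALLELES ||
      major_allele == minor_allele) {
    stop("major_allele and minor_allele must be distinct bases", call. = FALSE)
  }
  if (!risk_allele %in% c(major_allele, minor_allele)) {
    stop("risk_allele must be the major or the minor allele", call. = FALSE)
  }
  structure(list(snp_id = snp_id, major_allele = major_allele,
                 minor_allele = minor_allele, maf = maf, mode = mode,
                 effect_size = effect_size, risk_allele = risk_allele,
                 gene = gene, pathway = pathway),
            class = "snp_sim_spec")
}

#' Effect size for a target variance share
#'
#' Returns the per-code-unit effect beta such that a single SNP with the
#' given minor allele frequency and mode explains approximately the given
#' share of phenotype variance against Gaussian residual noise:
#' beta^2 Var(code) / (beta^2 Var(code) + sigma^2) = share, with
#' Var(code) from Hardy-Weinberg proportions.
#'
#' @param maf minor allele frequency.
#' @param mode inheritance mode.
#' @param share target variance proportion, in (0, 1).
#' @param residual_sd residual standard deviation sigma.
#' @param risk_is_minor logical; is the risk allele the minor one?
#' @return the effect size in phenotype units per code unit.
#' @export
effect_for_variance_share <- function(maf, mode, share, residual_sd,
                                      risk_is_minor = TRUE) {
  stopifnot(share > 0, share < 1, residual_sd > 0)
  q <- if (risk_is_minor) maf else 1 - maf
  var_code <- switch(mode,
                     additive = 2 * q * (1 - q),
                     dominant = (q^2 + 2 * q * (1 - q)) *
                       (1 - q^2 - 2 * q * (1 - q)),
                     recessive = q^2 * (1 - q^2),
                     stop("unknown mode", call. = FALSE))
  sqrt(share / (1 - share) * residual_sd^2 / var_code)
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the published cohort's composition: n = 326
#' subjects, 79.4\% male, male age 43.2 (SD 7.2) vs female 37.8 (6.3)
#' years, male BMI 23.0 (2.8) vs female 21.6 (2.8) kg/m^2, baseline
#' craving total around 27 with residual SD 9.5 score units.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param prop_male probability a subject is male.
#' @param age_mean_by_sex,age_sd_by_sex,bmi_mean_by_sex,bmi_sd_by_sex
#'   named numeric vectors with elements \code{female} and \code{male}.
#' @param snp_specs list of [snp_sim_spec] objects.
#' @param intercept latent phenotype baseline (score units).
#' @param covariate_effects named vector of phenotype units per covariate
#'   unit (\code{age}, \code{sex} with male = 1, \code{bmi}); default all
#'   zero.
#' @param residual_sd residual standard deviation (> 0).
#' @param missing_rate per-call missingness probability in [0, 1).
#' @param ascertainment optional lower-tail truncation quantile in (0, 1):
#'   only subjects above that total-score quantile are retained,
#'   emulating recruitment from the severe extreme of the phenotype
#'   range.
#' @param seed integer seed; one global seed feeds fixed substreams for
#'   covariates, genotypes, noise and missingness.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 326, prop_male = 259 / 326,
                          age_mean_by_sex = c(female = 37.8, male = 43.2),
                          age_sd_by_sex = c(female = 6.3, male = 7.2),
                          bmi_mean_by_sex = c(female = 21.6, male = 23.0),
                          bmi_sd_by_sex = c(female = 2.8, male = 2.8),
                          snp_specs = list(), intercept = 27,
                          covariate_effects = c(age = 0, sex = 0, bmi = 0),
                          residual_sd = 9.5, missing_rate = 0,
                          ascertainment = NULL, seed = 1L) {
  cfg <- structure(list(n_subjects = n_subjects, prop_male = prop_male,
                        age_mean_by_sex = age_mean_by_sex,
                        age_sd_by_sex = age_sd_by_sex,
                        bmi_mean_by_sex = bmi_mean_by_sex,
                        bmi_sd_by_sex = bmi_sd_by_sex,
                        snp_specs = snp_specs, intercept = intercept,
                        covariate_effects = covariate_effects,
                        residual_sd = residual_sd,
                        missing_rate = missing_rate,
                        ascertainment = ascertainment,
                        seed = as.integer(seed)),
                   class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort config: field '", field, "' ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 2) {
    fail("n_subjects", "must be >= 2")
  }
  if (cfg$prop_male < 0 || cfg$prop_male > 1) {
    fail("prop_male", "must be a probability in [0, 1]")
  }
  for (f in c("age_mean_by_sex", "age_sd_by_sex", "bmi_mean_by_sex",
              "bmi_sd_by_sex")) {
    v <- cfg[[f]]
    if (!all(c("female", "male") %in% names(v))) {
      fail(f, "needs named elements 'female' and 'male'")
    }
  }
  if (any(cfg$age_sd_by_sex < 0) || any(cfg$bmi_sd_by_sex < 0)) {
    fail("age_sd_by_sex/bmi_sd_by_sex", "must be non-negative")
  }
  if (!is.numeric(cfg$residual_sd) || cfg$residual_sd <= 0) {
    fail("residual_sd", "must be > 0")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    fail("missing_rate", "must be in [0, 1)")
  }
  if (!is.null(cfg$ascertainment) &&
      (cfg$ascertainment <= 0 || cfg$ascertainment >= 1)) {
    fail("ascertainment", "must be a quantile in (0, 1)")
  }
  for (sp in cfg$snp_specs) {
    if (!inherits(sp, "snp_sim_spec")) {
      fail("snp_specs", "must be a list of snp_sim_spec objects")
    }
  }
  ids <- vapply(cfg$snp_specs, `[[`, character(1), "snp_id")
  if (anyDuplicated(ids)) fail("snp_specs", "contains duplicate snp ids")
  invisible(cfg)
}

## Deterministic substream seeds from the single global seed, so that the
## genotype draw is unchanged when, say, only the noise parameters move.
substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 4L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  setNames(ss, c("covariates", "genotypes", "noise", "missingness"))
}

#' Distribute a total craving score over the 14 items
#'
#' Round-robin allocation: the target total (an integer in 0..56) is
#' distributed over items 1-14 in increments of 1, each item capped at 4,
#' so the item scores always sum exactly to the target.
#'
#' @param total integer vector of targets, each in 0..56.
#' @return integer matrix, one row per target, 14 columns.
#' @export
allocate_items <- function(total) {
  total <- as.integer(total)
  if (any(total < 0 | total > 56)) {
    stop("totals must be in 0..56", call. = FALSE)
  }
  base <- total %/% HUC_N_ITEMS
  rem <- total %% HUC_N_ITEMS
  items <- matrix(rep(base, HUC_N_ITEMS), ncol = HUC_N_ITEMS)
  for (i in seq_along(total)) {
    if (rem[i] > 0) items[i, seq_len(rem[i])] <- base[i] + 1L
  }
  storage.mode(items) <- "integer"
  colnames(items) <- PHENO_ITEM_COLS
  items
}

#' Simulate a genotype-phenotype cohort
#'
#' Draws genotypes per SNP from Hardy-Weinberg trinomial proportions
#' (p^2, 2pq, q^2), covariates from the configured sex-specific
#' distributions, a latent craving phenotype that is linear in the coded
#' genotypes and covariates plus Gaussian noise, clips the latent total
#' to the questionnaire range [0, 56], and allocates it over the 14
#' items so the scored total equals the clipped latent value. Output is
#' deterministic given (config, seed).
#'
#' @param config a [cohort_config].
#' @return list of class \code{sim_cohort} with components
#'   \code{genotypes} ([genotype_matrix]), \code{phenotypes} (phenotype
#'   table with item columns), \code{snps} ([snp_info]), and \code{truth}
#'   (config, substream seeds, realized per-SNP minor allele
#'   frequencies, latent phenotype, true codes).
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_subjects)
  ss <- substream_seeds(config$seed)
  sample_ids <- sprintf("S%04d", seq_len(n))

  # covariates
  set.seed(ss[["covariates"]])
  male <- rbinom(n, 1L, config$prop_male)
  sex <- ifelse(male == 1L, "male", "female")
  age <- rnorm(n, config$age_mean_by_sex[sex], config$age_sd_by_sex[sex])
  bmi <- rnorm(n, config$bmi_mean_by_sex[sex], config$bmi_sd_by_sex[sex])
  age <- pmax(age, 18)
  bmi <- pmax(bmi, 14)

  # genotypes under HWE
  set.seed(ss[["genotypes"]])
  n_snp <- length(config$snp_specs)
  calls <- matrix(MISSING_CALL, nrow = n, ncol = max(n_snp, 0L))
  codes <- matrix(0, nrow = n, ncol = max(n_snp, 0L))
  realized_maf <- numeric(n_snp)
  for (j in seq_len(n_snp)) {
    sp <- config$snp_specs[[j]]
    q <- sp$maf
    probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)  # 0/1/2 minor copies
    n_minor <- sample(0:2, n, replace = TRUE, prob = probs)
    lv <- genotype_levels(sp$major_allele, sp$minor_allele)
    calls[, j] <- lv[n_minor + 1L]
    codes[, j] <- code_genotypes(calls[, j], sp$risk_allele, sp$mode)
    realized_maf[j] <- sum(n_minor) / (2 * n)
  }

  # latent phenotype
  set.seed(ss[["noise"]])
  eff <- vapply(config$snp_specs, `[[`, numeric(1), "effect_size")
  genetic <- if (n_snp) drop(codes %*% eff) else rep(0, n)
  ce <- config$covariate_effects
  cov_part <- ce[["age"]] * age + ce[["sex"]] * male + ce[["bmi"]] * bmi
  latent <- config$intercept + genetic + cov_part +
    rnorm(n, 0, config$residual_sd)
  target <- pmin(pmax(round(latent), 0L), 56L)
  items <- allocate_items(target)

  phenotypes <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                           bmi = bmi, stringsAsFactors = FALSE)
  phenotypes <- cbind(phenotypes, as.data.frame(items))
  phenotypes <- score_huc_table(phenotypes)

  snp_ids <- vapply(config$snp_specs, `[[`, character(1), "snp_id")
  genotypes <- genotype_matrix(calls, sample_ids = sample_ids,
                               snp_ids = snp_ids)
  snps <- if (n_snp) {
    snp_info(snp_id = snp_ids,
             gene = vapply(config$snp_specs, `[[`, character(1), "gene"),
             alleles = vapply(config$snp_specs, function(sp) {
               paste(sp$major_allele, ">", sp$minor_allele)
             }, character(1)),
             pathway = vapply(config$snp_specs, `[[`, character(1),
                              "pathway"))
  } else NULL

  cohort <- structure(list(
    genotypes = genotypes, phenotypes = phenotypes, snps = snps,
    truth = list(config = config, substreams = ss,
                 realized_maf = setNames(realized_maf, snp_ids),
                 latent = latent, codes = codes,
                 ascertainment = NULL)), class = "sim_cohort")

  if (config$missing_rate > 0) {
    cohort$genotypes <- inject_missingness(cohort$genotypes,
                                           config$missing_rate,
                                           seed = ss[["missingness"]])
  }
  if (!is.null(config$ascertainment)) {
    cohort <- apply_extreme_sampling(cohort, config$ascertainment)
  }
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("simulated cohort:", nrow(x$phenotypes), "subjects,",
      ncol(x$genotypes), "SNPs\n")
  if (!is.null(x$truth$ascertainment)) {
    cat("  extreme-sampled above the", x$truth$ascertainment,
        "total-score quantile\n")
  }
  invisible(x)
}

#' Retain the upper extreme of the phenotype distribution
#'
#' Keeps subjects whose total craving score is at or above the given
#' cohort quantile, emulating recruitment from the severe margin of the
#' phenotype range. The truncation is recorded in \code{truth}.
#'
#' @param cohort a \code{sim_cohort}.
#' @param quantile lower-tail truncation quantile in (0, 1).
#' @return the truncated \code{sim_cohort}.
#' @export
apply_extreme_sampling <- function(cohort, quantile) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    stop("quantile must be in (0, 1)", call. = FALSE)
  }
  totals <- cohort$phenotypes$total
  thr <- stats::quantile(totals, quantile, na.rm = TRUE, names = FALSE)
  keep <- which(!is.na(totals) & totals >= thr)
  cohort$genotypes <- genotype_matrix(
    unclass(cohort$genotypes)[keep, , drop = FALSE])
  cohort$phenotypes <- cohort$phenotypes[keep, , drop = FALSE]
  rownames(cohort$phenotypes) <- NULL
  cohort$truth$latent <- cohort$truth$latent[keep]
  cohort$truth$codes <- cohort$truth$codes[keep, , drop = FALSE]
  cohort$truth$ascertainment <- quantile
  cohort
}

#' Inject missing genotype calls
#'
#' Independently replaces each call with the missing code \code{"./."}
#' with the given probability, so the expected call rate is 1 - rate.
#'
#' @param genotypes a [genotype_matrix].
#' @param rate missingness probability in [0, 1).
#' @param seed integer seed for the missingness draw.
#' @return the masked [genotype_matrix].
#' @export
inject_missingness <- function(genotypes, rate, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(genotypes)
  set.seed(seed)
  mask <- matrix(runif(length(genotypes)) < rate, nrow = nrow(genotypes))
  out <- unclass(genotypes)
  out[mask] <- MISSING_CALL
  genotype_matrix(out)
}
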