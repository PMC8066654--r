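# Shared fixture builders: everything is generated in code at test time.

# Genotype matrix from a character matrix/vector of calls.
geno <- function(calls, sample_ids = NULL, snp_ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(calls)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(ncol(calls)))
  genotype_matrix(calls, sample_ids = sample_ids, snp_ids = snp_ids)
}

# Minimal scored phenotype table (enough for unadjusted fits and
# stratified means); covariates included for adjusted fits.
pheno_stub <- function(total, sample_ids = sprintf("S%03d", seq_along(total)),
                       age = 40, sex = "male", bmi = 23) {
  data.frame(sample_id = sample_ids, age = age, sex = sex, bmi = bmi,
             total = total, urge = round(total * 0.4),
             ability = total - round(total * 0.4),
             stringsAsFactors = FALSE)
}

# One-SNP cohort configuration with the effect sized to a variance share.
one_snp_config <- function(n, maf = 0.45, mode = "recessive", share = 0.04,
                           residual_sd = 9.5, seed = 1L) {
  eff <- if (share > 0) {
    effect_for_variance_share(maf, mode, share, residual_sd)
  } else 0
  cohort_config(
    n_subjects = n,
    snp_specs = list(snp_sim_spec("rs0001", "C", "T", maf, mode,
                                  effect_size = eff, gene = "GENE1")),
    residual_sd = residual_sd, seed = seed)
}

# Random valid item vectors for property checks.
random_items <- function(n = 1) {
  matrix(sample(0:4, 14 * n, replace = TRUE), ncol = 14)
}
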