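## End-to-end pipeline: simulate (or read) -> QC -> score -> single-SNP
## association -> risk model -> GRS trend -> reports. Every stage writes a
## TSV that parses back through the package's readers; a run log records
## the seed, the configuration echo and the n used at each stage.

#' Parse a flat key/value pipeline configuration file
#'
#' One \code{key = value} assignment per line; blank lines and lines
#' starting with \code{#} are ignored. Recognized keys: \code{genotypes},
#' \code{phenotypes}, \code{snp_info} (input paths; omit all three to
#' simulate), \code{n_subjects}, \code{seed}, \code{maf_min},
#' \code{hwe_alpha}, \code{call_rate_min}, \code{phenotype},
#' \code{mode_policy}, \code{adjust}, \code{alpha},
#' \code{force_include} (comma-separated SNP ids), \code{out_dir}.
#'
#' @param path path to the configuration file.
#' @return a named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) {
      stop("malformed config line: '", ln, "'", call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full association and risk-score pipeline
#'
#' Orchestrates the analysis end to end. Inputs are either files
#' (\code{genotypes}, \code{phenotypes}, \code{snp_info} paths in
#' \code{config}) or, when absent, a cohort simulated from the built-in
#' five-SNP panel truth. Stages: genotype QC (MAF, HWE, call rate) ->
#' questionnaire scoring -> per-SNP association (all three phenotypes,
#' unadjusted and covariate-adjusted) -> risk-coding assignment for SNPs
#' with unadjusted p below \code{alpha} on the target phenotype (plus any
#' \code{force_include} ids) -> GRS and dose-response trend -> combined
#' report. Identical config and seed give identical outputs.
#'
#' @param config named list (see [read_pipeline_config()]); notable
#'   entries: \code{out_dir} (required), \code{seed} (default 1),
#'   \code{phenotype} target for risk-model selection (default
#'   \code{"total"}), \code{alpha} (default 0.05), \code{mode_policy}
#'   (default \code{"best_fit"}), QC thresholds.
#' @return the output directory path, invisibly. Writes qc_report.tsv,
#'   association_results.tsv, stratified_means.tsv, risk_model.tsv,
#'   grs.tsv, combined_report.tsv and run_log.txt.
#' @export
run_pipeline <- function(config) {
  out_dir <- config[["out_dir"]]
  if (is.null(out_dir)) stop("config must name an out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config[["seed"]] %||% 1L)
  alpha <- config[["alpha"]] %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  target_ph <- config[["phenotype"]] %||% "total"
  mode_policy <- config[["mode_policy"]] %||% "best_fit"
  adjust <- is.null(config[["adjust"]]) || as.logical(config[["adjust"]])
  log_lines <- c(paste("hucgrs pipeline, package version",
                       as.character(packageVersion("hucgrs"))),
                 paste("seed:", seed),
                 "config:",
                 paste0("  ", names(config), " = ",
                        vapply(config, function(x)
                          paste(as.character(x), collapse = ","),
                          character(1))))

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config[["genotypes"]])) {
      for (p in c("genotypes", "phenotypes", "snp_info")) {
        if (is.null(config[[p]]) || !file.exists(config[[p]])) {
          stop("input file for '", p, "' not found: ",
               config[[p]] %||% "<unset>", call. = FALSE)
        }
      }
      genotypes <- read_genotype_table(config[["genotypes"]])
      pheno <- read_phenotype_table(config[["phenotypes"]])
      snps_df <- read.delim(config[["snp_info"]], stringsAsFactors = FALSE)
      snps <- snp_info(snps_df$snp_id, snps_df$gene, snps_df$alleles,
                       snps_df$pathway)
    } else {
      cfg <- default_sim_config(n_subjects = config[["n_subjects"]] %||% 326,
                                seed = seed)
      cohort <- simulate_cohort(cfg)
      genotypes <- cohort$genotypes
      pheno <- cohort$phenotypes
      snps <- cohort$snps
    }
    log_lines <- c(log_lines, paste("input: n =", nrow(pheno), "subjects,",
                                    ncol(genotypes), "SNPs"))

    stage <- "qc"
    qc <- qc_filter(genotypes, snps,
                    maf_min = config[["maf_min"]] %||% 0.05,
                    hwe_alpha = config[["hwe_alpha"]] %||% 1e-4,
                    call_rate_min = config[["call_rate_min"]] %||% 0.9)
    write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    snps <- snps[snps$snp_id %in% qc$retained, , drop = FALSE]
    log_lines <- c(log_lines, paste("qc: retained", length(qc$retained),
                                    "of", nrow(qc$report), "SNPs"))
    if (!length(qc$retained)) stop("no SNPs retained after QC",
                                   call. = FALSE)

    stage <- "scoring"
    if (!"total" %in% names(pheno)) pheno <- score_huc_table(pheno)
    n_scored <- sum(!is.na(pheno$total))
    log_lines <- c(log_lines, paste("scoring: n =", n_scored,
                                    "subjects with complete questionnaires"))

    stage <- "association"
    assoc <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
      do.call(rbind, lapply(HUC_PHENOTYPES, function(ph) {
        rc <- assign_risk_coding(genotypes, pheno, snps[i, ], ph,
                                 mode_policy)
        associate_coding(genotypes, pheno, snps[i, ], rc, ph,
                         adjust = adjust)
      }))
    }))
    write_association_results(assoc,
                              file.path(out_dir, "association_results.tsv"))
    strat <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
      stratified_means(genotypes, pheno, snps[i, ], target_ph)
    }))
    write.table(strat, file.path(out_dir, "stratified_means.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines,
                   paste("association:", nrow(assoc), "fits, n range",
                         min(assoc$n), "-", max(assoc$n)))

    stage <- "risk_model"
    target_rows <- assoc[assoc$phenotype == target_ph, ]
    force_inc <- character(0)
    if (!is.null(config[["force_include"]])) {
      force_inc <- trimws(strsplit(as.character(config[["force_include"]]),
                                   ",")[[1]])
    }
    selected <- union(target_rows$snp[target_rows$p_unadjusted < alpha],
                      intersect(force_inc, snps$snp_id))
    if (!length(selected)) {
      log_lines <- c(log_lines,
                     paste0("risk_model: no SNP passed p < ", alpha,
                            " for ", target_ph, "; skipping GRS stage"))
      model <- NULL
    } else {
      codings <- lapply(selected, function(sid) {
        assign_risk_coding(genotypes, pheno,
                           snps[snps$snp_id == sid, ], target_ph,
                           mode_policy)
      })
      model <- risk_model(codings)
      write_risk_model(model, file.path(out_dir, "risk_model.tsv"))
      log_lines <- c(log_lines,
                     paste("risk_model:", length(selected),
                           "SNPs selected (derived in-sample: single-SNP",
                           "and combined estimates are optimistic)"))
    }

    stage <- "grs"
    if (!is.null(model)) {
      grs <- compute_grs(genotypes, model)
      write.table(grs, file.path(out_dir, "grs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      rep4 <- combined_report(genotypes, pheno, model, snps)
      num_cols <- grep("^(r2|p)_", names(rep4))
      rep4[num_cols] <- lapply(rep4[num_cols], render_number)
      write.table(rep4, file.path(out_dir, "combined_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tr <- grs_trend_test(grs, pheno, target_ph)
      log_lines <- c(log_lines,
                     sprintf("grs: n = %d scored, p for trend (%s) = %.4g",
                             sum(!is.na(grs$grs)), target_ph, tr$p_trend))
    }
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(res), call. = FALSE)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Simulation configuration used when the pipeline runs without input
## files: the five-SNP panel with its published codings as truth, each
## SNP contributing ~4% of phenotype variance, plus three null SNPs.
default_sim_config <- function(n_subjects = 326, seed = 1L,
                               share = 0.04, residual_sd = 9.5,
                               null_snps = TRUE) {
  panel <- list(
    list(id = "rs2240158", major = "T", minor = "C", maf = 0.45,
         mode = "dominant", risk = "C", gene = "GRIN3B",
         pathway = "Cognitive function"),
    list(id = "rs3983721", major = "C", minor = "T", maf = 0.45,
         mode = "recessive", risk = "T", gene = "GRIN3A",
         pathway = "Cognitive function"),
    list(id = "rs6583954", major = "T", minor = "C", maf = 0.40,
         mode = "additive", risk = "T", gene = "CYP2C19",
         pathway = "Methadone-metabolizing enzymes"),
    list(id = "rs2129575", major = "G", minor = "T", maf = 0.45,
         mode = "recessive", risk = "T", gene = "TPH2",
         pathway = "Dopamine and serotonin pathway"),
    list(id = "rs174699", major = "C", minor = "T", maf = 0.45,
         mode = "recessive", risk = "C", gene = "COMT",
         pathway = "Dopamine and serotonin pathway"))
  specs <- lapply(panel, function(p) {
    risk_is_minor <- p$risk == p$minor
    eff <- effect_for_variance_share(p$maf, p$mode, share, residual_sd,
                                     risk_is_minor)
    snp_sim_spec(p$id, p$major, p$minor, p$maf, p$mode,
                 effect_size = eff, risk_allele = p$risk, gene = p$gene,
                 pathway = p$pathway)
  })
  if (null_snps) {
    specs <- c(specs, list(
      snp_sim_spec("rs9900001", "A", "G", 0.30, "additive",
                   effect_size = 0, gene = "NULL1", pathway = "none"),
      snp_sim_spec("rs9900002", "C", "T", 0.20, "additive",
                   effect_size = 0, gene = "NULL2", pathway = "none"),
      snp_sim_spec("rs9900003", "G", "T", 0.10, "additive",
                   effect_size = 0, gene = "NULL3", pathway = "none")))
  }
  # keep the expected total near the published cohort mean (~27)
  exp_genetic <- sum(vapply(specs, function(sp) {
    q <- if (sp$risk_allele == sp$minor_allele) sp$maf else 1 - sp$maf
    mean_code <- switch(sp$mode, additive = 2 * q,
                        dominant = q^2 + 2 * q * (1 - q),
                        recessive = q^2)
    sp$effect_size * mean_code
  }, numeric(1)))
  cohort_config(n_subjects = n_subjects, snp_specs = specs,
                intercept = 27 - exp_genetic,
                residual_sd = residual_sd, seed = seed)
}

#' Write a small bundled example dataset
#'
#' Generates a 60-subject, 8-SNP cohort (the five-SNP craving panel with
#' its published codings as simulation truth, plus three null SNPs) and
#' writes genotypes.tsv, phenotypes.csv, snp_info.tsv and the truth
#' risk_model.tsv. Used by the test suite and the documentation examples;
#' regeneration with the same seed is byte-identical.
#'
#' @param outdir writable output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 2026L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- default_sim_config(n_subjects = 60, seed = seed)
  cohort <- simulate_cohort(cfg)
  paths <- c(genotypes = file.path(outdir, "genotypes.tsv"),
             phenotypes = file.path(outdir, "phenotypes.csv"),
             snp_info = file.path(outdir, "snp_info.tsv"),
             risk_model = file.path(outdir, "risk_model.tsv"))
  write_genotype_table(cohort$genotypes, paths[["genotypes"]])
  write_phenotype_table(cohort$phenotypes, paths[["phenotypes"]])
  write.table(as.data.frame(cohort$snps), paths[["snp_info"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_risk_model(craving_risk_model(), paths[["risk_model"]])
  invisible(paths)
}
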