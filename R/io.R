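## Tabular I/O: genotype TSV, phenotype CSV, VCF (read-only), results TSV.
##
## Genotype TSV dialect: tab-separated, header "sample_id" followed by SNP
## ids; each cell an allele pair "A/G" (orientation-free) or "./." for a
## missing call.

PHENO_ITEM_COLS <- paste0("huc", 1:14)
PHENO_REQUIRED <- c("sample_id", "age", "sex", "bmi", PHENO_ITEM_COLS)
PHENO_OPTIONAL <- c("mmt_max_dose", "onset_age", "use_duration",
                    "education", "marital")

#' Read a genotype table
#'
#' Reads the tab-separated genotype dialect: header \code{sample_id} plus one
#' column per SNP, cells \code{"A/G"}-style allele pairs or \code{"./."}.
#' Calls are normalized to alphabetical allele order on input.
#'
#' @param path path to a genotype TSV file.
#' @return a [genotype_matrix].
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty genotype file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "sample_id") {
    stop("genotype table line 1: first column must be 'sample_id', got '",
         header[1], "'", call. = FALSE)
  }
  snp_ids <- header[-1]
  n_col <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop("genotype table line ", bad + 1L, ": expected ", n_col,
         " fields, found ", widths[bad], call. = FALSE)
  }
  sample_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1]
    stop("genotype table line ", which(sample_ids == dup)[2] + 1L,
         ": duplicate sample id '", dup, "'", call. = FALSE)
  }
  calls <- matrix(MISSING_CALL, nrow = length(body), ncol = length(snp_ids))
  for (i in seq_along(body)) {
    row <- body[[i]][-1]
    norm <- tryCatch(normalize_calls(row), error = function(e) e)
    if (inherits(norm, "error")) {
      stop("genotype table line ", i + 1L, ": ", conditionMessage(norm),
           call. = FALSE)
    }
    calls[i, ] <- norm
  }
  genotype_matrix(calls, sample_ids = sample_ids, snp_ids = snp_ids)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: round-tripping a matrix through
#' write and read is the identity.
#'
#' @param genotypes a [genotype_matrix].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  header <- paste(c("sample_id", colnames(genotypes)), collapse = "\t")
  rows <- vapply(seq_len(nrow(genotypes)), function(i) {
    paste(c(rownames(genotypes)[i], genotypes[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Extracts the GT field of biallelic records into the same genotype-matrix
#' representation used by the TSV dialect. Allele indices are mapped to
#' REF/ALT bases, phase separators (\code{|}) are treated as unphased, and
#' \code{./.} becomes a missing call.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param snp_ids SNP (ID column) identifiers to retain.
#' @return a [genotype_matrix] with columns in \code{snp_ids} order.
#' @export
read_vcf_genotypes <- function(path, snp_ids) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  missing_ids <- setdiff(snp_ids, ids)
  if (length(missing_ids)) {
    stop("VCF does not contain requested record(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  calls <- matrix(MISSING_CALL, nrow = length(samples),
                  ncol = length(snp_ids))
  for (j in seq_along(snp_ids)) {
    k <- which(ids == snp_ids[j])[1]
    ref <- unname(fix[k, "REF"])
    alt <- unname(fix[k, "ALT"])
    if (grepl(",", alt, fixed = TRUE) || nchar(ref) != 1L ||
        nchar(alt) != 1L) {
      stop("record ", snp_ids[j], " is not a biallelic SNP (REF=", ref,
           ", ALT=", alt, ")", call. = FALSE)
    }
    allele_of <- c(`0` = ref, `1` = alt)
    g <- gsub("|", "/", gt[k, ], fixed = TRUE)
    call_j <- rep(MISSING_CALL, length(samples))
    ok <- !is.na(g) & g != "./." & g != "."
    if (any(ok)) {
      parts <- strsplit(g[ok], "/", fixed = TRUE)
      call_j[ok] <- vapply(parts, function(p) {
        if (length(p) != 2L || !all(p %in% names(allele_of))) {
          stop("record ", snp_ids[j], ": unsupported GT value", call. = FALSE)
        }
        paste(allele_of[p], collapse = "/")
      }, character(1))
    }
    calls[, j] <- call_j
  }
  genotype_matrix(calls, sample_ids = samples, snp_ids = snp_ids)
}

#' Read a phenotype table
#'
#' Reads the comma-separated phenotype table: required columns
#' \code{sample_id}, \code{age}, \code{sex} (\code{male}/\code{female}),
#' \code{bmi} and the 14 questionnaire items \code{huc1}..\code{huc14}
#' (each integer 0-4, empty for missing); optional clinical columns
#' \code{mmt_max_dose}, \code{onset_age}, \code{use_duration},
#' \code{education}, \code{marital}.
#'
#' @param path path to a phenotype CSV file.
#' @return a validated \code{data.frame}, one row per subject.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PHENO_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("phenotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_phenotypes(df)
  df
}

validate_phenotypes <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id in phenotype table: ",
         df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    bad <- which(!df$sex %in% c("male", "female"))[1]
    stop("phenotype row ", bad, ": sex must be 'male' or 'female'",
         call. = FALSE)
  }
  for (col in c("age", "bmi")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) {
      stop("phenotype row ", bad[1], ": ", col, " must be positive",
           call. = FALSE)
    }
  }
  for (col in PHENO_ITEM_COLS) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v %% 1 != 0 | v < 0 | v > 4))
    if (length(bad)) {
      stop("phenotype row ", bad[1], ", column ", col,
           ": item score must be an integer in 0..4, got ", v[bad[1]],
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Write a phenotype table
#'
#' @param phenotypes a phenotype \code{data.frame} as returned by
#'   [read_phenotype_table()] or [simulate_cohort()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotype_table <- function(phenotypes, path) {
  keep <- intersect(c(PHENO_REQUIRED, PHENO_OPTIONAL), names(phenotypes))
  utils::write.csv(phenotypes[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write association results
#'
#' Writes a deterministic TSV with one row per SNP x phenotype x mode fit:
#' columns snp, gene, pathway, phenotype, mode, n, beta, se, t,
#' p_unadjusted, p_adjusted, r2; numbers rendered with 6 significant
#' digits.
#'
#' @param results a \code{data.frame} of association results
#'   (see [associate_snp()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_association_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("no association results to write", call. = FALSE)
  }
  cols <- c("snp", "gene", "pathway", "phenotype", "mode", "n", "beta",
            "se", "t", "p_unadjusted", "p_adjusted", "r2")
  out <- results[, cols, drop = FALSE]
  num <- c("beta", "se", "t", "p_unadjusted", "p_adjusted", "r2")
  for (col in num) out[[col]] <- render_number(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association results written by [write_association_results()]
#' @param path path to a results TSV.
#' @return a \code{data.frame}.
#' @export
read_association_results <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

## 6 significant digits, "NA" for missing; deterministic.
render_number <- function(x) {
  out <- ifelse(is.na(x), "NA", formatC(signif(x, 6), digits = 6,
                                        format = "g"))
  as.character(out)
}
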