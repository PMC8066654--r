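## Genotype quality control: Hardy-Weinberg equilibrium, allele
## frequencies, duplicate concordance and threshold filtering.

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' The 1-df chi-square goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation (n p^2, 2 n p q, n q^2) at the
#' allele frequency estimated from the counts themselves. No continuity
#' correction is applied. Monomorphic SNPs (estimated allele frequency 0
#' or 1) return a defined result with chi-square 0 and are flagged.
#'
#' @param counts integer vector of length 3: genotype counts ordered
#'   (hom-major, het, hom-minor).
#' @param snp_id optional identifier carried into the result.
#' @return a list of class \code{hwe_result}: \code{snp_id},
#'   \code{observed}, \code{expected}, \code{chi_square}, \code{df} (1),
#'   \code{p_value}, \code{monomorphic}.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE: chi-square 0, p 1
#' hwe_test(c(30, 40, 30))  # chi-square 4, p ~ 0.0455
#' @export
hwe_test <- function(counts, snp_id = NA_character_) {
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0)) {
    stop("counts must be three non-negative genotype counts ",
         "(hom-major, het, hom-minor)", call. = FALSE)
  }
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be at least 1", call. = FALSE)
  p_hat <- (2 * counts[1] + counts[2]) / (2 * n)  # first-allele frequency
  q_hat <- 1 - p_hat
  expected <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
  monomorphic <- p_hat == 0 || p_hat == 1
  if (monomorphic) {
    chi_square <- 0
    p_value <- 1
  } else {
    chi_square <- sum((counts - expected)^2 / expected)
    p_value <- pchisq(chi_square, df = 1, lower.tail = FALSE)
  }
  structure(list(snp_id = snp_id,
                 observed = setNames(counts, c("hom_major", "het", "hom_minor")),
                 expected = setNames(expected, c("hom_major", "het", "hom_minor")),
                 chi_square = chi_square, df = 1L, p_value = p_value,
                 monomorphic = monomorphic),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("HWE goodness-of-fit",
      if (!is.na(x$snp_id)) paste0("(", x$snp_id, ")"), "\n")
  cat("  observed:", paste(round(x$observed, 2), collapse = " / "), "\n")
  cat("  expected:", paste(round(x$expected, 2), collapse = " / "), "\n")
  cat(sprintf("  chi-square = %.4g (1 df), p = %.4g%s\n", x$chi_square,
              x$p_value, if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

## Genotype counts (hom-major, het, hom-minor) for one SNP.
genotype_counts <- function(genotypes, snp_id, major, minor) {
  calls <- genotypes[, snp_id]
  lv <- genotype_levels(major, minor)
  obs <- calls[!is_missing_call(calls)]
  unknown <- setdiff(unique(obs), lv)
  if (length(unknown)) {
    stop("SNP ", snp_id, ": call(s) ", paste(unknown, collapse = ", "),
         " do not use declared alleles ", major, "/", minor, call. = FALSE)
  }
  setNames(vapply(lv, function(g) sum(obs == g), numeric(1)),
           c("hom_major", "het", "hom_minor"))
}

#' Allele frequencies and call rate for one SNP
#'
#' @param genotypes a [genotype_matrix].
#' @param snp_id SNP column to summarize.
#' @return list with \code{maf} (minor = rarer allele frequency among
#'   non-missing calls), \code{call_rate}, and the per-allele \code{freq}
#'   table.
#' @export
allele_frequencies <- function(genotypes, snp_id) {
  if (!snp_id %in% colnames(genotypes)) {
    stop("SNP ", snp_id, " not present in genotype matrix", call. = FALSE)
  }
  calls <- genotypes[, snp_id]
  ok <- !is_missing_call(calls)
  if (!any(ok)) stop("SNP ", snp_id, ": all calls missing", call. = FALSE)
  alleles <- unlist(strsplit(calls[ok], "/", fixed = TRUE))
  freq <- table(alleles) / length(alleles)
  maf <- if (length(freq) < 2L) 0 else min(freq)
  list(maf = as.numeric(maf), call_rate = mean(ok),
       freq = setNames(as.numeric(freq), names(freq)))
}

#' Duplicate-sample genotype concordance
#'
#' Concordance between designated duplicate sample pairs: the fraction of
#' pair-calls where both are non-missing and equal, over pair-calls where
#' both are non-missing. Pairs with no jointly non-missing calls are
#' skipped with a warning.
#'
#' @param genotypes a [genotype_matrix] containing both members of each pair.
#' @param pairs two-column \code{data.frame} (or matrix) of sample-id pairs.
#' @return list with \code{overall} concordance and \code{per_snp}
#'   \code{data.frame} (snp_id, n_compared, concordance).
#' @export
duplicate_concordance <- function(genotypes, pairs) {
  pairs <- as.matrix(pairs)
  ids <- as.vector(pairs)
  if (anyDuplicated(ids)) {
    stop("duplicate pairs must be disjoint", call. = FALSE)
  }
  absent <- setdiff(ids, rownames(genotypes))
  if (length(absent)) {
    stop("sample(s) not in genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  match_mat <- matrix(NA, nrow = nrow(pairs), ncol = ncol(genotypes))
  for (i in seq_len(nrow(pairs))) {
    a <- genotypes[pairs[i, 1], ]
    b <- genotypes[pairs[i, 2], ]
    both <- !is_missing_call(a) & !is_missing_call(b)
    if (!any(both)) {
      warning("pair (", pairs[i, 1], ", ", pairs[i, 2],
              ") has no jointly non-missing calls; skipped", call. = FALSE)
      next
    }
    match_mat[i, both] <- a[both] == b[both]
  }
  per_snp <- data.frame(
    snp_id = colnames(genotypes),
    n_compared = colSums(!is.na(match_mat)),
    concordance = colMeans(match_mat, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  per_snp$concordance[per_snp$n_compared == 0L] <- NA_real_
  overall <- mean(match_mat, na.rm = TRUE)
  list(overall = overall, per_snp = per_snp)
}

#' Filter SNPs on QC thresholds
#'
#' Drops SNPs failing any of: minor allele frequency below \code{maf_min}
#' (the panel's design threshold is MAF > 0.05), HWE goodness-of-fit
#' p-value below \code{hwe_alpha}, or call rate below
#' \code{call_rate_min}. A SNP failing several thresholds is reported with
#' the first reason in the order MAF, HWE, call rate.
#'
#' @param genotypes a [genotype_matrix].
#' @param snps a [snp_info] annotation table covering the matrix columns.
#' @param maf_min,hwe_alpha,call_rate_min thresholds; defaults 0.05,
#'   1e-4 and 0.9.
#' @return list with \code{retained} SNP ids and a \code{report}
#'   \code{data.frame} (snp_id, maf, call_rate, hwe_chi2, hwe_p, status,
#'   reason).
#' @export
qc_filter <- function(genotypes, snps, maf_min = 0.05, hwe_alpha = 1e-4,
                      call_rate_min = 0.9) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  report <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    sid <- snps$snp_id[i]
    al <- parse_alleles(snps$alleles[i])
    af <- allele_frequencies(genotypes, sid)
    cts <- genotype_counts(genotypes, sid, al["major"], al["minor"])
    hw <- hwe_test(cts, snp_id = sid)
    reason <- ""
    if (af$maf < maf_min) {
      reason <- "MAF"
    } else if (!hw$monomorphic && hw$p_value < hwe_alpha) {
      reason <- "HWE"
    } else if (af$call_rate < call_rate_min) {
      reason <- "call_rate"
    }
    data.frame(snp_id = sid, maf = af$maf, call_rate = af$call_rate,
               hwe_chi2 = hw$chi_square, hwe_p = hw$p_value,
               status = if (nzchar(reason)) "dropped" else "retained",
               reason = reason, stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  retained <- report$snp_id[report$status == "retained"]
  if (!length(retained)) {
    warning("no SNPs retained after QC", call. = FALSE)
  }
  list(retained = retained, report = report)
}
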