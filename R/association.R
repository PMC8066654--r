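## Single-SNP quantitative-trait association under inheritance-mode
## codings, plus the descriptive contingency and t tests used for cohort
## characteristics tables.

INHERITANCE_MODES <- c("additive", "dominant", "recessive")
HUC_PHENOTYPES <- c("total", "urge", "ability")
DEFAULT_COVARIATES <- c("age", "sex", "bmi")

#' Numeric genotype coding under an inheritance mode
#'
#' Codes allele-pair calls with respect to a risk allele: additive counts
#' risk-allele copies (0/1/2), dominant marks carriers (>= 1 copy) as 1,
#' recessive marks risk-allele homozygotes as 1. Missing calls code to NA
#' and are excluded from fits downstream.
#'
#' @param calls character vector of normalized calls (\code{"C/T"} style).
#' @param risk_allele the allele whose dosage increases the phenotype.
#' @param mode one of \code{"additive"}, \code{"dominant"},
#'   \code{"recessive"}.
#' @param alleles optional declared pair (character vector of length 2);
#'   when given, calls must use only those alleles and \code{risk_allele}
#'   must be one of them.
#' @return numeric vector of codes with NA for missing calls.
#' @examples
#' code_genotypes(c("C/C", "C/T", "T/T"), risk_allele = "T", "additive")
#' @export
code_genotypes <- function(calls, risk_allele,
                           mode = c("additive", "dominant", "recessive"),
                           alleles = NULL) {
  mode <- match.arg(mode)
  calls <- normalize_calls(calls)
  if (!is.null(alleles)) {
    if (!risk_allele %in% alleles) {
      stop("risk allele ", risk_allele, " is not one of the declared alleles ",
           paste(alleles, collapse = "/"), call. = FALSE)
    }
    valid <- c(genotype_levels(alleles[1], alleles[2]), MISSING_CALL)
    bad <- setdiff(unique(calls), valid)
    if (length(bad)) {
      stop("call(s) ", paste(bad, collapse = ", "),
           " do not use declared alleles ", paste(alleles, collapse = "/"),
           call. = FALSE)
    }
  }
  ok <- !is_missing_call(calls)
  dose <- rep(NA_real_, length(calls))
  parts <- strsplit(calls[ok], "/", fixed = TRUE)
  dose[ok] <- vapply(parts, function(p) sum(p == risk_allele), numeric(1))
  switch(mode,
         additive = dose,
         dominant = as.numeric(dose >= 1),
         recessive = as.numeric(dose == 2))
}

#' Ordinary least-squares fit with coefficient inference
#'
#' Fits a linear model to a design matrix that already contains its
#' intercept column, returning coefficient estimates, standard errors from
#' the unbiased residual variance, two-sided t-based p-values and the
#' coefficient of determination.
#'
#' @param response numeric response vector.
#' @param design numeric design matrix including an intercept column;
#'   column names label the coefficients.
#' @return list of class \code{lm_fit}: \code{coefficients} (data.frame
#'   term/beta/se/t/p), \code{r2}, \code{n}, \code{df_resid}, \code{sigma}.
#' @export
fit_linear_model <- function(response, design) {
  design <- as.matrix(design)
  n <- length(response)
  k <- ncol(design)
  if (nrow(design) != n) stop("design/response length mismatch", call. = FALSE)
  if (n <= k) stop("need more observations than predictors", call. = FALSE)
  if (anyNA(response) || anyNA(design)) {
    stop("fit_linear_model requires complete cases", call. = FALSE)
  }
  if (var(response) == 0) stop("zero-variance response", call. = FALSE)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(k))
  }
  qrX <- qr(design)
  if (qrX$rank < k) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("rank-deficient design: column(s) ",
         paste(dropped, collapse = ", "),
         " linearly dependent on the others", call. = FALSE)
  }
  beta <- qr.coef(qrX, response)
  fitted <- drop(design %*% beta)
  resid <- response - fitted
  rss <- sum(resid^2)
  df_resid <- n - k
  sigma2 <- rss / df_resid
  R <- qr.R(qrX)
  xtx_inv_piv <- chol2inv(R)
  piv <- qrX$pivot
  xtx_inv <- matrix(NA_real_, k, k)
  xtx_inv[piv, piv] <- xtx_inv_piv
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_resid)
  tss <- sum((response - mean(response))^2)
  structure(list(
    coefficients = data.frame(term = colnames(design), beta = as.numeric(beta),
                              se = se, t = tval, p = pval,
                              row.names = NULL, stringsAsFactors = FALSE),
    r2 = 1 - rss / tss, n = n, df_resid = df_resid,
    sigma = sqrt(sigma2)), class = "lm_fit")
}

#' @export
print.lm_fit <- function(x, ...) {
  cat("linear model fit: n =", x$n, ", R^2 =", signif(x$r2, 4), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

## Design matrix for phenotype ~ genotype (+ covariates), complete cases.
## Returns list(y, X, n_dropped).
build_design <- function(phenotypes, code, phenotype, covariates = NULL) {
  y <- phenotypes[[phenotype]]
  df <- data.frame(y = y, geno = code)
  if (length(covariates)) {
    for (cv in covariates) {
      v <- phenotypes[[cv]]
      if (cv == "sex") v <- as.numeric(v == "male")  # 0 = female, 1 = male
      df[[cv]] <- v
    }
  }
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, -1, drop = FALSE]))
  list(y = df$y, X = X, n = nrow(df), n_dropped = sum(!keep))
}

#' Single-SNP association with a craving phenotype
#'
#' Regresses a HUC phenotype on the mode-coded genotype, unadjusted and
#' (optionally) adjusted for age, sex and BMI. The reported p-values are
#' the genotype coefficient's p in each fit; the reported R-squared is
#' from the unadjusted genotype-only model (the marginal variance
#' explained by the SNP). Subjects with a missing genotype, phenotype or
#' (for the adjusted fit) covariate are dropped (complete-case).
#'
#' @param genotypes a [genotype_matrix].
#' @param phenotypes scored phenotype table (see [score_huc_table()]).
#' @param snp one row of a [snp_info] table (or a list with \code{snp_id},
#'   \code{gene}, \code{alleles}, \code{pathway}).
#' @param phenotype one of \code{"total"}, \code{"urge"}, \code{"ability"}.
#' @param mode inheritance mode for the genotype coding.
#' @param risk_allele allele counted as the risk allele; defaults to the
#'   declared minor allele.
#' @param adjust logical; also fit the covariate-adjusted model (default
#'   TRUE).
#' @param covariates covariate columns for the adjusted fit.
#' @return a one-row \code{data.frame} (class \code{association_result}):
#'   snp, gene, pathway, phenotype, mode, risk_allele, n, beta, se, t,
#'   p_unadjusted, p_adjusted, r2. Coefficient statistics (beta/se/t) are
#'   from the unadjusted fit; \code{beta_adjusted} carries the adjusted
#'   genotype coefficient.
#' @export
associate_snp <- function(genotypes, phenotypes, snp,
                          phenotype = c("total", "urge", "ability"),
                          mode = c("additive", "dominant", "recessive"),
                          risk_allele = NULL, adjust = TRUE,
                          covariates = DEFAULT_COVARIATES) {
  phenotype <- match.arg(phenotype)
  mode <- match.arg(mode)
  al <- parse_alleles(snp$alleles)
  if (is.null(risk_allele)) risk_allele <- unname(al["minor"])
  code <- code_genotypes(genotypes[, snp$snp_id], risk_allele, mode,
                         alleles = unname(al))
  names(code) <- NULL
  assoc_from_code(code, phenotypes, snp, phenotype, mode, risk_allele,
                  adjust, covariates)
}

#' Single-SNP association under an explicit risk coding
#'
#' Like [associate_snp()] but codes genotypes through a [risk_coding]'s
#' genotype-to-score map (which for carrier-style binary groupings is not
#' the strict textbook mode coding).
#'
#' @inheritParams associate_snp
#' @param coding a [risk_coding] for this SNP.
#' @return a one-row \code{data.frame}, as [associate_snp()].
#' @export
associate_coding <- function(genotypes, phenotypes, snp, coding,
                             phenotype = c("total", "urge", "ability"),
                             adjust = TRUE,
                             covariates = DEFAULT_COVARIATES) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(coding, "risk_coding"))
  calls <- genotypes[, snp$snp_id]
  code <- rep(NA_real_, length(calls))
  ok <- !is_missing_call(calls)
  unknown <- setdiff(unique(calls[ok]), names(coding$map))
  if (length(unknown)) {
    stop("genotype(s) ", paste(unknown, collapse = ", "),
         " not covered by the coding map for ", snp$snp_id, call. = FALSE)
  }
  code[ok] <- coding$map[calls[ok]]
  assoc_from_code(code, phenotypes, snp, phenotype, coding$mode,
                  coding$risk_allele, adjust, covariates)
}

assoc_from_code <- function(code, phenotypes, snp, phenotype, mode,
                            risk_allele, adjust, covariates) {
  d0 <- build_design(phenotypes, code, phenotype)
  if (length(unique(d0$X[, "geno"])) < 2L) {
    stop("no genotype variation for ", snp$snp_id, " under ", mode,
         " coding", call. = FALSE)
  }
  fit0 <- fit_linear_model(d0$y, d0$X)
  g0 <- fit0$coefficients[fit0$coefficients$term == "geno", ]
  p_adj <- NA_real_
  beta_adj <- NA_real_
  n_used <- d0$n
  if (adjust) {
    d1 <- build_design(phenotypes, code, phenotype, covariates)
    fit1 <- fit_linear_model(d1$y, d1$X)
    g1 <- fit1$coefficients[fit1$coefficients$term == "geno", ]
    p_adj <- g1$p
    beta_adj <- g1$beta
  }
  out <- data.frame(snp = snp$snp_id, gene = snp$gene,
                    pathway = if (!is.null(snp$pathway)) snp$pathway else NA,
                    phenotype = phenotype, mode = mode,
                    risk_allele = risk_allele, n = n_used,
                    beta = g0$beta, se = g0$se, t = g0$t,
                    p_unadjusted = g0$p, p_adjusted = p_adj,
                    beta_adjusted = beta_adj, r2 = fit0$r2,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Phenotype means stratified by genotype
#'
#' The genotype-stratified ladder of phenotype means used to assign risk
#' alleles: one row per genotype class (hom-major, het, hom-minor) with
#' complete-case n, mean and sample SD. Empty classes are reported with
#' n = 0.
#'
#' @inheritParams associate_snp
#' @return \code{data.frame} with columns snp, genotype, class, n, mean, sd.
#' @export
stratified_means <- function(genotypes, phenotypes, snp,
                             phenotype = c("total", "urge", "ability")) {
  phenotype <- match.arg(phenotype)
  al <- parse_alleles(snp$alleles)
  lv <- genotype_levels(al["major"], al["minor"])
  calls <- genotypes[, snp$snp_id]
  y <- phenotypes[[phenotype]]
  out <- do.call(rbind, lapply(seq_along(lv), function(i) {
    v <- y[calls == lv[i] & !is.na(y)]
    data.frame(snp = snp$snp_id, genotype = genotype_label(lv[i]),
               class = c("hom_major", "het", "hom_minor")[i],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square on an r x c table of counts (expected = row
#' total x column total / grand total), with (r-1)(c-1) degrees of
#' freedom and no continuity correction.
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @return list: \code{chi_square}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
contingency_chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(table < 0) || anyNA(table)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal total in contingency table", call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi_square = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Two-sample t test from raw data or summary statistics
#'
#' Pooled-variance (default) or Welch two-sided t test. Accepts either two
#' raw-data vectors or two summary triples (n, mean, sd); the two entry
#' points give identical results on matching data.
#'
#' @param x,y numeric vectors (raw-data entry point).
#' @param summary_x,summary_y numeric triples \code{c(n, mean, sd)}
#'   (summary entry point; used when \code{x}/\code{y} are NULL).
#' @param var_equal logical; TRUE (default) pools the variances, FALSE
#'   uses the Welch-Satterthwaite approximation.
#' @return list: \code{t}, \code{df}, \code{p_value}, \code{mean_diff}.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' two_sample_t(summary_x = c(259, 43.2, 7.2), summary_y = c(67, 37.8, 6.3))
#' @export
two_sample_t <- function(x = NULL, y = NULL, summary_x = NULL,
                         summary_y = NULL, var_equal = TRUE) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) {
      stop("both x and y are required for the raw-data entry point",
           call. = FALSE)
    }
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    summary_x <- c(length(x), mean(x), sd(x))
    summary_y <- c(length(y), mean(y), sd(y))
  }
  if (is.null(summary_x) || is.null(summary_y)) {
    stop("supply either raw vectors or two (n, mean, sd) summaries",
         call. = FALSE)
  }
  n1 <- summary_x[1]; m1 <- summary_x[2]; s1 <- summary_x[3]
  n2 <- summary_y[1]; m2 <- summary_y[2]; s2 <- summary_y[3]
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0 || anyNA(c(s1, s2))) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) {
      if (m1 == m2) {
        return(list(t = 0, df = n1 + n2 - 2, p_value = 1,
                    mean_diff = 0))
      }
      stop("zero pooled variance with unequal means", call. = FALSE)
    }
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    if (v1 + v2 == 0) {
      if (m1 == m2) {
        return(list(t = 0, df = n1 + n2 - 2, p_value = 1, mean_diff = 0))
      }
      stop("zero variance with unequal means", call. = FALSE)
    }
    tval <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = tval, df = df, p_value = 2 * pt(-abs(tval), df),
       mean_diff = m1 - m2)
}
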