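## Risk-allele assignment, the unweighted genetic risk score (GRS) and
## its dose-response trend test.
##
## A RiskCoding maps each of a SNP's three genotypes to an integer code:
## 0/1/2 under additive action (risk-allele count) or 0/1 under a binary
## grouping (one homozygote class vs the rest). A RiskModel is an ordered
## set of codings; the GRS of a subject is the unweighted sum of codes,
## here 0-6 for the five-SNP heroin-craving panel.

#' Construct a per-SNP risk coding
#'
#' @param snp_id SNP identifier.
#' @param mode inheritance mode the coding represents.
#' @param risk_allele the phenotype-increasing allele.
#' @param map named integer vector mapping all three normalized genotype
#'   calls (e.g. \code{"C/C"}) to codes; maximum 2 for additive, 1
#'   otherwise.
#' @param label human-readable grouping label (e.g. \code{"TT(0) vs
#'   CC+CT(1)"}).
#' @return an object of class \code{risk_coding}.
#' @export
risk_coding <- function(snp_id, mode, risk_allele, map, label = "") {
  if (length(map) != 3L || is.null(names(map))) {
    stop("map must cover all three genotypes", call. = FALSE)
  }
  names(map) <- normalize_calls(names(map))
  max_allowed <- if (mode == "additive") 2L else 1L
  if (max(map) != max_allowed || min(map) != 0L) {
    stop("map codes for a ", mode, " coding must span 0..", max_allowed,
         call. = FALSE)
  }
  structure(list(snp_id = snp_id, mode = mode, risk_allele = risk_allele,
                 map = map, label = label, max_code = max(map)),
            class = "risk_coding")
}

#' @export
print.risk_coding <- function(x, ...) {
  cat(x$snp_id, " [", x$mode, ", risk allele ", x$risk_allele, "]: ",
      paste(genotype_label(names(x$map)), "->", x$map, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Bundle risk codings into a risk model
#'
#' @param codings list of [risk_coding] objects.
#' @return object of class \code{risk_model} with \code{max_score} the sum
#'   of per-SNP maximum codes.
#' @export
risk_model <- function(codings) {
  if (!length(codings)) stop("risk model needs at least one coding",
                             call. = FALSE)
  stopifnot(all(vapply(codings, inherits, logical(1), "risk_coding")))
  names(codings) <- vapply(codings, `[[`, character(1), "snp_id")
  structure(list(codings = codings,
                 max_score = sum(vapply(codings, `[[`, numeric(1),
                                        "max_code"))),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk model:", length(x$codings), "SNPs, score range 0 -",
      x$max_score, "\n")
  for (rc in x$codings) print(rc)
  invisible(x)
}

#' Assign a risk coding from genotype-stratified phenotype means
#'
#' Derives the risk-allele direction (and, under \code{mode_policy =
#' "best_fit"}, the inheritance mode) from the cohort's own
#' genotype-stratified phenotype means:
#' \itemize{
#'   \item \code{additive}: the risk allele is the allele of the
#'     homozygote class with the higher mean; genotypes code 0/1/2 risk
#'     copies.
#'   \item \code{recessive}: the binary grouping isolates the homozygote
#'     class whose mean lies farther from the heterozygote mean; the
#'     group with the higher phenotype mean is coded 1. (When the
#'     isolated homozygote has the lower mean, code 1 therefore marks
#'     carriers of the other allele.)
#'   \item \code{dominant}: carriers of the candidate risk allele are
#'     coded 1; the candidate maximizing the carrier-vs-noncarrier mean
#'     difference is chosen.
#'   \item \code{best_fit}: all three codings are fitted (genotype-only
#'     model) and the one with the smallest genotype-coefficient p is
#'     kept; ties break toward larger R-squared, then additive-first.
#' }
#' Deriving the coding from the same cohort that is subsequently scored
#' is circular and optimistic; see [compute_grs()] for supplying a frozen
#' externally derived model instead.
#'
#' @inheritParams associate_snp
#' @param mode_policy \code{"best_fit"} or one of the three fixed modes.
#' @return a [risk_coding].
#' @export
assign_risk_coding <- function(genotypes, phenotypes, snp,
                               phenotype = c("total", "urge", "ability"),
                               mode_policy = c("best_fit", "additive",
                                               "dominant", "recessive")) {
  phenotype <- match.arg(phenotype)
  mode_policy <- match.arg(mode_policy)
  al <- parse_alleles(snp$alleles)
  sm <- stratified_means(genotypes, phenotypes, snp, phenotype)
  if (mode_policy == "best_fit") {
    cands <- lapply(INHERITANCE_MODES, function(m) {
      tryCatch(assign_risk_coding(genotypes, phenotypes, snp, phenotype, m),
               error = function(e) NULL)
    })
    cands <- Filter(Negate(is.null), cands)
    if (!length(cands)) {
      stop("no codable inheritance mode for ", snp$snp_id, call. = FALSE)
    }
    stats <- vapply(cands, function(rc) {
      code <- rc$map[genotypes[, snp$snp_id]]
      d <- build_design(phenotypes, unname(code), phenotype)
      fit <- fit_linear_model(d$y, d$X)
      g <- fit$coefficients[fit$coefficients$term == "geno", ]
      c(p = g$p, r2 = fit$r2)
    }, numeric(2))
    ord <- order(stats["p", ], -stats["r2", ])  # list order is additive-first
    return(cands[[ord[1]]])
  }
  lv <- genotype_levels(al["major"], al["minor"])
  hom_alleles <- c(al[["major"]], al[["minor"]])
  mu <- sm$mean            # hom-major, het, hom-minor
  nn <- sm$n
  # weighted mean over the non-empty classes in idx
  wmean <- function(idx) {
    idx <- idx[nn[idx] > 0]
    if (!length(idx)) return(NA_real_)
    sum(mu[idx] * nn[idx]) / sum(nn[idx])
  }
  if (mode_policy == "additive") {
    if (any(nn[c(1, 3)] == 0)) {
      stop("additive coding for ", snp$snp_id,
           ": empty homozygote class", call. = FALSE)
    }
    if (mu[1] == mu[3]) {
      stop("tie: homozygote means equal for ", snp$snp_id,
           "; specify the risk allele explicitly", call. = FALSE)
    }
    risk <- hom_alleles[which.max(c(mu[1], mu[3]))]
    map <- setNames(as.integer(code_genotypes(lv, risk, "additive")), lv)
    label <- paste(paste0(genotype_label(lv), "(", map, ")"),
                   collapse = " / ")
    return(risk_coding(snp$snp_id, "additive", risk, map, label))
  }
  if (mode_policy == "recessive") {
    # isolate the homozygote class farther from the heterozygote mean
    if (nn[2] == 0 || sum(nn[c(1, 3)] > 0) == 0) {
      stop("recessive coding for ", snp$snp_id,
           ": need a heterozygote class and a homozygote class",
           call. = FALSE)
    }
    dist <- abs(mu[c(1, 3)] - mu[2])
    dist[nn[c(1, 3)] == 0] <- -Inf
    if (dist[1] == dist[2]) {
      stop("tie: both homozygote classes equidistant from heterozygotes ",
           "for ", snp$snp_id, "; specify the coding explicitly",
           call. = FALSE)
    }
    iso <- c(1, 3)[which.max(dist)]          # row index of isolated hom
    rest <- setdiff(1:3, iso)
    mean_iso <- mu[iso]
    mean_rest <- wmean(rest)
    if (mean_iso == mean_rest) {
      stop("tie: grouped means equal for ", snp$snp_id,
           "; specify the coding explicitly", call. = FALSE)
    }
    iso_allele <- hom_alleles[c(1, 3) == iso][1]
    other_allele <- setdiff(hom_alleles, iso_allele)
    map <- setNames(rep(0L, 3), lv)
    if (mean_iso > mean_rest) {
      map[iso] <- 1L
      risk <- iso_allele
    } else {
      map[rest] <- 1L
      risk <- other_allele
    }
    zero_g <- genotype_label(lv[map == 0])
    one_g <- genotype_label(lv[map == 1])
    label <- paste0(paste(zero_g, collapse = "+"), "(0) vs ",
                    paste(one_g, collapse = "+"), "(1)")
    return(risk_coding(snp$snp_id, "recessive", risk, map, label))
  }
  # dominant: candidate risk allele maximizing carrier - noncarrier mean diff
  diffs <- vapply(hom_alleles, function(a) {
    carrier <- vapply(lv, function(g) {
      a %in% strsplit(g, "/", fixed = TRUE)[[1]]
    }, logical(1))
    if (sum(nn[carrier]) == 0 || sum(nn[!carrier]) == 0) return(NA_real_)
    wmean(which(carrier)) - wmean(which(!carrier))
  }, numeric(1))
  if (all(is.na(diffs))) {
    stop("dominant coding for ", snp$snp_id, ": degenerate genotype classes",
         call. = FALSE)
  }
  if (!anyNA(diffs) && diffs[1] == diffs[2]) {
    stop("tie: carrier means equal for ", snp$snp_id,
         "; specify the risk allele explicitly", call. = FALSE)
  }
  risk <- hom_alleles[which.max(diffs)]
  map <- setNames(as.integer(code_genotypes(lv, risk, "dominant")), lv)
  label <- paste0(paste(genotype_label(lv[map == 0]), collapse = "+"),
                  "(0) vs ", paste(genotype_label(lv[map == 1]),
                                   collapse = "+"), "(1)")
  risk_coding(snp$snp_id, "dominant", risk, map, label)
}

#' Compute the unweighted genetic risk score
#'
#' Sums each subject's per-SNP codes under a [risk_model]. Under the
#' default \code{missing_policy = "exclude"} a subject with any missing
#' component genotype gets an NA score (and is excluded from the trend
#' analysis); under \code{"partial"} the sum runs over the non-missing
#' components and the count of missing components flags the subject.
#'
#' @param genotypes a [genotype_matrix] containing every model SNP.
#' @param model a [risk_model].
#' @param missing_policy \code{"exclude"} (default) or \code{"partial"}.
#' @return \code{data.frame}: sample_id, grs, n_missing.
#' @export
compute_grs <- function(genotypes, model,
                        missing_policy = c("exclude", "partial")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(model, "risk_model"))
  absent <- setdiff(names(model$codings), colnames(genotypes))
  if (length(absent)) {
    stop("model SNP(s) missing from genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  code_mat <- vapply(model$codings, function(rc) {
    calls <- genotypes[, rc$snp_id]
    unknown <- setdiff(unique(calls[!is_missing_call(calls)]),
                       names(rc$map))
    if (length(unknown)) {
      stop("genotype(s) ", paste(unknown, collapse = ", "),
           " of ", rc$snp_id, " not covered by its coding map",
           call. = FALSE)
    }
    out <- rep(NA_real_, nrow(genotypes))
    ok <- !is_missing_call(calls)
    out[ok] <- rc$map[calls[ok]]
    out
  }, numeric(nrow(genotypes)))
  code_mat <- matrix(code_mat, nrow = nrow(genotypes))
  n_missing <- rowSums(is.na(code_mat))
  grs <- if (missing_policy == "exclude") {
    ifelse(n_missing > 0, NA_real_, rowSums(code_mat))
  } else {
    rowSums(code_mat, na.rm = TRUE)
  }
  data.frame(sample_id = rownames(genotypes), grs = grs,
             n_missing = n_missing, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Dose-response trend test of phenotype on the genetic risk score
#'
#' Fits a linear model of the phenotype on the integer GRS treated as a
#' continuous covariate; the p for trend is the GRS coefficient's
#' p-value. Optionally adjusts for age, sex and BMI. Also reports the
#' per-score-level phenotype ladder (n, mean, SD).
#'
#' @param grs \code{data.frame} from [compute_grs()].
#' @param phenotypes scored phenotype table (matched by \code{sample_id}).
#' @param phenotype one of \code{"total"}, \code{"urge"}, \code{"ability"}.
#' @param adjust logical; default FALSE (unadjusted trend).
#' @return list of class \code{grs_trend}: \code{beta}, \code{se},
#'   \code{t}, \code{p_trend}, \code{r2} (GRS-only model), \code{n},
#'   \code{levels} (per-GRS-level n/mean/sd).
#' @export
grs_trend_test <- function(grs, phenotypes,
                           phenotype = c("total", "urge", "ability"),
                           adjust = FALSE) {
  phenotype <- match.arg(phenotype)
  idx <- match(phenotypes$sample_id, grs$sample_id)
  score <- grs$grs[idx]
  if (length(unique(score[!is.na(score)])) < 2L) {
    stop("constant genetic risk score; trend undefined", call. = FALSE)
  }
  d0 <- build_design(phenotypes, score, phenotype)
  fit0 <- fit_linear_model(d0$y, d0$X)
  g <- fit0$coefficients[fit0$coefficients$term == "geno", ]
  p_adj <- NA_real_
  if (adjust) {
    d1 <- build_design(phenotypes, score, phenotype, DEFAULT_COVARIATES)
    fit1 <- fit_linear_model(d1$y, d1$X)
    g <- fit1$coefficients[fit1$coefficients$term == "geno", ]
    p_adj <- g$p
  }
  y <- d0$y
  s <- d0$X[, "geno"]
  levels_df <- do.call(rbind, lapply(sort(unique(s)), function(l) {
    v <- y[s == l]
    data.frame(grs = l, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2L) sd(v) else NA_real_)
  }))
  rownames(levels_df) <- NULL
  structure(list(phenotype = phenotype, beta = g$beta, se = g$se, t = g$t,
                 p_trend = g$p, p_trend_adjusted = p_adj, r2 = fit0$r2,
                 n = d0$n, adjusted = adjust, levels = levels_df),
            class = "grs_trend")
}

#' @export
print.grs_trend <- function(x, ...) {
  cat("GRS dose-response trend (", x$phenotype, ", ",
      if (x$adjusted) "adjusted" else "unadjusted", "): n = ", x$n, "\n",
      sep = "")
  cat(sprintf("  beta = %.3f (se %.3f), p for trend = %.4g, R^2 = %.4f\n",
              x$beta, x$se, x$p_trend, x$r2))
  print(x$levels, digits = 4)
  invisible(x)
}

#' Combined single-SNP and GRS report
#'
#' One row per model SNP (its mode, grouping label, and per-phenotype
#' unadjusted R-squared and p) plus a combined-GRS row carrying the
#' GRS-only R-squared and p for trend for each phenotype. The risk model
#' is typically derived from the same cohort (see [assign_risk_coding()]),
#' which makes the single-SNP rows optimistic; the report is descriptive,
#' not confirmatory.
#'
#' @param genotypes a [genotype_matrix].
#' @param phenotypes scored phenotype table.
#' @param model a [risk_model].
#' @param snps [snp_info] annotation covering the model SNPs.
#' @param phenotypes_tested character vector of phenotypes to report.
#' @return \code{data.frame}: term, gene, mode, grouping, then r2_<ph> and
#'   p_<ph> column pairs.
#' @export
combined_report <- function(genotypes, phenotypes, model, snps,
                            phenotypes_tested = HUC_PHENOTYPES) {
  stopifnot(inherits(model, "risk_model"))
  grs <- compute_grs(genotypes, model)
  rows <- lapply(model$codings, function(rc) {
    gene <- snps$gene[match(rc$snp_id, snps$snp_id)]
    row <- data.frame(term = rc$snp_id, gene = gene, mode = rc$mode,
                      grouping = rc$label, stringsAsFactors = FALSE)
    for (ph in phenotypes_tested) {
      code <- rep(NA_real_, nrow(genotypes))
      ok <- !is_missing_call(genotypes[, rc$snp_id])
      code[ok] <- rc$map[genotypes[ok, rc$snp_id]]
      d <- build_design(phenotypes, code, ph)
      fit <- fit_linear_model(d$y, d$X)
      g <- fit$coefficients[fit$coefficients$term == "geno", ]
      row[[paste0("r2_", ph)]] <- fit$r2
      row[[paste0("p_", ph)]] <- g$p
    }
    row
  })
  comb <- data.frame(term = "combined_grs", gene = "-", mode = "additive",
                     grouping = paste0("0-", model$max_score),
                     stringsAsFactors = FALSE)
  for (ph in phenotypes_tested) {
    tr <- grs_trend_test(grs, phenotypes, ph, adjust = FALSE)
    comb[[paste0("r2_", ph)]] <- tr$r2
    comb[[paste0("p_", ph)]] <- tr$p_trend
  }
  out <- rbind(do.call(rbind, rows), comb)
  rownames(out) <- NULL
  out
}

#' The published five-SNP heroin-craving risk model
#'
#' The fixed risk codings of the five-SNP panel (GRIN3B rs2240158, GRIN3A
#' rs3983721, CYP2C19 rs6583954, TPH2 rs2129575, COMT rs174699) reported
#' for heroin-craving phenotypes in Taiwanese methadone-maintenance
#' patients: four binary (recessive-style) groupings and one additive
#' coding, giving a GRS range of 0-6. Useful as a frozen externally
#' derived model and as ground truth for simulations.
#'
#' @return a [risk_model] with \code{max_score = 6}.
#' @export
craving_risk_model <- function() {
  risk_model(list(
    risk_coding("rs2240158", "recessive", "C",
                c("C/C" = 1L, "C/T" = 1L, "T/T" = 0L),
                label = "TT(0) vs CC+CT(1)"),
    risk_coding("rs3983721", "recessive", "T",
                c("C/C" = 0L, "C/T" = 0L, "T/T" = 1L),
                label = "CC+CT(0) vs TT(1)"),
    risk_coding("rs6583954", "additive", "T",
                c("C/C" = 0L, "C/T" = 1L, "T/T" = 2L),
                label = "CC(0) / CT(1) / TT(2)"),
    risk_coding("rs2129575", "recessive", "T",
                c("G/G" = 0L, "G/T" = 0L, "T/T" = 1L),
                label = "GG+GT(0) vs TT(1)"),
    risk_coding("rs174699", "recessive", "C",
                c("C/C" = 1L, "C/T" = 0L, "T/T" = 0L),
                label = "CT+TT(0) vs CC(1)")))
}

#' Annotation for the five-SNP heroin-craving panel
#'
#' @return a [snp_info] table (alleles written major > minor).
#' @export
craving_snp_info <- function() {
  snp_info(
    snp_id = c("rs2240158", "rs3983721", "rs6583954", "rs2129575",
               "rs174699"),
    gene = c("GRIN3B", "GRIN3A", "CYP2C19", "TPH2", "COMT"),
    alleles = c("T > C", "C > T", "T > C", "G > T", "C > T"),
    pathway = c("Cognitive function", "Cognitive function",
                "Methadone-metabolizing enzymes",
                "Dopamine and serotonin pathway",
                "Dopamine and serotonin pathway"))
}

#' Serialize a risk model to TSV
#'
#' Columns: snp_id, mode, risk_allele, label, then the three genotype
#' codes as genotype=code pairs.
#'
#' @param model a [risk_model].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_risk_model <- function(model, path) {
  rows <- lapply(model$codings, function(rc) {
    data.frame(snp_id = rc$snp_id, mode = rc$mode,
               risk_allele = rc$risk_allele, label = rc$label,
               genotype_1 = names(rc$map)[1], code_1 = rc$map[[1]],
               genotype_2 = names(rc$map)[2], code_2 = rc$map[[2]],
               genotype_3 = names(rc$map)[3], code_3 = rc$map[[3]],
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a risk model written by [write_risk_model()]
#' @param path path to a risk-model TSV.
#' @return a [risk_model].
#' @export
read_risk_model <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  codings <- lapply(seq_len(nrow(df)), function(i) {
    map <- setNames(as.integer(c(df$code_1[i], df$code_2[i], df$code_3[i])),
                    c(df$genotype_1[i], df$genotype_2[i], df$genotype_3[i]))
    risk_coding(df$snp_id[i], df$mode[i], df$risk_allele[i], map,
                df$label[i])
  })
  risk_model(codings)
}
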