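## Scoring of the 14-item heroin-use and craving (HUC) questionnaire.
##
## Part I (items 1-6) measures the urge for heroin; Part II (items 7-14)
## the ability to overcome heroin use (reverse-framed: higher = worse).
## Each item is scored 0-4, so urge ranges 0-24, ability 0-32 and the
## total craving score 0-56. Higher scores mean more severe craving.

HUC_N_ITEMS <- 14L
HUC_PART1 <- 1:6
HUC_PART2 <- 7:14
HUC_ITEM_MAX <- 4L

#' Score the HUC questionnaire
#'
#' @param items integer vector of exactly 14 item scores, each in 0..4.
#' @return a list of class \code{huc_scores} with integer components
#'   \code{urge} (items 1-6, range 0-24), \code{ability} (items 7-14,
#'   range 0-32) and \code{total} (their sum, range 0-56).
#' @examples
#' score_huc(rep(2, 14))
#' @export
score_huc <- function(items) {
  if (length(items) != HUC_N_ITEMS) {
    stop("expected ", HUC_N_ITEMS, " item scores, got ", length(items),
         call. = FALSE)
  }
  if (anyNA(items) || any(items %% 1 != 0) || any(items < 0) ||
      any(items > HUC_ITEM_MAX)) {
    stop("item scores must be integers in 0..", HUC_ITEM_MAX, call. = FALSE)
  }
  items <- as.integer(items)
  structure(list(urge = sum(items[HUC_PART1]),
                 ability = sum(items[HUC_PART2]),
                 total = sum(items)),
            class = "huc_scores")
}

#' @export
print.huc_scores <- function(x, ...) {
  cat("HUC scores: urge =", x$urge, "(0-24), ability =", x$ability,
      "(0-32), total =", x$total, "(0-56)\n")
  invisible(x)
}

#' Score every subject in a phenotype table
#'
#' Adds \code{urge}, \code{ability} and \code{total} columns. Subjects with
#' any missing item get NA scores (no imputation) and are reported via a
#' message; they are excluded from phenotype analyses downstream.
#'
#' @param phenotypes phenotype \code{data.frame} with columns
#'   \code{huc1}..\code{huc14}.
#' @return the table with score columns appended.
#' @export
score_huc_table <- function(phenotypes) {
  items <- as.matrix(phenotypes[, PHENO_ITEM_COLS, drop = FALSE])
  incomplete <- apply(items, 1L, anyNA)
  complete_idx <- which(!incomplete)
  if (length(complete_idx)) {
    # validate on complete rows only; per-subject sums
    rng_bad <- items[complete_idx, , drop = FALSE]
    if (any(rng_bad %% 1 != 0 | rng_bad < 0 | rng_bad > HUC_ITEM_MAX)) {
      stop("item scores must be integers in 0..", HUC_ITEM_MAX, call. = FALSE)
    }
  }
  urge <- rowSums(items[, HUC_PART1, drop = FALSE])
  ability <- rowSums(items[, HUC_PART2, drop = FALSE])
  phenotypes$urge <- ifelse(incomplete, NA_real_, urge)
  phenotypes$ability <- ifelse(incomplete, NA_real_, ability)
  phenotypes$total <- ifelse(incomplete, NA_real_, urge + ability)
  if (any(incomplete)) {
    message(sum(incomplete),
            " subject(s) with missing questionnaire items excluded from scoring")
  }
  phenotypes
}

#' Summarize HUC scores by group
#'
#' Per-group mean and sample standard deviation (n - 1 denominator) of the
#' urge, ability and total scores. Groups with fewer than two members get
#' an NA standard deviation.
#'
#' @param scores \code{data.frame} with columns \code{urge}, \code{ability},
#'   \code{total} (e.g. from [score_huc_table()]).
#' @param groups group labels, one per row; a single group when omitted.
#' @return a \code{data.frame} with one row per group x score with columns
#'   \code{group}, \code{score}, \code{n}, \code{mean}, \code{sd}.
#' @export
summarize_scores <- function(scores, groups = NULL) {
  if (nrow(scores) == 0L) stop("no scores to summarize", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", nrow(scores))
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    sub <- scores[groups == g, , drop = FALSE]
    do.call(rbind, lapply(c("urge", "ability", "total"), function(s) {
      v <- sub[[s]][!is.na(sub[[s]])]
      data.frame(group = g, score = s, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) >= 2L) sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
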