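## Core genotype containers: a genotype matrix of unordered allele-pair calls
## ("A/G", missing "./.") and the SNP annotation table.

MISSING_CALL <- "./."
VALID_ALLELES <- c("A", "C", "G", "T")

#' Normalize allele-pair genotype calls
#'
#' Genotype calls are unordered allele pairs: \code{"G/A"} and \code{"A/G"}
#' denote the same genotype. This canonicalizes every call to alphabetical
#' order (\code{"A/G"}); the missing code \code{"./."} passes through.
#'
#' @param calls character vector of calls such as \code{"A/G"} or \code{"./."}.
#' @return character vector of normalized calls.
#' @examples
#' normalize_calls(c("G/A", "A/G", "./."))
#' @export
normalize_calls <- function(calls) {
  calls <- as.character(calls)
  out <- calls
  todo <- !is.na(calls) & calls != MISSING_CALL
  if (any(todo)) {
    parts <- strsplit(calls[todo], "/", fixed = TRUE)
    bad <- vapply(parts, function(p) {
      length(p) != 2L || !all(p %in% VALID_ALLELES)
    }, logical(1))
    if (any(bad)) {
      stop("invalid genotype call(s): ",
           paste(unique(calls[todo][bad]), collapse = ", "),
           " (expected e.g. \"A/G\" with alleles A/C/G/T, or \"./.\")",
           call. = FALSE)
    }
    out[todo] <- vapply(parts, function(p) paste(sort(p), collapse = "/"),
                        character(1))
  }
  out[is.na(out)] <- MISSING_CALL
  out
}

#' Construct a genotype matrix
#'
#' A genotype matrix is a character matrix of normalized allele-pair calls
#' with samples in rows and SNPs in columns.
#'
#' @param calls character matrix (or object coercible to one) of calls.
#' @param sample_ids,snp_ids row and column identifiers; taken from
#'   \code{dimnames(calls)} when omitted.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            snp_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids) || is.null(snp_ids)) {
    stop("sample_ids and snp_ids are required", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1], call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) {
    stop("duplicate SNP id: ", snp_ids[duplicated(snp_ids)][1], call. = FALSE)
  }
  if (nrow(calls) != length(sample_ids) || ncol(calls) != length(snp_ids)) {
    stop("calls dimensions do not match id lengths", call. = FALSE)
  }
  m <- matrix(normalize_calls(calls), nrow = nrow(calls),
              dimnames = list(sample_ids, snp_ids))
  structure(m, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "samples x", ncol(x), "SNPs\n")
  n_show <- min(nrow(x), 5L)
  print(unclass(x)[seq_len(n_show), , drop = FALSE], quote = FALSE)
  if (nrow(x) > n_show) cat("... and", nrow(x) - n_show, "more samples\n")
  invisible(x)
}

is_missing_call <- function(calls) calls == MISSING_CALL

#' Build a SNP annotation table
#'
#' One row per SNP with its gene symbol, declared allele pair written
#' major > minor (e.g. \code{"T > C"}) and a free-text pathway label.
#'
#' @param snp_id character vector of SNP (rs) identifiers.
#' @param gene gene symbols.
#' @param alleles allele pairs written \code{"X > Y"}, major allele first.
#' @param pathway pathway labels.
#' @return a \code{data.frame} with class \code{snp_info}.
#' @export
snp_info <- function(snp_id, gene, alleles, pathway = NA_character_) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) {
    stop("duplicate SNP id in annotation: ",
         snp_id[duplicated(snp_id)][1], call. = FALSE)
  }
  for (a in alleles) parse_alleles(a)  # validates
  out <- data.frame(snp_id = snp_id, gene = as.character(gene),
                    alleles = as.character(alleles),
                    pathway = as.character(pathway),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_info", "data.frame")
  out
}

#' Parse a declared allele pair
#'
#' @param alleles a string such as \code{"T > C"} (major > minor).
#' @return named character vector \code{c(major = , minor = )}.
#' @export
parse_alleles <- function(alleles) {
  parts <- trimws(strsplit(alleles, ">", fixed = TRUE)[[1]])
  if (length(parts) != 2L || !all(parts %in% VALID_ALLELES) ||
      parts[1] == parts[2]) {
    stop("invalid allele pair: '", alleles,
         "' (expected two distinct alleles written e.g. \"T > C\")",
         call. = FALSE)
  }
  c(major = parts[1], minor = parts[2])
}

## The three possible genotypes for an allele pair, ordered
## hom-major, het, hom-minor, as normalized call strings.
genotype_levels <- function(major, minor) {
  normalize_calls(c(paste(major, major, sep = "/"),
                    paste(major, minor, sep = "/"),
                    paste(minor, minor, sep = "/")))
}

## Compact genotype label without separator (e.g. "TC"), alphabetical.
genotype_label <- function(call) gsub("/", "", call, fixed = TRUE)
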