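#' Genotype matrix with additive 1/2/3 coding
#'
#' Subjects x loci integer codes: 1 = major-allele homozygote,
#' 2 = heterozygote, 3 = minor-allele homozygote.
#'
#' @param codes integer matrix (subjects x loci) with values in `{1, 2, 3}`
#'   (`NA` allowed for missing calls).
#' @param subject_ids,locus_ids optional identifiers; taken from dimnames if
#'   absent.
#' @return An object of class `genotype_matrix` (an integer matrix).
#' @export
genotype_matrix <- function(codes, subject_ids = NULL, locus_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  ok <- codes %in% c(1L, 2L, 3L) | is.na(codes)
  if (!all(ok)) stop("genotype codes must be 1, 2 or 3 (or NA)")
  if (!is.null(subject_ids)) rownames(codes) <- subject_ids
  if (!is.null(locus_ids)) colnames(codes) <- locus_ids
  if (is.null(rownames(codes))) rownames(codes) <- paste0("S", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("L", seq_len(ncol(codes)))
  if (anyDuplicated(colnames(codes))) stop("locus ids must be unique")
  class(codes) <- c("genotype_matrix", "matrix", "array")
  codes
}

#' Code raw allele calls as 1/2/3 genotypes
#'
#' Converts allele-pair strings (e.g. `"AG"`) into additive codes using a
#' supplied per-locus major/minor designation. The designation comes from a
#' reference table rather than being recomputed from the sample, so the
#' coding is stable across subject subsets. Allele order within a pair is
#' irrelevant.
#'
#' @param raw_calls character matrix (subjects x loci) of two-letter allele
#'   pairs; `NA` or `""` marks a missing call.
#' @param allele_freqs data frame with columns `locus_id`, `major`, `minor`.
#' @return a [genotype_matrix] with `NA` for missing calls.
#' @export
code_genotypes <- function(raw_calls, allele_freqs) {
  raw_calls <- as.matrix(raw_calls)
  need <- c("locus_id", "major", "minor")
  if (!all(need %in% names(allele_freqs)))
    stop("'allele_freqs' needs columns locus_id, major, minor")
  loci <- colnames(raw_calls)
  if (is.null(loci)) stop("'raw_calls' must have locus ids as column names")
  miss <- setdiff(loci, allele_freqs$locus_id)
  if (length(miss))
    stop("no allele designation for loci: ", paste(miss, collapse = ", "))
  codes <- matrix(NA_integer_, nrow(raw_calls), ncol(raw_calls),
                  dimnames = dimnames(raw_calls))
  for (j in seq_along(loci)) {
    row <- allele_freqs[match(loci[j], allele_freqs$locus_id), ]
    calls <- raw_calls[, j]
    present <- !is.na(calls) & nzchar(calls)
    al <- strsplit(toupper(calls[present]), "")
    bad <- vapply(al, function(p) length(p) != 2L ||
                    !all(p %in% c(row$major, row$minor)), logical(1))
    if (any(bad))
      stop(sprintf("unknown allele in calls for locus %s: %s", loci[j],
                   paste(unique(calls[present][bad]), collapse = ", ")))
    nminor <- vapply(al, function(p) sum(p == row$minor), integer(1))
    codes[present, j] <- nminor + 1L
  }
  genotype_matrix(codes)
}

#' Weighted multi-locus gene score
#'
#' The score for subject i is `sum_j w_j * code_ij` over the scored loci,
#' with weights (signed regression coefficients from a prior association
#' model) supplied as data. Subjects with a missing genotype at any scored
#' locus are excluded with a warning by default; `missing = "impute"`
#' replaces missing codes by the per-locus mode instead.
#'
#' @param genotypes a [genotype_matrix].
#' @param weights named numeric vector (names = locus ids) or data frame with
#'   columns `locus_id`, `weight`.
#' @param missing `"exclude"` (default) or `"impute"`.
#' @return named numeric vector of scores (NA for excluded subjects).
#' @export
compute_gene_score <- function(genotypes, weights, missing = c("exclude", "impute")) {
  missing <- match.arg(missing)
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$weight, weights$locus_id)
  if (is.null(names(weights))) stop("'weights' must be named by locus id")
  if (!all(is.finite(weights))) stop("weights must be finite")
  absent <- setdiff(names(weights), colnames(genotypes))
  if (length(absent))
    stop("loci in weights absent from genotypes: ", paste(absent, collapse = ", "))
  codes <- unclass(genotypes)[, names(weights), drop = FALSE]
  storage.mode(codes) <- "double"
  if (anyNA(codes)) {
    if (missing == "impute") {
      for (j in seq_len(ncol(codes))) {
        na <- is.na(codes[, j])
        if (any(na)) {
          tab <- tabulate(codes[!na, j], nbins = 3L)
          codes[na, j] <- which.max(tab)
        }
      }
    } else {
      drop <- rowSums(is.na(codes)) > 0
      warning(sprintf("%d subject(s) with missing genotypes excluded from scoring",
                      sum(drop)))
      codes[drop, ] <- NA_real_
    }
  }
  drop(codes %*% weights)
}
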