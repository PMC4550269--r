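# internal helpers shared across modules

# z-score a vector using the sample (n-1) standard deviation
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance variable")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lower, upper))
  invisible(x)
}

#' Read or write a tab-separated table
#'
#' All tabular interchange in the package is TSV with a header row and
#' missing values written as `NA`.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv_table()` returns a data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
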