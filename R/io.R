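# Counts-table I/O. The on-disk format is a minimal delimited table
# mirroring the per-SNP count layout: columns snp_id, x1, x2, x3, n2, y
# (n1 is derived). Tab- and comma-separated files are both accepted.

#' Read a per-SNP counts table
#'
#' Expects columns `snp_id, x1, x2, x3, n2, y`; the separator (tab or
#' comma) is sniffed from the header line. Rows failing validation
#' (negative counts, `y > n2`, non-integers) are dropped with a warning
#' naming the offending line numbers; the dropped rows are attached in the
#' `errors` attribute.
#'
#' @param path path to the delimited file
#' @param sep optional explicit field separator
#' @return a data frame of validated records with derived column `n1`
#' @export
read_counts <- function(path, sep = NULL) {
  if (!file.exists(path)) .domain_error(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    warning("empty counts file: ", path)
    return(data.frame(snp_id = character(0), x1 = integer(0),
                      x2 = integer(0), x3 = integer(0), n2 = integer(0),
                      y = integer(0), n1 = integer(0)))
  }
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("snp_id", "x1", "x2", "x3", "n2", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .domain_error(paste("missing columns:", paste(miss, collapse = ", ")))
  numcols <- c("x1", "x2", "x3", "n2", "y")
  bad <- rep(FALSE, nrow(df))
  for (cl in numcols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- bad | !is.finite(v) | v < 0 | v != round(v)
    df[[cl]] <- v
  }
  bad <- bad | df$y > df$n2 | df$n2 < 1 | (df$x1 + df$x2 + df$x3) < 1
  if (any(bad)) {
    warning(sprintf("dropping %d invalid row(s) (file line %s)",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
  }
  out <- df[!bad, need, drop = FALSE]
  for (cl in numcols) out[[cl]] <- as.integer(out[[cl]])
  out$n1 <- out$x1 + out$x2 + out$x3
  rownames(out) <- NULL
  attr(out, "errors") <- df[bad, , drop = FALSE]
  out
}

#' Write test results as a tab-separated table
#'
#' @param results data frame from [hwx_test_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
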