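#' Write a table as TSV at full precision
#'
#' Numeric columns are serialized with 17 significant digits so a write /
#' read round trip reproduces doubles exactly.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msim_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_msim_tsv()]
#'
#' @param path input path.
#' @return Data frame.
#' @export
read_msim_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
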