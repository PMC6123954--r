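#' Write an analysis result to disk
#'
#' Serialises any tabular analysis result deterministically (fixed column
#' order, no row names, no timestamps): the same result written twice gives
#' byte-identical files. Exclusion-candidate flags are part of the result
#' columns and are never removed — artifact-prone genes are marked, not
#' dropped.
#'
#' @param result A data frame / tibble, or a list of them (JSON only).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  parent <- dirname(path)
  if (!dir.exists(parent)) {
    stop("unwritable path (directory does not exist): ", path)
  }
  if (format == "tsv") {
    if (!is.data.frame(result)) {
      stop("TSV output requires a data frame; got ", class(result)[1])
    }
    utils::write.table(result, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
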