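## MinKNOW sequencing-summary dialect: tab-separated with a header row.
## Column names are configurable because MinKNOW versions differ.

.defaultSummaryColumns <- function() {
    c(read_id = "read_id",
      length = "sequence_length_template",
      mean_q = "mean_qscore_template",
      end_reason = "end_reason")
}

#' Read a MinKNOW-style sequencing summary
#'
#' Parses the tab-separated per-read summary emitted by the sequencer.
#' The fate column is left unset; assign it with [classifyReads()].
#'
#' @param path Path to the TSV file.
#' @param columns Named character vector mapping the required fields
#'   (`read_id`, `length`, `mean_q`, `end_reason`) to column names in the
#'   file; defaults to the MinKNOW names.
#' @return A [ReadSet-class].
#' @export
readSequencingSummary <- function(path, columns = .defaultSummaryColumns()) {
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(unname(columns), colnames(tab))
    if (length(missing))
        stop("sequencing summary is missing column(s) ",
             paste(missing, collapse = ", "), "; found: ",
             paste(colnames(tab), collapse = ", "))
    ReadSet(read_id = tab[[columns[["read_id"]]]],
            length = tab[[columns[["length"]]]],
            mean_q = tab[[columns[["mean_q"]]]],
            end_reason = tab[[columns[["end_reason"]]]])
}

#' Write a ReadSet as a MinKNOW-style sequencing summary
#'
#' @param reads A [ReadSet-class].
#' @param path Output path.
#' @param columns Column-name mapping (see [readSequencingSummary()]).
#' @return The path, invisibly.
#' @export
writeSequencingSummary <- function(reads, path,
                                   columns = .defaultSummaryColumns()) {
    df <- data.frame(readIDs(reads), readLengths(reads), meanQ(reads),
                     endReason(reads), stringsAsFactors = FALSE)
    colnames(df) <- unname(columns[c("read_id", "length", "mean_q",
                                     "end_reason")])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
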