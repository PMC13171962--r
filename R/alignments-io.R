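#' @importFrom GenomicAlignments readGAlignments cigar explodeCigarOps
#'   explodeCigarOpLengths
#' @importFrom Rsamtools asBam ScanBamParam countBam
NULL

## Query offset of the first aligned base, in original read orientation:
## leading soft/hard clips for forward alignments, trailing clips for
## reverse alignments.
.queryOffsets <- function(cigars, strands) {
    ops <- explodeCigarOps(cigars)
    lens <- explodeCigarOpLengths(cigars)
    mapply(function(op, ln, st) {
        if (st == "-") { op <- rev(op); ln <- rev(ln) }
        off <- 0L
        for (k in seq_along(op)) {
            if (op[k] %in% c("S", "H")) off <- off + ln[k] else break
        }
        off
    }, ops, lens, strands, USE.NAMES = FALSE)
}

.alignmentGRanges <- function(contig, start, end, strand, read_id,
                              segment_index, read_class, layout = NULL) {
    gr <- GRanges(contig, IRanges(start, end), strand = strand)
    mcols(gr)$read_id <- as.character(read_id)
    mcols(gr)$segment_index <- as.integer(segment_index)
    mcols(gr)$read_class <- as.character(read_class)
    if (!is.null(layout)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo(layout))
        GenomeInfoDb::seqinfo(gr) <- seqinfo(layout)
    }
    gr
}

#' Read alignment segments from SAM/BAM or the plain-table dialect
#'
#' Returns one range per aligned block of a read (primary and
#' supplementary alignments both contribute), the carrier of split-read
#' breakpoint evidence. For SAM/BAM, reference spans are derived from the
#' CIGAR (M/=/X/D/N consume reference), unmapped records are skipped with
#' a logged count and `segment_index` numbers each read's blocks by query
#' offset (0-based). The documented tab-separated fallback dialect has
#' columns `read_id`, `segment_index`, `contig`, `start`, `end`, `strand`,
#' `read_class`, with BED-style 0-based half-open coordinates, and keeps
#' the full pipeline testable without binary alignment files.
#'
#' @param path Path to a `.sam`, `.bam` or tab-separated file.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"tsv"`.
#' @param layout Optional [GenomeLayout-class] used to set seqinfo.
#' @return `GRanges` with metadata columns `read_id`, `segment_index`,
#'   `read_class` (`"unknown"` for SAM/BAM input; see [assignReadClass()]).
#' @export
readAlignments <- function(path, format = c("auto", "sam", "bam", "tsv"),
                           layout = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "auto") {
        format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam"
                  else if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam"
                  else "tsv"
    }
    if (format == "tsv")
        return(.readAlignmentsTSV(path, layout))
    bam <- if (format == "sam")
        suppressMessages(asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE))
    else path
    ga <- readGAlignments(bam, param = ScanBamParam(what = "qname"))
    total <- countBam(bam)$records
    if (total > length(ga))
        message(total - length(ga), " unmapped record(s) skipped")
    gr <- GRanges(GenomeInfoDb::seqnames(ga),
                  IRanges(GenomicAlignments::start(ga),
                          GenomicAlignments::end(ga)),
                  strand = GenomicAlignments::strand(ga))
    qname <- mcols(ga)$qname
    off <- .queryOffsets(cigar(ga), as.character(strand(gr)))
    ## order blocks of each read along the query
    ord <- order(qname, off, seq_along(ga))
    dup <- duplicated(data.frame(qname, off)) |
           duplicated(data.frame(qname, off), fromLast = TRUE)
    if (any(dup) && length(unique(qname[dup])) > 0)
        warning("ambiguous segment order within ",
                length(unique(qname[dup])),
                " read(s); ordered by file appearance")
    gr <- gr[ord]
    qname <- qname[ord]
    r <- rle(qname)
    idx <- unlist(lapply(r$lengths, function(n) seq_len(n) - 1L),
                  use.names = FALSE)
    out <- .alignmentGRanges(as.character(GenomeInfoDb::seqnames(gr)),
                             start(gr), end(gr),
                             as.character(strand(gr)), qname, idx,
                             "unknown", layout)
    out
}

.readAlignmentsTSV <- function(path, layout = NULL) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "segment_index", "contig", "start", "end",
              "strand", "read_class")
    missing <- setdiff(need, colnames(tab))
    if (length(missing))
        stop("alignment table is missing column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(tab) == 0)
        return(.alignmentGRanges(character(0), integer(0), integer(0),
                                 character(0), character(0), integer(0),
                                 character(0), layout))
    if (any(tab$end <= tab$start))
        stop("alignment end must exceed start (0-based half-open)")
    .alignmentGRanges(tab$contig, tab$start + 1L, tab$end, tab$strand,
                      tab$read_id, tab$segment_index, tab$read_class,
                      layout)
}

#' Write alignment segments in the plain-table dialect
#'
#' Inverse of the TSV branch of [readAlignments()] (0-based half-open
#' coordinates).
#'
#' @param alignments `GRanges` with `read_id`, `segment_index`,
#'   `read_class` metadata columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAlignmentsTSV <- function(alignments, path) {
    df <- data.frame(read_id = alignments$read_id,
                     segment_index = alignments$segment_index,
                     contig = as.character(GenomeInfoDb::seqnames(alignments)),
                     start = start(alignments) - 1L,
                     end = end(alignments),
                     strand = as.character(strand(alignments)),
                     read_class = alignments$read_class,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Label alignment segments with their read's adaptive-sampling fate
#'
#' Joins classified reads (see [classifyReads()]) onto alignment segments
#' by read id, filling the `read_class` metadata column.
#'
#' @param alignments `GRanges` from [readAlignments()].
#' @param reads A classified [ReadSet-class].
#' @return The alignments with `read_class` set (`"unknown"` where the
#'   read id is absent from `reads`).
#' @export
assignReadClass <- function(alignments, reads) {
    fate <- readFate(reads)[match(alignments$read_id, readIDs(reads))]
    fate[is.na(fate)] <- "unknown"
    alignments$read_class <- fate
    alignments
}
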