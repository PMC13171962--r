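## Read-fate classification, quality filtering and run statistics.

#' Verbatim end reason marking adaptive-sampling ejection
#' @export
EJECTED_END_REASON <- "data_service_unblock_mux_change"

#' Classify reads by adaptive-sampling fate
#'
#' A read is `off_target` if and only if its `end_reason` equals
#' `"data_service_unblock_mux_change"` (the sequencer ejected the
#' molecule); every other end reason - including a completed
#' `signal_positive` read - is `on_target`. The partition is total.
#' Records with an empty or missing end reason are flagged `on_target`
#' and their count reported in a message.
#'
#' @param reads A [ReadSet-class].
#' @return The same `ReadSet` with `fate` filled in.
#' @export
classifyReads <- function(reads) {
    er <- endReason(reads)
    blank <- is.na(er) | !nzchar(er)
    if (any(blank))
        message(sum(blank), " read(s) with empty end_reason flagged on_target")
    fate <- ifelse(!blank & er == EJECTED_END_REASON,
                   "off_target", "on_target")
    reads@reads$fate <- fate
    validObject(reads)
    reads
}

#' Discard reads below the mean-quality threshold
#'
#' Reads with mean quality strictly below `minQ` are discarded; a read at
#' exactly the threshold is kept. The discarded count is reported in a
#' message.
#'
#' @param reads A [ReadSet-class].
#' @param minQ Phred-scale threshold (default 10).
#' @return The filtered `ReadSet`.
#' @export
qualityFilter <- function(reads, minQ = 10) {
    keep <- meanQ(reads) >= minQ
    message(sum(!keep), " read(s) below Q", minQ, " discarded")
    reads[keep]
}

#' Read-length N50
#'
#' The largest length L such that reads of length >= L together contain at
#' least half of all sequenced bases: sort descending, accumulate, and
#' return the first length at which the cumulative sum reaches half the
#' total.
#'
#' @param lengths Numeric vector of read lengths (bp), each >= 0.
#' @return The N50 in bp.
#' @examples
#' readN50(c(1, 2, 3, 4, 5))  # 4: total 15, and 5 + 4 = 9 >= 7.5
#' @export
readN50 <- function(lengths) {
    if (length(lengths) == 0)
        stop("N50 is undefined for an empty length set")
    if (any(lengths < 0))
        stop("lengths must be >= 0")
    s <- sort(lengths, decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1]]
}

.alignedBasesIn <- function(alignments, region) {
    ov <- GenomicRanges::findOverlaps(alignments, region)
    if (length(ov) == 0) return(0)
    sum(as.numeric(width(GenomicRanges::pintersect(
        alignments[S4Vectors::queryHits(ov)],
        region[S4Vectors::subjectHits(ov)]))))
}

#' Run-level statistics table
#'
#' Computes the per-run overview: read counts and N50 per
#' adaptive-sampling fate, passing yield, mean depth per target region
#' (aligned bases within the region over region length, using all passing
#' reads), the autosomal on-target mean depth (chromosome X and Y regions
#' excluded), chromosome X target depth, genome-wide depth of all passing
#' reads, and target enrichment defined as autosomal on-target depth over
#' genome-wide depth.
#'
#' @param reads A classified and quality-filtered [ReadSet-class].
#' @param alignments `GRanges` of alignment segments; segments whose
#'   `read_id` is absent from `reads` are ignored.
#' @param regions `GRanges` of target regions (with a `name` column).
#' @param layout A [GenomeLayout-class]; its sex gates nothing here beyond
#'   reporting, but no autosomal targets is an error since enrichment is
#'   then undefined.
#' @return A [RunStats-class].
#' @export
runSummary <- function(reads, alignments, regions, layout) {
    if (anyNA(readFate(reads)))
        stop("reads must be classified first (see classifyReads)")
    keep <- alignments$read_id %in% readIDs(reads)
    aln <- alignments[keep]
    fate <- readFate(reads)
    nReads <- c(on_target = sum(fate == "on_target"),
                off_target = sum(fate == "off_target"))
    gb <- sum(readLengths(reads)) / 1e9
    onN50 <- readN50(readLengths(reads)[fate == "on_target"])
    offN50 <- readN50(readLengths(reads)[fate == "off_target"])
    contig <- as.character(GenomeInfoDb::seqnames(regions))
    regDepth <- vapply(seq_along(regions), function(i)
        .alignedBasesIn(aln, regions[i]) / width(regions)[i], numeric(1))
    names(regDepth) <- if (!is.null(regions$name)) regions$name
                       else paste0("R", seq_along(regions))
    auto <- !(.isChrX(contig) | .isChrY(contig))
    if (!any(auto))
        stop("no autosomal target regions; enrichment is undefined",
             if (sampleSex(layout) == "male") " for a male sample" else "")
    w <- as.numeric(width(regions))
    autoDepth <- sum(regDepth[auto] * w[auto]) / sum(w[auto])
    xDepth <- if (any(.isChrX(contig)))
        sum(regDepth[.isChrX(contig)] * w[.isChrX(contig)]) /
            sum(w[.isChrX(contig)])
    else NA_real_
    genomeDepth <- sum(as.numeric(width(aln))) / genomeSize(layout)
    new("RunStats", nReads = as.integer(nReads) |>
            stats::setNames(names(nReads)),
        gigabases = gb, onTargetN50 = onN50, offTargetN50 = offN50,
        regionDepth = regDepth, autosomalTargetDepth = autoDepth,
        chrXDepth = xDepth, genomeDepth = genomeDepth,
        enrichment = autoDepth / genomeDepth)
}
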