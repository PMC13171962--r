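#' Read and merge exclusion regions
#'
#' Loads a BED file of intervals to mask from the background scan (target
#' regions, common CNV regions, centromeres/telomeres) and merges
#' overlapping intervals.
#'
#' @param path BED file path.
#' @return Reduced (non-overlapping, sorted) `GRanges`.
#' @export
readExclusions <- function(path) {
    GenomicRanges::reduce(rtracklayer::import(path, format = "BED"))
}

#' Genome-wide depth profile of ejected reads
#'
#' Bins the whole genome and computes mean depth using only off-target
#' (ejected) alignment segments. Accepted reads are excluded because stray
#' on-target reads align outside the targets and would create regions of
#' falsely high coverage; masking of targets and known-unreliable regions
#' happens later, in [backgroundScan()].
#'
#' @param alignments `GRanges` with a `read_class` metadata column (see
#'   [assignReadClass()]).
#' @param layout A [GenomeLayout-class].
#' @param binSize Bin width in bp (default 10,000).
#' @return A [DepthProfile-class] with `readClass = "off_target_only"`.
#' @export
backgroundProfile <- function(alignments, layout, binSize = 1e4) {
    if (is.null(alignments$read_class))
        stop("alignments must carry a read_class column")
    off <- alignments[alignments$read_class == "off_target"]
    if (length(off) == 0)
        stop("no off-target alignment segments; cannot build a background profile")
    sl <- seqlengths(seqinfo(layout))
    tiles <- GRanges(names(sl), IRanges(1, as.numeric(sl)))
    binnedDepth(off, tiles, binSize = binSize,
                readClass = "off_target_only")
}

#' Scan the genome background for large copy-number variants
#'
#' Masks excluded bins, computes a per-chromosome reference depth from the
#' remaining bins (mean by default; a median option is available for
#' robustness when a large event biases its own chromosome), scores
#' windows of `window` bp by the log2 ratio of their unmasked mean depth
#' to the chromosome reference, and merges consecutive same-direction
#' aberrant windows into calls. Windows with fewer than
#' `minUnmaskedFrac` of their bins unmasked are not scored. Chromosomes
#' that are fully masked (or have zero reference depth) are skipped with
#' a warning.
#'
#' @param profile A [DepthProfile-class] from [backgroundProfile()].
#' @param exclusions `GRanges` of masked intervals (include the target
#'   regions).
#' @param window Scan window in bp (default 1e6).
#' @param lossCut,gainCut log2 cut-offs (as in [segmentAndCall()]).
#' @param stat Per-chromosome reference statistic: `"mean"` (default) or
#'   `"median"`.
#' @param minUnmaskedFrac Minimum fraction of unmasked bins per scored
#'   window (default 0.5).
#' @param floor log2 floor for zero-depth windows (default -5).
#' @return `GRanges` of calls with metadata columns `mean_log2`,
#'   `direction` (`"loss"`/`"gain"`), `n_windows`.
#' @export
backgroundScan <- function(profile, exclusions, window = 1e6,
                           lossCut = -0.415, gainCut = 0.32,
                           stat = c("mean", "median"),
                           minUnmaskedFrac = 0.5, floor = -5) {
    stat <- match.arg(stat)
    if (window < binSize(profile))
        stop("window must be at least one bin wide")
    bins <- profileBins(profile)
    masked <- IRanges::overlapsAny(bins, exclusions)
    contigs <- as.character(GenomeInfoDb::seqnames(bins))
    calls <- list()
    for (ctg in unique(contigs)) {
        sel <- contigs == ctg
        ub <- sel & !masked
        if (!any(ub)) {
            warning("contig ", ctg, " fully masked; skipped")
            next
        }
        ref <- if (stat == "mean") mean(bins$depth[ub])
               else stats::median(bins$depth[ub])
        if (ref == 0) {
            warning("contig ", ctg, " has zero reference depth; skipped")
            next
        }
        b <- bins[sel]
        bm <- masked[sel]
        win <- (start(b) - 1) %/% window
        uw <- sort(unique(win))
        stats_ <- vapply(uw, function(wd) {
            ix <- which(win == wd)
            ok <- !bm[ix]
            if (mean(ok) < minUnmaskedFrac)
                return(c(NA_real_, NA_real_))
            w <- as.numeric(width(b)[ix][ok])
            d <- sum(b$depth[ix][ok] * w) / sum(w)
            c(max(ifelse(d > 0, log2(d / ref), -Inf), floor), d)
        }, numeric(2))
        wlog2 <- stats_[1, ]
        dir <- ifelse(is.na(wlog2), NA_character_,
                      ifelse(wlog2 <= lossCut, "loss",
                             ifelse(wlog2 >= gainCut, "gain", NA_character_)))
        ## merge consecutive aberrant windows of the same direction
        j <- 1
        while (j <= length(uw)) {
            if (is.na(dir[j])) { j <- j + 1; next }
            k <- j
            while (k + 1 <= length(uw) && !is.na(dir[k + 1]) &&
                   dir[k + 1] == dir[j] && uw[k + 1] == uw[k] + 1)
                k <- k + 1
            wix <- which(win %in% uw[j:k] & !bm)
            w <- as.numeric(width(b)[wix])
            d <- sum(b$depth[wix] * w) / sum(w)
            calls[[length(calls) + 1L]] <- data.frame(
                contig = ctg,
                start = uw[j] * window + 1,
                end = min(max(end(b)), (uw[k] + 1) * window),
                mean_log2 = max(ifelse(d > 0, log2(d / ref), -Inf), floor),
                direction = dir[j], n_windows = k - j + 1)
            j <- k + 1
        }
    }
    if (!length(calls)) {
        empty <- GRanges()
        mcols(empty) <- S4Vectors::DataFrame(mean_log2 = numeric(0),
            direction = character(0), n_windows = integer(0))
        return(empty)
    }
    tab <- do.call(rbind, calls)
    gr <- GRanges(tab$contig, IRanges(tab$start, tab$end))
    mcols(gr)$mean_log2 <- tab$mean_log2
    mcols(gr)$direction <- tab$direction
    mcols(gr)$n_windows <- as.integer(tab$n_windows)
    gr
}
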