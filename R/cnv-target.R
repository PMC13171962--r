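#' @importFrom IRanges Views viewMeans
#' @importFrom S4Vectors Rle queryHits subjectHits elementNROWS
NULL

## Coverage Rle per contig, padded with zeros to the requested lengths.
.paddedCoverage <- function(alignments, contigs, minLengths) {
    cvg <- GenomicRanges::coverage(alignments)
    out <- vector("list", length(contigs))
    names(out) <- contigs
    for (i in seq_along(contigs)) {
        ctg <- contigs[i]
        r <- if (ctg %in% names(cvg)) cvg[[ctg]] else Rle(0L, 0L)
        if (length(r) < minLengths[i])
            r <- c(r, Rle(0L, minLengths[i] - length(r)))
        out[[i]] <- r
    }
    out
}

#' Mean depth in fixed-width bins
#'
#' Tiles each interval with non-overlapping bins of `binSize` bp (the last
#' bin of an interval may be short) and computes the mean aligned depth
#' per bin: aligned bases overlapping the bin divided by the bin width,
#' with alignments clipped at bin boundaries - the mean-depth convention
#' of standard binned-coverage tools.
#'
#' @param alignments `GRanges` of alignment segments.
#' @param intervals `GRanges` to tile (target regions, or genome-wide
#'   tiles).
#' @param binSize Bin width in bp (default 500, the target-region
#'   convention; the genome-wide background uses 10,000).
#' @param readClass Provenance label stored on the profile
#'   (`"all_passing"` or `"off_target_only"`).
#' @return A [DepthProfile-class]; bins carry `depth` and the index
#'   (`region`) of the parent interval.
#' @export
binnedDepth <- function(alignments, intervals, binSize = 500,
                        readClass = "all_passing") {
    if (binSize < 1)
        stop("binSize must be >= 1")
    if (length(intervals) == 0 || any(width(intervals) < 1))
        stop("intervals must be non-empty with width >= 1")
    binsList <- GenomicRanges::slidingWindows(intervals, width = binSize,
                                              step = binSize)
    bins <- unlist(binsList)
    region <- rep(seq_along(intervals), elementNROWS(binsList))
    contigs <- as.character(GenomeInfoDb::seqnames(bins))
    uctg <- unique(contigs)
    maxEnd <- vapply(uctg, function(ctg) max(end(bins)[contigs == ctg]),
                     numeric(1))
    cvg <- .paddedCoverage(alignments, uctg, maxEnd)
    depth <- numeric(length(bins))
    for (ctg in uctg) {
        sel <- which(contigs == ctg)
        depth[sel] <- viewMeans(Views(cvg[[ctg]], start(bins)[sel],
                                      end(bins)[sel]))
    }
    mcols(bins) <- NULL
    mcols(bins)$depth <- depth
    mcols(bins)$region <- region
    new("DepthProfile", bins = bins, binSize = binSize,
        readClass = readClass)
}

#' Per-bin log2 depth ratio against the mean of all targets
#'
#' The reference level is the length-weighted mean depth over all target
#' bins; for a male sample, chromosome X bins are excluded from the
#' reference but still receive ratios, computed against the male-X
#' baseline of half the autosomal reference. Zero-depth bins (and any
#' ratio below the floor) are reported at the configurable log2 floor.
#'
#' @param profile A [DepthProfile-class] over all target regions.
#' @param layout A [GenomeLayout-class] (provides the sample sex).
#' @param floor log2 sentinel for zero-depth bins (default -5).
#' @return A [RatioTrack-class].
#' @export
targetLog2 <- function(profile, layout, floor = -5) {
    bins <- profileBins(profile)
    contigs <- as.character(GenomeInfoDb::seqnames(bins))
    male <- sampleSex(layout) == "male"
    norm <- if (male) !.isChrX(contigs) else rep(TRUE, length(bins))
    if (!any(norm))
        stop("no autosomal target bins available for normalization")
    w <- as.numeric(width(bins))
    mu <- sum(bins$depth[norm] * w[norm]) / sum(w[norm])
    if (mu == 0)
        stop("reference depth is zero; degenerate run")
    ref <- rep(mu, length(bins))
    if (male) ref[.isChrX(contigs)] <- mu / 2
    r <- ifelse(bins$depth > 0, log2(bins$depth / ref), -Inf)
    r <- pmax(r, floor)
    mcols(bins)$ref <- ref
    mcols(bins)$log2 <- r
    new("RatioTrack", bins = bins, reference = mu,
        sex = sampleSex(layout), floor = floor)
}

## Scaled-CUSUM binary segmentation of a run of window values. Returns a
## list of index vectors (contiguous), splitting recursively wherever the
## best change point separates means by at least minSplit and leaves at
## least minWindows windows on each side.
.splitRun <- function(v, minSplit, minWindows) {
    n <- length(v)
    if (n < 2 * minWindows)
        return(list(seq_len(n)))
    ks <- seq(minWindows, n - minWindows)
    cs <- cumsum(v)
    tot <- cs[n]
    delta <- cs[ks] / ks - (tot - cs[ks]) / (n - ks)
    g <- abs(delta) * sqrt(ks * (n - ks) / n)
    k <- ks[which.max(g)]
    if (abs(delta[which(ks == k)]) < minSplit)
        return(list(seq_len(n)))
    left <- .splitRun(v[seq_len(k)], minSplit, minWindows)
    right <- .splitRun(v[seq(k + 1, n)], minSplit, minWindows)
    c(left, lapply(right, function(ix) ix + k))
}

.segStatus <- function(cn, baseline) {
    ifelse(cn < baseline, "loss", ifelse(cn > baseline, "gain", "neutral"))
}

#' Segment a log2 track into copy-number calls
#'
#' Windows of `windowBins` consecutive bins are scored by the log2 ratio
#' of their mean depth to their reference level and classified as loss
#' (`<= lossCut`), gain (`>= gainCut`) or neutral; ties at a cut-off
#' classify as aberrant. Adjacent same-status windows merge; aberrant
#' runs shorter than `minWindows` windows are suppressed (relabelled
#' neutral). Because a complex rearrangement can hold several distinct
#' copy-number levels at the same status (e.g. triplicated flanks around a
#' quintuplicated core), each merged run is then split recursively at
#' mean-shift change points of at least `minSplit` log2 units, and
#' adjacent final segments with identical integer copy number re-merge.
#' Each segment reports its mean log2 ratio over bins, the integer
#' copy-number estimate `round(baseline * 2^mean_log2)` (baseline 2, or 1
#' on the male X) and a status consistent with that estimate.
#'
#' @param track A [RatioTrack-class] from [targetLog2()].
#' @param windowBins Bins per window (default 10, i.e. 5 kb at 500 bp
#'   bins).
#' @param lossCut,gainCut log2 cut-offs (defaults -0.415 and +0.32,
#'   symmetric in copy-number space about the diploid baseline).
#' @param minWindows Minimum windows per reported aberrant segment
#'   (default 3).
#' @param minSplit Minimum log2 mean shift for an intra-run split
#'   (default 0.4: about three standard deviations of a short window-run
#'   mean at 30x, while safely below the smallest same-status step the
#'   method resolves, CN 4 vs CN 6 at 0.585).
#' @return `GRanges` of segments with metadata columns `region`,
#'   `mean_log2`, `cn_estimate`, `n_bins`, `n_windows`, `status`.
#' @export
segmentAndCall <- function(track, windowBins = 10, lossCut = -0.415,
                           gainCut = 0.32, minWindows = 3,
                           minSplit = 0.4) {
    bins <- trackBins(track)
    if (length(bins) == 0)
        stop("empty track")
    male <- track@sex == "male"
    out <- list()
    for (reg in unique(bins$region)) {
        ix <- which(bins$region == reg)
        b <- bins[ix]
        n <- length(b)
        win <- rep(seq_len(ceiling(n / windowBins)),
                   each = windowBins)[seq_len(n)]
        w <- as.numeric(width(b))
        wdepth <- as.vector(tapply(b$depth * w, win, sum) /
                            tapply(b$ref * w, win, sum))
        wval <- pmax(ifelse(wdepth > 0, log2(wdepth), -Inf), track@floor)
        status <- ifelse(wval <= lossCut, "loss",
                         ifelse(wval >= gainCut, "gain", "neutral"))
        ## suppress short aberrant runs, then re-merge
        r <- rle(status)
        r$values[r$values != "neutral" & r$lengths < minWindows] <- "neutral"
        status <- inverse.rle(r)
        r <- rle(status)
        runEnd <- cumsum(r$lengths)
        runStart <- runEnd - r$lengths + 1
        segWins <- list()
        for (j in seq_along(r$lengths)) {
            wix <- seq(runStart[j], runEnd[j])
            parts <- .splitRun(wval[wix], minSplit, minWindows)
            segWins <- c(segWins, lapply(parts, function(p) wix[p]))
        }
        ## per-segment stats over member bins
        contig <- as.character(GenomeInfoDb::seqnames(b))[1]
        baseline <- if (male && .isChrX(contig)) 1 else 2
        mkSeg <- function(wix) {
            bix <- which(win %in% wix)
            ratio <- sum(b$depth[bix] * w[bix]) / sum(b$ref[bix] * w[bix])
            ml2 <- max(ifelse(ratio > 0, log2(ratio), -Inf), track@floor)
            cn <- as.integer(round(baseline * 2^ml2))
            data.frame(start = min(start(b)[bix]), end = max(end(b)[bix]),
                       mean_log2 = ml2, cn_estimate = cn,
                       n_bins = length(bix), n_windows = length(wix))
        }
        segs <- do.call(rbind, lapply(segWins, mkSeg))
        ## re-merge adjacent segments with identical copy number
        keep <- c(TRUE, segs$cn_estimate[-1] !=
                        segs$cn_estimate[-nrow(segs)])
        grp <- cumsum(keep)
        mergedWins <- lapply(split(seq_len(nrow(segs)), grp),
                             function(ii) sort(unlist(segWins[ii])))
        ## refine each boundary between different copy-number levels:
        ## with both segment means pinned, re-place the boundary within a
        ## local neighbourhood by whitened least squares. Depth noise is
        ## correlated over a read length (several windows), so an AR(1)
        ## whitening step is needed: under plain squared error a
        ## correlated excursion adjacent to the true step drags the
        ## boundary several windows off.
        if (length(mergedWins) > 1) {
            rho <- {
                resid <- wval[unlist(mergedWins)] -
                    unlist(lapply(mergedWins, function(W)
                        rep(mean(wval[W]), length(W))))
                r1 <- if (length(resid) > 5)
                    suppressWarnings(stats::cor(resid[-1],
                                                resid[-length(resid)]))
                else 0
                ## zero-variance residuals (noise-free tracks) give NA
                if (is.na(r1)) 0 else max(0, min(0.8, r1))
            }
            halo <- 15L
            for (j in seq_len(length(mergedWins) - 1)) {
                W1 <- mergedWins[[j]]; W2 <- mergedWins[[j + 1]]
                if (!length(W1) || !length(W2)) next
                m1 <- mean(wval[W1]); m2 <- mean(wval[W2])
                lo <- max(1L, length(W1) - halo)
                hi <- min(length(W2), halo)
                comb <- c(W1[seq(lo, length(W1))], W2[seq_len(hi)])
                v <- wval[comb]
                nl <- length(W1) - lo + 1L   # current boundary index
                best <- NULL
                for (k in seq_len(length(comb) - 1)) {
                    mu <- c(rep(m1, k), rep(m2, length(comb) - k))
                    r <- v - mu
                    wres <- r[-1] - rho * r[-length(r)]
                    sse <- r[1]^2 * (1 - rho^2) + sum(wres^2)
                    if (is.null(best) || sse < best$sse)
                        best <- list(k = k, sse = sse)
                }
                if (!is.null(best) && best$k != nl) {
                    allw <- c(W1, W2)
                    kAbs <- lo - 1L + best$k
                    mergedWins[[j]] <- allw[seq_len(kAbs)]
                    mergedWins[[j + 1]] <- allw[seq(kAbs + 1,
                                                    length(allw))]
                }
            }
        }
        ## refinement can change integer estimates: re-merge equal-CN
        ## neighbours until stable
        repeat {
            merged <- do.call(rbind, lapply(mergedWins, mkSeg))
            if (nrow(merged) < 2) break
            same <- merged$cn_estimate[-1] ==
                    merged$cn_estimate[-nrow(merged)]
            if (!any(same)) break
            grp2 <- cumsum(c(TRUE, !same))
            mergedWins <- lapply(split(seq_len(nrow(merged)), grp2),
                function(ii) sort(unlist(mergedWins[ii])))
        }
        merged$region <- reg
        merged$baseline <- baseline
        merged$contig <- contig
        out[[length(out) + 1L]] <- merged
    }
    tab <- do.call(rbind, out)
    gr <- GRanges(tab$contig, IRanges(tab$start, tab$end))
    mcols(gr) <- S4Vectors::DataFrame(
        region = tab$region, mean_log2 = tab$mean_log2,
        cn_estimate = tab$cn_estimate, n_bins = tab$n_bins,
        n_windows = tab$n_windows,
        status = .segStatus(tab$cn_estimate, tab$baseline))
    gr
}

#' Distinguish a deletion from two flanking duplications
#'
#' With targeted sequencing, a depth dip judged only against its immediate
#' flanks is ambiguous: the same picture arises from one deletion at the
#' diploid baseline or from two flanking duplications around a normal
#' block. Normalizing against the mean of all (additional) target regions
#' resolves it: a dip whose absolute log2 level reaches the loss cut-off
#' is a deletion, while a neutral-level block flanked by gain segments is
#' the two-duplications pattern. Requires at least two target regions so
#' that an external reference level exists.
#'
#' @param segments Segment calls from [segmentAndCall()].
#' @param track The [RatioTrack-class] the segments were called on.
#' @param lossCut,gainCut log2 cut-offs (as in [segmentAndCall()]).
#' @return The segments with an added `interpretation` metadata column:
#'   `"deletion (absolute)"`, `"duplication (absolute)"`,
#'   `"two flanking duplications"`, `"reference level"`, or
#'   `"indeterminate (no external reference)"` when only one target region
#'   is available.
#' @export
disambiguateDelVsDup <- function(segments, track, lossCut = -0.415,
                                 gainCut = 0.32) {
    nRegions <- length(unique(trackBins(track)$region))
    interp <- rep("reference level", length(segments))
    if (nRegions < 2) {
        segments$interpretation <-
            rep("indeterminate (no external reference)", length(segments))
        return(segments)
    }
    for (reg in unique(segments$region)) {
        ix <- which(segments$region == reg)
        st <- segments$status[ix]
        ml <- segments$mean_log2[ix]
        for (k in seq_along(ix)) {
            if (st[k] == "loss" && ml[k] <= lossCut)
                interp[ix[k]] <- "deletion (absolute)"
            else if (st[k] == "gain" && ml[k] >= gainCut)
                interp[ix[k]] <- "duplication (absolute)"
            else if (st[k] == "neutral" && k > 1 && k < length(ix) &&
                     st[k - 1] == "gain" && st[k + 1] == "gain")
                interp[ix[k]] <- "two flanking duplications"
        }
    }
    segments$interpretation <- interp
    segments
}
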