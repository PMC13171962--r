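#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqlevels seqinfo
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

## ---------------------------------------------------------------------------
## GenomeLayout: an ordered contig/length table plus the sample sex, which
## drives the copy-number baseline on chromosome X (2 on autosomes and the
## female X, 1 on the male X).
## ---------------------------------------------------------------------------

#' Genome description used throughout the pipeline
#'
#' A `GenomeLayout` bundles an ordered set of contigs with their lengths
#' (held as a [GenomeInfoDb::Seqinfo-class]) and the sex of the sample.
#' Sex is a configuration input, not inferred from data: it determines the
#' copy-number baseline on chromosome X (1 in males, 2 otherwise) and
#' whether chromosome X target regions enter the depth-normalization
#' reference.
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo-class] with contig names and lengths.
#' @slot sex One of `"male"`, `"female"`, `"unknown"`.
#' @export
setClass("GenomeLayout",
    representation(seqinfo = "Seqinfo", sex = "character"))

setValidity("GenomeLayout", function(object) {
    msg <- character()
    sl <- seqlengths(object@seqinfo)
    if (length(sl) == 0L)
        msg <- c(msg, "layout must contain at least one contig")
    if (anyNA(sl) || any(sl <= 0))
        msg <- c(msg, "all contig lengths must be positive and non-missing")
    if (anyDuplicated(names(sl)))
        msg <- c(msg, "contig names must be unique")
    if (length(object@sex) != 1L ||
        !object@sex %in% c("male", "female", "unknown"))
        msg <- c(msg, "sex must be one of 'male', 'female', 'unknown'")
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeLayout
#'
#' @param contigs Character vector of contig names, or a `Seqinfo`.
#' @param lengths Integer-like vector of contig lengths in bp (ignored when
#'   `contigs` is a `Seqinfo`).
#' @param sex Sample sex: `"male"`, `"female"` or `"unknown"` (default).
#' @return A [GenomeLayout-class] object.
#' @examples
#' gl <- GenomeLayout(c("chr1", "chr2", "chr3"), c(5e6, 5e6, 3e6))
#' genomeSize(gl)
#' @export
GenomeLayout <- function(contigs, lengths = NULL, sex = "unknown") {
    si <- if (is(contigs, "Seqinfo")) contigs
          else Seqinfo(seqnames = as.character(contigs),
                       seqlengths = as.integer(round(lengths)))
    new("GenomeLayout", seqinfo = si, sex = sex)
}

#' @describeIn GenomeLayout Sample sex.
#' @param x A `GenomeLayout`.
#' @export
setMethod("sampleSex", "GenomeLayout", function(x) x@sex)

#' @describeIn GenomeLayout Total genome length in bp.
#' @export
setMethod("genomeSize", "GenomeLayout",
    function(x) sum(as.numeric(seqlengths(x@seqinfo))))

#' @export
setMethod("seqinfo", "GenomeLayout", function(x) x@seqinfo)

setMethod("show", "GenomeLayout", function(object) {
    sl <- seqlengths(object@seqinfo)
    cat("GenomeLayout with", length(sl), "contigs,",
        sprintf("%.3f Mb total, sex =", sum(as.numeric(sl)) / 1e6),
        object@sex, "\n")
    n <- min(5L, length(sl))
    for (i in seq_len(n))
        cat(sprintf("  %s  %d bp\n", names(sl)[i], sl[i]))
    if (length(sl) > n) cat("  ...\n")
})

## ---------------------------------------------------------------------------
## ReadSet: per-read summary metadata from a sequencing run.
## ---------------------------------------------------------------------------

#' Per-read summary metadata
#'
#' One row per sequenced read, as parsed from a MinKNOW-style sequencing
#' summary: read id, read length (bp), phred-scale mean base quality and the
#' verbatim `end_reason` string. The adaptive-sampling fate
#' (`"on_target"`/`"off_target"`) is `NA` until assigned by [classifyReads()].
#'
#' @slot reads A [S4Vectors::DataFrame-class] with columns `read_id`,
#'   `length`, `mean_q`, `end_reason`, `fate`.
#' @export
setClass("ReadSet", representation(reads = "DataFrame"))

setValidity("ReadSet", function(object) {
    req <- c("read_id", "length", "mean_q", "end_reason", "fate")
    msg <- character()
    if (!all(req %in% colnames(object@reads)))
        msg <- c(msg, paste("missing columns:",
                 paste(setdiff(req, colnames(object@reads)), collapse = ", ")))
    else {
        if (any(object@reads$length < 0, na.rm = TRUE))
            msg <- c(msg, "read lengths must be >= 0")
        bad <- !object@reads$fate %in% c("on_target", "off_target", NA)
        if (any(bad))
            msg <- c(msg, "fate must be 'on_target', 'off_target' or NA")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ReadSet
#'
#' @param read_id Character vector of read identifiers.
#' @param length Numeric vector of read lengths (bp).
#' @param mean_q Numeric vector of mean base qualities (phred scale).
#' @param end_reason Character vector of verbatim MinKNOW end reasons.
#' @param fate Optional fate labels; defaults to `NA` (unclassified).
#' @return A [ReadSet-class].
#' @export
ReadSet <- function(read_id, length, mean_q, end_reason,
                    fate = NA_character_) {
    df <- DataFrame(read_id = as.character(read_id),
                    length = as.numeric(length),
                    mean_q = as.numeric(mean_q),
                    end_reason = as.character(end_reason),
                    fate = rep_len(as.character(fate), base::length(read_id)))
    new("ReadSet", reads = df)
}

#' @export
setMethod("length", "ReadSet", function(x) nrow(x@reads))

#' @describeIn ReadSet Read identifiers.
#' @param x A `ReadSet`.
#' @export
setMethod("readIDs", "ReadSet", function(x) x@reads$read_id)

#' @describeIn ReadSet Read lengths in bp.
#' @export
setMethod("readLengths", "ReadSet", function(x) x@reads$length)

#' @describeIn ReadSet Mean base qualities.
#' @export
setMethod("meanQ", "ReadSet", function(x) x@reads$mean_q)

#' @describeIn ReadSet Verbatim end-reason strings.
#' @export
setMethod("endReason", "ReadSet", function(x) x@reads$end_reason)

#' @describeIn ReadSet Adaptive-sampling fate labels.
#' @export
setMethod("readFate", "ReadSet", function(x) x@reads$fate)

#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, reads = x@reads[i, , drop = FALSE])
})

#' Coerce a ReadSet to data.frame
#' @param x A `ReadSet`.
#' @param ... Unused.
#' @export
as.data.frame.ReadSet <- function(x, ...) as.data.frame(x@reads)

setMethod("show", "ReadSet", function(object) {
    cat("ReadSet with", nrow(object@reads), "reads\n")
    ft <- table(object@reads$fate, useNA = "ifany")
    cat("  fate:", paste(names(ft), ft, sep = "=", collapse = " "), "\n")
    cat(sprintf("  total %.3f Mb, mean Q %.1f\n",
        sum(object@reads$length) / 1e6, mean(object@reads$mean_q)))
})

## ---------------------------------------------------------------------------
## DepthProfile / RatioTrack
## ---------------------------------------------------------------------------

#' Binned mean-depth profile
#'
#' Mean aligned depth in fixed-width bins tiling a set of intervals
#' (targets, or the whole genome). The last bin of an interval may be short.
#' `readClass` records the read-class provenance of the profile:
#' `"all_passing"` for target profiles, `"off_target_only"` for the
#' background scan.
#'
#' @slot bins A `GRanges` with metadata columns `depth` (mean depth) and
#'   `region` (index of the parent interval).
#' @slot binSize Nominal bin width in bp.
#' @slot readClass `"all_passing"` or `"off_target_only"`.
#' @export
setClass("DepthProfile",
    representation(bins = "GRanges", binSize = "numeric",
                   readClass = "character"))

setValidity("DepthProfile", function(object) {
    msg <- character()
    if (!"depth" %in% colnames(S4Vectors::mcols(object@bins)))
        msg <- c(msg, "bins must carry a 'depth' metadata column")
    else if (any(object@bins$depth < 0))
        msg <- c(msg, "depth must be >= 0")
    if (object@binSize < 1)
        msg <- c(msg, "binSize must be >= 1")
    if (!object@readClass %in% c("all_passing", "off_target_only"))
        msg <- c(msg, "readClass must be 'all_passing' or 'off_target_only'")
    if (length(msg)) msg else TRUE
})

#' @describeIn DepthProfile The bins as a `GRanges`.
#' @param x A `DepthProfile`.
#' @export
setMethod("profileBins", "DepthProfile", function(x) x@bins)

#' @describeIn DepthProfile Nominal bin width (bp).
#' @export
setMethod("binSize", "DepthProfile", function(x) x@binSize)

#' @describeIn DepthProfile Read-class provenance.
#' @export
setMethod("readClass", "DepthProfile", function(x) x@readClass)

setMethod("show", "DepthProfile", function(object) {
    cat("DepthProfile:", length(object@bins), "bins of", object@binSize,
        "bp,", object@readClass, "reads\n")
    cat(sprintf("  mean depth %.2fx\n", mean(object@bins$depth)))
})

#' Per-bin log2 depth-ratio track over target regions
#'
#' Produced by [targetLog2()]: each bin carries its raw depth, the
#' per-bin reference level (the length-weighted mean depth of all target
#' bins; halved on the male X) and the log2 ratio against that reference.
#'
#' @slot bins `GRanges` with metadata columns `depth`, `ref`, `log2`,
#'   `region`.
#' @slot reference The autosomal reference depth level (x-fold).
#' @slot sex Sample sex used when computing the reference.
#' @slot floor log2 floor substituted for zero-depth bins.
#' @export
setClass("RatioTrack",
    representation(bins = "GRanges", reference = "numeric",
                   sex = "character", floor = "numeric"))

#' @describeIn RatioTrack The bins as a `GRanges`.
#' @param x A `RatioTrack`.
#' @export
setMethod("trackBins", "RatioTrack", function(x) x@bins)

#' @describeIn RatioTrack The reference depth level.
#' @export
setMethod("referenceDepth", "RatioTrack", function(x) x@reference)

setMethod("show", "RatioTrack", function(object) {
    cat("RatioTrack:", length(object@bins), "bins, reference",
        sprintf("%.2fx, sex = %s\n", object@reference, object@sex))
})

## ---------------------------------------------------------------------------
## JunctionSet
## ---------------------------------------------------------------------------

#' Clustered breakpoint junctions
#'
#' Each row is one junction supported by `support` distinct
#' breakpoint-spanning reads. Sides are canonically ordered (lexicographic
#' contig, then position) so equality between junctions is well defined.
#' Orientations: `"tail"` means the retained sequence lies to the left of
#' the position (the junction sits at the 3' reference end of a
#' forward-oriented segment); `"head"` means it lies to the right.
#'
#' @slot junctions A `DataFrame` with columns `contig_a`, `pos_a`,
#'   `orient_a`, `contig_b`, `pos_b`, `orient_b`, `support`, `type`,
#'   `pos_a_lo`, `pos_a_hi`, `pos_b_lo`, `pos_b_hi` and a `CharacterList`
#'   column `read_ids`.
#' @export
setClass("JunctionSet", representation(junctions = "DataFrame"))

setValidity("JunctionSet", function(object) {
    req <- c("contig_a", "pos_a", "orient_a", "contig_b", "pos_b",
             "orient_b", "support", "type")
    msg <- character()
    if (!all(req %in% colnames(object@junctions)))
        msg <- c(msg, paste("missing columns:",
                 paste(setdiff(req, colnames(object@junctions)),
                       collapse = ", ")))
    else if (nrow(object@junctions) > 0 &&
             any(object@junctions$support < 1))
        msg <- c(msg, "support must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("length", "JunctionSet", function(x) nrow(x@junctions))

#' @describeIn JunctionSet The junction table as a `DataFrame`.
#' @param x A `JunctionSet`.
#' @export
setMethod("junctionTable", "JunctionSet", function(x) x@junctions)

#' @describeIn JunctionSet Per-junction spanning-read support.
#' @export
setMethod("junctionSupport", "JunctionSet", function(x) x@junctions$support)

#' @export
setMethod("[", "JunctionSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, junctions = x@junctions[i, , drop = FALSE])
})

#' Coerce a JunctionSet to data.frame (read ids collapsed)
#' @param x A `JunctionSet`.
#' @param ... Unused.
#' @export
as.data.frame.JunctionSet <- function(x, ...) {
    df <- x@junctions
    rid <- if ("read_ids" %in% colnames(df))
        vapply(df$read_ids, paste, character(1), collapse = ",")
    else character(nrow(df))
    df$read_ids <- NULL
    out <- as.data.frame(df)
    out$read_ids <- rid
    out
}

setMethod("show", "JunctionSet", function(object) {
    cat("JunctionSet with", nrow(object@junctions), "junctions\n")
    if (nrow(object@junctions)) {
        df <- object@junctions
        for (i in seq_len(min(8L, nrow(df))))
            cat(sprintf("  %s:%d(%s) -- %s:%d(%s)  %s support=%d\n",
                df$contig_a[i], df$pos_a[i], df$orient_a[i],
                df$contig_b[i], df$pos_b[i], df$orient_b[i],
                df$type[i], df$support[i]))
        if (nrow(df) > 8L) cat("  ...\n")
    }
})

## ---------------------------------------------------------------------------
## SegmentGraph
## ---------------------------------------------------------------------------

#' Copy-number segment graph of one rearrangement locus
#'
#' Nodes are the contiguous copy-number segments of a locus (tiling it in
#' reference order); edges are reference adjacencies plus observed
#' junctions. Each segment carries its multiplicity on the rearranged
#' haplotype (for a heterozygous event, the called total copy number minus
#' one reference copy). Flanking reference anchors are implicit: the walk
#' enters at the left edge of the first segment and must leave at the right
#' edge of the last.
#'
#' @slot segments `GRanges` with metadata columns `id` (short label) and
#'   `multiplicity` (non-negative integer copies on the derived haplotype).
#' @slot junctions A [JunctionSet-class].
#' @slot tol Breakpoint-matching tolerance in bp.
#' @export
setClass("SegmentGraph",
    representation(segments = "GRanges", junctions = "JunctionSet",
                   tol = "numeric"))

setValidity("SegmentGraph", function(object) {
    seg <- object@segments
    msg <- character()
    mc <- S4Vectors::mcols(seg)
    if (!all(c("id", "multiplicity") %in% colnames(mc)))
        return("segments need 'id' and 'multiplicity' metadata columns")
    if (any(mc$multiplicity < 0))
        msg <- c(msg, "multiplicities must be >= 0")
    if (anyDuplicated(mc$id))
        msg <- c(msg, "segment ids must be unique")
    if (length(seg) > 1L) {
        o <- order(GenomicRanges::start(seg))
        if (!identical(o, seq_along(seg)))
            msg <- c(msg, "segments must be sorted by start position")
    }
    ## every junction endpoint must sit near a segment boundary
    jt <- junctionTable(object@junctions)
    if (nrow(jt) > 0) {
        bnd <- c(GenomicRanges::start(seg) - 1L, GenomicRanges::end(seg))
        pos <- c(jt$pos_a, jt$pos_b)
        ok <- vapply(pos, function(p) any(abs(bnd - p) <= object@tol),
                     logical(1))
        if (!all(ok))
            msg <- c(msg, "junction endpoints must lie within tol of a segment boundary")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SegmentGraph
#'
#' @param segments `GRanges` tiling the locus, with metadata columns `id`
#'   and `multiplicity` (copies on the derived haplotype).
#' @param junctions A [JunctionSet-class] of observed junctions.
#' @param tol Breakpoint matching tolerance in bp (default 50).
#' @return A [SegmentGraph-class].
#' @export
SegmentGraph <- function(segments, junctions, tol = 50) {
    segments <- GenomicRanges::sort(segments)
    new("SegmentGraph", segments = segments, junctions = junctions,
        tol = tol)
}

#' @describeIn SegmentGraph Segment nodes.
#' @param x A `SegmentGraph`.
#' @export
setMethod("graphSegments", "SegmentGraph", function(x) x@segments)

#' @describeIn SegmentGraph Junction edges.
#' @export
setMethod("graphJunctions", "SegmentGraph", function(x) x@junctions)

setMethod("show", "SegmentGraph", function(object) {
    seg <- object@segments
    cat("SegmentGraph:", length(seg), "segments,",
        length(object@junctions), "junctions, tol", object@tol, "bp\n")
    cat("  multiplicities:",
        paste(seg$id, seg$multiplicity, sep = "x", collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

#' A structural variant planted in a simulated run
#'
#' Use the constructors [svDeletion()], [svDuplication()],
#' [svTriplication()], [svQuintuplication()], [svTranslocation()] and
#' [svComposite()] rather than `new()`.
#'
#' @slot kind One of `deletion`, `duplication`, `triplication`,
#'   `quintuplication`, `translocation`, `composite`.
#' @slot id Short label.
#' @slot genotype `"het"` or `"hom"`.
#' @slot cnProfile `GRanges` with a `cn` column: total copy number (both
#'   haplotypes) over each affected interval. Empty for balanced events.
#' @slot junctions `data.frame` of novel adjacencies with columns
#'   `contig_a`, `pos_a`, `orient_a`, `contig_b`, `pos_b`, `orient_b`,
#'   `traversals` (times the junction is crossed per derived haplotype).
#' @export
setClass("PlantedSV",
    representation(kind = "character", id = "character",
                   genotype = "character", cnProfile = "GRanges",
                   junctions = "data.frame"))

setValidity("PlantedSV", function(object) {
    msg <- character()
    kinds <- c("deletion", "duplication", "triplication",
               "quintuplication", "translocation", "composite")
    if (!object@kind %in% kinds)
        msg <- c(msg, "unknown SV kind")
    if (!object@genotype %in% c("het", "hom"))
        msg <- c(msg, "genotype must be 'het' or 'hom'")
    if (length(object@cnProfile) &&
        (!"cn" %in% colnames(S4Vectors::mcols(object@cnProfile)) ||
         any(object@cnProfile$cn < 0)))
        msg <- c(msg, "cnProfile needs a non-negative 'cn' column")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PlantedSV", function(object) {
    cat("PlantedSV", object@id, sprintf("(%s, %s)", object@kind,
        object@genotype), "\n")
    if (length(object@cnProfile))
        for (i in seq_along(object@cnProfile))
            cat(sprintf("  CN %d over %s:%d-%d\n",
                object@cnProfile$cn[i],
                as.character(GenomeInfoDb::seqnames(object@cnProfile))[i],
                GenomicRanges::start(object@cnProfile)[i],
                GenomicRanges::end(object@cnProfile)[i]))
    if (nrow(object@junctions))
        cat("  ", nrow(object@junctions), "junction(s)\n")
})

#' Configuration of a synthetic adaptive-sampling run
#'
#' Defaults emulate the statistical structure of a single-sample MinION
#' adaptive-sampling experiment: long accepted reads (N50 12 kb) at 28x
#' mean haploid-pair depth over the targets, short ejected reads
#' (N50 560 bp) at 5x genome-wide, about 5% of reads failing the Q10
#' filter, and every carrier read overlapping a planted junction emitted as
#' a split alignment.
#'
#' @slot genome A [GenomeLayout-class] (default: three contigs of 5, 5 and
#'   3 Mb).
#' @slot targets `GRanges` of target regions.
#' @slot svs List of [PlantedSV-class] objects.
#' @slot onTargetDepth Mean depth of accepted reads over targets at
#'   copy-number baseline (default 28).
#' @slot offTargetDepth Mean genome-wide depth of ejected reads (default 5).
#' @slot onN50,offN50 Read-length N50 targets in bp (defaults 12000, 560).
#' @slot qMean,qSD Mean-quality distribution (defaults 14, 3).
#' @slot qFailFrac Fraction of reads below Q10 (default 0.05).
#' @slot junctionReadFrac Fraction of junction-overlapping carrier reads
#'   emitted as split alignments (default 1).
#' @slot lnSigma Log-normal sdlog of the read-length distributions
#'   (default 0.9).
#' @slot seed Integer seed; identical seeds give identical runs.
#' @export
setClass("SimulationConfig",
    representation(genome = "GenomeLayout", targets = "GRanges",
                   svs = "list", onTargetDepth = "numeric",
                   offTargetDepth = "numeric", onN50 = "numeric",
                   offN50 = "numeric", qMean = "numeric", qSD = "numeric",
                   qFailFrac = "numeric", junctionReadFrac = "numeric",
                   lnSigma = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@onTargetDepth <= 0 || object@offTargetDepth <= 0)
        msg <- c(msg, "depths must be > 0")
    if (object@onN50 <= 0 || object@offN50 <= 0)
        msg <- c(msg, "N50 targets must be > 0")
    for (f in c(object@qFailFrac, object@junctionReadFrac))
        if (f < 0 || f > 1)
            msg <- c(msg, "fractions must lie in [0, 1]")
    if (!all(vapply(object@svs, is, logical(1), "PlantedSV")))
        msg <- c(msg, "svs must be a list of PlantedSV objects")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:",
        sprintf("%.1f Mb genome, %d target(s) (%.2f Mb), %d planted SV(s)\n",
            genomeSize(object@genome) / 1e6, length(object@targets),
            sum(GenomicRanges::width(object@targets)) / 1e6,
            length(object@svs)))
    cat(sprintf("  on-target %gx (N50 %g bp), off-target %gx (N50 %g bp), seed %d\n",
        object@onTargetDepth, object@onN50, object@offTargetDepth,
        object@offN50, object@seed))
})

#' Truth set accompanying a simulated run
#'
#' @slot svs List of the planted [PlantedSV-class] objects.
#' @slot fates `DataFrame` with `read_id` and true `fate` per read.
#' @slot junctions `DataFrame` of planted junctions with expected
#'   spanning-read support and the supporting read ids (`CharacterList`).
#' @export
setClass("TruthSet",
    representation(svs = "list", fates = "DataFrame",
                   junctions = "DataFrame"))

#' @describeIn TruthSet Planted SVs.
#' @param x A `TruthSet`.
#' @export
setMethod("truthSVs", "TruthSet", function(x) x@svs)

#' @describeIn TruthSet True per-read fate labels.
#' @export
setMethod("truthFates", "TruthSet", function(x) x@fates)

#' @describeIn TruthSet Planted junctions with supporting read ids.
#' @export
setMethod("truthJunctions", "TruthSet", function(x) x@junctions)

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", length(object@svs), "planted SV(s),",
        nrow(object@fates), "reads,", nrow(object@junctions),
        "junction(s)\n")
})

## ---------------------------------------------------------------------------
## RunStats
## ---------------------------------------------------------------------------

#' Run-level sequencing statistics
#'
#' Produced by [runSummary()]: read counts by adaptive-sampling fate,
#' yield, read-length N50 per fate, per-region mean depth, autosomal
#' on-target mean depth, chromosome X depth, genome-wide depth and target
#' enrichment (autosomal on-target depth over genome-wide depth).
#'
#' @slot nReads Named integer vector (`on_target`, `off_target`).
#' @slot gigabases Total passing yield in Gb.
#' @slot onTargetN50,offTargetN50 Read-length N50s in bp.
#' @slot regionDepth Named numeric vector of per-region mean depths.
#' @slot autosomalTargetDepth Mean depth over autosomal target regions.
#' @slot chrXDepth Mean depth over chromosome X targets (`NA` if none).
#' @slot genomeDepth Genome-wide mean depth of all passing reads.
#' @slot enrichment `autosomalTargetDepth / genomeDepth`.
#' @export
setClass("RunStats",
    representation(nReads = "integer", gigabases = "numeric",
                   onTargetN50 = "numeric", offTargetN50 = "numeric",
                   regionDepth = "numeric",
                   autosomalTargetDepth = "numeric", chrXDepth = "numeric",
                   genomeDepth = "numeric", enrichment = "numeric"))

#' @describeIn RunStats Target enrichment ratio.
#' @param x A `RunStats`.
#' @export
setMethod("enrichment", "RunStats", function(x) x@enrichment)

setMethod("show", "RunStats", function(object) {
    cat("RunStats\n")
    cat(sprintf("  reads: %d on-target / %d off-target, %.3f Gb passing\n",
        object@nReads[["on_target"]], object@nReads[["off_target"]],
        object@gigabases))
    cat(sprintf("  N50: on-target %g bp, off-target %g bp\n",
        object@onTargetN50, object@offTargetN50))
    cat(sprintf("  depth: autosomal targets %.2fx, chrX %s, genome-wide %.2fx\n",
        object@autosomalTargetDepth,
        if (is.na(object@chrXDepth)) "-" else
            sprintf("%.2fx", object@chrXDepth),
        object@genomeDepth))
    cat(sprintf("  enrichment: %.2fx\n", object@enrichment))
})
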