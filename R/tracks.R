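## bedGraph track and call-file output.

.orderByLayout <- function(gr, layout = NULL) {
    lev <- if (!is.null(layout)) seqlevels(seqinfo(layout))
           else sort(unique(as.character(GenomeInfoDb::seqnames(gr))))
    ord <- order(match(as.character(GenomeInfoDb::seqnames(gr)), lev),
                 start(gr))
    gr[ord]
}

.exportBedGraph <- function(gr, score, path, layout) {
    out <- GRanges(GenomeInfoDb::seqnames(gr),
                   IRanges(start(gr), end(gr)))
    mcols(out)$score <- score
    out <- .orderByLayout(out, layout)
    rtracklayer::export(out, path, format = "bedGraph")
    path
}

#' Write depth/log2 tracks and variant calls
#'
#' Writes each depth profile and log2 track as bedGraph (0-based
#' half-open, the format's convention), the copy-number segments and
#' junctions as a minimal VCF-like text file (`calls.vcf`) with
#' `SVTYPE`, `END`, `CN` and `SUPPORT` fields, and a flat tab-separated
#' report (`report.tsv`). Output ordering is deterministic: contigs in
#' layout order, then start position.
#'
#' @param profiles Named list of [DepthProfile-class] and/or
#'   [RatioTrack-class] objects (names become file stems).
#' @param segments `GRanges` of segment calls from [segmentAndCall()] or
#'   [backgroundScan()] (may be `NULL`).
#' @param junctions A [JunctionSet-class] (may be `NULL`).
#' @param outDir Output directory (created if needed).
#' @param layout Optional [GenomeLayout-class] fixing the contig order.
#' @return Character vector of the files written, invisibly.
#' @export
writeTracksAndCalls <- function(profiles = list(), segments = NULL,
                                junctions = NULL, outDir = ".",
                                layout = NULL) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    for (nm in names(profiles)) {
        p <- profiles[[nm]]
        if (is(p, "DepthProfile")) {
            f <- file.path(outDir, paste0(nm, ".depth.bedGraph"))
            .exportBedGraph(profileBins(p), profileBins(p)$depth, f,
                            layout)
        } else if (is(p, "RatioTrack")) {
            f <- file.path(outDir, paste0(nm, ".log2.bedGraph"))
            .exportBedGraph(trackBins(p), trackBins(p)$log2, f, layout)
        } else stop("profiles must be DepthProfile or RatioTrack objects")
        written <- c(written, f)
    }
    vcf <- file.path(outDir, "calls.vcf")
    lines <- c("##fileformat=VCFv4.2",
        "##source=svadapt",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Segment end\">",
        "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
        "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Partner contig\">",
        "##INFO=<ID=END2,Number=1,Type=Integer,Description=\"Partner position\">",
        "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Spanning reads\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    segLines <- character(0)
    if (!is.null(segments) && length(segments)) {
        seg <- .orderByLayout(segments, layout)
        aberr <- which(seg$status != "neutral")
        segLines <- vapply(seq_along(aberr), function(k) {
            i <- aberr[k]
            svtype <- if (seg$status[i] == "loss") "DEL" else "DUP"
            sprintf("%s\t%d\tseg%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;CN=%d",
                as.character(GenomeInfoDb::seqnames(seg))[i], start(seg)[i],
                k, svtype, svtype, end(seg)[i], seg$cn_estimate[i])
        }, character(1))
    }
    jxLines <- character(0)
    if (!is.null(junctions) && length(junctions)) {
        jt <- junctionTable(junctions)
        alt <- c("TRA" = "TRA", "DEL-like" = "DEL", "DUP-like" = "DUP",
                 "INV-like" = "INV", "ambiguous" = "BND")
        jxLines <- vapply(seq_len(nrow(jt)), function(i) {
            sprintf(
                "%s\t%d\tjx%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;CHR2=%s;END2=%d;SUPPORT=%d",
                jt$contig_a[i], jt$pos_a[i], i, alt[[jt$type[i]]],
                alt[[jt$type[i]]], jt$contig_b[i], jt$pos_b[i],
                jt$support[i])
        }, character(1))
    }
    writeLines(c(lines, segLines, jxLines), vcf)
    written <- c(written, vcf)
    rpt <- file.path(outDir, "report.tsv")
    segTab <- if (!is.null(segments) && length(segments)) {
        seg <- .orderByLayout(segments, layout)
        data.frame(record = "segment",
                   contig = as.character(GenomeInfoDb::seqnames(seg)),
                   start = start(seg), end = end(seg),
                   value = round(seg$mean_log2, 4),
                   label = paste0("CN", seg$cn_estimate, ";",
                                  seg$status))
    } else NULL
    jxTab <- if (!is.null(junctions) && length(junctions)) {
        jt <- junctionTable(junctions)
        data.frame(record = "junction", contig = jt$contig_a,
                   start = jt$pos_a, end = jt$pos_b,
                   value = jt$support,
                   label = paste0(jt$type, ";", jt$contig_b))
    } else NULL
    rtab <- rbind(segTab, jxTab)
    if (is.null(rtab))
        rtab <- data.frame(record = character(0), contig = character(0),
                           start = numeric(0), end = numeric(0),
                           value = numeric(0), label = character(0))
    write.table(rtab, rpt, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(written, rpt))
}
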