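## Small, fast simulation scenarios shared across tests.

tinyLayout <- function(sex = "unknown") {
    GenomeLayout(c("c1", "c2", "c3"), c(6e5, 6e5, 4e5), sex = sex)
}

tinyTargets <- function() {
    parseRegionStrings(
        c("c1:100,001-160,000", "c2:100,001-160,000",
          "c3:100,001-160,000"),
        names = c("T1", "T2", "T3"), role = "control")
}

tinyConfig <- function(..., targets = tinyTargets(), seed = 101L) {
    SimulationConfig(genome = tinyLayout(), targets = targets,
                     onN50 = 3000, offN50 = 400, seed = seed, ...)
}

## alignment GRanges of `depth` identical stacked reads over an interval
stackReads <- function(contig, lo, hi, depth, prefix = "s") {
    ids <- if (depth > 0)
        paste0(prefix, "_", contig, "_", lo, "_", seq_len(depth))
    else character(0)
    suppressWarnings(GenomicRanges::GRanges(
        rep(contig, depth),
        IRanges::IRanges(rep(lo, depth), rep(hi, depth)),
        read_id = ids,
        segment_index = rep(0L, depth),
        read_class = rep("on_target", depth)))
}

## classified + filtered reads and class-labelled alignments from a sim
simPipeline <- function(sim) {
    rc <- suppressMessages(qualityFilter(classifyReads(sim$reads)))
    aln <- sim$alignments[sim$alignments$read_id %in% readIDs(rc)]
    list(reads = rc, alignments = assignReadClass(aln, rc))
}
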