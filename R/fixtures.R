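## Canonical synthetic fixtures mirroring the targeted variant classes:
## duplicated flanks around a normal block, triplicated flanks around a
## (partially inverted) quintuplicated core, a one-sided inter-contig
## translocation, an untargeted deletion visible only in ejected reads,
## and a simple tandem duplication whose architecture is provably unique.

.segGR <- function(contig, starts, ends, ids, mult) {
    gr <- GRanges(contig, IRanges(starts, ends))
    mcols(gr)$id <- ids
    mcols(gr)$multiplicity <- as.integer(mult)
    gr
}

#' Canonical fixture configurations
#'
#' Returns the named list of simulation scenarios used throughout the
#' test surface. Each element holds the [SimulationConfig-class], and -
#' where a rearrangement architecture is defined - the segment nodes of
#' its [SegmentGraph-class] (with carrier-haplotype multiplicities) and
#' the planted derived-haplotype walk.
#'
#' Fixtures: `dup_nml_dup` (copy number 3/2/3 with its two junctions; the
#' repeated flanks are unanchored, so two walks explain the evidence),
#' `trip_quint_trip` (copy number 4/6/6/4 with an inverted middle, scored
#' against a large control target), `translocation_one_sided` (only one
#' partner contig targeted), `background_del` (untargeted heterozygous
#' 1 Mb deletion, visible only in ejected reads) and `tandem_dup` (fully
#' anchored; exactly one walk).
#'
#' @param seed Base integer seed; each fixture derives its own.
#' @return Named list of fixture descriptions.
#' @export
fixtureConfigs <- function(seed = 1L) {
    seed <- as.integer(seed)
    fx <- list()

    ## (a) DUP-NML-DUP: segments A/B/C at total CN 3/2/3; derived
    ## haplotype A B C A C (an A..C tandem copy with B spliced out).
    cn <- c(.cnGR("chr1", 1100001, 1250000, 3),
            .cnGR("chr1", 1450001, 1600000, 3))
    jx <- rbind(.jxRow("chr1", 1100001, "head", "chr1", 1600000, "tail"),
                .jxRow("chr1", 1250000, "tail", "chr1", 1450001, "head"))
    fx$dup_nml_dup <- list(
        config = SimulationConfig(
            targets = parseRegionStrings(
                c("chr1:1,000,001-1,700,000", "chr2:1,000,001-3,000,000",
                  "chr3:500,001-1,500,000"),
                names = c("SV", "C1", "C2"),
                role = c("rearrangement", "control", "control")),
            svs = list(svComposite(cn, jx, id = "dnd")),
            seed = seed + 11L),
        segments = .segGR("chr1", c(1100001, 1250001, 1450001),
                          c(1250000, 1450000, 1600000),
                          c("A", "B", "C"), c(2, 1, 2)),
        planted = c("A+", "B+", "C+", "A+", "C+"))

    ## (b) TRIP-QUINT-TRIP with inverted middle: CN 4/6/6/4 over
    ## A/B/C/D; derived haplotype (A B C D C- B-) x2 then A B C D.
    cn <- c(.cnGR("chr2", 1100001, 1250000, 4),
            .cnGR("chr2", 1250001, 1420000, 6),
            .cnGR("chr2", 1420001, 1590000, 6),
            .cnGR("chr2", 1590001, 1740000, 4))
    jx <- rbind(
        .jxRow("chr2", 1590000, "tail", "chr2", 1740000, "tail",
               traversals = 2),
        .jxRow("chr2", 1100001, "head", "chr2", 1250001, "head",
               traversals = 2))
    fx$trip_quint_trip <- list(
        config = SimulationConfig(
            genome = GenomeLayout(c("chr1", "chr2", "chr3"),
                                  c(40e6, 5e6, 3e6)),
            targets = parseRegionStrings(
                c("chr1:2,000,001-37,000,000", "chr2:800,001-2,000,000"),
                names = c("C1", "SV"),
                role = c("control", "rearrangement")),
            svs = list(svComposite(cn, jx, id = "tqt")),
            seed = seed + 23L),
        segments = .segGR("chr2",
                          c(1100001, 1250001, 1420001, 1590001),
                          c(1250000, 1420000, 1590000, 1740000),
                          c("A", "B", "C", "D"), c(3, 5, 5, 3)),
        planted = c("A+", "B+", "C+", "D+", "C-", "B-",
                    "A+", "B+", "C+", "D+", "C-", "B-",
                    "A+", "B+", "C+", "D+"))

    ## (c) inter-contig translocation, only the chr1 side targeted
    fx$translocation_one_sided <- list(
        config = SimulationConfig(
            targets = parseRegionStrings(
                c("chr1:2,000,001-2,500,000", "chr2:1,000,001-2,000,000"),
                names = c("SV", "C1"),
                role = c("rearrangement", "control")),
            svs = list(svTranslocation("chr1", 2250000, "tail",
                                       "chr3", 2000000, "head",
                                       id = "tra")),
            seed = seed + 37L))

    ## (d) untargeted 1 Mb heterozygous deletion: no junction reads, the
    ## dip is visible only in the ejected-read background profile.
    fx$background_del <- list(
        config = SimulationConfig(
            targets = parseRegionStrings("chr1:1,000,001-1,500,000",
                                         names = "C1", role = "control"),
            svs = list(svDeletion("chr2", 2000001, 3000000, id = "bgdel")),
            seed = seed + 41L))

    ## (e) fully anchored tandem duplication: unique architecture
    fx$tandem_dup <- list(
        config = SimulationConfig(
            targets = parseRegionStrings(
                c("chr3:1,500,001-2,100,000", "chr1:1,000,001-2,000,000"),
                names = c("SV", "C1"),
                role = c("rearrangement", "control")),
            svs = list(svDuplication("chr3", 1700001, 1900000,
                                     id = "tdup")),
            seed = seed + 53L),
        segments = .segGR("chr3", c(1500001, 1700001, 1900001),
                          c(1700000, 1900000, 2100000),
                          c("F1", "B", "F2"), c(1, 2, 1)),
        planted = c("F1+", "B+", "B+", "F2+"))

    fx
}

.svToList <- function(sv) {
    prof <- sv@cnProfile
    list(kind = sv@kind, id = sv@id, genotype = sv@genotype,
         cn_profile = if (length(prof)) data.frame(
             contig = as.character(GenomeInfoDb::seqnames(prof)),
             start = start(prof), end = end(prof), cn = prof$cn)
         else data.frame(),
         junctions = sv@junctions)
}

#' Write the canonical fixture suite to disk
#'
#' Simulates every fixture of [fixtureConfigs()] and writes, per fixture,
#' a sequencing summary (`<name>.summary.tsv`), alignment segments in the
#' plain-table dialect (`<name>.alignments.tsv`), the target regions
#' (`<name>.regions.bed`) and the truth set (`<name>.truth.json`).
#' Identical seeds produce identical files.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Base integer seed.
#' @return Named list of per-fixture file paths, invisibly.
#' @export
makeFixtureSuite <- function(outDir, seed = 1L) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fx <- fixtureConfigs(seed)
    out <- list()
    for (nm in names(fx)) {
        cfg <- fx[[nm]]$config
        sim <- simulateRun(cfg)
        paths <- list(
            summary = file.path(outDir, paste0(nm, ".summary.tsv")),
            alignments = file.path(outDir, paste0(nm, ".alignments.tsv")),
            regions = file.path(outDir, paste0(nm, ".regions.bed")),
            truth = file.path(outDir, paste0(nm, ".truth.json")))
        writeSequencingSummary(sim$reads, paths$summary)
        writeAlignmentsTSV(sim$alignments, paths$alignments)
        rtracklayer::export(cfg@targets, paths$regions, format = "BED")
        tj <- as.data.frame(truthJunctions(sim$truth))
        tj$read_ids <- vapply(truthJunctions(sim$truth)$read_ids,
                              paste, character(1), collapse = ",")
        jsonlite::write_json(list(
            svs = lapply(cfg@svs, .svToList),
            junctions = tj,
            genome = data.frame(
                contig = GenomeInfoDb::seqnames(seqinfo(cfg@genome)),
                length = seqlengths(seqinfo(cfg@genome))),
            sex = sampleSex(cfg@genome)),
            paths$truth, auto_unbox = TRUE, digits = NA)
        out[[nm]] <- paths
    }
    invisible(out)
}
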