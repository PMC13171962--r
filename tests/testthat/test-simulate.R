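test_that("expected depth ratios follow copy number over baseline", {
    gl <- tinyLayout()
    del <- svDeletion("c1", 1000, 2000)
    expect_equal(expectedDepthRatio(del, gl)$ratio, 0.5)
    expect_equal(expectedDepthRatio(del, gl)$log2, -1)
    dup <- svDuplication("c1", 1000, 2000)
    expect_equal(expectedDepthRatio(dup, gl)$ratio, 1.5)
    expect_equal(expectedDepthRatio(dup, gl)$log2, log2(1.5),
                 tolerance = 1e-12)  # ~ +0.585
    quint <- svQuintuplication("c1", 1000, 2000)
    expect_equal(expectedDepthRatio(quint, gl)$ratio, 3)
    expect_equal(expectedDepthRatio(quint, gl)$log2, log2(3))
    hom <- svDeletion("c1", 1000, 2000, genotype = "hom")
    expect_equal(expectedDepthRatio(hom, gl)$log2, -Inf)
    ## male X: hemizygous baseline 1
    glM <- GenomeLayout(c("chrX"), 1e6, sex = "male")
    delX <- svDeletion("chrX", 1000, 2000, genotype = "hom")
    expect_equal(expectedDepthRatio(delX, glM)$baseline, 1)
})

test_that("identical seeds reproduce a run exactly", {
    s1 <- simulateRun(tinyConfig(seed = 320L))
    s2 <- simulateRun(tinyConfig(seed = 320L))
    expect_identical(readIDs(s1$reads), readIDs(s2$reads))
    expect_equal(meanQ(s1$reads), meanQ(s2$reads))
    expect_identical(GenomicRanges::start(s1$alignments),
                     GenomicRanges::start(s2$alignments))
    s3 <- simulateRun(tinyConfig(seed = 321L))
    expect_false(identical(GenomicRanges::start(s1$alignments),
                           GenomicRanges::start(s3$alignments)))
})

test_that("realized depths and N50s are calibrated to the configuration", {
    cfg <- tinyConfig(seed = 322L)
    sim <- simulateRun(cfg)
    expect_length(truthSVs(sim$truth), 0)
    p <- simPipeline(sim)
    off <- p$alignments[p$alignments$read_class == "off_target"]
    gsize <- genomeSize(cfg@genome)
    offDepth <- sum(as.numeric(GenomicRanges::width(off))) / gsize
    expect_lt(abs(offDepth - cfg@offTargetDepth) / cfg@offTargetDepth,
              0.1)
    fate <- readFate(p$reads)
    expect_lt(abs(readN50(readLengths(p$reads)[fate == "off_target"]) -
                  cfg@offN50) / cfg@offN50, 0.1)
    expect_lt(abs(readN50(readLengths(p$reads)[fate == "on_target"]) -
                  cfg@onN50) / cfg@onN50, 0.1)
})

test_that("a heterozygous deletion halves raw depth relative to its flanks", {
    cfg <- tinyConfig(svs = list(svDeletion("c2", 200001, 400000)),
                      seed = 323L)
    sim <- simulateRun(cfg)
    p <- simPipeline(sim)
    off <- p$alignments[p$alignments$read_class == "off_target"]
    depthIn <- function(lo, hi) {
        r <- GenomicRanges::GRanges("c2", IRanges::IRanges(lo, hi))
        ov <- GenomicRanges::findOverlaps(off, r)
        sum(GenomicRanges::width(GenomicRanges::pintersect(
            off[S4Vectors::queryHits(ov)],
            r[S4Vectors::subjectHits(ov)]))) / (hi - lo + 1)
    }
    inside <- depthIn(220001, 380000)
    flank <- (depthIn(1, 180000) + depthIn(420001, 600000)) / 2
    expect_lt(abs(inside / flank - 0.5), 0.08)
})

test_that("carrier reads across a translocation split onto both contigs", {
    cfg <- tinyConfig(
        targets = parseRegionStrings("c1:100,001-160,000", names = "T"),
        svs = list(svTranslocation("c1", 130000, "tail",
                                   "c3", 300000, "head")),
        seed = 324L)
    sim <- simulateRun(cfg)
    tj <- truthJunctions(sim$truth)
    expect_gt(tj$support[1], 0)
    ids <- unlist(tj$read_ids[[1]])
    for (id in ids) {
        seg <- sim$alignments[sim$alignments$read_id == id]
        expect_length(seg, 2L)
        expect_setequal(as.character(GenomicRanges::seqnames(seg)),
                        c("c1", "c3"))
    }
})

test_that("default-run enrichment falls in the study's plausible envelope", {
    cfg <- SimulationConfig(seed = 9L)
    sim <- simulateRun(cfg)
    p <- simPipeline(sim)
    stats <- runSummary(p$reads, p$alignments, cfg@targets, cfg@genome)
    expect_gte(enrichment(stats), 3)
    expect_lte(enrichment(stats), 12)
})

test_that("the fixture suite is deterministic and writes complete runs", {
    d1 <- tempfile(); d2 <- tempfile()
    f1 <- makeFixtureSuite(d1, seed = 77L)
    f2 <- makeFixtureSuite(d2, seed = 77L)
    expect_setequal(names(f1),
                    c("dup_nml_dup", "trip_quint_trip",
                      "translocation_one_sided", "background_del",
                      "tandem_dup"))
    for (nm in names(f1)) for (part in names(f1[[nm]]))
        expect_identical(readLines(f1[[nm]][[part]]),
                         readLines(f2[[nm]][[part]]),
                         label = paste(nm, part))
    ## truth junctions present for the one-sided translocation fixture
    tj <- jsonlite::read_json(f1$translocation_one_sided$truth,
                              simplifyVector = TRUE)
    expect_gt(tj$junctions$support[1], 0)
})
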