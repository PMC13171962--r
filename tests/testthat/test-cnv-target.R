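test_that("binned depth equals mosdepth-style hand examples and the pileup oracle", {
    gl <- GenomeLayout("c1", 10000)
    iv <- parseRegionStrings("c1:1,001-2,000", names = "A")
    ## no alignments -> all bins zero
    none <- stackReads("c1", 1, 100, 0)
    prof0 <- binnedDepth(none, iv, 500)
    expect_true(all(profileBins(prof0)$depth == 0))
    ## one 250 bp alignment inside a 500 bp bin -> 0.5
    one <- stackReads("c1", 1101, 1350, 1)
    prof1 <- binnedDepth(one, iv, 500)
    expect_equal(profileBins(prof1)$depth, c(0.5, 0))
    ## random fixtures vs per-base pileup counting
    set.seed(41)
    for (k in 1:12) {
        n <- sample(20:80, 1)
        st <- sample(1:3000, n, replace = TRUE)
        en <- st + sample(1:800, n, replace = TRUE)
        aln <- GenomicRanges::GRanges("c1", IRanges::IRanges(st, en),
            read_id = paste0("r", seq_len(n)), segment_index = 0L,
            read_class = "on_target")
        bs <- sample(c(100, 250, 500), 1)
        iv2 <- GenomicRanges::GRanges("c1",
            IRanges::IRanges(501, 501 + sample(c(999, 1499), 1)))
        prof <- binnedDepth(aln, iv2, bs)
        b <- profileBins(prof)
        for (i in seq_along(b)) {
            expect_equal(b$depth[i],
                pileupBinDepth(st, en, GenomicRanges::start(b)[i],
                               GenomicRanges::end(b)[i]),
                tolerance = 1e-12)
        }
    }
    expect_error(binnedDepth(one, iv, 0), "binSize")
})

test_that("log2 normalization is anchored to the all-targets mean", {
    gl <- GenomeLayout(c("c1", "c2"), c(1e5, 1e5))
    iv <- parseRegionStrings(c("c1:1-20,000", "c2:1-20,000"),
                             names = c("A", "B"))
    ## depths 10 and 30 -> mu = 20; ratios -1 and +0.585
    aln <- suppressWarnings(c(stackReads("c1", 1, 20000, 10),
                              stackReads("c2", 1, 20000, 30)))
    tr <- targetLog2(binnedDepth(aln, iv, 500), gl)
    expect_equal(referenceDepth(tr), 20)
    b <- trackBins(tr)
    expect_equal(unique(b$log2[b$region == 1]), -1)
    expect_equal(unique(b$log2[b$region == 2]), log2(1.5))
    ## normalization closure: weighted mean of 2^r over norm bins is 1
    w <- GenomicRanges::width(b)
    expect_equal(sum(2^b$log2 * w) / sum(w), 1, tolerance = 1e-9)
    ## a bin at exactly mu has ratio 0
    aln2 <- suppressWarnings(c(stackReads("c1", 1, 20000, 20),
                               stackReads("c2", 1, 20000, 20)))
    tr2 <- targetLog2(binnedDepth(aln2, iv, 500), gl)
    expect_true(all(trackBins(tr2)$log2 == 0))
    ## zero-depth bins floor at the sentinel
    aln3 <- stackReads("c1", 1, 20000, 20)
    tr3 <- targetLog2(binnedDepth(aln3, iv, 500), gl)
    expect_true(all(trackBins(tr3)$log2[trackBins(tr3)$region == 2] ==
                    -5))
    expect_error(targetLog2(binnedDepth(none <- stackReads("c1", 1, 1, 0),
                                        iv, 500), gl), "zero")
})

test_that("integer copy number is exact in the noise-free limit for CN 0..8", {
    gl <- GenomeLayout("c1", 20e6)
    ## a dominant reference region pins mu at ~20; one region per CN level
    refIv <- parseRegionStrings("c1:1-10,000,000", names = "ref")
    cnIv <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(10e6 + (0:8) * 2e4 + 1, 10e6 + (1:9) * 2e4))
    cnIv$name <- paste0("cn", 0:8)
    cnIv$assembly <- "toy"; cnIv$role <- "control"
    iv <- suppressWarnings(c(refIv, cnIv))
    alnList <- list(stackReads("c1", 1, 10e6, 20))
    for (k in 0:8) {
        d <- k * 10
        if (d > 0)
            alnList[[length(alnList) + 1L]] <-
                stackReads("c1", 10e6 + k * 2e4 + 1, 10e6 + (k + 1) * 2e4,
                           d, prefix = paste0("cn", k))
    }
    aln <- suppressWarnings(do.call(c, alnList))
    tr <- targetLog2(binnedDepth(aln, iv, 500), gl)
    seg <- segmentAndCall(tr, minWindows = 1)
    for (k in 0:8) {
        s <- seg[seg$region == k + 2]
        expect_equal(s$cn_estimate, k, label = paste("CN", k))
    }
    ## flat reference region: one neutral CN 2 segment
    sref <- seg[seg$region == 1]
    expect_length(sref, 1L)
    expect_identical(sref$status, "neutral")
    expect_equal(sref$cn_estimate, 2L)
})

test_that("triplicated flanks around a quintuplicated core resolve to CN 4/6/4", {
    fx <- fixtureConfigs(5L)$trip_quint_trip
    cfg <- fx$config
    sim <- simulateRun(cfg)
    p <- simPipeline(sim)
    prof <- binnedDepth(p$alignments, cfg@targets, 500)
    seg <- segmentAndCall(targetLog2(prof, cfg@genome))
    sv <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1100001, 1740000))
    hit <- seg[IRanges::overlapsAny(seg, sv) & seg$status == "gain"]
    expect_equal(hit$cn_estimate, c(4L, 6L, 4L))
    truthBnd <- c(1100001, 1250001, 1590001, 1740000)
    got <- c(GenomicRanges::start(hit), GenomicRanges::end(hit)[3])
    expect_true(all(abs(sort(got) - sort(truthBnd)) <= 5000))
})

test_that("male chromosome X at hemizygous depth is called neutral CN 1", {
    gl <- GenomeLayout(c("chr1", "chrX"), c(1e6, 1e6), sex = "male")
    tg <- parseRegionStrings(c("chr1:1-100,000", "chrX:1-100,000"),
                             names = c("A", "X"))
    aln <- suppressWarnings(c(stackReads("chr1", 1, 1e5, 30),
                              stackReads("chrX", 1, 1e5, 15)))
    tr <- targetLog2(binnedDepth(aln, tg, 500), gl)
    expect_equal(referenceDepth(tr), 30)  # chrX excluded from the mean
    seg <- segmentAndCall(tr)
    sx <- seg[as.character(GenomicRanges::seqnames(seg)) == "chrX"]
    expect_identical(sx$status, "neutral")
    expect_equal(sx$cn_estimate, 1L)
})

test_that("absolute log2 level separates a deletion from two flanking duplications", {
    gl <- GenomeLayout(c("c1", "c2"), c(1e6, 1e6))
    ## dip to half depth against flat external targets -> deletion
    tg <- parseRegionStrings(c("c1:1-100,000", "c2:1-100,000",
                               "c2:200,001-300,000"),
                             names = c("E", "F1", "F2"))
    aln <- suppressWarnings(c(stackReads("c1", 1, 1e5, 10),
                              stackReads("c2", 1, 1e5, 20),
                              stackReads("c2", 200001, 3e5, 20)))
    tr <- targetLog2(binnedDepth(aln, tg, 500), gl)
    ann <- disambiguateDelVsDup(segmentAndCall(tr), tr)
    expect_identical(ann$interpretation[ann$region == 1],
                     "deletion (absolute)")
    ## inverse: flanks at 1.5x, event at the external mean
    tg2 <- parseRegionStrings(c("c1:1-300,000", "c2:1-300,000"),
                              names = c("SV", "C"))
    aln2 <- suppressWarnings(c(stackReads("c1", 1, 1e5, 30),
                               stackReads("c1", 100001, 2e5, 20),
                               stackReads("c1", 200001, 3e5, 30),
                               stackReads("c2", 1, 3e5, 20)))
    tr2 <- targetLog2(binnedDepth(aln2, tg2, 500), gl)
    ann2 <- disambiguateDelVsDup(segmentAndCall(tr2), tr2)
    a <- as.data.frame(ann2)
    mid <- a$interpretation[a$start == 100001 & a$seqnames == "c1"]
    expect_identical(mid, "two flanking duplications")
    ## all-neutral track has nothing to annotate
    aln3 <- suppressWarnings(c(stackReads("c1", 1, 3e5, 20),
                               stackReads("c2", 1, 3e5, 20)))
    tr3 <- targetLog2(binnedDepth(aln3, tg2, 500), gl)
    ann3 <- disambiguateDelVsDup(segmentAndCall(tr3), tr3)
    expect_true(all(ann3$interpretation == "reference level"))
    ## single target region -> indeterminate
    tg4 <- parseRegionStrings("c1:1-100,000", names = "only")
    aln4 <- stackReads("c1", 1, 1e5, 10)
    tr4 <- targetLog2(binnedDepth(aln4, tg4, 500), gl)
    ann4 <- disambiguateDelVsDup(segmentAndCall(tr4), tr4)
    expect_match(ann4$interpretation, "indeterminate")
})
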