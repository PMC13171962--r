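## Construct a background profile directly from chosen per-bin depths.
mkProfile <- function(depthByContig, binSize = 1e4) {
    grs <- lapply(names(depthByContig), function(ctg) {
        d <- depthByContig[[ctg]]
        n <- length(d)
        gr <- GenomicRanges::GRanges(ctg,
            IRanges::IRanges((seq_len(n) - 1) * binSize + 1,
                             seq_len(n) * binSize))
        gr$depth <- d
        gr$region <- 1L
        gr
    })
    bins <- suppressWarnings(do.call(c, grs))
    new("DepthProfile", bins = bins, binSize = binSize,
        readClass = "off_target_only")
}

noExclusions <- GenomicRanges::GRanges()

test_that("background profile uses only ejected reads and records provenance", {
    sim <- simulateRun(tinyConfig(seed = 330L))
    p <- simPipeline(sim)
    prof <- backgroundProfile(p$alignments, tinyLayout(), binSize = 1e4)
    expect_identical(readClass(prof), "off_target_only")
    expect_lt(abs(mean(profileBins(prof)$depth) - 5) / 5, 0.1)
    ## bins inside target regions are still present (masking is later)
    expect_true(any(IRanges::overlapsAny(profileBins(prof),
                                         tinyTargets())))
    onOnly <- p$alignments[p$alignments$read_class == "on_target"]
    expect_error(backgroundProfile(onOnly, tinyLayout()), "off-target")
    noClass <- onOnly
    S4Vectors::mcols(noClass)$read_class <- NULL
    expect_error(backgroundProfile(noClass, tinyLayout()), "read_class")
})

test_that("a flat genome yields no background calls", {
    prof <- mkProfile(list(cA = rep(5, 300), cB = rep(5, 200)))
    calls <- backgroundScan(prof, noExclusions)
    expect_length(calls, 0L)
})

test_that("planted loss and gain windows are called at their log2 levels", {
    d <- rep(8, 500)
    d[201:300] <- 4       # 1 Mb at half depth
    prof <- mkProfile(list(cA = d, cB = rep(8, 500) * 1.5 / 1))
    ## cB has uniformly 12x so its own mean absorbs it: no call there
    calls <- backgroundScan(prof, noExclusions)
    expect_length(calls, 1L)
    expect_identical(calls$direction, "loss")
    expect_equal(GenomicRanges::start(calls), 2000001)
    expect_equal(GenomicRanges::end(calls), 3000000)
    ## the level is measured against the chromosome mean (which includes
    ## the event itself)
    ref <- mean(d)
    expect_equal(calls$mean_log2, log2(4 / ref), tolerance = 1e-9)
    ## inverting the depths about the reference swaps the direction
    dInv <- ref^2 / d
    profInv <- mkProfile(list(cA = dInv))
    callsInv <- backgroundScan(profInv, noExclusions)
    expect_length(callsInv, 1L)
    expect_identical(callsInv$direction, "gain")
    expect_equal(GenomicRanges::start(callsInv),
                 GenomicRanges::start(calls))
})

test_that("masked windows never drive calls", {
    d <- rep(6, 500)
    d[101:200] <- 0.5     # a dip entirely inside the exclusion mask
    prof <- mkProfile(list(cA = d))
    excl <- GenomicRanges::GRanges("cA", IRanges::IRanges(1000001, 2000000))
    calls <- backgroundScan(prof, excl)
    expect_length(calls, 0L)
    ## partially masked window below the unmasked-bin threshold is skipped
    d2 <- rep(6, 300)
    d2[101:200] <- 3
    prof2 <- mkProfile(list(cA = d2))
    excl2 <- GenomicRanges::GRanges("cA",
        IRanges::IRanges(1000001, 1600000))  # 60% of the event window
    calls2 <- backgroundScan(prof2, excl2)
    expect_length(calls2, 0L)
    ## with a smaller mask the window is scored and the call excludes
    ## masked bins
    excl3 <- GenomicRanges::GRanges("cA",
        IRanges::IRanges(1000001, 1300000))
    calls3 <- backgroundScan(prof2, excl3)
    expect_length(calls3, 1L)
    expect_identical(calls3$direction, "loss")
    ## a fully masked chromosome is skipped with a warning
    expect_warning(
        backgroundScan(mkProfile(list(cA = rep(6, 100))),
            GenomicRanges::GRanges("cA", IRanges::IRanges(1, 1e6))),
        "fully masked")
})

test_that("an untargeted heterozygous deletion is recovered from ejected reads", {
    fx <- fixtureConfigs(3L)$background_del
    cfg <- fx$config
    sim <- simulateRun(cfg)
    p <- simPipeline(sim)
    prof <- backgroundProfile(p$alignments, cfg@genome)
    calls <- backgroundScan(prof, exclusions = cfg@targets)
    loss <- calls[calls$direction == "loss"]
    planted <- GenomicRanges::GRanges("chr2",
        IRanges::IRanges(2000001, 3000000))
    expect_true(any(IRanges::overlapsAny(loss, planted)))
    ## none of the calls overlap the exclusion mask
    expect_false(any(suppressWarnings(
        IRanges::overlapsAny(calls, cfg@targets))))
})

test_that("the chromosome-median reference restores the nominal loss level", {
    ## on a short contig the event biases its own chromosome mean; the
    ## median option recovers log2 = -1 for a half-depth megabase
    d <- rep(6, 500)
    d[201:300] <- 3
    prof <- mkProfile(list(cA = d))
    m <- backgroundScan(prof, noExclusions, stat = "median")
    expect_equal(m$mean_log2, -1, tolerance = 1e-9)
})
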