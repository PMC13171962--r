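test_that("printed coordinate strings parse with both conventions", {
    r <- parseRegionStrings("chr6:95,868,323-96,766,693")
    expect_equal(GenomicRanges::width(r), 898371)  # rounds to 898 kb
    r2 <- parseRegionStrings("chr16:28,242,001-29,708,000")
    expect_equal(GenomicRanges::width(r2), 1466000)  # ~1.47 Mb
    b <- parseRegionStrings("chr1:100-200", convention = "bed_0_half_open")
    expect_equal(GenomicRanges::start(b), 101)
    expect_equal(GenomicRanges::width(b), 100)
    expect_error(parseRegionStrings("chr1:500-100"), "precedes|positive")
    expect_error(parseRegionStrings("garbage"), "parse")
})

test_that("inclusive coordinate strings round-trip to the printed numerals", {
    set.seed(11)
    for (k in 1:25) {
        s <- sample(1:2e8, 1)
        str <- sprintf("chr%d:%s-%s", sample(1:22, 1),
                       formatC(s, format = "d", big.mark = ","),
                       formatC(s + sample(1:5e6, 1), format = "d",
                               big.mark = ","))
        expect_identical(regionString(parseRegionStrings(str)), str)
    }
})

test_that("region files read as BED or as coordinate tables", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t1000\t2000\tA", "chr2\t0\t500\tB"), bed)
    r <- readRegions(bed)
    expect_equal(GenomicRanges::start(r), c(1001, 1))
    expect_equal(r$name, c("A", "B"))
    tab <- tempfile(fileext = ".txt")
    writeLines(c("chr6:95,868,323-96,766,693\tK\tT2T-CHM13\trearrangement",
                 "chr16:28,242,001-29,708,000"), tab)
    r2 <- readRegions(tab)
    expect_equal(GenomicRanges::width(r2), c(898371, 1466000))
    expect_equal(r2$name[1], "K")
    expect_equal(r2$assembly[1], "T2T-CHM13")
    expect_equal(r2$role, c("rearrangement", "control"))
    ## auto-assigned name for the unnamed row
    expect_match(r2$name[2], "^R")
    empty <- tempfile(fileext = ".txt")
    writeLines(character(0), empty)
    expect_length(readRegions(empty), 0)
    bad <- tempfile(fileext = ".txt")
    writeLines(c("chr1:1-100", "not-a-region"), bad)
    expect_error(readRegions(bad), "line 2")
})

test_that("target FASTA extraction matches direct substring slicing", {
    set.seed(21)
    fa <- tempfile(fileext = ".fa")
    s1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    s2 <- paste(sample(c("a", "c", "g", "t"), 300, TRUE), collapse = "")
    writeLines(c(">tig1 some description", s1, ">tig2", s2), fa)
    regs <- suppressWarnings(c(
        GenomicRanges::GRanges("tig1", IRanges::IRanges(1, 10)),
        GenomicRanges::GRanges("tig2", IRanges::IRanges(51, 120)),
        GenomicRanges::GRanges("tig1", IRanges::IRanges(350, 400))))
    regs$name <- c("A", "B", "C")
    out <- extractTargetFasta(fa, regs)
    expect_equal(length(out), 3L)
    expect_identical(names(out)[1], "A:tig1:1-10")
    ## substring oracle, case preserved
    expect_identical(as.character(out[[1]]), substr(s1, 1, 10))
    expect_identical(as.character(out[[2]]), toupper(substr(s2, 51, 120)))
    expect_identical(as.character(out[[3]]), substr(s1, 350, 400))
    bad <- GenomicRanges::GRanges("tig2", IRanges::IRanges(250, 350))
    expect_error(extractTargetFasta(fa, bad), "bounds")
    missing <- GenomicRanges::GRanges("tigX", IRanges::IRanges(1, 5))
    expect_error(extractTargetFasta(fa, missing), "not present")
})

test_that("sequencing summaries parse verbatim and round-trip", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c(
        "read_id\tsequence_length_template\tmean_qscore_template\tend_reason",
        "r1\t5000\t14.2\tsignal_positive",
        "r2\t520\t11.0\tdata_service_unblock_mux_change",
        "r3\t0\t9.1\tunblock_mux_change"), f)
    rs <- readSequencingSummary(f)
    expect_equal(length(rs), 3L)
    expect_identical(endReason(rs),
                     c("signal_positive", "data_service_unblock_mux_change",
                       "unblock_mux_change"))
    expect_equal(readLengths(rs)[3], 0)  # zero-length read is not an error
    expect_true(all(is.na(readFate(rs))))
    bad <- tempfile(fileext = ".tsv")
    writeLines(c("read_id\tfoo", "r1\t1"), bad)
    expect_error(readSequencingSummary(bad), "missing column")
    ## simulator-written summary round-trips on all fields
    sim <- simulateRun(tinyConfig(seed = 301L))
    out <- tempfile(fileext = ".tsv")
    writeSequencingSummary(sim$reads, out)
    back <- readSequencingSummary(out)
    expect_identical(readIDs(back), readIDs(sim$reads))
    expect_equal(readLengths(back), readLengths(sim$reads))
    expect_equal(meanQ(back), meanQ(sim$reads), tolerance = 1e-10)
    expect_identical(endReason(back), endReason(sim$reads))
})

test_that("SAM alignments yield CIGAR-derived spans and query-ordered segments", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6",
        "@SQ\tSN:chrT\tLN:100000",
        "@SQ\tSN:chrU\tLN:100000",
        "r1\t0\tchrT\t1001\t60\t100M\t*\t0\t0\t*\t*",
        "r2\t0\tchrT\t2001\t60\t50M50S\t*\t0\t0\t*\t*",
        "r2\t2048\tchrU\t5001\t60\t50S50M\t*\t0\t0\t*\t*",
        "r3\t0\tchrT\t3001\t60\t10M5D10M\t*\t0\t0\t*\t*",
        "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
    expect_message(aln <- readAlignments(sam), "1 unmapped")
    expect_equal(length(aln), 4L)
    r1 <- aln[aln$read_id == "r1"]
    expect_equal(c(GenomicRanges::start(r1), GenomicRanges::end(r1)),
                 c(1001, 1100))
    r2 <- aln[aln$read_id == "r2"]
    expect_equal(r2$segment_index, 0:1)
    expect_identical(as.character(GenomicRanges::seqnames(r2)),
                     c("chrT", "chrU"))
    r3 <- aln[aln$read_id == "r3"]
    expect_equal(GenomicRanges::width(r3), 25)  # 10M5D10M spans 25 bp
})

test_that("the plain-table alignment dialect round-trips through GRanges", {
    sim <- simulateRun(tinyConfig(seed = 302L))
    f <- tempfile(fileext = ".tsv")
    writeAlignmentsTSV(sim$alignments, f)
    back <- readAlignments(f, layout = tinyLayout())
    expect_equal(length(back), length(sim$alignments))
    expect_identical(back$read_id, sim$alignments$read_id)
    expect_equal(GenomicRanges::start(back),
                 GenomicRanges::start(sim$alignments))
    expect_equal(GenomicRanges::end(back),
                 GenomicRanges::end(sim$alignments))
    expect_identical(as.character(GenomicRanges::strand(back)),
                     as.character(GenomicRanges::strand(sim$alignments)))
    expect_identical(back$read_class, sim$alignments$read_class)
})

test_that("track and call files are valid when empty and idempotent to rewrite", {
    d1 <- tempfile()
    files <- writeTracksAndCalls(list(), NULL, NULL, d1)
    vcf <- readLines(file.path(d1, "calls.vcf"))
    expect_match(vcf[1], "fileformat")
    expect_false(any(grepl("^[^#]", vcf)))  # header-only
    ## one loss segment becomes one DEL record with END and CN
    seg <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000, 5000),
        region = 1L, mean_log2 = -1, cn_estimate = 1L, n_bins = 8L,
        n_windows = 1L, status = "loss")
    d2 <- tempfile()
    writeTracksAndCalls(list(), seg, NULL, d2)
    rec <- grep("^[^#]", readLines(file.path(d2, "calls.vcf")),
                value = TRUE)
    expect_length(rec, 1L)
    expect_match(rec, "SVTYPE=DEL;END=5000;CN=1")
    ## bedGraph written, re-imported and re-exported is byte-identical
    sim <- simulateRun(tinyConfig(seed = 303L))
    p <- simPipeline(sim)
    prof <- binnedDepth(p$alignments, tinyTargets(), 500)
    d3 <- tempfile()
    f <- writeTracksAndCalls(list(t = prof), NULL, NULL, d3,
                             layout = tinyLayout())
    bg <- rtracklayer::import(f[1], format = "bedGraph")
    f2 <- tempfile(fileext = ".bedGraph")
    rtracklayer::export(bg, f2, format = "bedGraph")
    expect_identical(readLines(f[1]), readLines(f2))
})
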