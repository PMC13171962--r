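## two-segment split read helper: returns alignment GRanges
splitRead <- function(id, c1, s1, e1, st1, c2, s2, e2, st2) {
    suppressWarnings(GenomicRanges::GRanges(
        c(c1, c2), IRanges::IRanges(c(s1, s2), c(e1, e2)),
        strand = c(st1, st2), read_id = id, segment_index = 0:1,
        read_class = "on_target"))
}

test_that("raw junction observations follow read orientation", {
    ## clean deletion: read exits at 100,000, re-enters at 200,001
    del <- splitRead("d1", "c1", 95001, 100000, "+",
                     "c1", 200001, 205000, "+")
    obs <- extractRawJunctions(del)
    expect_equal(nrow(obs), 1L)
    expect_equal(obs$pos_a, 100000)
    expect_identical(obs$orient_a, "tail")
    expect_equal(obs$pos_b, 200001)
    expect_identical(obs$orient_b, "head")
    expect_identical(
        classifyJunction(obs$contig_a, obs$pos_a, obs$orient_a,
                         obs$contig_b, obs$pos_b, obs$orient_b),
        "DEL-like")
    ## inter-contig split is translocation-compatible
    tra <- splitRead("t1", "c1", 95001, 100000, "+",
                     "c2", 50001, 55000, "+")
    o2 <- extractRawJunctions(tra)
    expect_identical(
        classifyJunction(o2$contig_a, o2$pos_a, o2$orient_a,
                         o2$contig_b, o2$pos_b, o2$orient_b), "TRA")
    ## a three-segment read contributes two observations
    three <- suppressWarnings(GenomicRanges::GRanges(
        "c1", IRanges::IRanges(c(1, 5001, 9001), c(1000, 6000, 10000)),
        strand = "+", read_id = "x", segment_index = 0:2,
        read_class = "on_target"))
    expect_equal(nrow(extractRawJunctions(three)), 2L)
    ## single-segment reads contribute nothing
    expect_equal(nrow(extractRawJunctions(three[1])), 0L)
})

test_that("clustering is tolerant to jitter, thresholded, and order-invariant", {
    set.seed(51)
    jitter <- function(n, p) p + sample(-10:10, n, replace = TRUE)
    obs <- data.frame(
        read_id = paste0("r", 1:5),
        contig_a = "c1", pos_a = jitter(5, 100000), orient_a = "tail",
        contig_b = "c1", pos_b = jitter(5, 200000), orient_b = "head",
        stringsAsFactors = FALSE)
    jx <- clusterJunctions(obs, tol = 50, minSupport = 3)
    expect_length(jx, 1L)
    jt <- junctionTable(jx)
    expect_equal(jt$support, 5L)
    expect_equal(jt$pos_a, round(median(obs$pos_a)))
    expect_equal(jt$pos_b, round(median(obs$pos_b)))
    ## below the support threshold nothing is reported
    expect_length(clusterJunctions(obs[1:2, ], minSupport = 3), 0L)
    ## junctions 10 kb apart never merge at tol 50
    far <- obs
    far$pos_a <- far$pos_a + rep(c(0, 10000), c(3, 2))
    far$read_id <- paste0("s", 1:5)
    two <- clusterJunctions(rbind(obs, far), tol = 50, minSupport = 2)
    expect_length(two, 2L)
    ## permutation invariance
    perm <- rbind(obs, far)[sample(10), ]
    expect_identical(as.data.frame(clusterJunctions(perm, tol = 50,
                                                    minSupport = 2)),
                     as.data.frame(two))
    ## support conservation across clusters
    expect_equal(sum(junctionSupport(two)), 10L)
})

test_that("junction typing follows standard orientation algebra", {
    expect_identical(classifyJunction("c1", 100000, "tail",
                                      "c1", 200000, "head"), "DEL-like")
    expect_identical(classifyJunction("c1", 100000, "head",
                                      "c1", 200000, "tail"), "DUP-like")
    expect_identical(classifyJunction("c1", 100000, "head",
                                      "c1", 200000, "head"), "INV-like")
    expect_identical(classifyJunction("c1", 100000, "tail",
                                      "c1", 200000, "tail"), "INV-like")
    expect_identical(classifyJunction("c6", 96500931, "tail",
                                      "c22", 3117669, "head"), "TRA")
    expect_identical(classifyJunction("c1", 5, "tail", "c1", 5, "head"),
                     "ambiguous")
})

test_that("breakpoint verification distinguishes nucleotide, depth-only and absent evidence", {
    obs <- data.frame(read_id = paste0("r", 1:8), contig_a = "c1",
                      pos_a = 130000, orient_a = "tail", contig_b = "c3",
                      pos_b = 300000, orient_b = "head",
                      stringsAsFactors = FALSE)
    jx <- clusterJunctions(obs)
    expected <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(100001, 160000))
    v <- verifyBreakpoint(expected, jx)
    expect_identical(v$verdict, "confirmed_nucleotide")
    expect_equal(v$position, 130000)
    expect_equal(v$support, 8L)
    ## depth-only: no junction, but a loss segment overlaps
    seg <- GenomicRanges::GRanges("c2", IRanges::IRanges(1, 50000),
        region = 1L, mean_log2 = -1, cn_estimate = 1L, n_bins = 10L,
        n_windows = 1L, status = "loss")
    exp2 <- GenomicRanges::GRanges("c2", IRanges::IRanges(1000, 2000))
    v2 <- verifyBreakpoint(exp2, clusterJunctions(obs[0, ]), seg)
    expect_identical(v2$verdict, "supported_depth_only")
    ## nothing at all
    v3 <- verifyBreakpoint(exp2, clusterJunctions(obs[0, ]))
    expect_identical(v3$verdict, "not_confirmed")
    ## support below threshold does not confirm
    v4 <- verifyBreakpoint(expected, jx, minSupport = 20)
    expect_identical(v4$verdict, "not_confirmed")
})

test_that("simulated split reads reproduce their planted junctions exactly", {
    cfg <- tinyConfig(
        svs = list(svDeletion("c1", 120001, 140000)), seed = 340L)
    sim <- simulateRun(cfg)
    p <- simPipeline(sim)
    jx <- clusterJunctions(extractRawJunctions(p$alignments))
    expect_length(jx, 1L)
    jt <- junctionTable(jx)
    expect_identical(jt$type, "DEL-like")
    expect_equal(jt$pos_a, 120000)
    expect_equal(jt$pos_b, 140001)
    tj <- truthJunctions(sim$truth)
    expect_setequal(unlist(jt$read_ids), unlist(tj$read_ids))
})
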