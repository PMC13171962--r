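## Independent oracles, deliberately naive implementations kept separate
## from the package's code paths.

## N50 by explicit accumulation loop
bruteN50 <- function(lengths) {
    s <- sort(lengths, decreasing = TRUE)
    half <- sum(s) / 2
    acc <- 0
    for (x in s) {
        acc <- acc + x
        if (acc >= half) return(x)
    }
    NA_real_
}

## per-base pileup mean depth for one bin, from raw alignment coordinates
pileupBinDepth <- function(alnStart, alnEnd, binStart, binEnd) {
    counts <- integer(binEnd - binStart + 1)
    for (i in seq_along(alnStart)) {
        lo <- max(alnStart[i], binStart)
        hi <- min(alnEnd[i], binEnd)
        if (lo <= hi)
            counts[(lo:hi) - binStart + 1] <-
                counts[(lo:hi) - binStart + 1] + 1L
    }
    mean(counts)
}

## brute-force CIGAR interpreter: reference span consumed by M/=/X/D/N
cigarRefSpan <- function(cigar) {
    m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    span <- 0L
    for (tok in m) {
        n <- as.integer(sub("[MIDNSHP=X]", "", tok))
        op <- sub("[0-9]+", "", tok)
        if (op %in% c("M", "=", "X", "D", "N")) span <- span + n
    }
    span
}

randomCigar <- function() {
    nops <- sample(1:6, 1)
    ops <- sample(c("M", "I", "D", "S", "N", "=", "X"), nops,
                  replace = TRUE, prob = c(6, 1, 1, 1, 1, 1, 1))
    ## a SAM-valid CIGAR needs at least one M/=/X and clips only at ends
    ops <- ops[!(ops == "S" & seq_along(ops) > 1 &
                 seq_along(ops) < nops)]
    if (!any(ops %in% c("M", "=", "X"))) ops <- c(ops, "M")
    lens <- sample(1:200, length(ops), replace = TRUE)
    paste0(lens, ops, collapse = "")
}

## independent walk validator for a segment graph: checks multiplicities
## and that every consecutive pair (and the anchors) is a legal adjacency
validWalk <- function(walk, segs, jx, tol = 50) {
    ids <- sub("[+-]$", "", walk)
    ori <- sub("^.*([+-])$", "\\1", walk)
    cnt <- table(factor(ids, levels = segs$id))
    if (!all(as.integer(cnt) == segs$multiplicity)) return(FALSE)
    exitPoint <- function(id, o) {
        i <- match(id, segs$id)
        if (o == "+") c(segs$contig[i], segs$end[i], "tail")
        else c(segs$contig[i], segs$start[i], "head")
    }
    entryPoint <- function(id, o) {
        i <- match(id, segs$id)
        if (o == "+") c(segs$contig[i], segs$start[i], "head")
        else c(segs$contig[i], segs$end[i], "tail")
    }
    okAdj <- function(ex, en) {
        ## reference adjacency
        if (ex[1] == en[1] && ex[3] == "tail" && en[3] == "head" &&
            as.numeric(en[2]) == as.numeric(ex[2]) + 1) return(TRUE)
        if (ex[1] == en[1] && ex[3] == "head" && en[3] == "tail" &&
            as.numeric(en[2]) == as.numeric(ex[2]) - 1) return(TRUE)
        ## junction edges (either traversal direction)
        if (nrow(jx)) for (i in seq_len(nrow(jx))) {
            a <- c(jx$contig_a[i], jx$pos_a[i], jx$orient_a[i])
            b <- c(jx$contig_b[i], jx$pos_b[i], jx$orient_b[i])
            near <- function(p, q)
                p[1] == q[1] && p[3] == q[3] &&
                abs(as.numeric(p[2]) - as.numeric(q[2])) <= tol
            if ((near(ex, a) && near(en, b)) ||
                (near(ex, b) && near(en, a))) return(TRUE)
        }
        FALSE
    }
    n <- nrow(segs)
    first <- match(ids[1], segs$id)
    ## left anchor: must enter segment 1 forward or arrive via a junction
    ## from the boundary left of segment 1
    leftOK <- (ids[1] == segs$id[1] && ori[1] == "+") ||
        okAdj(c(segs$contig[1], segs$start[1] - 1, "tail"),
              entryPoint(ids[1], ori[1]))
    if (!leftOK) return(FALSE)
    lastOK <- (ids[length(ids)] == segs$id[n] &&
               ori[length(ids)] == "+") ||
        okAdj(exitPoint(ids[length(ids)], ori[length(ids)]),
              c(segs$contig[n], segs$end[n] + 1, "head"))
    if (!lastOK) return(FALSE)
    if (length(walk) > 1) {
        for (k in seq_len(length(walk) - 1)) {
            if (!okAdj(exitPoint(ids[k], ori[k]),
                       entryPoint(ids[k + 1], ori[k + 1])))
                return(FALSE)
        }
    }
    TRUE
}

## exhaustive permutation oracle: all orderings/orientations of the
## oriented segment multiset, filtered by validWalk
bruteArchitectures <- function(segs, jx, tol = 50) {
    copies <- rep(segs$id, segs$multiplicity)
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (x in unique(v)) {
            rest <- v[-match(x, v)]
            for (p in perms(rest))
                out[[length(out) + 1L]] <- c(x, p)
        }
        out
    }
    base <- perms(copies)
    sols <- list()
    for (p in base) {
        k <- length(p)
        for (mask in 0:(2^k - 1)) {
            ori <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0, "-", "+")
            walk <- paste0(p, ori)
            if (validWalk(walk, segs, jx, tol)) {
                key <- paste(walk, collapse = " ")
                sols[[key]] <- walk
            }
        }
    }
    unname(sols[order(names(sols))])
}

segsAsDF <- function(gr) {
    data.frame(id = gr$id, contig = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               multiplicity = gr$multiplicity,
               stringsAsFactors = FALSE)
}

jxAsDF <- function(js) {
    as.data.frame(junctionTable(js)[, c("contig_a", "pos_a", "orient_a",
                                        "contig_b", "pos_b", "orient_b")])
}
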