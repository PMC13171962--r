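#' @importFrom stats rlnorm runif qnorm pnorm median setNames
NULL

## Log-normal read-length model. The N50 of a log-normal(mu, sigma) length
## distribution is the median of the length-biased distribution, which is
## log-normal(mu + sigma^2, sigma); hence N50 = exp(mu + sigma^2) and
## mu = log(N50) - sigma^2. Mean length is exp(mu + sigma^2 / 2).
.lnMeanlog <- function(n50, sigma) log(n50) - sigma^2
.lnMeanLength <- function(n50, sigma) n50 * exp(-sigma^2 / 2)

.drawLengths <- function(n, n50, sigma) {
    pmax(30, round(rlnorm(n, .lnMeanlog(n50, sigma), sigma)))
}

## Truncated-normal mean qualities: passing reads >= 10, failing < 10.
.drawQ <- function(n, qMean, qSD, pass) {
    p10 <- pnorm(10, qMean, qSD)
    u <- if (pass) runif(n, p10, 1) else runif(n, 0, p10)
    pmax(1, qnorm(u, qMean, qSD))
}

## --------------------------------------------------------------------------
## Planted SV constructors
## --------------------------------------------------------------------------

.svNew <- function(kind, id, genotype, cnProfile, junctions) {
    if (!"traversals" %in% colnames(junctions) && nrow(junctions))
        junctions$traversals <- 1
    new("PlantedSV", kind = kind, id = id, genotype = genotype,
        cnProfile = cnProfile, junctions = junctions)
}

.cnGR <- function(contig, start, end, cn) {
    gr <- GRanges(contig, IRanges(start, end))
    mcols(gr)$cn <- as.integer(cn)
    gr
}

.jxRow <- function(ca, pa, oa, cb, pb, ob, traversals = 1) {
    data.frame(contig_a = ca, pos_a = pa, orient_a = oa, contig_b = cb,
               pos_b = pb, orient_b = ob, traversals = traversals,
               stringsAsFactors = FALSE)
}

#' Plant a deletion
#'
#' Total copy number 1 (het) or 0 (hom) over the interval, with the
#' deletion junction joining the last retained base before the event to
#' the first retained base after it.
#'
#' @param contig,start,end Deleted interval (1-based inclusive).
#' @param genotype `"het"` or `"hom"`.
#' @param id Label.
#' @return A [PlantedSV-class].
#' @export
svDeletion <- function(contig, start, end, genotype = "het", id = "del") {
    cn <- if (genotype == "het") 1L else 0L
    .svNew("deletion", id, genotype, .cnGR(contig, start, end, cn),
           .jxRow(contig, start - 1, "tail", contig, end + 1, "head"))
}

#' Plant a tandem duplication
#' @inheritParams svDeletion
#' @return A [PlantedSV-class] with total copy number 3 (het) or 4 (hom).
#' @export
svDuplication <- function(contig, start, end, genotype = "het",
                          id = "dup") {
    cn <- if (genotype == "het") 3L else 4L
    .svNew("duplication", id, genotype, .cnGR(contig, start, end, cn),
           .jxRow(contig, start, "head", contig, end, "tail"))
}

#' Plant a tandem triplication
#' @inheritParams svDeletion
#' @return A [PlantedSV-class] with total copy number 4 (het): three
#'   tandem copies on the carrier haplotype, whose junction is traversed
#'   twice per derived chromosome.
#' @export
svTriplication <- function(contig, start, end, genotype = "het",
                           id = "trip") {
    cn <- if (genotype == "het") 4L else 6L
    .svNew("triplication", id, genotype, .cnGR(contig, start, end, cn),
           .jxRow(contig, start, "head", contig, end, "tail",
                  traversals = 2))
}

#' Plant a tandem quintuplication
#' @inheritParams svDeletion
#' @return A [PlantedSV-class] with total copy number 6 (het).
#' @export
svQuintuplication <- function(contig, start, end, genotype = "het",
                              id = "quint") {
    cn <- if (genotype == "het") 6L else 10L
    .svNew("quintuplication", id, genotype, .cnGR(contig, start, end, cn),
           .jxRow(contig, start, "head", contig, end, "tail",
                  traversals = 4))
}

#' Plant a (balanced) translocation junction
#'
#' No copy-number change is modeled; the derived chromosome joins
#' `contig_a` at `pos_a` to `contig_b` at `pos_b` with the given
#' orientations (`"tail"`: sequence left of the position is retained;
#' `"head"`: sequence right of it).
#'
#' @param contig_a,pos_a,orient_a First side.
#' @param contig_b,pos_b,orient_b Second side.
#' @param genotype `"het"` or `"hom"`.
#' @param id Label.
#' @return A [PlantedSV-class].
#' @export
svTranslocation <- function(contig_a, pos_a, orient_a = "tail",
                            contig_b, pos_b, orient_b = "head",
                            genotype = "het", id = "tra") {
    .svNew("translocation", id, genotype, GRanges(),
           .jxRow(contig_a, pos_a, orient_a, contig_b, pos_b, orient_b))
}

#' Plant a composite rearrangement
#'
#' Explicit copy-number profile plus novel-adjacency list, for complex
#' events (e.g. duplicated flanks around a normal block, or triplicated
#' flanks around an inverted quintuplicated core).
#'
#' @param cnProfile `GRanges` with a `cn` column: total copy number over
#'   each affected interval.
#' @param junctions `data.frame` with side columns as in [junctionSet()]
#'   and an optional `traversals` column (crossings per derived
#'   haplotype, default 1).
#' @param genotype `"het"` or `"hom"`.
#' @param id Label.
#' @return A [PlantedSV-class].
#' @export
svComposite <- function(cnProfile, junctions, genotype = "het",
                        id = "cpx") {
    .svNew("composite", id, genotype, cnProfile, junctions)
}

#' Expected depth ratio and log2 level of a planted SV
#'
#' The expected depth ratio over an affected interval is its total copy
#' number over the local baseline (2 on autosomes and the female X, 1 on
#' the male X); an autosomal heterozygous deletion gives ratio 0.5 and
#' log2 -1, a heterozygous single-copy gain ratio 1.5 and log2 +0.585.
#' Copy number 0 reports `-Inf`.
#'
#' @param sv A [PlantedSV-class].
#' @param layout A [GenomeLayout-class] (sex context).
#' @return `data.frame` with one row per affected interval: `contig`,
#'   `start`, `end`, `cn`, `baseline`, `ratio`, `log2`.
#' @export
expectedDepthRatio <- function(sv, layout) {
    prof <- sv@cnProfile
    if (length(prof) == 0)
        return(data.frame(contig = character(0), start = numeric(0),
                          end = numeric(0), cn = integer(0),
                          baseline = numeric(0), ratio = numeric(0),
                          log2 = numeric(0)))
    contig <- as.character(GenomeInfoDb::seqnames(prof))
    baseline <- .baselineCN(contig, sampleSex(layout))
    ratio <- prof$cn / baseline
    data.frame(contig = contig, start = start(prof), end = end(prof),
               cn = prof$cn, baseline = baseline, ratio = ratio,
               log2 = ifelse(ratio > 0, log2(ratio), -Inf))
}

## --------------------------------------------------------------------------
## SimulationConfig
## --------------------------------------------------------------------------

.defaultSimLayout <- function(sex = "unknown") {
    GenomeLayout(c("chr1", "chr2", "chr3"), c(5e6, 5e6, 3e6), sex = sex)
}

.defaultSimTargets <- function() {
    parseRegionStrings(
        c("chr1:1,000,001-1,500,000", "chr2:1,000,001-1,500,000",
          "chr3:500,001-1,000,000"),
        names = c("T1", "T2", "T3"), role = "control")
}

#' Construct a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning and defaults of every
#' parameter.
#'
#' @param genome A [GenomeLayout-class].
#' @param targets `GRanges` of target regions.
#' @param svs List of [PlantedSV-class] objects.
#' @param onTargetDepth,offTargetDepth Mean depths (x-fold).
#' @param onN50,offN50 Read-length N50s (bp).
#' @param qMean,qSD,qFailFrac Quality model.
#' @param junctionReadFrac Fraction of carrier junction reads emitted as
#'   split alignments.
#' @param lnSigma Log-normal sdlog of read lengths.
#' @param seed Integer seed.
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(genome = .defaultSimLayout(),
                             targets = .defaultSimTargets(),
                             svs = list(),
                             onTargetDepth = 28, offTargetDepth = 5,
                             onN50 = 12000, offN50 = 560,
                             qMean = 14, qSD = 3, qFailFrac = 0.05,
                             junctionReadFrac = 1, lnSigma = 0.9,
                             seed = 1L) {
    cfg <- new("SimulationConfig", genome = genome, targets = targets,
               svs = svs, onTargetDepth = onTargetDepth,
               offTargetDepth = offTargetDepth, onN50 = onN50,
               offN50 = offN50, qMean = qMean, qSD = qSD,
               qFailFrac = qFailFrac,
               junctionReadFrac = junctionReadFrac, lnSigma = lnSigma,
               seed = as.integer(seed))
    sl <- seqlengths(seqinfo(genome))
    chk <- function(gr, what) {
        ctg <- as.character(GenomeInfoDb::seqnames(gr))
        if (!all(ctg %in% names(sl)))
            stop(what, " on unknown contig: ",
                 paste(setdiff(ctg, names(sl)), collapse = ", "))
        if (any(end(gr) > sl[ctg]) || any(start(gr) < 1))
            stop(what, " outside genome bounds")
    }
    chk(targets, "target region")
    allCN <- .collectCNProfile(svs)
    if (length(allCN)) {
        chk(allCN, "planted SV")
        hits <- GenomicRanges::findOverlaps(allCN, allCN)
        if (any(S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)))
            stop("planted SV copy-number intervals must not overlap")
    }
    if (offN50 >= onN50)
        warning("off-target N50 is not smaller than on-target N50")
    cfg
}

.collectCNProfile <- function(svs) {
    prof <- lapply(svs, function(sv) sv@cnProfile)
    prof <- prof[vapply(prof, length, integer(1)) > 0]
    if (!length(prof)) return(GRanges())
    do.call(c, unname(prof))
}

.collectJunctions <- function(svs) {
    rows <- lapply(svs, function(sv) {
        if (!nrow(sv@junctions)) return(NULL)
        j <- sv@junctions
        j$sv <- sv@id
        j$genotype <- sv@genotype
        j
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame())
    do.call(rbind, rows)
}

## --------------------------------------------------------------------------
## Read generation
## --------------------------------------------------------------------------

## Partition a generation domain into chunks of constant depth multiplier
## cn / 2 (baseline cn 2 on autosomes, 1 on the male X).
.cnChunks <- function(domain, cnGR, sex) {
    base <- GenomicRanges::setdiff(domain, cnGR, ignore.strand = TRUE)
    mcols(base)$mult <- .baselineCN(
        as.character(GenomeInfoDb::seqnames(base)), sex) / 2
    if (length(cnGR)) {
        ov <- GenomicRanges::findOverlaps(domain, cnGR)
        alt <- GenomicRanges::pintersect(cnGR[S4Vectors::subjectHits(ov)],
                                         domain[S4Vectors::queryHits(ov)])
        m <- alt$cn / 2
        mcols(alt) <- NULL
        mcols(alt)$mult <- m
        chunks <- c(base, alt)
    } else chunks <- base
    GenomicRanges::sort(chunks)
}

## Budgeted uniform read placement over a set of constant-multiplier
## chunks: within each chunk, reads are drawn until their aligned bases
## reach depth * mult * width. A read of length L starts uniformly in
## [chunkStart - L, chunkEnd], keeping expected coverage flat at
## depth * mult across the whole chunk. Returns plain vectors for speed.
.placeClassReads <- function(chunks, depth, n50, sigma, prefix, sl) {
    meanL <- .lnMeanLength(n50, sigma)
    ctgAll <- as.character(GenomeInfoDb::seqnames(chunks))
    key <- paste(ctgAll, start(chunks))
    endKey <- paste(ctgAll, end(chunks))
    Ls <- sts <- ens <- vector("list", length(chunks))
    ctgs <- character(length(chunks))
    for (i in seq_along(chunks)) {
        w <- as.numeric(width(chunks)[i])
        budget <- depth * chunks$mult[i] * w
        if (budget <= 0) next
        s <- start(chunks)[i]
        e <- end(chunks)[i]
        ## at an internal copy-number boundary alignments are clipped (a
        ## real read crossing a junction splits there); at domain edges
        ## they spill over naturally
        leftInternal <- paste(ctgAll[i], s - 1) %in% endKey
        rightInternal <- paste(ctgAll[i], e + 1) %in% key
        loClip <- if (leftInternal) s else 1
        hiClip <- if (rightInternal) e else sl[[ctgAll[i]]]
        mkBatch <- function(n) {
            L <- .drawLengths(n, n50, sigma)
            s0 <- floor(runif(n, min = s - L, max = e + 1))
            aStart <- pmax(loClip, s0)
            aEnd <- pmin(hiClip, s0 + L - 1)
            list(L = L, aStart = aStart, aEnd = aEnd,
                 contrib = pmax(0, aEnd - aStart + 1))
        }
        b <- mkBatch(ceiling(budget / meanL * 1.4) + 20)
        while (sum(b$contrib) < budget) {
            b2 <- mkBatch(ceiling(budget / meanL * 0.4) + 20)
            b <- Map(c, b, b2)
        }
        n <- which(cumsum(b$contrib) >= budget)[1]
        keep <- seq_len(n)[b$contrib[seq_len(n)] > 0]
        Ls[[i]] <- b$L[keep]
        sts[[i]] <- b$aStart[keep]
        ens[[i]] <- b$aEnd[keep]
        ctgs[i] <- ctgAll[i]
    }
    n_per <- vapply(Ls, length, integer(1))
    tot <- sum(n_per)
    list(read_id = paste0(prefix, seq_len(tot)),
         length = unlist(Ls, use.names = FALSE),
         contig = rep(ctgs, n_per),
         start = unlist(sts, use.names = FALSE),
         end = unlist(ens, use.names = FALSE))
}

## Junction-spanning split reads are carved out of the already-placed
## depth reads so that total depth stays exactly budgeted: the half of a
## spanning read on each junction side is an existing alignment ending
## (or truncated) at the side position, and the two halves are fused into
## one two-segment read. A read truncated at a side leaves behind a
## compensation read covering the removed interval (the reciprocal
## derived chromosome supplies that coverage in reality). On an
## untargeted partner side of a translocation no accepted reads exist, so
## that half is synthesized instead - one-sided targeting still yields
## spanning alignments on the far side.
##
## Side orientation to alignment strand: the first (3'-exiting) half is
## "+" at a tail side and "-" at a head side; the second (5'-entering)
## half is "+" at a head side and "-" at a tail side.
.sideCandidates <- function(pool, contig, pos, orient, minLen = 50) {
    if (orient == "tail") {
        clipped <- which(pool$contig == contig & pool$end == pos &
                         pos - pool$start + 1 >= minLen & !pool$used)
        crossing <- which(pool$contig == contig & pool$start <= pos &
                          pool$end > pos &
                          pos - pool$start + 1 >= minLen & !pool$used)
    } else {
        clipped <- which(pool$contig == contig & pool$start == pos &
                         pool$end - pos + 1 >= minLen & !pool$used)
        crossing <- which(pool$contig == contig & pool$start < pos &
                          pool$end >= pos &
                          pool$end - pos + 1 >= minLen & !pool$used)
    }
    list(clipped = clipped, crossing = setdiff(crossing, clipped))
}

## take up to n candidates for one junction side (clipped reads first);
## crossing reads are truncated at the position, the removed interval
## kept for a compensation read
.takeSide <- function(pool, cand, n, pos, orient) {
    avail <- c(cand$clipped, cand$crossing)
    avail <- avail[!pool$used[avail]]
    pick <- avail[seq_len(min(n, length(avail)))]
    segs <- data.frame(contig = pool$contig[pick],
                       start = pool$start[pick],
                       end = pool$end[pick], stringsAsFactors = FALSE)
    cross <- if (orient == "tail") segs$end > pos else segs$start < pos
    orig <- segs
    if (orient == "tail") segs$end <- pmin(segs$end, pos)
    else segs$start <- pmax(segs$start, pos)
    list(pick = pick, segs = segs, cross = cross, orig = orig,
         pos = pos, orient = orient)
}

## compensation intervals for the truncated (crossing) picks of one side
.sideComp <- function(tk, n) {
    keep <- seq_len(n)
    cross <- tk$cross[keep]
    if (!any(cross)) return(NULL)
    if (tk$orient == "tail")
        comp <- data.frame(contig = tk$orig$contig[keep][cross],
                           start = tk$pos + 1,
                           end = tk$orig$end[keep][cross])
    else
        comp <- data.frame(contig = tk$orig$contig[keep][cross],
                           start = tk$orig$start[keep][cross],
                           end = tk$pos - 1)
    comp[comp$end >= comp$start, , drop = FALSE]
}

#' Simulate a complete adaptive-sampling run
#'
#' Generates a sequencing summary, alignment segments and a truth set for
#' the configured genome, targets and planted SVs. Accepted (on-target)
#' reads start within one read length of a target and carry end reason
#' `"signal_positive"`; ejected (off-target) reads are uniform
#' genome-wide with end reason `"data_service_unblock_mux_change"`.
#' Read lengths are log-normal with parameters solved in closed form from
#' the configured N50s. Local depth over a planted SV scales with its
#' total copy number over the baseline, and carrier reads crossing a
#' planted junction inside a target are emitted as two-segment split
#' alignments meeting at the junction (ejected reads are too short to
#' span junctions informatively and are never split). Reads failing the
#' Q10 filter appear in the summary but have no alignments, mirroring a
#' pipeline that discards them before mapping. Identical seeds give
#' identical output.
#'
#' @param config A [SimulationConfig-class].
#' @return A list with elements `reads` ([ReadSet-class], unclassified),
#'   `alignments` (`GRanges` with `read_id`, `segment_index`,
#'   `read_class`), and `truth` ([TruthSet-class]).
#' @export
simulateRun <- function(config) {
    set.seed(config@seed)
    layout <- config@genome
    sex <- sampleSex(layout)
    sl <- seqlengths(seqinfo(layout))
    GenomeInfoDb::seqlevels(config@targets) <- names(sl)
    cnGR <- .collectCNProfile(config@svs)
    if (length(cnGR))
        GenomeInfoDb::seqlevels(cnGR) <- names(sl)
    jxTab <- .collectJunctions(config@svs)

    ## on-target depth reads
    onChunks <- .cnChunks(config@targets, cnGR, sex)
    on <- .placeClassReads(onChunks, config@onTargetDepth, config@onN50,
                           config@lnSigma, "on_", sl)

    ## off-target depth reads, genome-wide
    genomeGR <- GRanges(names(sl), IRanges(1, as.numeric(sl)))
    offChunks <- .cnChunks(genomeGR, cnGR, sex)
    off <- .placeClassReads(offChunks, config@offTargetDepth,
                            config@offN50, config@lnSigma, "off_", sl)

    ## fuse junction-spanning split reads out of the on-target pool
    pool <- list(contig = on$contig, start = on$start, end = on$end,
                 used = logical(length(on$read_id)))
    jxTruth <- list()
    fusedSeg <- list()   # per junction: two-segment alignment rows
    fusedLen <- numeric(0)
    fusedIDs <- character(0)
    compSeg <- list()    # single-segment compensation reads
    if (nrow(jxTab)) {
        sideIn <- function(ctg, pos)
            any(as.character(GenomeInfoDb::seqnames(config@targets)) ==
                    ctg &
                start(config@targets) <= pos &
                end(config@targets) >= pos)
        for (i in seq_len(nrow(jxTab))) {
            jx <- jxTab[i, ]
            inA <- sideIn(jx$contig_a, jx$pos_a)
            inB <- sideIn(jx$contig_b, jx$pos_b)
            carrier <- if (jx$genotype == "het") 0.5 else 1
            nWant <- if (inA || inB)
                round(config@junctionReadFrac * config@onTargetDepth *
                      carrier * jx$traversals)
            else 0L
            takeOrSynth <- function(inTarget, contig, pos, orient, n) {
                if (inTarget) {
                    cand <- .sideCandidates(pool, contig, pos, orient)
                    tk <- .takeSide(pool, cand, n, pos, orient)
                    pool$used[tk$pick] <<- TRUE
                    tk
                } else {
                    ## synthesized half on an untargeted partner side
                    l <- pmax(50, round(.drawLengths(n, config@onN50,
                                                     config@lnSigma) / 2))
                    st <- if (orient == "tail") pmax(1, pos - l + 1)
                          else rep(pos, n)
                    en <- if (orient == "tail") rep(pos, n)
                          else pmin(sl[[contig]], pos + l - 1)
                    list(pick = integer(0),
                         segs = data.frame(contig = rep(contig, n),
                                           start = st, end = en,
                                           stringsAsFactors = FALSE),
                         cross = logical(n), orig = NULL, pos = pos,
                         orient = orient)
                }
            }
            n <- 0L
            if (nWant >= 1) {
                A <- takeOrSynth(inA, jx$contig_a, jx$pos_a,
                                 jx$orient_a, nWant)
                B <- takeOrSynth(inB, jx$contig_b, jx$pos_b,
                                 jx$orient_b, nWant)
                n <- min(nrow(A$segs), nrow(B$segs))
                ## release any surplus picks beyond the pairable count
                for (tk in list(A, B))
                    if (length(tk$pick) > n)
                        pool$used[tk$pick[seq(n + 1,
                                              length(tk$pick))]] <- FALSE
            }
            if (n >= 1) {
                ids <- sprintf("jx_%s_%02d_%04d", jx$sv, i, seq_len(n))
                strandA <- if (jx$orient_a == "tail") "+" else "-"
                strandB <- if (jx$orient_b == "head") "+" else "-"
                keep <- seq_len(n)
                fusedSeg[[length(fusedSeg) + 1L]] <- data.frame(
                    read_id = rep(ids, 2L),
                    segment_index = rep(0:1, each = n),
                    contig = c(A$segs$contig[keep], B$segs$contig[keep]),
                    start = c(A$segs$start[keep], B$segs$start[keep]),
                    end = c(A$segs$end[keep], B$segs$end[keep]),
                    strand = rep(c(strandA, strandB), each = n),
                    stringsAsFactors = FALSE)
                fusedLen <- c(fusedLen,
                              (A$segs$end[keep] - A$segs$start[keep] + 1) +
                              (B$segs$end[keep] - B$segs$start[keep] + 1))
                fusedIDs <- c(fusedIDs, ids)
                for (tk in list(A, B)) {
                    if (is.null(tk$orig)) next
                    cp <- .sideComp(tk, n)
                    if (!is.null(cp) && nrow(cp))
                        compSeg[[length(compSeg) + 1L]] <- cp
                }
            }
            jxTruth[[i]] <- data.frame(
                sv = jx$sv, contig_a = jx$contig_a, pos_a = jx$pos_a,
                orient_a = jx$orient_a, contig_b = jx$contig_b,
                pos_b = jx$pos_b, orient_b = jx$orient_b,
                support = n,
                read_ids = I(list(if (n) sprintf("jx_%s_%02d_%04d",
                                                 jx$sv, i, seq_len(n))
                                  else character(0))),
                stringsAsFactors = FALSE)
        }
    }
    ## drop consumed reads from the on pool, append compensation reads
    if (any(pool$used)) {
        keep <- !pool$used
        on <- lapply(on, `[`, keep)
    }
    if (length(compSeg)) {
        cp <- do.call(rbind, compSeg)
        on$read_id <- c(on$read_id, paste0("cmp_", seq_len(nrow(cp))))
        on$contig <- c(on$contig, cp$contig)
        on$start <- c(on$start, cp$start)
        on$end <- c(on$end, cp$end)
        on$length <- c(on$length, cp$end - cp$start + 1)
    }
    jxAln <- if (length(fusedSeg)) do.call(rbind, fusedSeg) else NULL

    ## assemble summary (vectors; passing reads first, then Q-failures)
    jxIDs <- fusedIDs
    jxLen <- fusedLen
    qf <- config@qFailFrac
    nOn <- length(on$read_id) + length(jxIDs)
    nOff <- length(off$read_id)
    nFailOn <- round(nOn * qf / (1 - qf))
    nFailOff <- round(nOff * qf / (1 - qf))
    ids <- c(on$read_id, jxIDs, sprintf("onfail_%06d", seq_len(nFailOn)),
             off$read_id, sprintf("offfail_%06d", seq_len(nFailOff)))
    lens <- c(on$length, jxLen,
              .drawLengths(nFailOn, config@onN50, config@lnSigma),
              off$length,
              .drawLengths(nFailOff, config@offN50, config@lnSigma))
    qs <- c(.drawQ(nOn, config@qMean, config@qSD, TRUE),
            .drawQ(nFailOn, config@qMean, config@qSD, FALSE),
            .drawQ(nOff, config@qMean, config@qSD, TRUE),
            .drawQ(nFailOff, config@qMean, config@qSD, FALSE))
    reasons <- rep(c("signal_positive", EJECTED_END_REASON),
                   c(nOn + nFailOn, nOff + nFailOff))
    reads <- ReadSet(ids, lens, qs, reasons)

    ## assemble alignments (passing reads only)
    nJxSeg <- if (is.null(jxAln)) 0L else nrow(jxAln)
    alignments <- .alignmentGRanges(
        contig = c(on$contig, if (nJxSeg) jxAln$contig, off$contig),
        start = c(on$start, if (nJxSeg) jxAln$start, off$start),
        end = c(on$end, if (nJxSeg) jxAln$end, off$end),
        strand = c(rep("+", length(on$read_id)),
                   if (nJxSeg) jxAln$strand,
                   rep("+", length(off$read_id))),
        read_id = c(on$read_id, if (nJxSeg) jxAln$read_id, off$read_id),
        segment_index = c(rep(0L, length(on$read_id)),
                          if (nJxSeg) jxAln$segment_index,
                          rep(0L, length(off$read_id))),
        read_class = rep(c("on_target", "off_target"),
                         c(length(on$read_id) + nJxSeg,
                           length(off$read_id))),
        layout = layout)

    fates <- DataFrame(
        read_id = ids,
        fate = rep(c("on_target", "off_target"),
                   c(nOn + nFailOn, nOff + nFailOff)))
    jxDF <- if (length(jxTruth)) do.call(rbind, jxTruth)
            else data.frame()
    truthJx <- if (nrow(jxDF))
        DataFrame(sv = jxDF$sv, contig_a = jxDF$contig_a,
                  pos_a = jxDF$pos_a, orient_a = jxDF$orient_a,
                  contig_b = jxDF$contig_b, pos_b = jxDF$pos_b,
                  orient_b = jxDF$orient_b, support = jxDF$support,
                  read_ids = IRanges::CharacterList(jxDF$read_ids))
    else DataFrame(sv = character(0), contig_a = character(0),
                   pos_a = numeric(0), orient_a = character(0),
                   contig_b = character(0), pos_b = numeric(0),
                   orient_b = character(0), support = integer(0),
                   read_ids = IRanges::CharacterList())
    truth <- new("TruthSet", svs = config@svs, fates = fates,
                 junctions = truthJx)
    list(reads = reads, alignments = alignments, truth = truth)
}
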