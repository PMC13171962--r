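#' Build a JunctionSet from a plain side table
#'
#' Convenience constructor for assembling a [JunctionSet-class] from known
#' junction sides (e.g. a truth set, or externally curated breakpoints).
#' Sides are canonicalized and typed.
#'
#' @param sides `data.frame` with columns `contig_a`, `pos_a`, `orient_a`,
#'   `contig_b`, `pos_b`, `orient_b` and optionally `support`.
#' @return A [JunctionSet-class].
#' @export
junctionSet <- function(sides) {
    if (nrow(sides) == 0)
        return(clusterJunctions(data.frame(read_id = character(0),
            contig_a = character(0), pos_a = numeric(0),
            orient_a = character(0), contig_b = character(0),
            pos_b = numeric(0), orient_b = character(0))))
    o <- .canonicalizeObservations(sides)
    jt <- DataFrame(contig_a = o$contig_a, pos_a = o$pos_a,
        orient_a = o$orient_a, contig_b = o$contig_b, pos_b = o$pos_b,
        orient_b = o$orient_b,
        support = if ("support" %in% colnames(o)) as.integer(o$support)
                  else rep(1L, nrow(o)),
        type = classifyJunction(o$contig_a, o$pos_a, o$orient_a,
                                o$contig_b, o$pos_b, o$orient_b),
        pos_a_lo = o$pos_a, pos_a_hi = o$pos_a,
        pos_b_lo = o$pos_b, pos_b_hi = o$pos_b,
        read_ids = IRanges::CharacterList(
            lapply(seq_len(nrow(o)), function(i) character(0))))
    new("JunctionSet", junctions = jt)
}

## A "point" is one side of an adjacency: list(contig, pos, orient).
.pointMatches <- function(contig, pos, orient, side, tol) {
    contig == side$contig && orient == side$orient &&
        abs(pos - side$pos) <= tol
}

#' Enumerate rearrangement architectures from a segment graph
#'
#' Performs a depth-first enumeration of all walks of the derived
#' haplotype from the left reference anchor to the right reference
#' anchor, consuming each segment exactly its multiplicity times, and
#' moving only along graph edges: reference adjacencies (in either
#' orientation) and observed junctions (traversable in both directions,
#' orientation-respecting). Solutions are deduplicated; the count is
#' capped at `maxSolutions` with a `truncated` attribute. An empty result
#' signals copy-number/junction evidence inconsistent with any single
#' derived haplotype.
#'
#' @param graph A [SegmentGraph-class]. Total multiplicity must not
#'   exceed 20 (exhaustive search).
#' @param maxSolutions Cap on returned solutions (default 100).
#' @return A list of solutions, each a character vector of oriented
#'   segment ids (`"A+"`, `"B-"`, ...), with attribute `truncated`.
#' @export
enumerateArchitectures <- function(graph, maxSolutions = 100) {
    seg <- graphSegments(graph)
    tol <- graph@tol
    mult <- seg$multiplicity
    if (sum(mult) > 20)
        stop("total segment multiplicity exceeds the exhaustive-search cap (20)")
    n <- length(seg)
    ctg <- as.character(GenomeInfoDb::seqnames(seg))
    segStart <- start(seg)
    segEnd <- end(seg)
    jt <- junctionTable(graphJunctions(graph))
    sideOf <- function(i, which) {
        list(contig = jt[[paste0("contig_", which)]][i],
             pos = jt[[paste0("pos_", which)]][i],
             orient = jt[[paste0("orient_", which)]][i])
    }
    ## entry points: entering segment j forward = head@start_j,
    ## entering reverse = tail@end_j. The right anchor is head@(end_n + 1).
    rightAnchor <- list(contig = ctg[n], pos = segEnd[n] + 1,
                        orient = "head")
    entryFor <- function(side) {
        ## returns list of moves: list(kind = "seg", j, orientation) or
        ## list(kind = "anchor")
        moves <- list()
        if (.pointMatches(side$contig, side$pos, side$orient,
                          rightAnchor, tol))
            moves[[length(moves) + 1L]] <- list(kind = "anchor")
        if (side$orient == "head") {
            j <- which(ctg == side$contig & abs(segStart - side$pos) <= tol)
            for (jj in j)
                moves[[length(moves) + 1L]] <-
                    list(kind = "seg", j = jj, o = "+")
        } else {
            j <- which(ctg == side$contig & abs(segEnd - side$pos) <= tol)
            for (jj in j)
                moves[[length(moves) + 1L]] <-
                    list(kind = "seg", j = jj, o = "-")
        }
        moves
    }
    movesFromExit <- function(exit) {
        ## exit is a point: tail@p (came from the left) or head@p
        moves <- list()
        ## reference adjacency
        if (exit$orient == "tail") {
            j <- which(ctg == exit$contig & segStart == exit$pos + 1)
            if (length(j))
                moves[[length(moves) + 1L]] <-
                    list(kind = "seg", j = j[1], o = "+")
            if (exit$contig == ctg[n] && exit$pos == segEnd[n])
                moves[[length(moves) + 1L]] <- list(kind = "anchor")
        } else {
            j <- which(ctg == exit$contig & segEnd == exit$pos - 1)
            if (length(j))
                moves[[length(moves) + 1L]] <-
                    list(kind = "seg", j = j[1], o = "-")
        }
        ## junction edges, traversable both ways
        if (nrow(jt)) for (i in seq_len(nrow(jt))) {
            sa <- sideOf(i, "a"); sb <- sideOf(i, "b")
            if (.pointMatches(exit$contig, exit$pos, exit$orient, sa, tol))
                moves <- c(moves, entryFor(sb))
            if (.pointMatches(exit$contig, exit$pos, exit$orient, sb, tol))
                moves <- c(moves, entryFor(sa))
        }
        moves
    }
    exitOf <- function(j, o) {
        if (o == "+") list(contig = ctg[j], pos = segEnd[j], orient = "tail")
        else list(contig = ctg[j], pos = segStart[j], orient = "head")
    }
    solutions <- new.env()
    solutions$paths <- list()
    solutions$truncated <- FALSE
    recurse <- function(exit, remaining, path) {
        if (solutions$truncated) return(invisible())
        for (mv in movesFromExit(exit)) {
            if (mv$kind == "anchor") {
                if (all(remaining == 0)) {
                    key <- paste(path, collapse = " ")
                    if (is.null(solutions$paths[[key]])) {
                        solutions$paths[[key]] <- path
                        if (length(solutions$paths) >= maxSolutions)
                            solutions$truncated <- TRUE
                    }
                }
            } else if (remaining[mv$j] > 0) {
                remaining[mv$j] <- remaining[mv$j] - 1
                recurse(exitOf(mv$j, mv$o), remaining,
                        c(path, paste0(seg$id[mv$j], mv$o)))
                remaining[mv$j] <- remaining[mv$j] + 1
            }
        }
        invisible()
    }
    ## left anchor: exit point tail@(start_1 - 1)
    leftExit <- list(contig = ctg[1], pos = segStart[1] - 1,
                     orient = "tail")
    recurse(leftExit, mult, character(0))
    out <- unname(as.list(solutions$paths))
    out <- out[order(vapply(out, paste, character(1), collapse = " "))]
    attr(out, "truncated") <- solutions$truncated
    out
}
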