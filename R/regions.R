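#' @importFrom GenomicRanges GRanges start end width mcols mcols<- strand
#' @importFrom IRanges IRanges
NULL

.parseOneRegionString <- function(s) {
    s <- gsub(",", "", trimws(s))
    m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 4L) return(NULL)
    list(contig = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Parse coordinate strings into target regions
#'
#' Parses strings of the form `"chr6:95,868,323-96,766,693"` (thousands
#' separators allowed) into a `GRanges`. Two conventions are supported:
#' `"table_1_inclusive"` treats coordinates as 1-based and inclusive of the
#' end base (the convention of printed coordinate tables), while
#' `"bed_0_half_open"` treats them as 0-based half-open (BED arithmetic).
#' Internally everything is held 1-based inclusive (the GRanges
#' convention), so half-open inputs are shifted by `start + 1`.
#'
#' @param strings Character vector of `contig:start-end` strings.
#' @param convention `"table_1_inclusive"` (default) or `"bed_0_half_open"`.
#' @param names Optional region names; auto-assigned `"R1"`, `"R2"`, ...
#'   when absent.
#' @param assembly Free-text assembly label stored as metadata.
#' @param role `"control"` or `"rearrangement"`, recycled.
#' @return `GRanges` with metadata columns `name`, `assembly`, `role`.
#' @examples
#' r <- parseRegionStrings("chr6:95,868,323-96,766,693")
#' GenomicRanges::width(r)  # 898,371 bp, i.e. 898 kb
#' @export
parseRegionStrings <- function(strings,
                               convention = c("table_1_inclusive",
                                              "bed_0_half_open"),
                               names = NULL, assembly = "GRCh38",
                               role = "control") {
    convention <- match.arg(convention)
    parts <- lapply(strings, .parseOneRegionString)
    bad <- which(vapply(parts, is.null, logical(1)))
    if (length(bad))
        stop("cannot parse region string at position ", bad[1], ": '",
             strings[bad[1]], "'")
    contig <- vapply(parts, `[[`, character(1), "contig")
    start <- vapply(parts, `[[`, numeric(1), "start")
    end <- vapply(parts, `[[`, numeric(1), "end")
    if (convention == "bed_0_half_open") start <- start + 1
    if (any(end < start))
        stop("region end precedes start after coordinate conversion")
    if (is.null(names))
        names <- if (length(contig)) paste0("R", seq_along(contig))
                 else character(0)
    gr <- GRanges(contig, IRanges(start, end))
    mcols(gr)$name <- as.character(names)
    mcols(gr)$assembly <- rep_len(as.character(assembly), length(gr))
    mcols(gr)$role <- rep_len(as.character(role), length(gr))
    if (any(width(gr) <= 0))
        stop("regions must have positive length")
    gr
}

#' Format regions back into coordinate strings
#'
#' Inverse of [parseRegionStrings()]: under `"table_1_inclusive"` with
#' `big.mark = ","` the original printed numerals are reproduced exactly.
#'
#' @param regions `GRanges`.
#' @param convention Output convention (see [parseRegionStrings()]).
#' @param big.mark Thousands separator (default `","`).
#' @return Character vector of `contig:start-end` strings.
#' @export
regionString <- function(regions,
                         convention = c("table_1_inclusive",
                                        "bed_0_half_open"),
                         big.mark = ",") {
    convention <- match.arg(convention)
    s <- start(regions)
    e <- end(regions)
    if (convention == "bed_0_half_open") s <- s - 1
    fmt <- function(x) formatC(x, format = "d", big.mark = big.mark)
    paste0(as.character(GenomeInfoDb::seqnames(regions)), ":", fmt(s), "-",
           fmt(e))
}

#' Read target regions from BED or a coordinate table
#'
#' BED files (`.bed`) are imported with their native 0-based half-open
#' convention via \pkg{rtracklayer}. Any other file is treated as a
#' tab-separated coordinate table in which each line holds either a
#' `contig:start-end` string optionally followed by name, assembly and
#' role columns, or explicit `contig`, `start`, `end` and optional `name`
#' columns; the `convention` argument then applies (printed tables are
#' 1-based inclusive by default).
#'
#' @param path File path.
#' @param convention Coordinate convention for non-BED tables.
#' @return `GRanges` with metadata columns `name`, `assembly`, `role`.
#' @export
readRegions <- function(path,
                        convention = c("table_1_inclusive",
                                       "bed_0_half_open")) {
    convention <- match.arg(convention)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path, format = "BED")
        nm <- if (!is.null(gr$name) && !anyNA(gr$name)) gr$name
              else paste0("R", seq_along(gr))
        mcols(gr) <- NULL
        mcols(gr)$name <- nm
        mcols(gr)$assembly <- rep(NA_character_, length(gr))
        mcols(gr)$role <- rep("control", length(gr))
        if (length(gr) && any(width(gr) <= 0))
            stop("regions must have positive length")
        return(gr)
    }
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^#", lines)]
    if (!length(lines))
        return(parseRegionStrings(character(0)))
    fields <- strsplit(lines, "\t")
    out <- vector("list", length(lines))
    for (i in seq_along(fields)) {
        f <- trimws(fields[[i]])
        if (grepl(":", f[1])) {
            p <- .parseOneRegionString(f[1])
            if (is.null(p))
                stop("malformed region on line ", i, ": '", lines[i], "'")
            out[[i]] <- data.frame(contig = p$contig, start = p$start,
                end = p$end,
                name = if (length(f) >= 2) f[2] else NA_character_,
                assembly = if (length(f) >= 3) f[3] else NA_character_,
                role = if (length(f) >= 4) f[4] else NA_character_)
        } else {
            if (length(f) < 3 || anyNA(suppressWarnings(
                    as.numeric(gsub(",", "", f[2:3])))))
                stop("malformed region on line ", i, ": '", lines[i], "'")
            out[[i]] <- data.frame(contig = f[1],
                start = as.numeric(gsub(",", "", f[2])),
                end = as.numeric(gsub(",", "", f[3])),
                name = if (length(f) >= 4) f[4] else NA_character_,
                assembly = NA_character_, role = NA_character_)
        }
    }
    tab <- do.call(rbind, out)
    start <- tab$start
    if (convention == "bed_0_half_open") start <- start + 1
    if (any(tab$end < start))
        stop("region end precedes start after coordinate conversion (line ",
             which(tab$end < start)[1], ")")
    gr <- GRanges(tab$contig, IRanges(start, tab$end))
    nm <- tab$name
    nm[is.na(nm)] <- paste0("R", which(is.na(nm)))
    mcols(gr)$name <- nm
    asmb <- tab$assembly
    asmb[is.na(asmb)] <- "GRCh38"
    mcols(gr)$assembly <- asmb
    role <- tab$role
    role[is.na(role)] <- "control"
    mcols(gr)$role <- role
    gr
}

#' Extract target-region sequences from a genome FASTA
#'
#' Cuts the targeted subsequences out of a reference genome, e.g. to build
#' the custom FASTA supplied to the sequencer for adaptive sampling.
#' Record ids are `name:contig:start-end` (1-based inclusive).
#'
#' @param genome Path to a FASTA file or a
#'   [Biostrings::DNAStringSet-class].
#' @param regions `GRanges` of target regions (a `name` metadata column is
#'   used for ids when present).
#' @param outPath Optional path; when given the records are also written
#'   as FASTA.
#' @return A [Biostrings::DNAStringSet-class], one record per region in
#'   input order.
#' @export
extractTargetFasta <- function(genome, regions, outPath = NULL) {
    seqs <- if (is(genome, "DNAStringSet")) genome
            else Biostrings::readDNAStringSet(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    contig <- as.character(GenomeInfoDb::seqnames(regions))
    missing <- setdiff(unique(contig), names(seqs))
    if (length(missing))
        stop("contig(s) not present in the genome: ",
             paste(missing, collapse = ", "))
    lens <- Biostrings::width(seqs)[match(contig, names(seqs))]
    if (any(end(regions) > lens) || any(start(regions) < 1))
        stop("region exceeds contig bounds: ",
             regionString(regions[end(regions) > lens | start(regions) < 1][1]))
    out <- Biostrings::DNAStringSet(lapply(seq_along(regions), function(i)
        Biostrings::subseq(seqs[[contig[i]]], start(regions)[i],
                           end(regions)[i])))
    nm <- if (!is.null(regions$name)) regions$name
          else paste0("R", seq_along(regions))
    names(out) <- paste0(nm, ":", regionString(regions, big.mark = ""))
    if (!is.null(outPath))
        Biostrings::writeXStringSet(out, outPath)
    out
}
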