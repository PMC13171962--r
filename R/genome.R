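#' @importFrom utils read.delim write.table
NULL

## Contig names recognized as chromosome X / Y when applying sex-aware
## baselines and the "autosomal" qualifier.
.isChrX <- function(contig) as.character(contig) %in% c("chrX", "X")
.isChrY <- function(contig) as.character(contig) %in% c("chrY", "Y")

## Copy-number baseline per contig for a given sex.
.baselineCN <- function(contig, sex) {
    ifelse(sex == "male" & (.isChrX(contig) | .isChrY(contig)), 1, 2)
}

#' Read a genome description from FASTA or a contig-length table
#'
#' Accepts either a FASTA file (contig lengths taken from the sequences)
#' or a two-column tab-separated table with a header line naming `contig`
#' and `length` columns.
#'
#' @param path Path to a FASTA (`.fa`, `.fasta`, `.fna`) or TSV file.
#' @param sex Sample sex (`"male"`, `"female"`, `"unknown"`).
#' @return A [GenomeLayout-class].
#' @export
readGenomeLayout <- function(path, sex = "unknown") {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) {
        seqs <- Biostrings::readDNAStringSet(path)
        nm <- sub("\\s.*$", "", names(seqs))
        return(GenomeLayout(nm, Biostrings::width(seqs), sex = sex))
    }
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "length")
    if (!all(need %in% colnames(tab)))
        stop("length table must have 'contig' and 'length' columns; found: ",
             paste(colnames(tab), collapse = ", "))
    GenomeLayout(tab$contig, tab$length, sex = sex)
}

#' GRCh38 primary-assembly chromosome lengths
#'
#' Convenience layout built from the canonical GRCh38 chromosome lengths
#' (chr1-chr22, chrX, chrY, chrM) shipped with the package, for computing
#' target fractions of the human genome.
#'
#' @param sex Sample sex.
#' @return A [GenomeLayout-class] totalling about 3.1 Gb.
#' @examples
#' genomeSize(grch38Layout()) / 1e9
#' @export
grch38Layout <- function(sex = "unknown") {
    path <- system.file("extdata", "grch38_lengths.tsv", package = "svadapt")
    readGenomeLayout(path, sex = sex)
}

#' Fraction of a genome covered by target regions
#'
#' @param regions `GRanges` of target regions.
#' @param layout A [GenomeLayout-class]; defaults to GRCh38.
#' @return Percentage of the genome targeted (0-100 scale).
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 36e6))
#' round(targetFraction(r), 1)  # 36 Mb of GRCh38 ~ 1.2%
#' @export
targetFraction <- function(regions, layout = grch38Layout()) {
    100 * sum(as.numeric(GenomicRanges::width(regions))) / genomeSize(layout)
}
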