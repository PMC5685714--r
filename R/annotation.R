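# Reference annotation: GRCh37 chromosome sizes, chromosome-arm table and a
# small panel of cancer genes (shipped as BED fixtures under extdata).
# chrY and alt/decoy contigs are excluded throughout: Y is unreliable at
# ultra-low coverage while X is kept because AR lives on it.

.GRCH37_SIZES <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560)

# approximate GRCh37 centromere positions (p-arm end), 1-based
.GRCH37_CENTROMERES <- c(
    chr1 = 125000000, chr2 = 93300000, chr3 = 91000000, chr4 = 50400000,
    chr5 = 48400000, chr6 = 61000000, chr7 = 59900000, chr8 = 45600000,
    chr9 = 49000000, chr10 = 40200000, chr11 = 53700000, chr12 = 35800000,
    chr13 = 17900000, chr14 = 17600000, chr15 = 19000000, chr16 = 36600000,
    chr17 = 24000000, chr18 = 17200000, chr19 = 26500000, chr20 = 27500000,
    chr21 = 13200000, chr22 = 14700000, chrX = 60600000)

#' GRCh37 chromosome sizes (autosomes + X)
#'
#' @param scale integer divisor; \code{scale = 20} yields the miniature
#'   genome used by the desk-scale simulations (same chromosome names and
#'   proportions at 1/20 length).
#' @return named numeric vector of chromosome lengths in bp.
#' @examples
#' grch37Sizes()[c("chr8", "chrX")]
#' sum(grch37Sizes(scale = 20))
#' @export
grch37Sizes <- function(scale = 1) {
    stopifnot(scale >= 1)
    floor(.GRCH37_SIZES / scale)
}

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "plasmaCNA")
    if (!nzchar(path)) stop("missing extdata fixture: ", file)
    path
}

#' Load the shipped gene, arm and 21q22.2 annotation
#'
#' Versioned GRCh37 BED fixtures covering a small panel of copy-number
#' driver genes (AR, EGFR, FGFR1, PTEN, RB1, BRCA1, BRCA2, MYC), the
#' chromosome arms, and the ERG--TMPRSS2 span on 21q22.2 whose interstitial
#' deletion is the copy-number proxy for the TMPRSS2:ERG fusion.
#'
#' @param scale integer divisor applied to all coordinates (use the same
#'   value as [grch37Sizes()] for miniature-genome work).
#' @return a \code{GRanges} (genes and span carry a \code{name} column; arms
#'   carry \code{name} like "8p"/"8q").
#' @examples
#' geneAnnotation()["AR"]
#' armAnnotation()[c("8p", "8q")]
#' @export
geneAnnotation <- function(scale = 1) {
    gr <- rtracklayer::import(.extdata("genes_grch37.bed"), format = "BED")
    gr <- scaleAnnotation(gr, scale)
    names(gr) <- S4Vectors::mcols(gr)$name
    gr
}

#' @rdname geneAnnotation
#' @export
armAnnotation <- function(scale = 1) {
    gr <- rtracklayer::import(.extdata("arms_grch37.bed"), format = "BED")
    gr <- scaleAnnotation(gr, scale)
    names(gr) <- S4Vectors::mcols(gr)$name
    gr
}

#' @rdname geneAnnotation
#' @export
ergTmprss2Span <- function(scale = 1) {
    gr <- rtracklayer::import(.extdata("erg_tmprss2_grch37.bed"), format = "BED")
    scaleAnnotation(gr, scale)
}

#' Scale annotation coordinates onto a shrunken genome
#'
#' Divides interval coordinates by \code{scale} (floor), mirroring
#' [grch37Sizes()] so that annotation and miniature simulation genomes stay
#' aligned. Intervals are kept at least 1 bp wide.
#'
#' @param gr a \code{GRanges}.
#' @param scale integer divisor (1 = identity).
#' @return rescaled \code{GRanges} with seqlengths divided accordingly.
#' @export
scaleAnnotation <- function(gr, scale = 1) {
    stopifnot(scale >= 1)
    if (scale == 1) return(gr)
    # map 1-based closed [start, end] so that abutting intervals stay abutting
    st <- floor((BiocGenerics::start(gr) - 1) / scale) + 1
    en <- pmax(st, floor(BiocGenerics::end(gr) / scale))
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                  IRanges::IRanges(st, en))
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    sl <- GenomeInfoDb::seqlengths(gr)
    if (!all(is.na(sl)))
        GenomeInfoDb::seqlengths(out) <- floor(sl / scale)
    names(out) <- names(gr)
    out
}

# used by fixture generation at build/test time
.grch37Centromeres <- function(scale = 1) floor(.GRCH37_CENTROMERES / scale)
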