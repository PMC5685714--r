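# Genome-wide concordance between two segmented profiles (e.g. cfDNA vs
# tissue), gene-level comparison against targeted-NGS log2 tables, and the
# variant-fraction utility.

#' Project two segmented profiles onto a common bin grid
#'
#' Each grid bin takes the mean log2 ratio of the segment covering its
#' midpoint, per profile; bins whose midpoint is uncovered in either
#' profile are masked. The default 1 Mb grid is coarser than either
#' platform's native resolution, which dampens platform-specific edge
#' effects.
#'
#' @param a,b [SegmentedProfile] objects with common chromosome naming.
#' @param binWidth comparison grid width in bp (default 1 Mb).
#' @return a [PairedGrid].
#' @export
projectToGrid <- function(a, b, binWidth = 1e6) {
    stopifnot(methods::is(a, "SegmentedProfile"),
              methods::is(b, "SegmentedProfile"))
    chroms <- intersect(as.character(unique(GenomeInfoDb::seqnames(a))),
                        as.character(unique(GenomeInfoDb::seqnames(b))))
    if (!length(chroms))
        stop("profiles share no chromosome; nothing to compare")
    maxEnd <- function(p, chr) max(BiocGenerics::end(
        p[as.character(GenomeInfoDb::seqnames(p)) == chr]))
    sizes <- vapply(chroms, function(chr)
        max(maxEnd(a, chr), maxEnd(b, chr)), 0)
    gb <- makeBins(sizes, max(binWidth, 1e4))
    mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gb),
        IRanges::IRanges(floor((BiocGenerics::start(gb) +
                                BiocGenerics::end(gb)) / 2), width = 1L))
    lookup <- function(p) {
        hit <- GenomicRanges::findOverlaps(mids, methods::as(p, "GRanges"),
                                           select = "first")
        ifelse(is.na(hit), NA_real_, segMeans(p)[hit])
    }
    va <- lookup(a); vb <- lookup(b)
    gr <- methods::as(gb, "GRanges")
    S4Vectors::mcols(gr) <- NULL
    S4Vectors::mcols(gr)$valueA <- va
    S4Vectors::mcols(gr)$valueB <- vb
    S4Vectors::mcols(gr)$masked <- is.na(va) | is.na(vb)
    methods::new("PairedGrid", gr)
}

#' Pearson correlation of two projected profiles
#'
#' Standard Pearson correlation over the unmasked bins of a [PairedGrid].
#'
#' @param grid a [PairedGrid] with at least \code{minBins} unmasked bins.
#' @param minBins required unmasked bins (default 10).
#' @return list with \code{r} (NA when either vector has zero variance) and
#'   \code{n}.
#' @export
profileCorrelation <- function(grid, minBins = 10) {
    stopifnot(methods::is(grid, "PairedGrid"))
    mc <- S4Vectors::mcols(grid)
    ok <- !mc$masked
    if (sum(ok) < minBins)
        stop("need at least ", minBins, " unmasked bins; have ", sum(ok))
    x <- mc$valueA[ok]; y <- mc$valueB[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero variance in a profile; correlation undefined")
        return(list(r = NA_real_, n = sum(ok)))
    }
    list(r = stats::cor(x, y), n = sum(ok))
}

#' Gene-level comparison against a targeted-NGS copy-number table
#'
#' The WGS value of a gene is the mean log2 ratio of the segment covering
#' the gene midpoint. Comparison is restricted to genes whose targeted
#' |log2 ratio| is at least \code{minAbsLog2} (the targeted panel's
#' reportable range); genes absent from the WGS profile are dropped with a
#' message.
#'
#' @param wgs a [SegmentedProfile].
#' @param targeted data.frame with columns \code{gene}, \code{log2ratio}.
#' @param genes named gene intervals (e.g. [geneAnnotation()]).
#' @param minAbsLog2 targeted magnitude filter (default 0.5).
#' @return list with \code{table} (gene, targeted, wgs, agree),
#'   \code{r}, \code{directionAgreement}, \code{n}.
#' @export
geneLevelCompare <- function(wgs, targeted, genes, minAbsLog2 = 0.5) {
    stopifnot(methods::is(wgs, "SegmentedProfile"),
              all(c("gene", "log2ratio") %in% names(targeted)))
    geneNames <- if (!is.null(names(genes))) names(genes)
                 else S4Vectors::mcols(genes)$name
    known <- targeted$gene %in% geneNames
    if (any(!known))
        message("dropping gene(s) absent from annotation: ",
                paste(targeted$gene[!known], collapse = ", "))
    targeted <- targeted[known, , drop = FALSE]
    sel <- abs(targeted$log2ratio) >= minAbsLog2
    targeted <- targeted[sel, , drop = FALSE]
    if (!nrow(targeted))
        return(list(table = data.frame(), r = NA_real_,
                    directionAgreement = NA_real_, n = 0L))
    g <- genes[targeted$gene]
    mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(g),
        IRanges::IRanges(floor((BiocGenerics::start(g) +
                                BiocGenerics::end(g)) / 2), width = 1L))
    hit <- GenomicRanges::findOverlaps(mids, methods::as(wgs, "GRanges"),
                                       select = "first")
    wgsVal <- ifelse(is.na(hit), NA_real_, segMeans(wgs)[hit])
    ok <- !is.na(wgsVal)
    if (any(!ok))
        message("gene(s) not covered by the WGS profile: ",
                paste(targeted$gene[!ok], collapse = ", "))
    tab <- data.frame(gene = targeted$gene[ok],
                      targeted = targeted$log2ratio[ok], wgs = wgsVal[ok])
    tab$agree <- sign(tab$targeted) == sign(tab$wgs)
    r <- if (nrow(tab) >= 3 && stats::sd(tab$targeted) > 0 &&
             stats::sd(tab$wgs) > 0) stats::cor(tab$targeted, tab$wgs)
         else NA_real_
    list(table = tab, r = r,
         directionAgreement = if (nrow(tab)) mean(tab$agree) else NA_real_,
         n = nrow(tab))
}

#' Variant fraction as a printed percentage
#'
#' 100 x alt / total, rounded half-away-from-zero to one decimal (so
#' 105/504 reads report as 20.8%, independent of banker's rounding).
#'
#' @param altReads supporting reads (0 <= altReads <= totalReads).
#' @param totalReads covering reads (> 0).
#' @return percentage with one decimal.
#' @examples
#' variantFraction(105, 504)  # 20.8
#' @export
variantFraction <- function(altReads, totalReads) {
    if (any(totalReads <= 0)) stop("totalReads must be positive")
    if (any(altReads < 0) || any(altReads > totalReads))
        stop("altReads must lie in [0, totalReads]")
    pct <- 100 * altReads / totalReads
    sign(pct) * floor(abs(pct) * 10 + 0.5) / 10
}
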