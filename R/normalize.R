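#' Coverage-adaptive bin-width selection
#'
#' Picks the smallest width on the ladder whose expected reads per bin
#' (totalReads x width / genomeLength) reaches \code{minMeanReadsPerBin};
#' falls back to the largest ladder width when none qualifies. Keeping at
#' least ~30 reads per bin bounds the per-bin Poisson coefficient of
#' variation near 18%, so bins grow as coverage falls (0.005x coverage of a
#' 3.1 Gb genome, ~82,000 reads, selects 2.5 Mb bins).
#'
#' @param totalReads retained high-quality reads.
#' @param genomeLength genome length in bp (default human, 3.1 Gb).
#' @param ladder candidate widths in bp, ascending.
#' @param minMeanReadsPerBin required expected reads per bin (default 30).
#' @return selected bin width in bp.
#' @examples
#' chooseBinWidth(6.2e6)   # ~1x: 100 kb
#' chooseBinWidth(82000)   # 0.005x: 2.5 Mb
#' @export
chooseBinWidth <- function(totalReads, genomeLength = 3.1e9,
                           ladder = c(1e5, 2.5e5, 5e5, 1e6, 2.5e6, 5e6),
                           minMeanReadsPerBin = 30) {
    if (length(ladder) == 0L) stop("bin-width ladder must not be empty")
    if (length(totalReads) != 1L || is.na(totalReads) || totalReads <= 0)
        stop("totalReads must be a single positive number")
    ladder <- sort(ladder)
    ok <- totalReads * ladder / genomeLength >= minMeanReadsPerBin
    if (any(ok)) ladder[which(ok)[1L]] else ladder[length(ladder)]
}

#' GC-bias correction of bin counts
#'
#' Fits a smooth trend of count versus GC fraction (median count within
#' \code{nGcBins} equal-width GC bins, linearly interpolated) over the
#' usable, GC-annotated bins, then divides counts by the trend and rescales
#' so the pre-correction median count is preserved. Deterministic and
#' idempotent up to the trend tolerance; with all-equal GC no trend can be
#' fitted and the counts are returned unchanged with a warning.
#'
#' @param x a [BinCounts] with GC-annotated usable bins (>= 100 of them).
#' @param nGcBins number of GC strata for the trend (default 20).
#' @return a [BinCounts] with corrected (non-negative real) counts.
#' @export
correctGC <- function(x, nGcBins = 20) {
    stopifnot(methods::is(x, "BinCounts"))
    gc <- S4Vectors::mcols(x@bins)$gc
    usable <- S4Vectors::mcols(x@bins)$usable & !is.na(gc)
    if (sum(usable) < 100)
        stop("GC correction needs >= 100 usable GC-annotated bins")
    g <- gc[usable]
    cnt <- x@counts[usable]
    if (diff(range(g)) < 1e-9) {
        warning("all bins share one GC value; GC correction is the identity")
        return(x)
    }
    breaks <- seq(min(g), max(g), length.out = nGcBins + 1L)
    stratum <- cut(g, breaks, include.lowest = TRUE)
    med <- tapply(cnt, stratum, stats::median)
    centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
    keep <- !is.na(med)
    if (sum(keep) < 2L) {
        warning("too few populated GC strata; GC correction is the identity")
        return(x)
    }
    trend <- stats::approx(centers[keep], med[keep], xout = g, rule = 2)$y
    overall <- stats::median(cnt)
    trend <- pmax(trend, 0.05 * overall)  # guard against empty-tail collapse
    corrected <- x@counts
    corrected[usable] <- cnt / trend * overall
    methods::new("BinCounts", bins = x@bins, counts = corrected,
                 sampleId = x@sampleId, totalReads = x@totalReads,
                 meanReadLength = x@meanReadLength, filterStats = x@filterStats)
}

#' Log2 copy-ratio normalization against a panel of normals
#'
#' Converts (GC-corrected) counts into per-bin log2 copy ratios. With a
#' panel, the per-bin reference rate is the median across panel samples of
#' each sample's per-bin count fraction (the panel is presumed copy-neutral
#' and must be sex-matched for chrX calls to be interpretable); without a
#' panel the reference is uniform, i.e. median-only normalization. A
#' pseudocount of 0.5 reads on both numerator and denominator avoids
#' log(0) at ultra-low coverage. The profile is median-centered to 0 over
#' usable autosomal bins.
#'
#' @param x a [BinCounts].
#' @param panel optional list of [BinCounts] sharing the identical bin grid.
#' @param pseudocount reads added to both sides of the ratio (default 0.5).
#' @return a [CopyRatioProfile].
#' @export
toLog2Ratio <- function(x, panel = NULL, pseudocount = 0.5) {
    stopifnot(methods::is(x, "BinCounts"))
    b <- x@bins
    usable <- S4Vectors::mcols(b)$usable
    counts <- x@counts
    if (!is.null(panel) && length(panel)) {
        rates <- vapply(panel, function(p) {
            stopifnot(methods::is(p, "BinCounts"))
            if (length(p@bins) != length(b) ||
                !identical(as.character(GenomeInfoDb::seqnames(p@bins)),
                           as.character(GenomeInfoDb::seqnames(b))) ||
                !identical(BiocGenerics::start(p@bins), BiocGenerics::start(b)))
                stop("panel sample ", p@sampleId,
                     " is not on the same bin grid as ", x@sampleId)
            tot <- sum(p@counts[usable])
            if (tot <= 0) stop("panel sample ", p@sampleId, " has no reads")
            p@counts / tot
        }, numeric(length(b)))
        refRate <- apply(rates, 1L, stats::median)
        usable <- usable & refRate > 0
    } else {
        refRate <- rep(1, length(b))
    }
    refRate[!usable] <- NA_real_
    # expected counts under copy neutrality, at this sample's depth
    norm <- refRate / sum(refRate[usable], na.rm = TRUE)
    expected <- norm * sum(counts[usable])
    lr <- rep(NA_real_, length(b))
    lr[usable] <- log2((counts[usable] + pseudocount) /
                       (expected[usable] + pseudocount))
    auto <- usable & !(as.character(GenomeInfoDb::seqnames(b)) %in%
                       c("chrX", "chrY", "X", "Y"))
    center <- stats::median(lr[if (any(auto)) auto else usable])
    lr[usable] <- lr[usable] - center
    wt <- rep(NA_real_, length(b))
    wt[usable] <- pmax(expected[usable], pseudocount)
    wt[usable] <- wt[usable] / mean(wt[usable])
    methods::new("CopyRatioProfile", bins = b, log2ratio = lr, weight = wt,
                 sampleId = x@sampleId,
                 binWidth = max(BiocGenerics::width(b)))
}
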