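#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges findOverlaps tileGenome
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths seqinfo seqlevels seqlevelsInUse Seqinfo
#' @importFrom BiocGenerics start end width
#' @importFrom stats median approx rpois rbinom rnorm quantile isoreg cor complete.cases setNames sd
#' @importFrom utils read.table write.table head tail
NULL

#' GenomeBins: a fixed-width genomic bin grid
#'
#' A \linkS4class{GRanges} subclass holding a tiling bin grid with per-bin
#' GC fraction, mappability and a usability flag. Bins within a chromosome
#' are sorted, non-overlapping, and tile the chromosome with a single
#' (possibly shorter) terminal bin; all non-terminal bins share one width.
#'
#' Metadata columns: \code{gc} (fraction of G/C among non-N bases, NA when
#' unannotated), \code{mappability} (fraction in [0,1], NA when unannotated)
#' and \code{usable} (logical; FALSE for blacklisted / mostly-N bins).
#'
#' @seealso [makeBins()], [annotateGC()]
#' @export
setClass("GenomeBins", contains = "GRanges")

.validGenomeBins <- function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object)
    need <- c("gc", "mappability", "usable")
    if (!all(need %in% colnames(mc)))
        return(paste("missing metadata column(s):",
                     paste(setdiff(need, colnames(mc)), collapse = ", ")))
    if (!is.logical(mc$usable) || anyNA(mc$usable))
        msg <- c(msg, "'usable' must be logical without NA")
    for (col in c("gc", "mappability")) {
        v <- mc[[col]]
        if (!is.numeric(v))
            msg <- c(msg, sprintf("'%s' must be numeric", col))
        else if (any(v < 0 | v > 1, na.rm = TRUE))
            msg <- c(msg, sprintf("'%s' must lie in [0, 1]", col))
    }
    sl <- GenomeInfoDb::seqlengths(object)
    for (chr in GenomeInfoDb::seqlevelsInUse(object)) {
        gr <- object[GenomeInfoDb::seqnames(object) == chr]
        st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
        o <- order(st)
        st <- st[o]; en <- en[o]
        if (length(st) > 1L) {
            if (any(st[-1L] != en[-length(en)] + 1L))
                msg <- c(msg, sprintf("bins on %s do not tile without gaps/overlaps", chr))
            w <- en - st + 1L
            if (length(unique(w[-length(w)])) > 1L)
                msg <- c(msg, sprintf("non-terminal bins on %s are not of uniform width", chr))
            if (w[length(w)] > w[1L])
                msg <- c(msg, sprintf("terminal bin on %s is wider than the grid width", chr))
        }
        if (st[1L] != 1L)
            msg <- c(msg, sprintf("first bin on %s does not start at position 1", chr))
        if (!is.na(sl[chr]) && en[length(en)] != sl[chr])
            msg <- c(msg, sprintf("terminal bin on %s is not clipped to the chromosome end", chr))
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenomeBins", .validGenomeBins)

#' BinCounts: per-bin filtered read counts for one sample
#'
#' Holds the read count assigned to every bin of a [GenomeBins] grid,
#' together with sample metadata. Counts are non-negative; they are integer
#' after [countReads()] / [simulateCounts()] and may be real after
#' [correctGC()].
#'
#' @slot bins a [GenomeBins] grid.
#' @slot counts numeric vector, one value per bin, all >= 0.
#' @slot sampleId single character identifier.
#' @slot totalReads reads retained after filtering and assigned to bins.
#' @slot meanReadLength mean aligned read length in bases.
#' @slot filterStats named numeric vector of exclusion tallies
#'   (unmapped, secondary, supplementary, duplicate, low_mapq, out_of_bins).
#' @seealso [countReads()], [readCountsTable()], [effectiveCoverage()]
#' @export
setClass("BinCounts",
    slots = c(bins = "GenomeBins", counts = "numeric", sampleId = "character",
              totalReads = "numeric", meanReadLength = "numeric",
              filterStats = "numeric"))

setValidity("BinCounts", function(object) {
    msg <- character()
    if (length(object@counts) != length(object@bins))
        msg <- c(msg, "length(counts) must equal number of bins")
    if (any(object@counts < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative")
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    if (length(msg)) msg else TRUE
})

#' CopyRatioProfile: GC-corrected, reference-normalized log2 copy ratios
#'
#' Per-bin log2 copy-number ratios on a [GenomeBins] grid, median-centered
#' so that the median over usable autosomal bins is 0. \code{log2ratio} is NA
#' on unusable bins.
#'
#' @slot bins a [GenomeBins] grid.
#' @slot log2ratio numeric per bin (NA on unusable bins).
#' @slot weight positive per-bin reliability weight (NA on unusable bins).
#' @slot sampleId single character identifier.
#' @slot binWidth grid width in bp.
#' @seealso [toLog2Ratio()], [cbsSegment()]
#' @export
setClass("CopyRatioProfile",
    slots = c(bins = "GenomeBins", log2ratio = "numeric", weight = "numeric",
              sampleId = "character", binWidth = "numeric"))

setValidity("CopyRatioProfile", function(object) {
    msg <- character()
    if (length(object@log2ratio) != length(object@bins))
        msg <- c(msg, "length(log2ratio) must equal number of bins")
    if (length(object@weight) != length(object@bins))
        msg <- c(msg, "length(weight) must equal number of bins")
    usable <- S4Vectors::mcols(object@bins)$usable
    if (any(!is.na(object@log2ratio[!usable])))
        msg <- c(msg, "log2ratio must be NA on unusable bins")
    if (any(object@weight <= 0, na.rm = TRUE))
        msg <- c(msg, "weights must be positive")
    if (length(msg)) msg else TRUE
})

#' SegmentedProfile: piecewise-constant log2 copy-ratio segments
#'
#' A \linkS4class{GRanges} subclass; each range is one segment with metadata
#' columns \code{nBins} (usable bins in the segment) and \code{meanLog2}
#' (mean of member-bin log2 ratios). Segments partition the usable bins of
#' each chromosome in order. This is the SEG-file-shaped object shared by
#' the caller, the tumor-content estimator and the concordance module.
#'
#' @slot sampleId sample identifier.
#' @slot alpha significance threshold used at segmentation (NA for imported
#'   or hand-built profiles).
#' @slot binWidth bin width (bp) of the underlying grid (NA when unknown).
#' @seealso [cbsSegment()], [segRead()], [segWrite()]
#' @export
setClass("SegmentedProfile", contains = "GRanges",
    representation(sampleId = "character", alpha = "numeric",
                   binWidth = "numeric"))

setValidity("SegmentedProfile", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object)
    if (!all(c("nBins", "meanLog2") %in% colnames(mc)))
        return("segments need metadata columns 'nBins' and 'meanLog2'")
    if (any(mc$nBins < 1))
        msg <- c(msg, "every segment must contain at least one bin")
    for (chr in GenomeInfoDb::seqlevelsInUse(object)) {
        gr <- object[GenomeInfoDb::seqnames(object) == chr]
        st <- sort(BiocGenerics::start(gr))
        en <- BiocGenerics::end(gr)[order(BiocGenerics::start(gr))]
        if (length(st) > 1L && any(st[-1L] <= en[-length(en)]))
            msg <- c(msg, sprintf("segments overlap on %s", chr))
    }
    if (length(msg)) msg else TRUE
})

#' TumorContentEstimate: tumor-fraction approximation for one sample
#'
#' @slot lss length-weighted RMS deviation of segment means from 0.
#' @slot tcLss tumor fraction mapped from LSS via a [CalibrationCurve]
#'   (NA when no curve was supplied).
#' @slot tcFit tumor fraction from the integer copy-number grid fit.
#' @slot fitResidual length-weighted least-squares residual at \code{tcFit}.
#' @slot assignments integer copy number per segment at \code{tcFit}
#'   (NA when \code{tcFit} is 0).
#' @slot classification "high" (lss >= 0.1) or "low".
#' @slot singleEventFlag TRUE when a single segment dominates the LSS
#'   (suspect, e.g. a lone clonal-hematopoiesis deletion).
#' @slot segments the [SegmentedProfile] the estimate was computed from.
#' @slot sex "male" or "female" (controls the chrX baseline copy number).
#' @seealso [estimateTumorContent()], [fitTumorFraction()], [computeLSS()]
#' @export
setClass("TumorContentEstimate",
    slots = c(lss = "numeric", tcLss = "numeric", tcFit = "numeric",
              fitResidual = "numeric", assignments = "integer",
              classification = "character", singleEventFlag = "logical",
              segments = "SegmentedProfile", sex = "character"))

setValidity("TumorContentEstimate", function(object) {
    msg <- character()
    if (object@lss < 0) msg <- c(msg, "lss must be >= 0")
    if (!object@classification %in% c("high", "low"))
        msg <- c(msg, "classification must be 'high' or 'low'")
    expect <- if (object@lss >= 0.1) "high" else "low"
    # a single-event-flagged sample may be reclassified low despite its LSS
    if (object@classification != expect &&
        !(object@singleEventFlag && object@classification == "low"))
        msg <- c(msg, "classification inconsistent with the 0.1 LSS threshold")
    if (length(msg)) msg else TRUE
})

#' CalibrationCurve: monotone LSS-to-tumor-content mapping
#'
#' Sorted (lss, tc) knots interpolated linearly; passes through (0, 0) and
#' through the decision anchor (0.1, 0.0875): an LSS of 0.1 corresponds to
#' an estimated tumor content of 8.75%.
#'
#' @slot knots data.frame with strictly increasing columns \code{lss},
#'   \code{tc}.
#' @slot provenance list describing the simulation that built the curve
#'   (truth label, fractions, coverage, seeds).
#' @seealso [calibrateLSS()], [lssToTc()]
#' @export
setClass("CalibrationCurve",
    slots = c(knots = "data.frame", provenance = "list"))

setValidity("CalibrationCurve", function(object) {
    k <- object@knots
    if (!all(c("lss", "tc") %in% names(k)))
        return("knots need columns 'lss' and 'tc'")
    if (nrow(k) < 2L) return("need at least two knots")
    if (any(diff(k$lss) <= 0) || any(diff(k$tc) <= 0))
        return("knots must be strictly increasing in both coordinates")
    if (abs(k$lss[1L]) > 1e-12 || abs(k$tc[1L]) > 1e-12)
        return("curve must pass through (0, 0)")
    TRUE
})

#' TruthProfile: ground-truth integer copy-number intervals
#'
#' A \linkS4class{GRanges} subclass; each range carries an integer tumor
#' copy number \code{n}. Regions not covered by any interval are implicitly
#' copy-neutral (n = 2 on autosomes; on chrX, 1 for a male sample).
#'
#' @slot sex "male" or "female".
#' @slot label free-text description (e.g. "mCRPC-like").
#' @seealso [mcrpcTruth()], [simulateCounts()]
#' @export
setClass("TruthProfile", contains = "GRanges",
    representation(sex = "character", label = "character"))

setValidity("TruthProfile", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object)
    if (!"n" %in% colnames(mc)) return("truth intervals need an 'n' column")
    if (any(mc$n < 0) || any(mc$n != round(mc$n)))
        msg <- c(msg, "'n' must be non-negative integers")
    if (!object@sex %in% c("male", "female"))
        msg <- c(msg, "sex must be 'male' or 'female'")
    if (any(S4Vectors::queryHits(GenomicRanges::findOverlaps(object,
            drop.self = TRUE, drop.redundant = TRUE)) > 0))
        msg <- c(msg, "truth intervals must not overlap")
    if (length(msg)) msg else TRUE
})

#' PairedGrid: two segmented profiles projected on a common bin grid
#'
#' A \linkS4class{GRanges} subclass with metadata columns \code{valueA},
#' \code{valueB} (segment mean of each profile at the bin midpoint) and
#' \code{masked} (TRUE when either profile does not cover the bin midpoint;
#' masked bins are excluded from all statistics).
#'
#' @seealso [projectToGrid()], [profileCorrelation()]
#' @export
setClass("PairedGrid", contains = "GRanges")

setValidity("PairedGrid", function(object) {
    mc <- S4Vectors::mcols(object)
    if (!all(c("valueA", "valueB", "masked") %in% colnames(mc)))
        return("needs metadata columns valueA, valueB, masked")
    TRUE
})
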