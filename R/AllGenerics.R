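#' Accessors for plasmaCNA objects
#'
#' Small accessor generics: \code{binCounts} returns the per-bin count
#' vector, \code{bins} the underlying [GenomeBins] grid, \code{sampleId}
#' the sample identifier, \code{totalReads} the retained read total,
#' \code{effectiveCoverage} totalReads x meanReadLength / genome length,
#' \code{log2Ratio} the per-bin log2 copy-ratio vector, \code{segMeans}
#' the per-segment means, and \code{genomeLength} the summed chromosome
#' lengths of a grid.
#'
#' @param x a plasmaCNA object.
#' @return the accessed component (see Description).
#' @examples
#' gb <- makeBins(c(chr1 = 2e6), 5e5)
#' genomeLength(gb)
#' @name accessors
#' @aliases binCounts bins sampleId totalReads effectiveCoverage log2Ratio
#'   segMeans genomeLength
NULL

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("effectiveCoverage", function(x) standardGeneric("effectiveCoverage"))
#' @rdname accessors
#' @export
setGeneric("log2Ratio", function(x) standardGeneric("log2Ratio"))
#' @rdname accessors
#' @export
setGeneric("segMeans", function(x) standardGeneric("segMeans"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname accessors
setMethod("binCounts", "BinCounts", function(x) x@counts)
#' @rdname accessors
setMethod("bins", "BinCounts", function(x) x@bins)
#' @rdname accessors
setMethod("bins", "CopyRatioProfile", function(x) x@bins)
#' @rdname accessors
setMethod("sampleId", "BinCounts", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "CopyRatioProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "SegmentedProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("totalReads", "BinCounts", function(x) x@totalReads)
#' @rdname accessors
setMethod("genomeLength", "GenomeBins",
    function(x) sum(as.numeric(GenomeInfoDb::seqlengths(x)), na.rm = TRUE))
#' @rdname accessors
setMethod("effectiveCoverage", "BinCounts", function(x)
    x@totalReads * x@meanReadLength / genomeLength(x@bins))
#' @rdname accessors
setMethod("log2Ratio", "CopyRatioProfile", function(x) x@log2ratio)
#' @rdname accessors
setMethod("segMeans", "SegmentedProfile",
    function(x) S4Vectors::mcols(x)$meanLog2)

setMethod("show", "BinCounts", function(object) {
    cat("BinCounts for sample", object@sampleId, "\n",
        " ", length(object@bins), "bins,", format(object@totalReads, big.mark = ","),
        "retained reads, effective coverage",
        sprintf("%.4gx", effectiveCoverage(object)), "\n")
})

setMethod("show", "CopyRatioProfile", function(object) {
    u <- S4Vectors::mcols(object@bins)$usable
    cat("CopyRatioProfile for sample", object@sampleId, "\n",
        " ", sum(u), "usable /", length(object@bins), "bins, bin width",
        format(object@binWidth, big.mark = ","), "bp\n")
})

setMethod("show", "SegmentedProfile", function(object) {
    cat("SegmentedProfile for sample", object@sampleId, ":",
        length(object), "segments on",
        length(GenomeInfoDb::seqlevelsInUse(object)), "chromosomes\n")
    callNextMethod()
})

setMethod("show", "TumorContentEstimate", function(object) {
    cat("TumorContentEstimate\n",
        sprintf("  LSS        : %.4f (%s tumor content)\n", object@lss,
                object@classification),
        sprintf("  tcFit      : %.3f (residual %.3g)\n", object@tcFit,
                object@fitResidual),
        if (!is.na(object@tcLss))
            sprintf("  tcLss      : %.3f\n", object@tcLss) else "",
        if (object@singleEventFlag)
            "  flag       : single-event-dominated LSS (suspect)\n" else "",
        sep = "")
})

setMethod("show", "CalibrationCurve", function(object) {
    cat("CalibrationCurve with", nrow(object@knots), "knots; anchor tc(lss=0.1) =",
        signif(lssToTc(0.1, object), 4), "\n")
})

setMethod("show", "TruthProfile", function(object) {
    cat("TruthProfile '", object@label, "' (", object@sex, "): ",
        length(object), " altered intervals\n", sep = "")
})
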