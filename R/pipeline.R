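#' Run the full screening pipeline on one sample
#'
#' Chains GC correction (when the grid is GC-annotated), panel
#' normalization, circular binary segmentation, tumor-content estimation,
#' focal/arm/deep-deletion calling and FGA scoring.
#'
#' @param counts a [BinCounts].
#' @param panel optional list of [BinCounts] normals on the same grid.
#' @param genes gene intervals for call annotation (NULL to skip).
#' @param arms arm intervals (NULL to skip arm calls).
#' @param span21q the ERG--TMPRSS2 interval for the 21q22.2 deletion proxy
#'   (NULL to skip).
#' @param curve optional [CalibrationCurve].
#' @param sex "male" or "female".
#' @param alpha,nPerm,seed segmentation parameters.
#' @param gcCorrect apply [correctGC()] first (default: TRUE when any bin
#'   has a GC annotation).
#' @param ... further arguments to [cbsSegment()].
#' @return list with elements \code{profile}, \code{segments}, \code{tc},
#'   \code{focal}, \code{arms}, \code{fga}, \code{deletion21q}.
#' @export
runPipeline <- function(counts, panel = NULL, genes = NULL, arms = NULL,
                        span21q = NULL, curve = NULL, sex = "male", alpha = 0.01,
                        nPerm = 1000, seed = 1,
                        gcCorrect = !all(is.na(
                            S4Vectors::mcols(bins(counts))$gc)), ...) {
    if (gcCorrect) counts <- correctGC(counts)
    profile <- toLog2Ratio(counts, panel = panel)
    seg <- cbsSegment(profile, alpha = alpha, nPerm = nPerm, seed = seed, ...)
    tc <- estimateTumorContent(seg, curve = curve, sex = sex)
    focal <- callFocal(seg)
    if (!is.null(genes) && length(focal))
        focal <- annotateGenes(focal, genes)
    if (length(focal) && tc@tcFit > 0) {
        isLoss <- S4Vectors::mcols(focal)$direction == "loss"
        deep <- rep(NA, length(focal))
        if (any(isLoss)) {
            ncopy <- ifelse(as.character(GenomeInfoDb::seqnames(
                focal[isLoss])) %in% c("chrX", "X") & sex == "male", 1, 2)
            deep[isLoss] <- mapply(function(m, nc)
                classifyDeepDeletion(m, tc@tcFit, normalCopy = nc),
                S4Vectors::mcols(focal)$meanLog2[isLoss], ncopy)
        }
        S4Vectors::mcols(focal)$deepDeletion <- deep
    }
    armStatus <- if (!is.null(arms)) armLevelEvents(seg, arms = arms)
                 else NULL
    list(profile = profile, segments = seg, tc = tc, focal = focal,
         arms = armStatus, fga = computeFGA(seg),
         deletion21q = if (!is.null(span21q))
             detect21qDeletion(seg, interval = span21q) else NA)
}
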