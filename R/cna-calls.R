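# Event calling on segmented profiles: focal CNAs (1.5-20 Mb, |log2| >= 0.2),
# gene annotation, deep (2-copy) deletion classification at the fitted tumor
# fraction, arm-level gain/loss, the 21q22.2 interstitial-deletion proxy for
# TMPRSS2:ERG, and the fraction of genome altered (FGA).

#' Call focal copy-number alterations
#'
#' Focal CNAs are segments between \code{minLen} and \code{maxLen} long
#' (bounds inclusive) whose mean log2 ratio is at least \code{minAbsLog2}
#' in magnitude: gains at mean >= +0.2, losses at mean <= -0.2 (the
#' symmetric loss rule makes focal deep deletions expressible).
#'
#' @param seg a [SegmentedProfile].
#' @param minLen,maxLen focal length window in bp (defaults 1.5 and 20 Mb).
#' @param minAbsLog2 magnitude threshold (default 0.2).
#' @return a \code{GRanges} of focal calls with columns \code{direction}
#'   ("gain"/"loss"), \code{meanLog2}, \code{nBins}, \code{genes} (empty
#'   until [annotateGenes()]), \code{deepDeletion} (NA until
#'   [classifyDeepDeletion()]).
#' @export
callFocal <- function(seg, minLen = 1.5e6, maxLen = 2e7, minAbsLog2 = 0.2) {
    stopifnot(methods::is(seg, "SegmentedProfile"))
    len <- as.numeric(BiocGenerics::width(seg))
    mu <- segMeans(seg)
    keep <- len >= minLen & len <= maxLen & abs(mu) >= minAbsLog2
    calls <- methods::as(seg[keep], "GRanges")
    S4Vectors::mcols(calls)$direction <-
        ifelse(segMeans(seg)[keep] > 0, "gain", "loss")
    S4Vectors::mcols(calls)$genes <- IRanges::CharacterList(
        rep(list(character()), sum(keep)))
    S4Vectors::mcols(calls)$deepDeletion <- rep(NA, length(calls))
    calls
}

#' Annotate focal calls with overlapping genes
#'
#' Attaches every gene whose interval overlaps a call by at least 1 bp.
#'
#' @param calls focal calls from [callFocal()].
#' @param genes a \code{GRanges} of gene intervals with a \code{name}
#'   column or names (e.g. [geneAnnotation()]).
#' @return the calls with their \code{genes} column filled.
#' @export
annotateGenes <- function(calls, genes) {
    geneNames <- if (!is.null(names(genes))) names(genes)
                 else S4Vectors::mcols(genes)$name
    if (is.null(geneNames)) stop("gene intervals need names")
    unknown <- setdiff(as.character(unique(GenomeInfoDb::seqnames(calls))),
                       GenomeInfoDb::seqlevels(genes))
    if (length(unknown) && length(calls))
        warning("call chromosome(s) absent from gene annotation: ",
                paste(unknown, collapse = ", "))
    hits <- GenomicRanges::findOverlaps(calls, genes, ignore.strand = TRUE)
    lst <- split(geneNames[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits), levels = seq_along(calls)))
    S4Vectors::mcols(calls)$genes <- IRanges::CharacterList(lst)
    calls
}

#' Classify a focal loss as a deep (2-copy) deletion
#'
#' A loss is deep when, at the fitted tumor fraction, the nearest integer
#' copy-number state to its mean log2 ratio is n = 0 (homozygous loss in
#' the tumor compartment).
#'
#' @param meanLog2 segment mean log2 ratio(s).
#' @param tcFit fitted tumor fraction (> 0; at 0 the state is
#'   unclassifiable and FALSE is returned with a warning).
#' @param nMax largest copy number considered (default 40).
#' @param normalCopy normal copy number of the region (default 2).
#' @return logical, TRUE for deep deletions.
#' @examples
#' classifyDeepDeletion(-1.0, 0.5)    # TRUE: expectedLog2(0, 0.5) = -1
#' classifyDeepDeletion(-0.15, 0.5)   # FALSE
#' @export
classifyDeepDeletion <- function(meanLog2, tcFit, nMax = 40, normalCopy = 2) {
    if (length(tcFit) != 1L || is.na(tcFit))
        stop("tcFit must be a single tumor fraction")
    if (tcFit <= 0) {
        warning("tumor fraction 0: deep-deletion state unclassifiable")
        return(rep(FALSE, length(meanLog2)))
    }
    levels <- expectedLog2(0:nMax, tcFit, normalCopy = normalCopy)
    vapply(meanLog2, function(m) which.min(abs(m - levels)) == 1L, NA)
}

#' Arm-level gain/loss calls
#'
#' An arm is called gained (lost) when at least \code{minFrac} of its length
#' lies in segments with mean log2 ratio >= +\code{minAbsLog2}
#' (<= -\code{minAbsLog2}).
#'
#' @param seg a [SegmentedProfile].
#' @param arms arm intervals (default [armAnnotation()]), named like "8p".
#' @param minFrac arm-length fraction required (default 0.5; values below
#'   0.5 are rejected because they would let one arm qualify as both gained
#'   and lost).
#' @param minAbsLog2 magnitude threshold (default 0.1).
#' @return named character vector over arms: "gain", "loss" or "neutral"
#'   (the exact-tie case where both directions reach \code{minFrac} is
#'   reported neutral).
#' @export
armLevelEvents <- function(seg, arms = armAnnotation(), minFrac = 0.5,
                           minAbsLog2 = 0.1) {
    stopifnot(methods::is(seg, "SegmentedProfile"))
    if (minFrac < 0.5)
        stop("minFrac < 0.5 would allow an arm to be both gained and lost")
    mu <- segMeans(seg)
    armLen <- as.numeric(BiocGenerics::width(arms))
    dirFrac <- function(sel) {
        frac <- numeric(length(arms))
        if (!any(sel)) return(frac)
        ov <- GenomicRanges::findOverlaps(arms, seg[sel], ignore.strand = TRUE)
        if (!length(ov)) return(frac)
        inter <- IRanges::pintersect(
            arms[S4Vectors::queryHits(ov)],
            methods::as(seg[sel], "GRanges")[S4Vectors::subjectHits(ov)])
        covered <- tapply(as.numeric(BiocGenerics::width(inter)),
                          S4Vectors::queryHits(ov), sum)
        idx <- as.integer(names(covered))
        frac[idx] <- covered / armLen[idx]
        frac
    }
    gainFrac <- dirFrac(mu >= minAbsLog2)
    lossFrac <- dirFrac(mu <= -minAbsLog2)
    status <- rep("neutral", length(arms))
    status[gainFrac >= minFrac & lossFrac < minFrac] <- "gain"
    status[lossFrac >= minFrac & gainFrac < minFrac] <- "loss"
    stats::setNames(status,
        if (!is.null(names(arms))) names(arms) else S4Vectors::mcols(arms)$name)
}

#' Detect the 21q22.2 interstitial deletion (TMPRSS2:ERG proxy)
#'
#' TRUE when a loss segment (mean <= -\code{minAbsLog2}) reciprocally
#' overlaps the ERG--TMPRSS2 span by at least \code{minReciprocal} of both
#' lengths. This is a copy-number proxy for the deletion-type TMPRSS2:ERG
#' rearrangement, not fusion detection.
#'
#' @param seg a [SegmentedProfile].
#' @param interval the 21q22.2 span (default [ergTmprss2Span()]).
#' @param minAbsLog2 loss threshold (default 0.1).
#' @param minReciprocal reciprocal-overlap requirement (default 0.5).
#' @return logical scalar.
#' @export
detect21qDeletion <- function(seg, interval = ergTmprss2Span(),
                              minAbsLog2 = 0.1, minReciprocal = 0.5) {
    stopifnot(methods::is(seg, "SegmentedProfile"))
    loss <- seg[segMeans(seg) <= -minAbsLog2]
    if (!length(loss)) return(FALSE)
    ov <- GenomicRanges::findOverlaps(methods::as(loss, "GRanges"), interval,
                                      ignore.strand = TRUE)
    if (!length(ov)) return(FALSE)
    inter <- IRanges::pintersect(
        methods::as(loss, "GRanges")[S4Vectors::queryHits(ov)],
        interval[S4Vectors::subjectHits(ov)])
    w <- as.numeric(BiocGenerics::width(inter))
    wl <- as.numeric(BiocGenerics::width(loss))[S4Vectors::queryHits(ov)]
    wi <- as.numeric(BiocGenerics::width(interval))[S4Vectors::subjectHits(ov)]
    any(w / wl >= minReciprocal & w / wi >= minReciprocal)
}

#' Fraction of the genome altered (FGA)
#'
#' The fraction of total segment length lying in segments whose |mean log2
#' ratio| meets \code{log2Cutoff}. Samples with FGA above 0.15 are flagged
#' as having elevated copy-number burden.
#'
#' @param seg a [SegmentedProfile].
#' @param log2Cutoff altered/neutral threshold (default 0.2, matching the
#'   focal-call threshold).
#' @param elevatedCutoff FGA above which the sample is flagged (default
#'   0.15, strict inequality).
#' @return list with \code{fga}, \code{log2Cutoff}, \code{elevated}.
#' @export
computeFGA <- function(seg, log2Cutoff = 0.2, elevatedCutoff = 0.15) {
    stopifnot(methods::is(seg, "SegmentedProfile"))
    len <- as.numeric(BiocGenerics::width(seg))
    tot <- sum(len)
    if (tot <= 0) stop("total segment length is zero")
    fga <- sum(len[abs(segMeans(seg)) >= log2Cutoff]) / tot
    list(fga = fga, log2Cutoff = log2Cutoff, elevated = fga > elevatedCutoff)
}
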