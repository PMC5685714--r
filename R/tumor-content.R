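# Tumor-fraction approximation from segmented log2 copy-ratio profiles:
# the LSS statistic (length-weighted RMS deviation of segment means from
# copy-neutral), a grid fit of the two-component mixture model over integer
# tumor copy numbers, LSS-to-tumor-content calibration by simulation, and a
# single-event artifact flag.

#' Expected log2 copy ratio of the tumor/normal mixture
#'
#' For a region at integer tumor copy number \code{n} in a sample with tumor
#' fraction \code{f}, the observed depth ratio is
#' (f n + c (1 - f)) / c where c is the normal copy number (2 on autosomes;
#' 1 on chrX in males). Values are clamped at -8 log2 units (the n = 0,
#' f = 1 case is -Inf in exact arithmetic).
#'
#' @param n integer tumor copy number(s), >= 0.
#' @param f tumor fraction in [0, 1].
#' @param normalCopy normal copy number of the region (default 2).
#' @return expected log2 copy ratio (vectorized over \code{n}).
#' @examples
#' expectedLog2(2, 0.3)      # 0: copy-neutral at any fraction
#' expectedLog2(4, 1)        # 1: pure tumor, doubled
#' expectedLog2(0, 0.5)      # -1
#' expectedLog2(3, 0.2)      # log2(1.1)
#' @export
expectedLog2 <- function(n, f, normalCopy = 2) {
    if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
        stop("tumor fraction f must be a single value in [0, 1]")
    if (any(n < 0)) stop("copy number n must be >= 0")
    pmax(log2((f * n + normalCopy * (1 - f)) / normalCopy), -8)
}

.segWeights <- function(seg) {
    w <- as.numeric(BiocGenerics::width(seg))
    w / sum(w)
}

#' Least-squares distance statistic (LSS)
#'
#' The length-weighted root-mean-square deviation of segment means from the
#' copy-neutral level 0: sqrt(sum(w_s * mean_s^2)) with w_s the segment
#' length fraction. LSS is 0 exactly when every segment mean is 0, scales
#' linearly with the segment means, and is the monotone tumor-content proxy
#' behind the 0.1 decision threshold (LSS >= 0.1 classifies a sample as
#' high tumor content, corresponding to an estimated tumor content above
#' 8.75%).
#'
#' @param seg a [SegmentedProfile] with at least one segment.
#' @return non-negative LSS value.
#' @export
computeLSS <- function(seg) {
    stopifnot(methods::is(seg, "SegmentedProfile"))
    if (length(seg) < 1L) stop("cannot compute LSS of an empty profile")
    if (sum(as.numeric(BiocGenerics::width(seg))) <= 0)
        stop("total segment length must be positive")
    sqrt(sum(.segWeights(seg) * segMeans(seg)^2))
}

.normalCopies <- function(seg, sex) {
    chr <- as.character(GenomeInfoDb::seqnames(seg))
    ifelse(chr %in% c("chrX", "X") & sex == "male", 1, 2)
}

#' Integer copy-number grid fit of the tumor fraction
#'
#' Scans a tumor-fraction grid; at each f every altered segment is assigned
#' the integer copy number n in [0, nMax] whose [expectedLog2()] level is
#' closest to the segment mean, giving the length-weighted residual
#' R(f) = sum(w_s min_n (mean_s - level(n, f))^2) over altered segments.
#' The fit clusters on the altered segments only: segments with
#' |mean| < \code{neutralGate} are held at the copy-neutral state and do
#' not enter the residual -- otherwise near-neutral noise snaps to the fine
#' level spacing available at small f and drags the fit toward the f/2
#' solution. The reported fraction is the smallest f whose residual is
#' within \code{slack} of the minimum: the mixture model is scale-ambiguous
#' ((f, n) fits are reproduced by (f/2, 2n - 2) whenever all 2n - 2 >= 0),
#' and preferring the smallest near-optimal fraction is the conventional
#' identifiability fix. A fit with no altered segment, or assigning
#' copy-neutral states to >= 99% of the genome length, is reported as tumor
#' fraction 0.
#'
#' @param seg a [SegmentedProfile].
#' @param fGrid tumor-fraction grid (default 0 to 0.95 in steps of 0.005).
#' @param nMax largest tumor copy number considered (default 40, enough for
#'   high-level focal amplifications).
#' @param slack relative residual slack for the smallest-f rule (default
#'   0.05).
#' @param neutralGate |log2| below which a segment is treated as
#'   copy-neutral (default 0.1, the arm-level threshold).
#' @param sex "female" (default) or "male"; male samples use a 1-copy
#'   baseline on chrX.
#' @return list with \code{tcFit}, \code{fitResidual}, \code{assignments}
#'   (integer copy number per segment; NA when tcFit = 0).
#' @export
fitTumorFraction <- function(seg, fGrid = seq(0, 0.95, by = 0.005),
                             nMax = 40, slack = 0.05, neutralGate = 0.1,
                             sex = "female") {
    stopifnot(methods::is(seg, "SegmentedProfile"))
    if (length(seg) < 3L)
        warning("fewer than 3 segments; tumor-fraction fit is poorly determined")
    mu <- segMeans(seg)
    w <- .segWeights(seg)
    ncopy <- .normalCopies(seg, sex)
    altered <- abs(mu) >= neutralGate
    if (!any(altered))
        return(list(tcFit = 0, fitResidual = 0,
                    assignments = rep(NA_integer_, length(seg))))
    nGrid <- 0:nMax
    resid <- numeric(length(fGrid))
    assign <- matrix(NA_integer_, length(fGrid), length(seg))
    for (gi in seq_along(fGrid)) {
        f <- fGrid[gi]
        r <- 0
        assign[gi, !altered] <- ncopy[!altered]
        for (cc in unique(ncopy)) {
            idx <- which(ncopy == cc & altered)
            if (!length(idx)) next
            levels <- expectedLog2(nGrid, f, normalCopy = cc)
            d2 <- outer(mu[idx], levels, function(a, b) (a - b)^2)
            bi <- max.col(-d2, ties.method = "first")
            assign[gi, idx] <- nGrid[bi]
            r <- r + sum(w[idx] * d2[cbind(seq_along(idx), bi)])
        }
        resid[gi] <- r
    }
    minR <- min(resid)
    cand <- which(resid <= (1 + slack) * minR)
    gi <- cand[1L]
    tcFit <- fGrid[gi]
    a <- assign[gi, ]
    neutralFrac <- sum(w[a == ncopy])
    if (tcFit == 0 || neutralFrac >= 0.99) {
        tcFit <- 0
        a <- rep(NA_integer_, length(seg))
    }
    list(tcFit = tcFit, fitResidual = resid[gi], assignments = as.integer(a))
}

#' Map an LSS value to tumor content via a calibration curve
#'
#' Monotone linear interpolation through the curve's knots; values above
#' the last knot are clamped to the last knot's tumor content with a
#' warning.
#'
#' @param lss non-negative LSS value(s).
#' @param curve a [CalibrationCurve].
#' @return tumor-content fraction(s).
#' @examples
#' curve <- defaultCalibration()
#' lssToTc(0.1, curve)   # 0.0875, the decision anchor
#' @export
lssToTc <- function(lss, curve) {
    stopifnot(methods::is(curve, "CalibrationCurve"))
    if (any(lss < 0)) stop("LSS must be non-negative")
    k <- curve@knots
    if (any(lss > max(k$lss)))
        warning("LSS beyond the calibrated range; clamped to the last knot")
    stats::approx(k$lss, k$tc, xout = pmin(lss, max(k$lss)), rule = 2)$y
}

#' Flag LSS elevation driven by a single event
#'
#' A lone large deletion (e.g. from clonal hematopoiesis) can push LSS over
#' the decision threshold without genuine genome-wide tumor signal. The
#' flag fires when one segment contributes more than \code{maxContrib} of
#' the squared LSS mass while less than \code{maxAlteredFrac} of the genome
#' is non-neutral.
#'
#' @param seg a [SegmentedProfile].
#' @param maxContrib single-segment share of sum(w * mean^2) above which
#'   the profile is suspect (default 0.8).
#' @param maxAlteredFrac genome fraction with |mean| >= \code{neutralCut}
#'   below which the profile is suspect (default 0.02).
#' @param neutralCut |log2| bound for "non-neutral" (default 0.1).
#' @return TRUE when the LSS is single-event-dominated.
#' @export
flagSingleEvent <- function(seg, maxContrib = 0.8, maxAlteredFrac = 0.02,
                            neutralCut = 0.1) {
    stopifnot(methods::is(seg, "SegmentedProfile"))
    w <- .segWeights(seg)
    mu <- segMeans(seg)
    contrib <- w * mu^2
    tot <- sum(contrib)
    if (tot == 0) return(FALSE)
    alteredFrac <- sum(w[abs(mu) >= neutralCut])
    max(contrib) / tot > maxContrib && alteredFrac < maxAlteredFrac
}

#' Build an LSS-to-tumor-content calibration curve by simulation
#'
#' Simulates the supplied truth profile across a tumor-fraction ladder,
#' runs the full pipeline (counts, normalization against a simulated
#' sex-matched panel, segmentation), records the median LSS per fraction,
#' enforces monotonicity by isotonic regression when needed, and rescales
#' the tumor-content coordinate so the curve passes through the decision
#' anchor (LSS 0.1, tumor content 0.0875). The curve always starts at
#' (0, 0).
#'
#' @param truth a [TruthProfile] (default [mcrpcTruth()]).
#' @param fractions tumor-fraction ladder including 0 (default the dilution
#'   ladder 0, 0.01, 0.05, 0.10, 0.25, 0.50).
#' @param coverage effective coverage of each simulated sample (default
#'   0.1).
#' @param seeds integer seeds, one simulation per seed per fraction.
#' @param binWidth simulation bin width in bp.
#' @param nPerm,alpha segmentation parameters.
#' @return a [CalibrationCurve].
#' @export
calibrateLSS <- function(truth = mcrpcTruth(),
                         fractions = c(0, 0.01, 0.05, 0.10, 0.25, 0.50),
                         coverage = 0.1, seeds = 1:5, binWidth = 2.5e5,
                         nPerm = 500, alpha = 0.01) {
    stopifnot(methods::is(truth, "TruthProfile"))
    fractions <- sort(fractions)
    if (fractions[1L] != 0) stop("fractions must include 0")
    sizes <- GenomeInfoDb::seqlengths(truth)
    if (any(is.na(sizes))) stop("truth profile needs seqlengths")
    gb <- makeBins(sizes, binWidth)
    panel <- simulateNormalPanel(gb, sex = truth@sex, coverage = coverage,
                                 seed = 987654)
    med <- vapply(fractions, function(f) {
        lssVals <- vapply(seeds, function(s) {
            bc <- simulateCounts(truth, fraction = f, coverage = coverage,
                                 x = gb, seed = s)
            prof <- toLog2Ratio(bc, panel = panel)
            seg <- cbsSegment(prof, alpha = alpha, nPerm = nPerm, seed = s)
            computeLSS(seg)
        }, 0)
        stats::median(lssVals)
    }, 0)
    knLss <- c(0, med[-1L])
    knTc <- c(0, fractions[-1L])
    if (any(diff(knLss) <= 0)) {
        warning("non-monotone median LSS across fractions; isotonic regression applied")
        iso <- stats::isoreg(seq_along(knLss), knLss)
        knLss <- iso$yf
        eps <- 1e-6
        for (i in seq_along(knLss)[-1L])
            if (knLss[i] <= knLss[i - 1L]) knLss[i] <- knLss[i - 1L] + eps
    }
    # anchor: rescale tumor content so that tc(lss = 0.1) = 0.0875
    t0 <- stats::approx(knLss, knTc, xout = 0.1, rule = 2)$y
    if (t0 <= 0) stop("calibration failed: no LSS signal at the anchor")
    knTc <- knTc * (0.0875 / t0)
    kn <- data.frame(lss = knLss, tc = knTc)
    if (!any(abs(kn$lss - 0.1) < 1e-12) && 0.1 < max(kn$lss)) {
        kn <- rbind(kn, data.frame(lss = 0.1, tc = 0.0875))
        kn <- kn[order(kn$lss), ]
    }
    methods::new("CalibrationCurve", knots = kn,
        provenance = list(truth = truth@label, fractions = fractions,
                          coverage = coverage, seeds = seeds,
                          binWidth = binWidth, anchor = c(lss = 0.1, tc = 0.0875)))
}

#' A fixed fallback calibration curve
#'
#' Piecewise-linear knots through (0, 0) and the decision anchor
#' (0.1, 0.0875), extended proportionally; use [calibrateLSS()] for a
#' simulation-matched curve.
#'
#' @return a [CalibrationCurve].
#' @export
defaultCalibration <- function() {
    kn <- data.frame(lss = c(0, 0.1, 0.4, 0.8),
                     tc = c(0, 0.0875, 0.35, 0.70))
    methods::new("CalibrationCurve", knots = kn,
                 provenance = list(truth = "fixed-anchor fallback"))
}

#' Estimate tumor content from a segmented profile
#'
#' Combines [computeLSS()], the high/low classification at the 0.1
#' threshold, [fitTumorFraction()], optional LSS-to-tumor-content mapping
#' and the [flagSingleEvent()] artifact check into one
#' [TumorContentEstimate].
#'
#' @param seg a [SegmentedProfile].
#' @param curve optional [CalibrationCurve] for \code{tcLss}.
#' @param sex "female" (default) or "male".
#' @param reclassifySingleEvent when TRUE (default), a single-event-flagged
#'   sample is reported as low tumor content regardless of its LSS.
#' @param ... passed to [fitTumorFraction()].
#' @return a [TumorContentEstimate].
#' @export
estimateTumorContent <- function(seg, curve = NULL, sex = "female",
                                 reclassifySingleEvent = FALSE, ...) {
    lss <- computeLSS(seg)
    fit <- fitTumorFraction(seg, sex = sex, ...)
    flag <- flagSingleEvent(seg)
    cls <- if (lss >= 0.1) "high" else "low"
    if (flag && reclassifySingleEvent) cls <- "low"
    methods::new("TumorContentEstimate",
        lss = lss, tcLss = if (!is.null(curve)) lssToTc(lss, curve)
                              else NA_real_,
        tcFit = fit$tcFit, fitResidual = fit$fitResidual,
        assignments = fit$assignments, classification = cls,
        singleEventFlag = flag, segments = seg, sex = sex)
}
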