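# Circular binary segmentation with permutation-based change-point testing.
#
# Each chromosome is treated as a circle; the candidate split is the pair
# (i, j) maximizing the two-sample t-like statistic between the arc
# (i, j] and its complement, and is accepted when its permutation p-value
# (value shuffles within the tested span) is <= alpha. Accepted splits are
# recursed. The permutation stream is part of the algorithm definition:
# each tested span draws a deterministic seed from (seed, chromosome index,
# span offset, span length), so identical inputs and seeds always yield
# identical segmentations.

.spanSeed <- function(seed, chromIdx, offset, n) {
    ((seed %% 2147483647) * 48271 + chromIdx * 7919 +
     offset * 104729 + n * 131) %% 2147483646 + 1
}

# Fisher-Yates shuffles via R's sample.int under a derived seed; both the
# segmenter and the exhaustive test oracle consume this same stream.
.permMatrix <- function(n, nPerm, seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    matrix(vapply(seq_len(nPerm), function(i) sample.int(n), integer(n)),
           nrow = n)
}

# t^2-like statistic for all valid (i, j) pairs; returns max and argmax
# (lexicographically first on ties). x must have length >= 2*m.
.scanSpan <- function(x, m) {
    n <- length(x)
    S <- c(0, cumsum(x))
    Qtot <- sum(x * x)
    best <- list(stat = -Inf, i = NA_integer_, j = NA_integer_)
    # canonical split set: arcs (i, j] with j <= n - m; a split at (i, n)
    # is the circular complement of (0, i) and is excluded so that every
    # partition has exactly one representative
    for (i in 0:(n - 2L * m)) {
        if (i != 0L && i < m) next
        js <- seq.int(i + m, n - m)
        k <- js - i
        sum1 <- S[js + 1L] - S[i + 1L]
        m1 <- sum1 / k
        m2 <- (S[n + 1L] - sum1) / (n - k)
        pv <- (Qtot - k * m1^2 - (n - k) * m2^2) / (n - 2L)
        pv <- pmax(pv, 0)
        den <- pv * (1 / k + 1 / (n - k))
        num <- (m1 - m2)^2
        stat <- ifelse(num == 0, 0, num / den)  # 0/0 -> 0; x/0 -> Inf
        # ties break to the lexicographically first (i, j): ascending i in
        # the outer loop with strict '>', first maximum within each i
        b <- which.max(stat)
        if (length(b) && stat[b] > best$stat)
            best <- list(stat = stat[b], i = i, j = js[b])
    }
    best
}

# max statistic only, for a matrix of permuted spans (n x P)
.scanMaxMatrix <- function(xm, m) {
    n <- nrow(xm)
    S <- rbind(0, apply(xm, 2L, cumsum))
    Qtot <- colSums(xm * xm)
    tot <- S[n + 1L, ]
    mx <- rep(-Inf, ncol(xm))
    for (i in 0:(n - 2L * m)) {
        if (i != 0L && i < m) next
        js <- seq.int(i + m, n - m)
        k <- js - i
        sum1 <- S[js + 1L, , drop = FALSE] -
            matrix(S[i + 1L, ], length(js), ncol(xm), byrow = TRUE)
        m1 <- sum1 / k
        m2 <- (matrix(tot, length(js), ncol(xm), byrow = TRUE) - sum1) / (n - k)
        pv <- (matrix(Qtot, length(js), ncol(xm), byrow = TRUE) -
               k * m1^2 - (n - k) * m2^2) / (n - 2L)
        pv[pv < 0] <- 0
        den <- pv * (1 / k + 1 / (n - k))
        num <- (m1 - m2)^2
        stat <- num / den
        stat[num == 0] <- 0
        cm <- apply(stat, 2L, max)
        mx <- pmax(mx, cm)
    }
    mx
}

# permutation test with early termination: returns TRUE when the split is
# accepted, i.e. (1 + #exceedances) / (nPerm + 1) <= alpha. Early stop once
# the exceedance budget is exhausted (decision is already 'reject split').
.permAccept <- function(x, obsStat, alpha, nPerm, seed, m, chunk = 100L) {
    if (!is.finite(obsStat) && obsStat < 0) return(FALSE)
    budget <- floor(alpha * (nPerm + 1) - 1)
    if (budget < 0) return(FALSE)
    perms <- .permMatrix(length(x), nPerm, seed)
    count <- 0L
    p <- 1L
    while (p <= nPerm) {
        q <- min(p + chunk - 1L, nPerm)
        xm <- matrix(x[perms[, p:q, drop = FALSE]], nrow = length(x))
        mx <- .scanMaxMatrix(xm, m)
        count <- count + sum(mx >= obsStat)
        if (count > budget) return(FALSE)
        p <- q + 1L
    }
    TRUE
}

.segmentSpan <- function(x, offset, chromIdx, alpha, nPerm, seed, m) {
    n <- length(x)
    if (n < 2L * m || diff(range(x)) < 1e-12) return(integer())
    best <- .scanSpan(x, m)
    if (!is.finite(best$stat) && best$stat < 0) return(integer())
    if (is.na(best$i)) return(integer())
    spanSeed <- .spanSeed(seed, chromIdx, offset, n)
    if (!.permAccept(x, best$stat, alpha, nPerm, spanSeed, m)) return(integer())
    i <- best$i; j <- best$j
    cuts <- integer()
    pieces <- list()
    if (i > 0L) pieces[[length(pieces) + 1L]] <- c(1L, i)
    pieces[[length(pieces) + 1L]] <- c(i + 1L, j)
    if (j < n) pieces[[length(pieces) + 1L]] <- c(j + 1L, n)
    if (i > 0L) cuts <- c(cuts, offset + i)
    if (j < n) cuts <- c(cuts, offset + j)
    for (pc in pieces) {
        sub <- x[pc[1L]:pc[2L]]
        cuts <- c(cuts, .segmentSpan(sub, offset + pc[1L] - 1L, chromIdx,
                                     alpha, nPerm, seed, m))
    }
    sort(unique(cuts))
}

# post-hoc merge: repeatedly merge the adjacent pair with the smallest mean
# difference below tol (ties: leftmost); means recombine bin-weighted so the
# mean-consistency invariant is preserved.
.mergeSegments <- function(meanVec, nBinsVec, tol) {
    repeat {
        if (length(meanVec) < 2L) break
        d <- abs(diff(meanVec))
        if (min(d) >= tol) break
        k <- which.min(d)
        w1 <- nBinsVec[k]; w2 <- nBinsVec[k + 1L]
        meanVec[k] <- (w1 * meanVec[k] + w2 * meanVec[k + 1L]) / (w1 + w2)
        nBinsVec[k] <- w1 + w2
        meanVec <- meanVec[-(k + 1L)]
        nBinsVec <- nBinsVec[-(k + 1L)]
    }
    list(means = meanVec, nBins = nBinsVec)
}

#' Circular binary segmentation of a log2 copy-ratio profile
#'
#' Recursively splits each chromosome at the circular arc maximizing the
#' pooled-SD-normalized mean-difference statistic, accepting splits whose
#' within-span permutation p-value is at most \code{alpha}; accepted
#' sub-spans are segmented recursively and adjacent segments closer than
#' \code{mergeTol} in mean are re-merged. Identical inputs and seeds give
#' identical output.
#'
#' @param profile a [CopyRatioProfile].
#' @param alpha permutation p-value threshold (default 0.01).
#' @param nPerm number of within-span value shuffles (default 1000).
#' @param seed integer seed driving the permutation stream.
#' @param minSegBins minimum usable bins per segment (default 2).
#' @param mergeTol post-hoc merge tolerance in log2 units (default 0.05).
#' @return a [SegmentedProfile].
#' @examples
#' gb <- makeBins(c(chr1 = 2e7), 5e5)
#' prof <- methods::new("CopyRatioProfile", bins = gb,
#'     log2ratio = rep(c(0, 1), each = 20), weight = rep(1, 40),
#'     sampleId = "toy", binWidth = 5e5)
#' cbsSegment(prof, seed = 1)
#' @export
cbsSegment <- function(profile, alpha = 0.01, nPerm = 1000, seed = 1,
                       minSegBins = 2, mergeTol = 0.05) {
    stopifnot(methods::is(profile, "CopyRatioProfile"))
    b <- profile@bins
    usable <- S4Vectors::mcols(b)$usable & !is.na(profile@log2ratio)
    chroms <- GenomeInfoDb::seqlevelsInUse(b)
    segs <- list()
    for (ci in seq_along(chroms)) {
        chr <- chroms[ci]
        sel <- which(as.character(GenomeInfoDb::seqnames(b)) == chr & usable)
        if (!length(sel)) next
        x <- profile@log2ratio[sel]
        n <- length(x)
        if (n < minSegBins)
            warning("chromosome ", chr, " has fewer than ", minSegBins,
                    " usable bins; kept as a single segment")
        cuts <- if (n >= 2L * minSegBins)
            .segmentSpan(x, 0L, ci, alpha, nPerm, seed, minSegBins)
        else integer()
        bounds <- c(0L, cuts, n)
        sIdx <- Map(function(a, z) seq.int(a + 1L, z),
                    bounds[-length(bounds)], bounds[-1L])
        means <- vapply(sIdx, function(ii) mean(x[ii]), 0)
        nb <- lengths(sIdx)
        merged <- .mergeSegments(means, nb, mergeTol)
        # recover bin membership after merges from cumulative bin counts
        ends <- cumsum(merged$nBins)
        starts <- c(1L, head(ends, -1L) + 1L)
        for (s in seq_along(ends)) {
            binIdx <- sel[starts[s]:ends[s]]
            segs[[length(segs) + 1L]] <- data.frame(
                chrom = chr,
                start = BiocGenerics::start(b)[binIdx[1L]],
                end = BiocGenerics::end(b)[binIdx[length(binIdx)]],
                nBins = length(binIdx),
                meanLog2 = mean(profile@log2ratio[binIdx]))
        }
    }
    if (!length(segs)) stop("profile has no usable bins to segment")
    df <- do.call(rbind, segs)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 seqinfo = GenomeInfoDb::seqinfo(b))
    S4Vectors::mcols(gr)$nBins <- df$nBins
    S4Vectors::mcols(gr)$meanLog2 <- df$meanLog2
    methods::new("SegmentedProfile", gr, sampleId = profile@sampleId,
                 alpha = alpha, binWidth = profile@binWidth)
}

#' Construct a SegmentedProfile by hand
#'
#' Convenience constructor used by the simulator, tests and SEG import.
#'
#' @param chrom,start,end segment coordinates (1-based inclusive).
#' @param meanLog2 per-segment mean log2 ratio.
#' @param nBins usable bins per segment (default 1).
#' @param sampleId sample identifier.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a [SegmentedProfile].
#' @export
segmentedProfile <- function(chrom, start, end, meanLog2, nBins = 1L,
                             sampleId = "sample", seqlengths = NULL) {
    si <- if (!is.null(seqlengths))
        GenomeInfoDb::Seqinfo(names(seqlengths), as.integer(seqlengths))
    else NULL
    gr <- if (is.null(si)) GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start, end))
          else GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
            seqinfo = si)
    S4Vectors::mcols(gr)$nBins <- as.integer(rep_len(nBins, length(gr)))
    S4Vectors::mcols(gr)$meanLog2 <- meanLog2
    methods::new("SegmentedProfile", gr, sampleId = sampleId,
                 alpha = NA_real_, binWidth = NA_real_)
}

#' Read and write SEG files
#'
#' Standard SEG dialect: tab-separated \code{ID}, \code{chrom},
#' \code{loc.start} (1-based), \code{loc.end} (inclusive), \code{num.mark},
#' \code{seg.mean} with a header line. Internal coordinates are identical
#' (GRanges are 1-based closed), so the round trip is exact.
#'
#' @param x a [SegmentedProfile].
#' @param path file path.
#' @return \code{segRead} returns a [SegmentedProfile]; \code{segWrite}
#'   returns \code{path} invisibly.
#' @export
segWrite <- function(x, path) {
    stopifnot(methods::is(x, "SegmentedProfile"))
    df <- data.frame(ID = x@sampleId,
        chrom = as.character(GenomeInfoDb::seqnames(x)),
        loc.start = BiocGenerics::start(x), loc.end = BiocGenerics::end(x),
        num.mark = S4Vectors::mcols(x)$nBins,
        seg.mean = S4Vectors::mcols(x)$meanLog2)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname segWrite
#' @export
segRead <- function(path) {
    lines <- readLines(path)
    if (!length(lines)) stop("empty SEG file: ", path)
    rows <- strsplit(lines, "\t", fixed = TRUE)
    if (length(rows[[1L]]) < 6L)
        stop("malformed SEG header at line 1 of ", path)
    bad <- which(lengths(rows) != length(rows[[1L]]))
    if (length(bad)) stop("malformed SEG row at line ", bad[1L], " of ", path)
    df <- as.data.frame(do.call(rbind, rows[-1L]), stringsAsFactors = FALSE)
    names(df) <- rows[[1L]]
    suppressWarnings({
        st <- as.numeric(df$loc.start); en <- as.numeric(df$loc.end)
        nm <- as.numeric(df$num.mark); mu <- as.numeric(df$seg.mean)
    })
    badnum <- which(is.na(st) | is.na(en) | is.na(nm) | is.na(mu))
    if (length(badnum))
        stop("malformed SEG row at line ", 1L + badnum[1L], " of ", path)
    segmentedProfile(df$chrom, st, en, mu, nBins = nm,
                     sampleId = df$ID[1L])
}
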