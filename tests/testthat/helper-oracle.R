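# Independent oracles used by the segmentation and calling tests.
#
# The CBS oracle re-derives the maximizing circular split, its permutation
# p-value, the recursion and the merge rule from first principles (plain
# loops over all pairs). It consumes the same documented permutation stream
# as the implementation (plasmaCNA:::.permMatrix with the span-derived
# seed): the permutation indices are part of the algorithm definition, and
# sharing them is what makes two finite-Monte-Carlo p-value estimates
# comparable decision for decision.

# two-sample t^2 statistic of arc (i, j] vs complement, plain arithmetic
oracleArcStat <- function(x, i, j) {
    n <- length(x)
    arc <- x[(i + 1):j]
    comp <- x[-((i + 1):j)]
    m1 <- mean(arc); m2 <- mean(comp)
    pv <- (sum(x^2) - length(arc) * m1^2 - length(comp) * m2^2) / (n - 2)
    pv <- max(pv, 0)
    num <- (m1 - m2)^2
    den <- pv * (1 / length(arc) + 1 / length(comp))
    if (num == 0) 0 else num / den
}

# exhaustive search over all valid circular splits
oracleScan <- function(x, m) {
    n <- length(x)
    best <- list(stat = -Inf, i = NA_integer_, j = NA_integer_)
    # canonical split set (matches the implementation's definition): arcs
    # (i, j] with j <= n - m; (i, n) splits are complements of (0, i) ones
    for (i in 0:(n - 2 * m)) {
        if (i != 0 && i < m) next
        for (j in seq.int(i + m, n - m)) {
            s <- oracleArcStat(x, i, j)
            if (s > best$stat) best <- list(stat = s, i = i, j = j)
        }
    }
    best
}

oracleSegmentSpan <- function(x, offset, chromIdx, alpha, nPerm, seed, m) {
    n <- length(x)
    if (n < 2 * m || diff(range(x)) < 1e-12) return(integer())
    best <- oracleScan(x, m)
    if (is.na(best$i)) return(integer())
    perms <- plasmaCNA:::.permMatrix(n, nPerm,
        plasmaCNA:::.spanSeed(seed, chromIdx, offset, n))
    count <- 0L
    for (p in seq_len(nPerm)) {
        if (oracleScan(x[perms[, p]], m)$stat >= best$stat)
            count <- count + 1L
    }
    if ((1 + count) / (nPerm + 1) > alpha) return(integer())
    i <- best$i; j <- best$j
    cuts <- integer()
    pieces <- list()
    if (i > 0) { cuts <- c(cuts, offset + i); pieces <- c(pieces, list(c(1, i))) }
    pieces <- c(pieces, list(c(i + 1, j)))
    if (j < n) { cuts <- c(cuts, offset + j); pieces <- c(pieces, list(c(j + 1, n))) }
    for (pc in pieces) {
        cuts <- c(cuts, oracleSegmentSpan(x[pc[1]:pc[2]], offset + pc[1] - 1,
                                          chromIdx, alpha, nPerm, seed, m))
    }
    sort(unique(cuts))
}

oracleMerge <- function(means, nb, tol) {
    repeat {
        if (length(means) < 2) break
        d <- abs(diff(means))
        if (min(d) >= tol) break
        k <- which.min(d)
        means[k] <- (nb[k] * means[k] + nb[k + 1] * means[k + 1]) /
            (nb[k] + nb[k + 1])
        nb[k] <- nb[k] + nb[k + 1]
        means <- means[-(k + 1)]
        nb <- nb[-(k + 1)]
    }
    data.frame(meanLog2 = means, nBins = nb)
}

# full oracle segmentation of one chromosome's bin values
oracleCBS <- function(x, chromIdx, alpha = 0.01, nPerm = 1000, seed = 1,
                      m = 2, mergeTol = 0.05) {
    cuts <- if (length(x) >= 2 * m)
        oracleSegmentSpan(x, 0, chromIdx, alpha, nPerm, seed, m)
    else integer()
    bounds <- c(0, cuts, length(x))
    means <- nb <- numeric(0)
    for (s in seq_len(length(bounds) - 1)) {
        idx <- (bounds[s] + 1):bounds[s + 1]
        means <- c(means, mean(x[idx]))
        nb <- c(nb, length(idx))
    }
    oracleMerge(means, nb, mergeTol)
}

# helper to build a single-chromosome CopyRatioProfile from raw bin values
profileFromValues <- function(values, binWidth = 5e5, chrom = "chr1",
                              sampleId = "toy") {
    chrom <- rep_len(chrom, length(values))
    lens <- tapply(rep(binWidth, length(values)), chrom, sum)
    gb <- makeBins(lens[unique(chrom)], binWidth)
    methods::new("CopyRatioProfile", bins = gb,
                 log2ratio = as.numeric(values),
                 weight = rep(1, length(values)),
                 sampleId = sampleId, binWidth = binWidth)
}

segTable <- function(seg) {
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(seg)),
               start = BiocGenerics::start(seg), end = BiocGenerics::end(seg),
               nBins = S4Vectors::mcols(seg)$nBins,
               meanLog2 = S4Vectors::mcols(seg)$meanLog2)
}
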