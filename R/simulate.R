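# Synthetic-data engine: ground-truth copy-number profiles, Poisson bin-count
# simulation with tunable GC bias, in-silico tumor/normal mixing and read
# downsampling. Emulates the cfDNA dilution (50/25/10/5/1/0%) and coverage
# titration (down to 0.005x) experiments at desk scale.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    force(expr)
}

#' Construct a ground-truth copy-number profile
#'
#' @param gr a \code{GRanges} with an integer \code{n} column (tumor copy
#'   number); uncovered regions are implicitly copy-neutral (2 on autosomes,
#'   1 on chrX for a male sample). Needs seqlengths.
#' @param sex "male" or "female".
#' @param label free-text description.
#' @return a [TruthProfile].
#' @export
truthProfile <- function(gr, sex = "male", label = "custom") {
    methods::new("TruthProfile", gr, sex = sex, label = label)
}

.truthFromTable <- function(df, sizes, sex, label) {
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start, df$end),
        seqinfo = GenomeInfoDb::Seqinfo(names(sizes), as.integer(sizes)))
    S4Vectors::mcols(gr)$n <- as.integer(df$n)
    truthProfile(gr, sex = sex, label = label)
}

#' A copy-neutral (flat) truth profile
#'
#' @param sizes named chromosome lengths.
#' @param sex "male" or "female".
#' @return a [TruthProfile] with no altered interval.
#' @export
flatTruth <- function(sizes, sex = "male") {
    gr <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
        names(sizes), as.integer(sizes)))
    S4Vectors::mcols(gr)$n <- integer()
    truthProfile(gr, sex = sex, label = "normal")
}

#' Built-in ground-truth profiles
#'
#' \code{mcrpcTruth}: a metastatic castration-resistant prostate cancer
#' archetype -- 8p loss, 8q gain, focal high-level AR amplification (n = 12),
#' focal 2-copy PTEN and RB1 deletions, and a one-copy interstitial 21q22.2
#' deletion over the ERG--TMPRSS2 span. \code{vcapTruth}: a VCaP-like
#' prostate cell-line profile (stronger AR amplification, 8p loss / 8q
#' gain, 21q22.2 deletion). \code{umuc5Truth}: a UMUC-5-like urothelial
#' profile with focal high-level EGFR amplification and 9p loss.
#'
#' Focal events are 2 Mb wide in the coordinates of the chosen genome and
#' centered on the (scaled) gene loci, so they satisfy the 1.5-20 Mb focal
#' rule on the full-size and the miniature genome alike.
#'
#' @param scale genome divisor, as in [grch37Sizes()] (default 20, the
#'   miniature desk-scale genome).
#' @param focalWidth width of focal events in bp (default 2 Mb).
#' @return a [TruthProfile].
#' @examples
#' mcrpcTruth()
#' @export
mcrpcTruth <- function(scale = 20, focalWidth = 2e6) {
    sizes <- grch37Sizes(scale)
    genes <- geneAnnotation(scale)
    arms <- armAnnotation(scale)
    span <- ergTmprss2Span(scale)
    focal <- function(gene, n) {
        mid <- (BiocGenerics::start(genes[gene]) +
                BiocGenerics::end(genes[gene])) / 2
        chr <- as.character(GenomeInfoDb::seqnames(genes[gene]))
        st <- max(1, round(mid - focalWidth / 2))
        data.frame(chrom = chr, start = st,
                   end = min(sizes[chr], st + focalWidth - 1), n = n)
    }
    armRow <- function(arm, n) data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(arms[arm])),
        start = BiocGenerics::start(arms[arm]),
        end = BiocGenerics::end(arms[arm]), n = n)
    df <- rbind(
        armRow("8p", 1), armRow("8q", 3),
        focal("AR", 12), focal("PTEN", 0), focal("RB1", 0),
        data.frame(chrom = "chr21", start = BiocGenerics::start(span),
                   end = BiocGenerics::end(span), n = 1))
    .truthFromTable(df, sizes, sex = "male", label = "mCRPC-like")
}

#' @rdname mcrpcTruth
#' @export
vcapTruth <- function(scale = 20, focalWidth = 2e6) {
    sizes <- grch37Sizes(scale)
    genes <- geneAnnotation(scale)
    arms <- armAnnotation(scale)
    span <- ergTmprss2Span(scale)
    ar <- genes["AR"]
    mid <- (BiocGenerics::start(ar) + BiocGenerics::end(ar)) / 2
    st <- max(1, round(mid - focalWidth / 2))
    df <- rbind(
        data.frame(chrom = "chr8", start = BiocGenerics::start(arms["8p"]),
                   end = BiocGenerics::end(arms["8p"]), n = 1),
        data.frame(chrom = "chr8", start = BiocGenerics::start(arms["8q"]),
                   end = BiocGenerics::end(arms["8q"]), n = 3),
        data.frame(chrom = "chrX", start = st,
                   end = min(sizes["chrX"], st + focalWidth - 1), n = 14),
        data.frame(chrom = "chr21", start = BiocGenerics::start(span),
                   end = BiocGenerics::end(span), n = 1))
    .truthFromTable(df, sizes, sex = "male", label = "VCaP-like")
}

#' @rdname mcrpcTruth
#' @export
umuc5Truth <- function(scale = 20, focalWidth = 2e6) {
    sizes <- grch37Sizes(scale)
    genes <- geneAnnotation(scale)
    arms <- armAnnotation(scale)
    egfr <- genes["EGFR"]
    mid <- (BiocGenerics::start(egfr) + BiocGenerics::end(egfr)) / 2
    st <- max(1, round(mid - focalWidth / 2))
    df <- rbind(
        data.frame(chrom = "chr7", start = st,
                   end = min(sizes["chr7"], st + focalWidth - 1), n = 20),
        data.frame(chrom = "chr9", start = BiocGenerics::start(arms["9p"]),
                   end = BiocGenerics::end(arms["9p"]), n = 1),
        data.frame(chrom = "chr5", start = BiocGenerics::start(arms["5q"]),
                   end = BiocGenerics::end(arms["5q"]), n = 3))
    .truthFromTable(df, sizes, sex = "male", label = "UMUC-5-like")
}

# per-bin expected tumor copy number (length-weighted over truth intervals;
# uncovered regions are copy-neutral) and normal copy baseline
.binCopyNumbers <- function(truth, x) {
    chrom <- as.character(GenomeInfoDb::seqnames(x))
    normalCopy <- ifelse(chrom %in% c("chrX", "X") & truth@sex == "male", 1, 2)
    nbar <- normalCopy
    ov <- GenomicRanges::findOverlaps(methods::as(x, "GRanges"),
                                      methods::as(truth, "GRanges"),
                                      ignore.strand = TRUE)
    if (length(ov)) {
        inter <- IRanges::pintersect(
            methods::as(x, "GRanges")[S4Vectors::queryHits(ov)],
            methods::as(truth, "GRanges")[S4Vectors::subjectHits(ov)])
        wOv <- as.numeric(BiocGenerics::width(inter))
        nTruth <- S4Vectors::mcols(truth)$n[S4Vectors::subjectHits(ov)]
        q <- S4Vectors::queryHits(ov)
        binW <- as.numeric(BiocGenerics::width(x))
        dn <- tapply(wOv * (nTruth - normalCopy[q]), q, sum)
        idx <- as.integer(names(dn))
        nbar[idx] <- nbar[idx] + dn / binW[idx]
    }
    list(nbar = nbar, normalCopy = normalCopy)
}

#' Simulate per-bin read counts for a tumor/normal cfDNA mixture
#'
#' The expected rate of bin i is proportional to
#' (f n_i + (1 - f) c_i) (1 + gcBias (gc_i - 0.5)) w_i, with n_i the
#' length-weighted truth copy number over the bin, c_i the normal baseline,
#' and w_i the bin width; rates are normalized so the expected total equals
#' coverage x genome length / readLength, and counts are drawn per bin from
#' a Poisson (optionally gamma-overdispersed).
#'
#' @param truth a [TruthProfile] (use a flat truth for a normal sample).
#' @param fraction tumor fraction f in [0, 1].
#' @param coverage target effective coverage (x).
#' @param x a [GenomeBins] grid on the truth's genome.
#' @param readLength mean read length in bp (default 180, the cfDNA-like
#'   fragmentation target).
#' @param gcBias linear GC-bias strength (default 0; needs GC-annotated
#'   bins otherwise).
#' @param overdispersion gamma overdispersion (variance multiplier - 1)/mean
#'   style parameter; 0 (default) gives pure Poisson.
#' @param seed integer seed (local RNG; global random state is untouched).
#' @param sampleId sample identifier.
#' @return a [BinCounts].
#' @export
simulateCounts <- function(truth, fraction, coverage, x, readLength = 180,
                           gcBias = 0, overdispersion = 0, seed = 1,
                           sampleId = sprintf("%s_f%s_s%d", truth@label,
                                              fraction, seed)) {
    stopifnot(methods::is(truth, "TruthProfile"), methods::is(x, "GenomeBins"))
    if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
    if (coverage <= 0) stop("coverage must be positive")
    cn <- .binCopyNumbers(truth, x)
    rate <- fraction * cn$nbar + (1 - fraction) * cn$normalCopy
    if (gcBias != 0) {
        gc <- S4Vectors::mcols(x)$gc
        if (all(is.na(gc)))
            stop("gcBias != 0 requires GC-annotated bins")
        mult <- 1 + gcBias * (gc - 0.5)
        mult[is.na(mult)] <- 1
        if (any(mult < 0)) {
            warning("extreme GC bias clipped at rate 0")
            mult <- pmax(mult, 0)
        }
        rate <- rate * mult
    }
    rate <- rate * as.numeric(BiocGenerics::width(x))
    totalReads <- coverage * genomeLength(x) / readLength
    lambda <- rate / sum(rate) * totalReads
    counts <- .withSeed(seed, {
        if (overdispersion > 0) {
            shape <- 1 / overdispersion
            lam <- lambda * stats::rgamma(length(lambda), shape = shape,
                                          rate = shape)
            stats::rpois(length(lambda), lam)
        } else stats::rpois(length(lambda), lambda)
    })
    methods::new("BinCounts", bins = x, counts = as.numeric(counts),
        sampleId = sampleId, totalReads = sum(counts),
        meanReadLength = readLength,
        filterStats = c(unmapped = 0, secondary = 0, supplementary = 0,
                        duplicate = 0, low_mapq = 0, out_of_bins = 0))
}

#' Simulate a panel of copy-neutral normals
#'
#' @param x a [GenomeBins] grid.
#' @param sex panel sex ("male" keeps chrX at one copy so male samples
#'   normalize correctly).
#' @param coverage effective coverage per panel sample.
#' @param n number of panel samples (default 5).
#' @param seed base seed; sample k uses seed + k.
#' @param ... passed to [simulateCounts()].
#' @return list of [BinCounts].
#' @export
simulateNormalPanel <- function(x, sex = "male", coverage = 0.1, n = 5,
                                seed = 1000, ...) {
    flat <- flatTruth(GenomeInfoDb::seqlengths(x), sex = sex)
    lapply(seq_len(n), function(k)
        simulateCounts(flat, fraction = 0, coverage = coverage, x = x,
                       seed = seed + k,
                       sampleId = sprintf("normal_%d", k), ...))
}

#' Mix tumor and normal bin counts in silico
#'
#' Draws round(f x totalReads) reads from the tumor sample and the
#' remainder from the normal by per-bin binomial thinning (the
#' large-population approximation to multivariate hypergeometric sampling),
#' then sums.
#'
#' @param tumor,normal [BinCounts] on the identical grid.
#' @param fraction tumor read fraction f in [0, 1].
#' @param totalReads reads in the mixture; must not exceed either source
#'   pool's requirement.
#' @param seed integer seed.
#' @return a [BinCounts].
#' @export
inSilicoMix <- function(tumor, normal, fraction, totalReads, seed = 1) {
    stopifnot(methods::is(tumor, "BinCounts"), methods::is(normal, "BinCounts"))
    if (length(tumor@bins) != length(normal@bins))
        stop("tumor and normal are not on the same bin grid")
    nT <- round(fraction * totalReads)
    nN <- totalReads - nT
    if (nT > sum(tumor@counts) || nN > sum(normal@counts))
        stop("requested reads exceed the available source reads")
    .withSeed(seed, {
        tPart <- if (nT > 0)
            stats::rbinom(length(tumor@counts), size = round(tumor@counts),
                          prob = nT / sum(tumor@counts)) else 0
        nPart <- if (nN > 0)
            stats::rbinom(length(normal@counts), size = round(normal@counts),
                          prob = nN / sum(normal@counts)) else 0
        counts <- as.numeric(tPart + nPart)
        methods::new("BinCounts", bins = tumor@bins, counts = counts,
            sampleId = sprintf("mix_f%s_%s", fraction, tumor@sampleId),
            totalReads = sum(counts),
            meanReadLength = mean(c(tumor@meanReadLength,
                                    normal@meanReadLength)),
            filterStats = numeric())
    })
}

#' Downsample bin counts by binomial thinning
#'
#' Each bin keeps Binomial(count, p) reads with p = targetReads /
#' totalReads, emulating in-silico downsampling of the read stream.
#'
#' @param x a [BinCounts].
#' @param targetReads desired read total; must be <= the current total
#'   unless \code{allowUnchanged} (then the input is returned as is).
#' @param seed integer seed.
#' @param allowUnchanged return the input when targetReads >= total.
#' @return a [BinCounts].
#' @export
downsampleCounts <- function(x, targetReads, seed = 1, allowUnchanged = FALSE) {
    stopifnot(methods::is(x, "BinCounts"))
    tot <- sum(x@counts)
    if (targetReads > tot) {
        if (allowUnchanged) return(x)
        stop("targetReads exceeds available reads (", tot, ")")
    }
    p <- targetReads / tot
    counts <- if (p >= 1) x@counts else .withSeed(seed,
        as.numeric(stats::rbinom(length(x@counts), size = round(x@counts),
                                 prob = p)))
    methods::new("BinCounts", bins = x@bins, counts = counts,
        sampleId = x@sampleId, totalReads = sum(counts),
        meanReadLength = x@meanReadLength, filterStats = x@filterStats)
}

#' Write a deterministic simulation fixture suite
#'
#' Builds the three built-in truth profiles, simulates the dilution ladder
#' (50, 25, 10, 5, 1, 0%) for the mCRPC-like truth at the requested
#' coverage, and writes truth JSON plus count tables. Same seed, same bytes.
#'
#' @param outDir output directory (created if needed).
#' @param seed base seed.
#' @param coverage effective coverage of the simulated samples.
#' @param binWidth bin width in bp.
#' @param scale genome divisor (default 20: miniature genome).
#' @return invisible character vector of written files.
#' @export
makeFixtureSuite <- function(outDir, seed = 1, coverage = 0.1,
                             binWidth = 5e5, scale = 20) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create ", outDir)
    truths <- list(mcrpc = mcrpcTruth(scale), vcap = vcapTruth(scale),
                   umuc5 = umuc5Truth(scale))
    files <- character()
    for (nm in names(truths)) {
        tr <- truths[[nm]]
        tj <- file.path(outDir, paste0(nm, "_truth.json"))
        jsonlite::write_json(list(label = tr@label, sex = tr@sex,
            intervals = data.frame(
                chrom = as.character(GenomeInfoDb::seqnames(tr)),
                start = BiocGenerics::start(tr), end = BiocGenerics::end(tr),
                n = S4Vectors::mcols(tr)$n)),
            tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        files <- c(files, tj)
    }
    gb <- makeBins(grch37Sizes(scale), binWidth)
    for (f in c(0.5, 0.25, 0.10, 0.05, 0.01, 0)) {
        bc <- simulateCounts(truths$mcrpc, fraction = f, coverage = coverage,
                             x = gb, seed = seed + round(1000 * f))
        path <- file.path(outDir, sprintf("mcrpc_f%03d.counts.tsv",
                                          round(100 * f)))
        writeCountsTable(bc, path)
        files <- c(files, path)
    }
    invisible(files)
}
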