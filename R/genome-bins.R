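#' Build a fixed-width genomic bin grid
#'
#' Tiles every chromosome with \code{binWidth}-bp bins; the terminal bin of
#' each chromosome is clipped to the chromosome length. GC and mappability
#' start unannotated (NA) and every bin starts \code{usable}.
#'
#' @param genomeSizes named numeric vector of chromosome lengths in bp.
#' @param binWidth bin width in bp (>= 10000); the screening default is
#'   500 kb, with smaller widths only justified at higher coverage (see
#'   [chooseBinWidth()]).
#' @return a [GenomeBins] object.
#' @examples
#' gb <- makeBins(c(chr1 = 10.2e6), 5e5)
#' length(gb)            # 21 bins, the last one 200 kb
#' @export
makeBins <- function(genomeSizes, binWidth = 5e5) {
    if (length(genomeSizes) == 0L || is.null(names(genomeSizes)) ||
        any(!nzchar(names(genomeSizes))))
        stop("genomeSizes must be a non-empty named vector of chromosome lengths")
    if (any(genomeSizes <= 0)) stop("all chromosome lengths must be > 0")
    if (length(binWidth) != 1L || is.na(binWidth) || binWidth < 1e4)
        stop("binWidth must be a single value >= 10000 bp")
    sl <- stats::setNames(as.integer(genomeSizes), names(genomeSizes))
    gr <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(binWidth),
                                    cut.last.tile.in.chrom = TRUE)
    S4Vectors::mcols(gr)$gc <- NA_real_
    S4Vectors::mcols(gr)$mappability <- NA_real_
    S4Vectors::mcols(gr)$usable <- TRUE
    methods::new("GenomeBins", gr)
}

#' Annotate bins with GC content from a reference sequence
#'
#' Sets each bin's \code{gc} to the G+C fraction of its non-N bases. Bins
#' with more than \code{maxNFrac} N bases are marked unusable and left
#' unannotated (their sequence is unplaced assembly gap).
#'
#' @param x a [GenomeBins] grid.
#' @param reference a \code{DNAStringSet} named by chromosome, or a path /
#'   \code{Rsamtools::FaFile} for an indexed FASTA.
#' @param maxNFrac bins with a larger N fraction become unusable (default
#'   0.5).
#' @return the grid with \code{gc} and \code{usable} updated.
#' @export
annotateGC <- function(x, reference, maxNFrac = 0.5) {
    stopifnot(methods::is(x, "GenomeBins"))
    if (is.character(reference)) reference <- Rsamtools::FaFile(reference)
    chroms <- GenomeInfoDb::seqlevelsInUse(x)
    if (methods::is(reference, "DNAStringSet")) {
        missing <- setdiff(chroms, names(reference))
        if (length(missing))
            stop("reference lacks chromosome(s): ", paste(missing, collapse = ", "))
        binChrom <- as.character(GenomeInfoDb::seqnames(x))
        pieces <- lapply(chroms, function(chr) {
            sel <- binChrom == chr
            Biostrings::extractAt(reference[[chr]],
                IRanges::IRanges(BiocGenerics::start(x)[sel],
                                 BiocGenerics::end(x)[sel]))
        })
        # bins are grouped by chromosome in seqlevels order (grid invariant)
        seqs <- do.call(c, pieces)
    } else if (methods::is(reference, "FaFile")) {
        missing <- setdiff(chroms, GenomeInfoDb::seqnames(
            GenomeInfoDb::seqinfo(reference)))
        if (length(missing))
            stop("reference lacks chromosome(s): ", paste(missing, collapse = ", "))
        seqs <- Rsamtools::getSeq(reference, methods::as(x, "GRanges"))
    } else stop("reference must be a DNAStringSet, FaFile or FASTA path")
    freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    nfrac <- 1 - acgt / BiocGenerics::width(x)
    gc <- ifelse(acgt > 0, rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt,
                 NA_real_)
    bad <- nfrac > maxNFrac
    gc[bad] <- NA_real_
    S4Vectors::mcols(x)$gc <- gc
    S4Vectors::mcols(x)$usable <- S4Vectors::mcols(x)$usable & !bad
    methods::validObject(x)
    x
}

#' Count filtered reads per bin from a BAM file
#'
#' Assigns each retained alignment to exactly one bin by its leftmost
#' aligned base. Unmapped, secondary and supplementary alignments,
#' duplicate-flagged reads (when \code{dropDuplicates}) and reads below
#' \code{minMapq} are excluded; exclusion tallies are kept in
#' \code{filterStats} so that counts + exclusions + out-of-bin reads always
#' reconcile with the input records.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param x a [GenomeBins] grid built on the same assembly.
#' @param minMapq minimum mapping quality; the screening default keeps only
#'   high-quality alignments (MAPQ >= 37).
#' @param dropDuplicates exclude duplicate-flagged reads (default TRUE; this
#'   consumes the flag, it does not mark duplicates).
#' @param sampleId sample identifier (default: BAM basename).
#' @return a [BinCounts] object.
#' @export
countReads <- function(bam, x, minMapq = 37, dropDuplicates = TRUE,
                       sampleId = sub("\\.bam$", "", basename(bam))) {
    stopifnot(methods::is(x, "GenomeBins"))
    param <- Rsamtools::ScanBamParam(
        what = c("rname", "pos", "mapq", "flag", "qwidth"))
    rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
    n <- length(rec$flag)
    flag <- rec$flag
    unmapped <- bitwAnd(flag, 4L) > 0L
    secondary <- bitwAnd(flag, 256L) > 0L & !unmapped
    supplementary <- bitwAnd(flag, 2048L) > 0L & !unmapped & !secondary
    dup <- bitwAnd(flag, 1024L) > 0L & !unmapped & !secondary & !supplementary
    if (!dropDuplicates) dup[] <- FALSE
    mapq <- rec$mapq
    mapq[is.na(mapq)] <- 0L
    lowq <- !unmapped & !secondary & !supplementary & !dup & mapq < minMapq
    keep <- !(unmapped | secondary | supplementary | dup | lowq)

    chroms <- as.character(rec$rname[keep])
    unknown <- setdiff(unique(chroms), GenomeInfoDb::seqlevels(x))
    if (length(unknown))
        stop("alignment chromosome(s) absent from the bin grid: ",
             paste(sort(unknown), collapse = ", "))
    counts <- numeric(length(x))
    outOfBins <- 0L
    if (any(keep)) {
        pos <- rec$pos[keep]
        reads <- GenomicRanges::GRanges(chroms, IRanges::IRanges(pos, width = 1L),
            seqinfo = GenomeInfoDb::seqinfo(x))
        hits <- GenomicRanges::findOverlaps(reads, methods::as(x, "GRanges"),
                                            select = "first")
        outOfBins <- sum(is.na(hits))
        tab <- table(hits[!is.na(hits)])
        counts[as.integer(names(tab))] <- as.numeric(tab)
    }
    meanLen <- if (any(keep)) mean(rec$qwidth[keep], na.rm = TRUE) else 0
    stats <- c(unmapped = sum(unmapped), secondary = sum(secondary),
               supplementary = sum(supplementary), duplicate = sum(dup),
               low_mapq = sum(lowq), out_of_bins = outOfBins)
    methods::new("BinCounts", bins = x, counts = counts, sampleId = sampleId,
                 totalReads = sum(counts), meanReadLength = meanLen,
                 filterStats = stats)
}

#' Read and write per-bin count tables
#'
#' TSV dialect: \code{#}-prefixed header metadata lines
#' (\code{sample_id}, \code{total_reads}, \code{mean_read_length},
#' chromosome lengths) followed by tab-separated columns \code{chrom},
#' \code{start} (0-based), \code{end} (half-open), \code{count}, \code{gc},
#' \code{mappability}, \code{usable}. \code{writeCountsTable} then
#' \code{readCountsTable} is the identity on all fields.
#'
#' @param path file path.
#' @param x a [BinCounts] object.
#' @return \code{readCountsTable} returns a [BinCounts];
#'   \code{writeCountsTable} returns \code{path} invisibly.
#' @export
readCountsTable <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    meta <- list()
    for (h in lines[hdr]) {
        kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
        if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
    }
    body <- if (length(hdr)) lines[-hdr] else lines
    offset <- length(hdr) + 1L  # header column line follows the meta block
    cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    need <- c("chrom", "start", "end", "count")
    if (!all(need %in% cols))
        stop("counts table must have columns chrom, start, end, count (line ",
             offset, ")")
    rows <- strsplit(body[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(rows) != length(cols))
    if (length(bad))
        stop("malformed row at line ", offset + bad[1L], " of ", path)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- cols
    for (cc in c("start", "end", "count", "gc", "mappability"))
        if (cc %in% names(df)) suppressWarnings(df[[cc]] <- as.numeric(df[[cc]]))
    badnum <- which(!complete.cases(df[, need]))
    if (length(badnum))
        stop("non-numeric coordinate or count at line ", offset + 1L + badnum[1L])
    if (any(df$count < 0))
        stop("negative count at line ",
             offset + 1L + which(df$count < 0)[1L], " of ", path)
    sl <- NULL
    if (!is.null(meta$seqlengths)) {
        parts <- strsplit(strsplit(meta$seqlengths, ",", fixed = TRUE)[[1L]],
                          ":", fixed = TRUE)
        sl <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                              vapply(parts, `[`, "", 1L))
    } else {
        sl <- tapply(df$end, df$chrom, max)[unique(df$chrom)]
    }
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        seqinfo = GenomeInfoDb::Seqinfo(names(sl), as.integer(sl)))
    S4Vectors::mcols(gr)$gc <- if ("gc" %in% names(df)) df$gc else NA_real_
    S4Vectors::mcols(gr)$mappability <-
        if ("mappability" %in% names(df)) df$mappability else NA_real_
    S4Vectors::mcols(gr)$usable <-
        if ("usable" %in% names(df)) df$usable == "TRUE" else TRUE
    grid <- methods::new("GenomeBins", gr)
    methods::new("BinCounts", bins = grid, counts = df$count,
        sampleId = if (!is.null(meta$sample_id)) meta$sample_id else "sample",
        totalReads = if (!is.null(meta$total_reads))
            as.numeric(meta$total_reads) else sum(df$count),
        meanReadLength = if (!is.null(meta$mean_read_length))
            as.numeric(meta$mean_read_length) else NA_real_,
        filterStats = numeric())
}

#' @rdname readCountsTable
#' @export
writeCountsTable <- function(x, path) {
    stopifnot(methods::is(x, "BinCounts"))
    b <- x@bins
    sl <- GenomeInfoDb::seqlengths(b)
    meta <- c(
        sprintf("# sample_id=%s", x@sampleId),
        sprintf("# total_reads=%.10g", x@totalReads),
        sprintf("# mean_read_length=%.10g", x@meanReadLength),
        sprintf("# seqlengths=%s",
                paste(sprintf("%s:%d", names(sl), sl), collapse = ",")))
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(b)),
        start = BiocGenerics::start(b) - 1L, end = BiocGenerics::end(b),
        count = x@counts, gc = S4Vectors::mcols(b)$gc,
        mappability = S4Vectors::mcols(b)$mappability,
        usable = S4Vectors::mcols(b)$usable)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    writeLines(paste(names(df), collapse = "\t"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
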