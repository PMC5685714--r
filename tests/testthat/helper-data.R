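# Shared fixtures built in code. Heavier objects (panels) are cached per
# session so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

miniBins <- function(width = 2.5e5, scale = 20) {
    key <- sprintf("bins_%g_%g", width, scale)
    if (is.null(.cache[[key]]))
        .cache[[key]] <- makeBins(grch37Sizes(scale), width)
    .cache[[key]]
}

miniPanel <- function(width = 2.5e5, coverage = 0.1, scale = 20, n = 5) {
    key <- sprintf("panel_%g_%g_%g_%d", width, coverage, scale, n)
    if (is.null(.cache[[key]]))
        .cache[[key]] <- simulateNormalPanel(miniBins(width, scale),
            sex = "male", coverage = coverage, n = n, seed = 4242)
    .cache[[key]]
}

# one full pipeline run reused across report/concordance tests
demoRun <- function() {
    if (is.null(.cache$demoRun)) {
        gb <- miniBins()
        bc <- simulateCounts(mcrpcTruth(), fraction = 0.4, coverage = 0.1,
                             x = gb, seed = 11)
        .cache$demoRun <- list(
            counts = bc,
            res = runPipeline(bc, panel = miniPanel(),
                              genes = geneAnnotation(20),
                              arms = armAnnotation(20),
                              sex = "male", nPerm = 500, seed = 11))
    }
    .cache$demoRun
}

# minimal SAM text for countReads tests; reads must be coordinate-sorted
writeSam <- function(path, chromLens, reads) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLens),
                     as.integer(chromLens)))
    body <- character(0)
    if (nrow(reads)) {
        o <- order(match(reads$chrom, names(chromLens)), reads$pos)
        reads <- reads[o, , drop = FALSE]
        seq <- strrep("A", 20)
        body <- sprintf("r%04d\t%d\t%s\t%d\t%d\t20M\t*\t0\t0\t%s\t*",
                        seq_len(nrow(reads)), reads$flag, reads$chrom,
                        reads$pos, reads$mapq, seq)
    }
    writeLines(c(hdr, body), path)
    path
}

samToBam <- function(samPath) {
    bam <- sub("\\.sam$", "", samPath)
    suppressMessages(Rsamtools::asBam(samPath, destination = bam,
                                      overwrite = TRUE,
                                      indexDestination = TRUE))
}
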