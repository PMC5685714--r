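test_that("makeBins tiles chromosomes with a clipped terminal bin", {
    gb <- makeBins(c(chr1 = 1e7), 5e5)
    expect_s4_class(gb, "GenomeBins")
    expect_length(gb, 20L)
    expect_equal(max(BiocGenerics::end(gb)), 1e7)
    expect_true(all(BiocGenerics::width(gb) == 5e5))

    gb2 <- makeBins(c(chr1 = 10.2e6), 5e5)
    expect_length(gb2, 21L)
    expect_equal(BiocGenerics::width(gb2)[21L], 2e5)
    expect_equal(BiocGenerics::end(gb2)[21L], 10.2e6)

    # GRCh37 grid matches per-chromosome ceiling division
    sizes <- grch37Sizes()
    gb3 <- makeBins(sizes, 5e5)
    expect_length(gb3, sum(ceiling(sizes / 5e5)))
    per <- table(GenomeInfoDb::seqnames(gb3))
    expect_equal(as.integer(per[names(sizes)]),
                 as.integer(ceiling(sizes / 5e5)))
})

test_that("makeBins rejects degenerate input", {
    expect_error(makeBins(numeric(), 5e5), "non-empty")
    expect_error(makeBins(c(chr1 = 1e6), 5e3), ">= 10000")
    expect_error(makeBins(c(chr1 = -5), 5e5), "> 0")
})

test_that("annotateGC computes GC of non-N bases and drops N bins", {
    ref <- Biostrings::DNAStringSet(c(
        chr1 = paste0(strrep("GGCC", 10000 / 4),          # bin 1: gc 1
                      strrep("N", 10000),                 # bin 2: all N
                      strrep("AT", 10000 / 2))))          # bin 3: gc 0
    gb <- makeBins(c(chr1 = 30000), 1e4)
    gb <- annotateGC(gb, ref)
    gc <- S4Vectors::mcols(gb)$gc
    expect_equal(gc[1L], 1)
    expect_true(is.na(gc[2L]))
    expect_false(S4Vectors::mcols(gb)$usable[2L])
    expect_equal(gc[3L], 0)

    # random sequence: gc equals a direct base tally
    set.seed(99)
    chars <- sample(c("A", "C", "G", "T", "N"), 40000,
                    replace = TRUE, prob = c(.3, .2, .2, .25, .05))
    ref2 <- Biostrings::DNAStringSet(c(chrZ = paste(chars, collapse = "")))
    gb2 <- annotateGC(makeBins(c(chrZ = 40000), 1e4), ref2)
    for (b in 1:4) {
        seg <- chars[((b - 1) * 10000 + 1):(b * 10000)]
        expect_equal(S4Vectors::mcols(gb2)$gc[b],
                     sum(seg %in% c("G", "C")) / sum(seg != "N"))
    }
    expect_error(annotateGC(makeBins(c(chrQ = 2e4), 1e4), ref),
                 "chrQ")
})

test_that("countReads applies the MAPQ >= 37 and duplicate filters", {
    gb <- makeBins(c(chr1 = 1e5), 1e4)
    reads <- data.frame(
        chrom = "chr1",
        pos = c(100, 200, 300, 400),
        mapq = c(36, 37, 60, 60),
        flag = c(0, 0, 1024, 0))
    sam <- writeSam(tempfile(fileext = ".sam"), c(chr1 = 1e5), reads)
    bam <- samToBam(sam)
    bc <- countReads(bam, gb)              # default minMapq = 37
    expect_equal(totalReads(bc), 2)        # MAPQ 36 and the duplicate drop
    expect_equal(binCounts(bc)[1L], 2)
    expect_equal(unname(bc@filterStats["low_mapq"]), 1)
    expect_equal(unname(bc@filterStats["duplicate"]), 1)

    bcKeepDup <- countReads(bam, gb, dropDuplicates = FALSE)
    expect_equal(totalReads(bcKeepDup), 3)
    bc36 <- countReads(bam, gb, minMapq = 36)
    expect_equal(totalReads(bc36), 3)
})

test_that("countReads handles empty input and matches an interval oracle", {
    gb <- makeBins(c(chr1 = 2e5, chr2 = 1e5), 1e4)
    empty <- writeSam(tempfile(fileext = ".sam"),
                      c(chr1 = 2e5, chr2 = 1e5),
                      data.frame(chrom = character(), pos = integer(),
                                 mapq = integer(), flag = integer()))
    bc0 <- countReads(samToBam(empty), gb)
    expect_true(all(binCounts(bc0) == 0))
    expect_equal(totalReads(bc0), 0)

    set.seed(7)
    n <- 1000
    reads <- data.frame(
        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        pos = NA_integer_,
        mapq = sample(c(20, 37, 60), n, replace = TRUE),
        flag = sample(c(0, 0, 0, 1024, 256), n, replace = TRUE))
    reads$pos <- ifelse(reads$chrom == "chr1",
                        sample(1e5 * 2 - 19, n, replace = TRUE),
                        sample(1e5 - 19, n, replace = TRUE))
    sam <- writeSam(tempfile(fileext = ".sam"),
                    c(chr1 = 2e5, chr2 = 1e5), reads)
    bc <- countReads(samToBam(sam), gb)

    kept <- reads$flag == 0 & reads$mapq >= 37
    oracle <- numeric(length(gb))
    binChrom <- as.character(GenomeInfoDb::seqnames(gb))
    binStart <- BiocGenerics::start(gb); binEnd <- BiocGenerics::end(gb)
    for (r in which(kept)) {
        hit <- which(binChrom == reads$chrom[r] & binStart <= reads$pos[r] &
                     binEnd >= reads$pos[r])
        oracle[hit[1L]] <- oracle[hit[1L]] + 1
    }
    expect_equal(binCounts(bc), oracle)
    # conservation: counts + exclusions + out-of-bin = records
    expect_equal(sum(binCounts(bc)) + sum(bc@filterStats), n)
})

test_that("countReads errors on unknown chromosomes, naming them", {
    gb <- makeBins(c(chr1 = 1e5), 1e4)
    sam <- writeSam(tempfile(fileext = ".sam"),
                    c(chr1 = 1e5, chr9 = 1e5),
                    data.frame(chrom = c("chr1", "chr9"), pos = c(5, 5),
                               mapq = 60, flag = 0))
    expect_error(countReads(samToBam(sam), gb), "chr9")
})

test_that("counts tables round-trip and reject malformed input", {
    gb <- miniBins(5e5)
    bc <- simulateCounts(mcrpcTruth(), fraction = 0.25, coverage = 0.05,
                         x = gb, seed = 3)
    path <- tempfile(fileext = ".tsv")
    writeCountsTable(bc, path)
    back <- readCountsTable(path)
    expect_equal(binCounts(back), binCounts(bc))
    expect_equal(sampleId(back), sampleId(bc))
    expect_equal(totalReads(back), totalReads(bc))
    expect_equal(back@meanReadLength, bc@meanReadLength)
    expect_equal(BiocGenerics::start(bins(back)), BiocGenerics::start(bins(bc)))
    expect_equal(as.character(GenomeInfoDb::seqnames(bins(back))),
                 as.character(GenomeInfoDb::seqnames(bins(bc))))
    # byte-identical rewrite (determinism of the writer)
    path2 <- tempfile(fileext = ".tsv")
    writeCountsTable(back, path2)
    expect_identical(readLines(path), readLines(path2))

    # hand-written 3-bin table parses in order
    hand <- tempfile(fileext = ".tsv")
    writeLines(c("# sample_id=hand",
                 "chrom\tstart\tend\tcount",
                 "chr1\t0\t500000\t5",
                 "chr1\t500000\t1000000\t0",
                 "chr1\t1000000\t1500000\t12"), hand)
    h <- readCountsTable(hand)
    expect_equal(binCounts(h), c(5, 0, 12))
    expect_equal(sampleId(h), "hand")

    neg <- tempfile(fileext = ".tsv")
    writeLines(c("chrom\tstart\tend\tcount",
                 "chr1\t0\t500000\t-3"), neg)
    expect_error(readCountsTable(neg), "negative count")

    malformed <- tempfile(fileext = ".tsv")
    writeLines(c("chrom\tstart\tend\tcount",
                 "chr1\t0\t500000\t5",
                 "chr1\t500000"), malformed)
    expect_error(readCountsTable(malformed), "line 3")
})
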