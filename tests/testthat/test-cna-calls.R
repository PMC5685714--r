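test_that("focal calls apply the 1.5-20 Mb / |log2| >= 0.2 filter inclusively", {
    seg <- segmentedProfile(
        rep("chr1", 6),
        start = c(1, 10e6, 40e6, 70e6, 95e6, 120e6),
        end = c(10e6 - 1, 20e6, 41.5e6 - 1, 90e6 - 1, 96.5e6 - 1, 145e6 - 1),
        meanLog2 = c(0.5, 0.5, 0.19, 0.8, -0.2, 0.05))
    # widths: 10 Mb (gain), 10 Mb + 1 (gain), 1.5 Mb but below threshold,
    # 20 Mb (gain, inclusive), 1.5 Mb at exactly -0.2 (loss, inclusive),
    # 25 Mb (excluded: too long)
    calls <- callFocal(seg)
    expect_equal(length(calls), 4L)
    expect_equal(S4Vectors::mcols(calls)$direction,
                 c("gain", "gain", "gain", "loss"))
    expect_equal(as.numeric(BiocGenerics::width(calls)),
                 c(10e6 - 1, 10e6 + 1, 20e6, 1.5e6))

    # a 25 Mb strong gain alone is excluded by length
    big <- segmentedProfile("chr2", 1, 25e6, meanLog2 = 0.8)
    expect_length(callFocal(big), 0L)
})

test_that("focal calls equal the exhaustive filter on random segment tables", {
    for (s in 1:5) {
        set.seed(500 + s)
        n <- 200
        lens <- round(runif(n, 0.5e6, 30e6))
        mus <- rnorm(n, sd = 0.25)
        chrom <- sample(paste0("chr", 1:5), n, replace = TRUE)
        df <- do.call(rbind, lapply(split(seq_len(n), chrom), function(ii) {
            st <- cumsum(c(1, head(lens[ii], -1)))
            data.frame(chrom = chrom[ii], start = st,
                       end = st + lens[ii] - 1, mu = mus[ii])
        }))
        seg <- segmentedProfile(df$chrom, df$start, df$end, df$mu)
        calls <- callFocal(seg)
        len <- df$end - df$start + 1
        oracle <- which(len >= 1.5e6 & len <= 2e7 & abs(df$mu) >= 0.2)
        got <- paste(as.character(GenomeInfoDb::seqnames(calls)),
                     BiocGenerics::start(calls))
        want <- paste(df$chrom[oracle], df$start[oracle])
        expect_setequal(got, want)
    }
})

test_that("gene annotation attaches overlapping genes only", {
    genes <- geneAnnotation()
    ar <- genes["AR"]
    seg <- segmentedProfile(
        c("chrX", "chr10"),
        start = c(BiocGenerics::start(ar) - 1e6, 5e6),
        end = c(BiocGenerics::end(ar) + 1e6, 8e6),
        meanLog2 = c(1.5, 0.7))
    calls <- annotateGenes(callFocal(seg), genes)
    expect_true("AR" %in% S4Vectors::mcols(calls)$genes[[1L]])
    expect_length(S4Vectors::mcols(calls)$genes[[2L]], 0L)

    # random intervals vs the gene panel: match a quadratic-scan oracle
    set.seed(77)
    n <- 50
    chrom <- sample(GenomeInfoDb::seqlevels(genes), n, replace = TRUE)
    st <- sample(1e6:1.3e8, n)
    calls2 <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(st, st + sample(2e6:1.9e7, n)))
    calls2 <- annotateGenes(calls2, genes)
    gdf <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes)),
                      start = BiocGenerics::start(genes),
                      end = BiocGenerics::end(genes),
                      name = names(genes))
    for (k in seq_along(calls2)) {
        kc <- as.character(GenomeInfoDb::seqnames(calls2))[k]
        ks <- BiocGenerics::start(calls2)[k]; ke <- BiocGenerics::end(calls2)[k]
        oracle <- gdf$name[gdf$chrom == kc & gdf$start <= ke & gdf$end >= ks]
        expect_setequal(S4Vectors::mcols(calls2)$genes[[k]], oracle)
    }
})

test_that("deep deletions are the n = 0 nearest state at the fitted fraction", {
    expect_true(classifyDeepDeletion(-1.0, 0.5))
    expect_false(classifyDeepDeletion(-0.15, 0.5))
    # at tc 0.25 the n = 0 level is -0.415 and n = 1 is -0.193: a mean of
    # -0.32 is nearer the deep level
    expect_true(classifyDeepDeletion(-0.32, 0.25))
    expect_false(classifyDeepDeletion(-0.25, 0.25))
    expect_warning(res <- classifyDeepDeletion(-1.0, 0), "unclassifiable")
    expect_false(res)
})

test_that("arm-level events need half the arm in a consistent direction", {
    arms <- armAnnotation()
    sizes <- grch37Sizes()
    p8 <- arms["8p"]; q8 <- arms["8q"]
    seg <- segmentedProfile(
        rep("chr8", 2),
        start = c(1, BiocGenerics::start(q8)),
        end = c(BiocGenerics::end(p8), sizes["chr8"]),
        meanLog2 = c(-0.3, 0.25))
    st <- armLevelEvents(seg, arms)
    expect_equal(unname(st["8p"]), "loss")
    expect_equal(unname(st["8q"]), "gain")

    neutral <- segmentedProfile(names(sizes), 1, sizes,
                                meanLog2 = rep(0, length(sizes)))
    expect_true(all(armLevelEvents(neutral, arms) == "neutral"))

    # 40% of the arm gained: neutral at the 50% rule
    w8p <- BiocGenerics::end(p8)
    seg40 <- segmentedProfile(
        rep("chr8", 2), start = c(1, round(0.4 * w8p) + 1),
        end = c(round(0.4 * w8p), sizes["chr8"]),
        meanLog2 = c(0.5, 0))
    expect_equal(unname(armLevelEvents(seg40, arms)["8p"]), "neutral")
    expect_error(armLevelEvents(seg, arms, minFrac = 0.3), "both")
})

test_that("the 21q22.2 deletion proxy requires 50% reciprocal overlap", {
    span <- ergTmprss2Span()
    st <- BiocGenerics::start(span); en <- BiocGenerics::end(span)
    sizes <- grch37Sizes()

    hit <- segmentedProfile(
        rep("chr21", 3),
        start = c(1, st, en + 1),
        end = c(st - 1, en, sizes["chr21"]),
        meanLog2 = c(0, -0.45, 0))
    expect_true(detect21qDeletion(hit))

    neutral <- segmentedProfile("chr21", 1, sizes["chr21"], meanLog2 = 0)
    expect_false(detect21qDeletion(neutral))

    # deletion overlapping only 40% of the span: rejected
    w <- en - st + 1
    part <- segmentedProfile(
        rep("chr21", 2),
        start = c(1, st + round(0.6 * w)),
        end = c(st + round(0.6 * w) - 1, en),
        meanLog2 = c(0, -0.45))
    expect_false(detect21qDeletion(part))
})

test_that("FGA is a length fraction with the > 0.15 elevation rule", {
    sizes <- grch37Sizes()
    neutral <- segmentedProfile(names(sizes), 1, sizes,
                                meanLog2 = rep(0, length(sizes)))
    f0 <- computeFGA(neutral)
    expect_equal(f0$fga, 0)
    expect_false(f0$elevated)

    # exactly half the genome altered
    half <- segmentedProfile(
        c("chr1", "chr1", "chr2", "chr2"),
        start = c(1, 60e6 + 1, 1, 50e6 + 1),
        end = c(60e6, 150e6, 50e6, 140e6),
        meanLog2 = c(0.5, 0, -0.6, 0))
    expect_equal(computeFGA(half)$fga, 110e6 / 290e6)
    half2 <- segmentedProfile(
        c("chr1", "chr1"), start = c(1, 50e6 + 1), end = c(50e6, 100e6),
        meanLog2 = c(-0.5, 0.1))
    expect_equal(computeFGA(half2)$fga, 0.5)
    expect_true(computeFGA(half2)$elevated)

    # elevation boundary is strict
    boundary <- segmentedProfile(c("chr1", "chr1"), c(1, 151),
                                 c(150, 1000), meanLog2 = c(0.9, 0))
    expect_equal(computeFGA(boundary)$fga, 0.15)
    expect_false(computeFGA(boundary)$elevated)
    above <- segmentedProfile(c("chr1", "chr1"), c(1, 152),
                              c(151, 1000), meanLog2 = c(0.9, 0))
    expect_true(computeFGA(above)$elevated)

    # monotone non-increasing in the cutoff
    set.seed(13)
    st <- cumsum(c(1, rep(1e6, 49)))
    rand <- segmentedProfile("chr3", st, st + 1e6 - 1, rnorm(50, sd = 0.3))
    cuts <- seq(0, 1, by = 0.05)
    fgas <- vapply(cuts, function(ct) computeFGA(rand, ct)$fga, 0)
    expect_true(all(diff(fgas) <= 0))
    expect_true(all(fgas >= 0 & fgas <= 1))
})
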