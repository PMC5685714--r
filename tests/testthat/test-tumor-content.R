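test_that("expectedLog2 reproduces the mixture-model levels", {
    expect_equal(expectedLog2(2, 0), 0)
    expect_equal(expectedLog2(2, 0.73), 0)
    expect_equal(expectedLog2(4, 1), 1)
    expect_equal(expectedLog2(0, 0.5), -1)
    expect_equal(expectedLog2(3, 0.2), log2(1.1))
    expect_equal(expectedLog2(0, 1), -8)          # clamped sentinel
    # male chrX baseline: one normal copy
    expect_equal(expectedLog2(12, 0.4, normalCopy = 1), log2(5.4))
    expect_error(expectedLog2(2, 1.2), "\\[0, 1\\]")
    expect_error(expectedLog2(-1, 0.5), ">= 0")
})

test_that("expectedLog2 is monotone in n and in f as the model demands", {
    for (f in c(0.1, 0.4, 0.9)) {
        lv <- expectedLog2(0:10, f)
        expect_true(all(diff(lv) > 0))
    }
    fs <- seq(0.05, 0.95, by = 0.05)
    gains <- vapply(fs, function(f) expectedLog2(5, f), 0)
    losses <- vapply(fs, function(f) expectedLog2(1, f), 0)
    expect_true(all(diff(gains) > 0))
    expect_true(all(diff(losses) < 0))
})

test_that("computeLSS is the length-weighted RMS of segment means", {
    flat <- segmentedProfile("chr1", 1, 1e8, meanLog2 = 0)
    expect_equal(computeLSS(flat), 0)
    single <- segmentedProfile("chr1", 1, 1e8, meanLog2 = 0.3)
    expect_equal(computeLSS(single), 0.3)

    set.seed(31)
    lens <- sample(1e6:5e7, 10)
    mus <- rnorm(10, sd = 0.4)
    starts <- cumsum(c(1, head(lens, -1)))
    seg <- segmentedProfile("chr1", starts, starts + lens - 1, mus)
    oracle <- sqrt(sum((lens / sum(lens)) * mus^2))
    expect_equal(computeLSS(seg), oracle, tolerance = 1e-12)

    # scale equivariance
    seg3 <- segmentedProfile("chr1", starts, starts + lens - 1, 3 * mus)
    expect_equal(computeLSS(seg3), 3 * computeLSS(seg), tolerance = 1e-12)
})

test_that("classification flips exactly at LSS 0.1", {
    mkSeg <- function(mu) segmentedProfile("chr1", 1, 1e8, meanLog2 = mu)
    suppressWarnings({
        hi <- estimateTumorContent(mkSeg(0.1))
        lo <- estimateTumorContent(mkSeg(0.0999999))
    })
    expect_equal(hi@classification, "high")
    expect_equal(lo@classification, "low")
})

test_that("the grid fit recovers a noiseless profile exactly", {
    f0 <- 0.25
    # deep deletion present: the halving degeneracy (f, n) -> (f/2, 2n-2)
    # cannot apply because 2*0 - 2 < 0, so f0 is the unique exact optimum
    ns <- c(0, 1, 3, 4, 2, 2)
    lens <- c(2e6, 40e6, 30e6, 2e6, 100e6, 120e6)
    starts <- cumsum(c(1, head(lens, -1)))
    seg <- segmentedProfile("chr1", starts, starts + lens - 1,
                            vapply(ns, expectedLog2, 0, f = f0))
    fit <- fitTumorFraction(seg)
    expect_equal(fit$tcFit, 0.25)
    expect_equal(fit$assignments, as.integer(ns))
    expect_equal(fit$fitResidual, 0)

    # without a deep deletion the model is scale-ambiguous and the
    # smallest-f rule lands on f0/2 with states 2n - 2
    ns2 <- c(1, 2, 3, 4)
    lens2 <- c(40e6, 100e6, 30e6, 2e6)
    starts2 <- cumsum(c(1, head(lens2, -1)))
    seg2 <- segmentedProfile("chr1", starts2, starts2 + lens2 - 1,
                             vapply(ns2, expectedLog2, 0, f = f0))
    fit2 <- fitTumorFraction(seg2)
    expect_equal(fit2$tcFit, f0 / 2)
    expect_equal(fit2$assignments, as.integer(2 * ns2 - 2))
})

test_that("flat profiles fit tumor fraction 0", {
    seg <- segmentedProfile(rep("chr1", 4),
                            start = c(1, 1e7, 2e7, 3e7) + c(0, 1, 1, 1),
                            end = c(1e7, 2e7, 3e7, 4e7),
                            meanLog2 = rep(0, 4))
    fit <- fitTumorFraction(seg)
    expect_equal(fit$tcFit, 0)
    expect_true(all(is.na(fit$assignments)))
})

test_that("lssToTc interpolates monotonically through the anchor", {
    curve <- defaultCalibration()
    expect_equal(lssToTc(0, curve), 0)
    expect_equal(lssToTc(0.1, curve), 0.0875)
    ls <- seq(0, 0.8, by = 0.01)
    tc <- lssToTc(ls, curve)
    expect_true(all(diff(tc) >= 0))
    expect_warning(hi <- lssToTc(5, curve), "clamp")
    expect_equal(hi, max(curve@knots$tc))
    expect_error(lssToTc(-0.1, curve), "non-negative")
})

test_that("single-event domination is flagged and broad alteration is not", {
    sizes <- grch37Sizes()
    # genome flat except one 19 Mb deletion on chr20 (clonal-hematopoiesis
    # archetype): elevated LSS from one lone segment
    segs <- data.frame(chrom = names(sizes), start = 1, end = sizes,
                       mu = 0)
    lone <- rbind(
        data.frame(chrom = "chr20", start = 1, end = 30e6, mu = 0),
        data.frame(chrom = "chr20", start = 30e6 + 1, end = 49e6, mu = -1),
        data.frame(chrom = "chr20", start = 49e6 + 1, end = sizes["chr20"],
                   mu = 0),
        segs[segs$chrom != "chr20", ])
    seg1 <- segmentedProfile(lone$chrom, lone$start, lone$end, lone$mu)
    expect_true(flagSingleEvent(seg1))

    # broad multi-chromosome alterations: not flagged
    broad <- segs
    broad$mu <- rep(c(0.4, -0.4, 0), length.out = nrow(broad))
    seg2 <- segmentedProfile(broad$chrom, broad$start, broad$end, broad$mu)
    expect_false(flagSingleEvent(seg2))

    # two equal events, each ~45% of the squared mass: not flagged
    two <- rbind(
        data.frame(chrom = "chr1", start = 1, end = 19e6, mu = -1),
        data.frame(chrom = "chr1", start = 19e6 + 1, end = sizes["chr1"],
                   mu = 0),
        data.frame(chrom = "chr2", start = 1, end = 19e6, mu = -1),
        data.frame(chrom = "chr2", start = 19e6 + 1, end = sizes["chr2"],
                   mu = 0),
        segs[!segs$chrom %in% c("chr1", "chr2"), ])
    seg3 <- segmentedProfile(two$chrom, two$start, two$end, two$mu)
    expect_false(flagSingleEvent(seg3))
})

test_that("estimateTumorContent assembles a coherent estimate", {
    run <- demoRun()
    tc <- run$res$tc
    expect_s4_class(tc, "TumorContentEstimate")
    expect_equal(tc@classification, "high")
    expect_gt(tc@lss, 0.1)
    expect_equal(length(tc@assignments), length(run$res$segments))
    expect_true(abs(tc@tcFit - 0.4) < 0.1)
    # deep-deletion classification is consistent with the fit assignments
    deep <- which(tc@assignments == 0)
    for (d in deep) {
        nc <- if (as.character(GenomeInfoDb::seqnames(
                run$res$segments))[d] == "chrX") 1 else 2
        expect_true(classifyDeepDeletion(segMeans(run$res$segments)[d],
                                         tc@tcFit, normalCopy = nc))
    }
})
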