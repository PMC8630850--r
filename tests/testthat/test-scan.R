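## One small trained hybrid model shared across the scan tests.
scanFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            ds <- tinyDataset(nPerClass = 60L, mutationRate = 0.05,
                              seed = 21L)
            model <- trainHybrid(ds, tinyNetworkSpec(seed = 22L),
                                 dlEpochs = 8L, nrounds = 60L, seed = 22L)
            cache <<- list(ds = ds, model = model)
        }
        cache
    }
})

test_that("every tiled window receives exactly one scored record", {
    fx <- scanFixture()
    toy <- assembleToyGenome(fx$ds, shuffleSeed = 31L)
    rec <- scanGenome(fx$model, toy$genome)
    expect_equal(length(rec), length(fx$ds))
    expect_true(all(S4Vectors::mcols(rec)$probability >= 0 &
                        S4Vectors::mcols(rec)$probability <= 1))
    expect_identical(S4Vectors::mcols(rec)$call,
                     ifelse(S4Vectors::mcols(rec)$probability >= 0.5,
                            "DMR", "nonDMR"))
})

test_that("scan calls recover the planted classes on the toy genome", {
    fx <- scanFixture()
    toy <- assembleToyGenome(fx$ds, shuffleSeed = 32L)
    rec <- scanGenome(fx$model, toy$genome)
    truth <- toy$truth[match(paste(GenomicRanges::start(rec)),
                             paste(GenomicRanges::start(toy$truth)))]
    acc <- mean(S4Vectors::mcols(rec)$call ==
                    S4Vectors::mcols(truth)$label)
    expect_gte(acc, 0.95)
})

test_that("short and all-N chromosomes are handled totally", {
    fx <- scanFixture()
    genome <- Biostrings::DNAStringSet(c(tiny = strrep("A", 50),
                                         ok = strrep("N", 240)))
    expect_message(rec <- scanGenome(fx$model, genome), "shorter than")
    expect_equal(length(rec), 2L)   # the 240 bp all-N chromosome tiles
    expect_true(all(is.finite(S4Vectors::mcols(rec)$probability)))
})

test_that("scan summaries recompute percentages consistently", {
    fx <- scanFixture()
    toy <- assembleToyGenome(fx$ds, shuffleSeed = 33L, nChrom = 2L)
    windows <- tileWindows(toy$genome, windowSize = 120L)
    rec <- scanGenome(fx$model, windows)
    trainDmr <- windowKeys(fx$ds)[windowLabels(fx$ds) == "DMR"]
    ## training keys live on the synthetic coordinate system; use the
    ## scan's own calls as the reference instead
    truthKeys <- sprintf("%s:%d-%d",
                         as.character(GenomicRanges::seqnames(toy$truth)),
                         GenomicRanges::start(toy$truth) - 1L,
                         GenomicRanges::end(toy$truth))
    dmrKeys <- truthKeys[S4Vectors::mcols(toy$truth)$label == "DMR"]
    sm <- summarizeScan(rec, windows, trainingDmrKeys = dmrKeys)
    expect_identical(sm$chrom[nrow(sm)], "Total")
    tot <- sm[nrow(sm), ]
    expect_equal(tot$nWindows, length(rec))
    expect_equal(tot$pctGenome,
                 100 * tot$nPredictedDmr / tot$nWindows, tolerance = 1e-10)
    expect_equal(tot$pctMaxPossible,
                 100 * tot$nMaxPossible / tot$nWindows, tolerance = 1e-10)
    perChrom <- sm[sm$chrom != "Total", ]
    expect_equal(sum(perChrom$nWindows), tot$nWindows)
    expect_equal(sum(perChrom$nPredictedDmr), tot$nPredictedDmr)
    expect_equal(sum(perChrom$nMaxPossible), tot$nMaxPossible)
    ## recall of planted DMRs should be high on the separable fixture
    expect_gte(tot$pctRecallTrainingDmrs, 90)
    ## predicted DMRs should essentially be confined to CpG windows:
    ## every zero-CpG window carries no methylation substrate
    zeroCpg <- windowKeys(windows)[cpgCount(windows) == 0]
    recKeys <- sprintf("%s:%d-%d",
                       as.character(GenomicRanges::seqnames(rec)),
                       GenomicRanges::start(rec) - 1L,
                       GenomicRanges::end(rec))
    calledDmr <- recKeys[S4Vectors::mcols(rec)$call == "DMR"]
    maxPoss <- maxPossibleDmrs(windows)
    expect_lte(sum(!calledDmr %in% maxPoss), length(zeroCpg))
})

test_that("track sampling is seeded, uniform and sized by the fraction", {
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(
        start = (0:199) * 120 + 1, width = 120))
    S4Vectors::mcols(gr)$probability <- rep(c(0.9, 0.1), 100)
    S4Vectors::mcols(gr)$call <- rep(c("DMR", "nonDMR"), 100)
    s <- sampleTrack(gr, fraction = 0.02, seed = 5L)
    expect_equal(length(s), 2L)   # round(0.02 * 100)
    expect_true(all(S4Vectors::mcols(s)$call == "DMR"))
    expect_identical(sampleTrack(gr, fraction = 0.02, seed = 5L), s)
    all <- sampleTrack(gr, fraction = 1, seed = 1L)
    expect_equal(length(all), 100L)
    expect_error(sampleTrack(gr, fraction = 0), "fraction")
})

test_that("BED output follows the 6-column convention and round-trips", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = 1, width = 1000))
    S4Vectors::mcols(gr)$probability <- 0.9
    S4Vectors::mcols(gr)$call <- "DMR"
    f <- withr::local_tempfile(fileext = ".bed")
    writeScanBed(gr, f)
    expect_identical(readLines(f), "chr1\t0\t1000\tDMR\t900\t.")
    back <- rtracklayer::import(f)
    expect_equal(GenomicRanges::start(back), 1)
    expect_equal(GenomicRanges::end(back), 1000)
    ## empty record set -> empty file
    writeScanBed(gr[0], f)
    expect_length(readLines(f), 0L)
    ## unsorted input: sorted by default, an error when sort = FALSE
    gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(2001, 1), width = 1000))
    S4Vectors::mcols(gr2)$probability <- c(0.2, 0.8)
    S4Vectors::mcols(gr2)$call <- c("nonDMR", "DMR")
    expect_error(writeScanBed(gr2, f, sort = FALSE), "not coordinate-sorted")
    writeScanBed(gr2, f)
    expect_equal(length(readLines(f)), 2L)
    expect_match(readLines(f)[1], "^chr1\t0\t1000")
})
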