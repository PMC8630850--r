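## A 10-window toy genome: windows 1-2 carry DMR-grade p-values, windows
## 8-10 are CpG-free (all A), the rest hold CpGs but no significant
## p-value and stay unlabeled.
toyGenome <- function() {
    winSeqs <- c(cpgWindow(5), cpgWindow(3), cpgWindow(1), cpgWindow(2),
                 cpgWindow(4), cpgWindow(6), cpgWindow(7),
                 strrep("A", 1000), strrep("T", 1000), strrep("A", 1000))
    tileWindows(paste(winSeqs, collapse = ""), windowSize = 1000,
                chrom = "chr1")
}

toyStats <- function() {
    data.frame(chrom = "chr1", start = c(0, 1000, 2000),
               end = c(1000, 2000, 3000),
               exposure = c("atrazine", "DDT", "dioxin"),
               p_value = c(1e-6, 1e-7, 0.2), stringsAsFactors = FALSE)
}

test_that("DMR labeling is a strict threshold with union over exposures", {
    stats <- data.frame(chrom = "chr1",
                        start = c(0, 0, 1000, 2000),
                        end = c(1000, 1000, 2000, 3000),
                        exposure = c("atrazine", "DDT", "DDT", "DDT"),
                        p_value = c(1e-6, 0.5, 1e-5, 0.9))
    keys <- labelDmrs(stats)
    ## union rule: significant under atrazine alone is enough
    expect_identical(keys, "chr1:0-1000")
    ## p exactly 1e-5 is NOT a DMR (strict inequality)
    expect_false("chr1:1000-2000" %in% keys)
})

test_that("all exposure combinations for two exposures follow the union rule", {
    ## enumerate (below, above) x (below, above) for two exposures
    grid <- expand.grid(p1 = c(1e-6, 0.5), p2 = c(1e-6, 0.5))
    for (i in seq_len(nrow(grid))) {
        stats <- data.frame(chrom = "c", start = 0, end = 1000,
                            exposure = c("a", "b"),
                            p_value = c(grid$p1[i], grid$p2[i]))
        got <- length(labelDmrs(stats)) == 1L
        expect_equal(got, grid$p1[i] < 1e-5 || grid$p2[i] < 1e-5)
    }
})

test_that("duplicate (window, exposure) rows collapse to the minimum p", {
    stats <- data.frame(chrom = "c", start = 0, end = 1000,
                        exposure = "a", p_value = c(0.5, 1e-6))
    expect_warning(keys <- labelDmrs(stats), "duplicate")
    expect_identical(keys, "c:0-1000")
})

test_that("lowering the threshold never adds DMRs", {
    set.seed(5)
    stats <- data.frame(chrom = "c", start = (0:99) * 1000,
                        end = (1:100) * 1000, exposure = "a",
                        p_value = 10^stats::runif(100, -8, 0))
    prev <- labelDmrs(stats, threshold = 1e-2)
    for (thr in c(1e-3, 1e-4, 1e-5, 1e-6)) {
        cur <- labelDmrs(stats, threshold = thr)
        expect_true(all(cur %in% prev))
        prev <- cur
    }
})

test_that("negatives are exactly the zero-CpG windows", {
    gw <- toyGenome()
    neg <- selectNonDmrs(gw)
    expect_setequal(neg, c("chr1:7000-8000", "chr1:8000-9000",
                           "chr1:9000-10000"))
    ## a single CG excludes a window from the negatives
    one <- tileWindows(paste0("CG", strrep("A", 998)), windowSize = 1000)
    expect_length(selectNonDmrs(one), 0L)
    ## all-N windows have zero CpGs and count as negatives
    allN <- tileWindows(strrep("N", 1000), windowSize = 1000)
    expect_length(selectNonDmrs(allN), 1L)
    ## conflict with the DMR set is flagged and excluded
    expect_warning(neg2 <- selectNonDmrs(gw, dmrKeys = "chr1:7000-8000"),
                   "zero CpGs")
    expect_false("chr1:7000-8000" %in% neg2)
})

test_that("maximum possible DMRs are windows with 1 to 200 CpGs", {
    gw <- tileWindows(paste0(cpgWindow(0), cpgWindow(1), cpgWindow(200),
                             cpgWindow(201)), windowSize = 1000,
                      chrom = "chr1")
    keys <- maxPossibleDmrs(gw)
    expect_setequal(keys, c("chr1:1000-2000", "chr1:2000-3000"))
    ## the 10% island definition tightens the bound
    keys10 <- maxPossibleDmrs(gw, maxCpgDensityPct = 10)
    expect_setequal(keys10, "chr1:1000-2000")
})

test_that("the toy dataset is assembled from positives and zero-CpG negatives", {
    ds <- buildDataset(toyGenome(), toyStats())
    expect_s4_class(ds, "LabeledWindows")
    expect_equal(length(ds), 5L)
    cc <- classCounts(ds)
    expect_equal(unname(cc["nDmr"]), 2L)
    expect_equal(unname(cc["nNonDmr"]), 3L)
    ## the two label sets are disjoint and exclude unlabeled windows
    expect_length(intersect(windowKeys(ds)[windowLabels(ds) == "DMR"],
                            windowKeys(ds)[windowLabels(ds) == "nonDMR"]),
                  0L)
    expect_false("chr1:2000-3000" %in% windowKeys(ds))  # p = 0.2, has CpGs
})

test_that("an empty stats table yields a negatives-only dataset", {
    ds <- buildDataset(toyGenome(), stats = NULL)
    expect_equal(unname(classCounts(ds)["nDmr"]), 0L)
    expect_equal(sum(windowLabels(ds) == "nonDMR"), 3L)
})

test_that("misaligned stats coordinates are reported as errors", {
    stats <- toyStats()
    stats$start[1] <- 17
    stats$end[1] <- 1017
    expect_error(buildDataset(toyGenome(), stats), "chr1:17-1017")
})

test_that("per-chromosome subsets partition the whole-genome dataset", {
    g1 <- as.character(windowSeqs(toyGenome()))
    genome <- Biostrings::DNAStringSet(c(
        chr1 = paste(g1, collapse = ""),
        chr2 = paste(c(cpgWindow(2), strrep("A", 1000)), collapse = "")))
    gw <- tileWindows(genome)
    stats <- rbind(toyStats(),
                   data.frame(chrom = "chr2", start = 0, end = 1000,
                              exposure = "DDT", p_value = 1e-8))
    all <- buildDataset(gw, stats)
    c1 <- buildDataset(gw, stats, chrom = "chr1")
    c2 <- buildDataset(gw, stats, chrom = "chr2")
    expect_equal(length(c1) + length(c2), length(all))
    expect_setequal(c(windowKeys(c1), windowKeys(c2)), windowKeys(all))
})

test_that("label sets and the max-possible bound are mutually consistent", {
    gw <- toyGenome()
    ds <- buildDataset(gw, toyStats())
    dmr <- windowKeys(ds)[windowLabels(ds) == "DMR"]
    non <- windowKeys(ds)[windowLabels(ds) == "nonDMR"]
    maxPoss <- maxPossibleDmrs(gw)
    expect_length(intersect(non, maxPoss), 0L)
    expect_true(all(dmr %in% maxPoss))
})

test_that("optional island and high-p negatives extend the negative set", {
    gw <- tileWindows(paste0(cpgWindow(250), cpgWindow(3), cpgWindow(1),
                             strrep("A", 1000)),
                      windowSize = 1000, chrom = "chr1")
    stats <- data.frame(chrom = "chr1", start = c(1000, 2000),
                        end = c(2000, 3000), exposure = "a",
                        p_value = c(1e-6, 0.95))
    base <- buildDataset(gw, stats)
    expect_equal(sum(windowLabels(base) == "nonDMR"), 1L)
    isl <- buildDataset(gw, stats, includeCpgIslandNegatives = TRUE)
    expect_true("chr1:0-1000" %in%
                    windowKeys(isl)[windowLabels(isl) == "nonDMR"])
    hp <- buildDataset(gw, stats, includeHighPNegatives = TRUE)
    expect_true("chr1:2000-3000" %in%
                    windowKeys(hp)[windowLabels(hp) == "nonDMR"])
})

test_that("region stats reader validates schema and p-value range", {
    f <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(toyStats(), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stats <- readRegionStats(f)
    expect_identical(stats$key[1], "chr1:0-1000")
    bad <- toyStats()
    bad$p_value[1] <- 0
    utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readRegionStats(f), "p_value")
})
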