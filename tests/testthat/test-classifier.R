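## Brute-force confusion-matrix oracle used throughout.
confusionOracle <- function(yt, yp) {
    tp <- sum(yt == 1 & yp == 1); fp <- sum(yt == 0 & yp == 1)
    fn <- sum(yt == 1 & yp == 0); tn <- sum(yt == 0 & yp == 0)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    c(accuracy = (tp + tn) / length(yt), precision = prec, recall = rec,
      f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

test_that("metrics match the hand-enumerated confusion matrix", {
    m <- computeMetrics(c(1, 1, 0, 0), c(1, 0, 1, 0))  # TP=FP=FN=TN=1
    expect_equal(unname(m), rep(0.5, 4))
    perfect <- computeMetrics(c("DMR", "nonDMR"), c("DMR", "nonDMR"))
    expect_equal(unname(perfect), rep(1, 4))
    ## label encodings are interchangeable (factor, logical, 0/1)
    lab <- factor(c("DMR", "DMR", "nonDMR"), levels = c("nonDMR", "DMR"))
    expect_equal(computeMetrics(lab, c(TRUE, FALSE, TRUE)),
                 computeMetrics(c(1, 1, 0), c(1, 0, 1)))
    expect_error(computeMetrics(c("DMR", "weird"), c("DMR", "DMR")),
                 "labels must be")
    expect_error(computeMetrics(c(1, 0), c(1)), "equal length")
    expect_error(computeMetrics(numeric(), numeric()), "at least one")
    ## degenerate cases report 0 with a note
    expect_message(z <- computeMetrics(c(1, 1), c(0, 0)), "precision")
    expect_equal(unname(z[c("precision", "recall", "f1")]), c(0, 0, 0))
})

test_that("metrics agree with the brute-force oracle on random labelings", {
    set.seed(3)
    for (i in 1:1000) {
        n <- sample(1:50, 1)
        yt <- stats::rbinom(n, 1, 0.5)
        yp <- stats::rbinom(n, 1, 0.5)
        expect_equal(suppressMessages(computeMetrics(yt, yp)),
                     confusionOracle(yt, yp))
    }
})

test_that("the harmonic-mean F1 reproduces published reference rows", {
    ref <- ratCvReference()
    for (ch in c("chr1", "chr2", "chr5", "chr12")) {
        row <- ref[ref$chrom == ch, ]
        ## precision/recall are printed rounded to 4 dp, so the recomputed
        ## F1 can only be expected to agree to that printed precision
        expect_lt(abs(f1Score(row$precision, row$recall) - row$f1), 1e-4)
    }
    ## the half-product-over-sum variant does NOT reproduce the table
    halfF1 <- function(p, r) 0.5 * p * r / (p + r)
    row <- ref[ref$chrom == "chr1", ]
    expect_gt(abs(round(halfF1(row$precision, row$recall), 4) - row$f1),
              0.4)
})

test_that("boosted classifier separates informative features", {
    set.seed(21)
    n <- 200
    y <- rep(c(1, 0), each = n / 2)
    x <- matrix(stats::rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 0:5)))
    x[, 4] <- x[, 4] + 3 * y
    bst <- trainClassifier(x, y, seed = 5)
    acc <- mean((predictClassifier(bst, x) >= 0.5) == y)
    expect_gte(acc, 0.99)
})

test_that("constant features fall back to the majority class", {
    y <- rep(c(1, 0), c(30, 70))
    x <- matrix(1, 100, 4, dimnames = list(NULL, paste0("f", 0:3)))
    ## no usable splits: without the imbalance weight the ensemble must
    ## predict the majority class everywhere
    bst <- trainClassifier(x, y, params = list(scale_pos_weight = 1),
                           seed = 2)
    p <- predictClassifier(bst, x)
    expect_true(all((p >= 0.5) == FALSE))
    expect_equal(length(unique(p)), 1L)
})

test_that("classifier training is deterministic and validates input", {
    set.seed(8)
    x <- matrix(stats::rnorm(300), 100, 3,
                dimnames = list(NULL, paste0("f", 0:2)))
    y <- stats::rbinom(100, 1, 0.5)
    p1 <- predictClassifier(trainClassifier(x, y, seed = 7), x)
    p2 <- predictClassifier(trainClassifier(x, y, seed = 7), x)
    expect_identical(p1, p2)
    expect_error(trainClassifier(matrix(0, 0, 3), integer()), "non-empty")
    expect_error(trainClassifier(x, rep(1, 100)), "both classes")
})

test_that("gain importance ranks the informative feature first", {
    set.seed(31)
    n <- 300
    y <- stats::rbinom(n, 1, 0.5)
    x <- matrix(stats::rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("f", 0:7)))
    x[, 4] <- x[, 4] + 2.5 * y            # feature f3 carries the signal
    bst <- trainClassifier(x, y, seed = 1)
    imp <- featureImportance(bst, featureNames = colnames(x))
    expect_equal(imp$feature[1], "f3")
    expect_setequal(imp$featureId, 0:7)
    expect_false(is.unsorted(rev(imp$gain)))
    expect_true(all(imp$gain >= 0))
})

test_that("pure-noise features spread importance without a dominant winner", {
    set.seed(77)
    n <- 400
    y <- stats::rbinom(n, 1, 0.5)
    x <- matrix(stats::rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("f", 0:7)))
    bst <- trainClassifier(x, y, seed = 3)
    imp <- featureImportance(bst, featureNames = colnames(x))
    expect_lte(max(imp$gain), 3 * stats::median(imp$gain))
})

test_that("stratified cross-validation partitions cleanly and without leakage", {
    ds <- tinyDataset(nPerClass = 25L)
    rep <- crossValidate(ds, k = 5L, spec = tinyNetworkSpec(seed = 2L),
                         dlEpochs = 2L, nrounds = 30L, seed = 12L)
    expect_s4_class(rep, "CVReport")
    folds <- rep@foldAssignments
    expect_length(folds, 50L)
    sizes <- table(folds)
    expect_equal(length(sizes), 5L)
    expect_lte(max(sizes) - min(sizes), 1L)
    ## stratification: each fold holds both classes
    lab <- windowLabels(ds)[match(names(folds), windowKeys(ds))]
    strat <- table(folds, lab)
    expect_true(all(strat > 0))
    ## leakage audit: every window is tested exactly once, in its own fold
    expect_setequal(names(folds), windowKeys(ds))
    expect_equal(sum(sizes), length(ds))
    ## the mean is the arithmetic mean of the folds
    expect_equal(rep@mean[["accuracy"]], mean(rep@perFold$accuracy))
    expect_equal(rep@nDmr + rep@nNonDmr, 50L)
})

test_that("cross-validation refuses classes smaller than k", {
    ds <- tinyDataset(nPerClass = 3L)
    expect_error(crossValidate(ds, k = 5L), "at least k")
})

test_that("chromosome summaries average accuracies unweighted", {
    ref <- ratCvReference()
    sm <- summarizeChromosomeCv(ref)
    ## 22 per-chromosome models; the pooled All row is excluded
    expect_equal(sum(!(toupper(sm$table$chrom) %in% "ALL")), 22L)
    expect_equal(round(100 * sm$meanAccuracy, 2), 95.14)
    two <- summarizeChromosomeCv(data.frame(chrom = c("chr1", "chr2"),
                                            accuracy = c(0.9, 1.0)))
    expect_equal(two$meanAccuracy, 0.95)
    one <- summarizeChromosomeCv(data.frame(chrom = "chr1",
                                            accuracy = 0.97))
    expect_equal(one$meanAccuracy, 0.97)
})

test_that("chromosome summaries accept CVReport lists and write TSV", {
    ds <- tinyDataset(nPerClass = 12L)
    r <- crossValidate(ds, k = 3L, spec = tinyNetworkSpec(seed = 4L),
                       dlEpochs = 1L, nrounds = 20L, seed = 3L)
    f <- withr::local_tempfile(fileext = ".tsv")
    sm <- summarizeChromosomeCv(list(chrA = r, chrB = r), path = f)
    expect_equal(sm$meanAccuracy, r@mean[["accuracy"]])
    tab <- utils::read.delim(f)
    expect_identical(tab$chrom, c("chrA", "chrB"))
    expect_identical(names(tab),
                     c("chrom", "nNonDmr", "nDmr", "accuracy", "f1",
                       "precision", "recall"))
})
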