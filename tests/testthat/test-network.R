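test_that("the default architecture matches the published configuration", {
    net <- buildNetwork(networkSpec(), inputLength = 1000)
    shp <- networkShapes(net)
    ## block structure: conv(valid) bn relu conv(same) bn relu pool dropout
    blockTypes <- c("conv", "bn", "relu", "conv", "bn", "relu", "pool",
                    "dropout")
    expect_identical(shp$type,
                     c(blockTypes, blockTypes, "flatten", "dense", "dense",
                       "dense"))
    ## first conv: 32 kernels with a 5 x 20 receptive field -> 3232 params
    expect_equal(shp$nParams[1], 32 * 5 * 20 + 32)
    expect_equal(shp$channels[1], 32)
    expect_equal(shp$length[1], 981)        # 1000 - 20 + 1, valid
    expect_equal(shp$length[4], 981)        # same padding preserves length
    expect_equal(shp$length[7], 490)        # pool 2
    expect_equal(shp$channels[9], 64)
    expect_equal(shp$length[9], 471)        # 490 - 20 + 1, valid
    expect_equal(shp$length[15], 235)       # pool 2
    expect_equal(shp$channels[17], 64 * 235)  # flatten
    expect_equal(shp$channels[18:20], c(256, 128, 2))
    k <- conv1Kernels(net)
    expect_identical(dim(k), c(5L, 20L, 32L))
})

test_that("block1 filter count propagates to the feature dimension", {
    net16 <- buildNetwork(networkSpec(blockFilters = c(16L, 64L)),
                          inputLength = 1000)
    expect_identical(dim(conv1Kernels(net16))[3], 16L)
    ds <- tinyDataset(nPerClass = 4L)
    net <- buildNetwork(tinyNetworkSpec(), inputLength = 120)
    expect_equal(ncol(reexpress(net, ds)), 4L)
})

test_that("a one-block spec collapses to a single conv-pool block", {
    net <- buildNetwork(networkSpec(nBlocks = 1L, blockFilters = 8L),
                        inputLength = 1000)
    shp <- networkShapes(net)
    expect_equal(sum(shp$type == "pool"), 1L)
    expect_equal(sum(shp$type == "conv"), 2L)
})

test_that("too-short inputs are rejected with the computed minimum", {
    spec <- networkSpec()
    expect_error(buildNetwork(spec, inputLength = 50),
                 "minimum input length")
    ## the reported minimum is itself buildable
    minLen <- hybridDMR:::.minInputLength(spec)
    expect_s4_class(buildNetwork(spec, inputLength = minLen),
                    "TrainedNetwork")
})

test_that("softmax head yields complementary class probabilities", {
    ds <- tinyDataset(nPerClass = 8L)
    net <- buildNetwork(tinyNetworkSpec(), inputLength = 120)
    enc <- oneHotEncode(ds)
    fw <- hybridDMR:::.nnForward(net@layers, enc, training = FALSE)
    probs <- hybridDMR:::.softmax(fw$out)
    expect_equal(unname(colSums(probs)), rep(1, length(ds)))
    expect_true(all(probs >= 0 & probs <= 1))
    p <- predictDL(net, ds)
    expect_equal(p, probs[2L, ])
})

test_that("training is bit-reproducible for a fixed seed", {
    ds <- tinyDataset(nPerClass = 20L)
    spec <- tinyNetworkSpec(seed = 7L)
    n1 <- trainNetwork(ds, spec, maxEpochs = 4L)
    n2 <- trainNetwork(ds, spec, maxEpochs = 4L)
    expect_identical(n1@history, n2@history)
    expect_identical(n1@layers, n2@layers)
    n3 <- trainNetwork(ds, spec, maxEpochs = 4L, seed = 8L)
    expect_false(identical(n1@history, n3@history))
})

test_that("the network learns a separable planted-motif fixture", {
    ds <- tinyDataset(nPerClass = 150L, mutationRate = 0)
    ## patience spans the epoch cap: the claim under test is that the
    ## network can fit a separable set, not where validation loss
    ## bottoms out on a 30-window split
    net <- trainNetwork(ds, tinyNetworkSpec(seed = 3L, maxEpochs = 100L,
                                            earlyStopPatience = 100L,
                                            validationFraction = 0.1))
    p <- predictDL(net, ds)
    acc <- mean((p >= 0.5) == (windowLabels(ds) == "DMR"))
    expect_gte(acc, 0.99)
})

test_that("shuffled labels collapse validation accuracy to chance", {
    ds <- tinyDataset(nPerClass = 40L)
    set.seed(99)
    shuffled <- ds
    shuffled@labels <- sample(ds@labels)
    net <- trainNetwork(shuffled, tinyNetworkSpec(seed = 5L),
                        maxEpochs = 6L)
    lastValAcc <- utils::tail(net@history$valAccuracy, 1)
    expect_lt(abs(lastValAcc - 0.5), 0.2)
})

test_that("early stopping halts within patience of the best epoch", {
    ds <- tinyDataset(nPerClass = 30L)
    spec <- tinyNetworkSpec(seed = 2L, earlyStopPatience = 3L)
    net <- trainNetwork(ds, spec, maxEpochs = 25L)
    best <- which.min(net@history$valLoss)
    expect_lte(nrow(net@history), best + spec@earlyStopPatience)
})

test_that("prediction is batch-invariant", {
    ds <- tinyDataset(nPerClass = 10L)
    net <- trainNetwork(ds, tinyNetworkSpec(seed = 4L), maxEpochs = 3L)
    pAll <- predictDL(net, ds)
    pOne <- predictDL(net, ds[3L])
    expect_equal(pOne, pAll[3L])
    pSmallBatch <- predictDL(net, ds, batchSize = 3L)
    expect_equal(pSmallBatch, pAll)
})

test_that("degenerate training inputs are rejected", {
    ds <- tinyDataset(nPerClass = 10L)
    onlyPos <- ds[which(windowLabels(ds) == "DMR")]
    expect_error(trainNetwork(onlyPos, tinyNetworkSpec()), "both classes")
    expect_error(predictDL(trainNetwork(ds, tinyNetworkSpec(),
                                        maxEpochs = 1L),
                           oneHotEncode(strrep("A", 60))),
                 "does not match")
})

test_that("network spec validity bounds are enforced", {
    expect_error(networkSpec(nBlocks = 6L), "nBlocks")
    expect_error(networkSpec(dropoutRate = 1), "dropoutRate")
    expect_error(networkSpec(validationFraction = 0.9),
                 "validationFraction")
    expect_error(networkSpec(blockFilters = c(8L, 8L, 8L)), "one entry")
})
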