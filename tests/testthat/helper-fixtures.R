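## Shared small fixtures: a reduced network spec and dataset that train in
## seconds, plus a hand-built single-kernel network with an identity
## batchnorm, used as a transparent convolution oracle target.

tinyNetworkSpec <- function(seed = 1L, ...) {
    args <- utils::modifyList(
        list(nBlocks = 1L, blockFilters = 4L, kernelSize = 8L,
             denseSizes = c(16L, 8L), batchSize = 16L, maxEpochs = 60L,
             learningRate = 5e-3, dropoutRate = 0.2,
             earlyStopPatience = 10L, validationFraction = 0.2,
             seed = seed),
        list(...))
    do.call(networkSpec, args)
}

tinySyntheticSpec <- function(seed = 11L, nPerClass = 60L,
                              mutationRate = 0, ...) {
    syntheticSpec(nPerClass = nPerClass, windowSize = 120L,
                  motifs = "TCACGTGA", mutationRate = mutationRate,
                  posCpgRate = 3, seed = seed, ...)
}

tinyDataset <- function(...) generateDataset(tinySyntheticSpec(...))

## A 1-kernel, 1-block network whose first conv stage is transparent:
## batchnorm is set to the identity (running mean 0, running var 1 - eps,
## gamma 1, beta 0), so conv1 activations equal relu(W * x + b).
indicatorNetwork <- function(W, b = 0, inputLength = 25L) {
    stopifnot(is.matrix(W), nrow(W) == 5L)
    K <- ncol(W)
    spec <- networkSpec(nBlocks = 1L, blockFilters = 1L,
                        kernelSize = as.integer(K),
                        denseSizes = c(4L, 2L), seed = 1L)
    net <- buildNetwork(spec, inputLength = inputLength)
    lys <- net@layers
    lys[[1L]]$W <- array(as.numeric(t(W)), c(1L, 5L, K))
    ## W slot layout is (filters, channels, offsets): fill from the 5 x K
    ## matrix so that lys[[1]]$W[1, c, k] == W[c, k]
    for (k in seq_len(K)) lys[[1L]]$W[1L, , k] <- W[, k]
    lys[[1L]]$b <- as.numeric(b)
    lys[[2L]]$gamma <- sqrt(1)  # keep gamma 1
    lys[[2L]]$runMean <- 0
    lys[[2L]]$runVar <- 1 - hybridDMR:::.BN_EPS
    methods::initialize(net, layers = lys)
}

## Brute-force sliding dot product + ReLU: the convolution oracle.
slidingDotOracle <- function(seqChar, W, b = 0) {
    x <- oneHotEncode(seqChar)
    K <- ncol(W)
    L <- ncol(x)
    vapply(seq_len(L - K + 1L), function(t)
        max(0, sum(W * x[, t:(t + K - 1L)]) + b), numeric(1))
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Windows with an exact CpG count: k copies of "CG" then A padding.
cpgWindow <- function(k, windowSize = 1000L) {
    paste0(strrep("CG", k), strrep("A", windowSize - 2L * k))
}
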