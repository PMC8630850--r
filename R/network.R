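#' @include AllClasses.R nn-layers.R
NULL

#' Construct a network specification
#'
#' Returns a \linkS4class{NetworkSpec} with the published defaults: two
#' convolutional blocks (32 and 64 filters, kernel size 20, two
#' convolutions per block with the first unpadded and the second
#' length-preserving, batch normalization then ReLU after each, max
#' pooling of 2 and dropout 0.4 per block), dense layers of 256 and 128
#' nodes, and a two-node softmax head trained with cross-entropy, Adam,
#' and early stopping with patience 5 on the validation loss. Learning
#' rate, batch size and the epoch cap are not part of the published
#' configuration; the defaults (5e-4, 64, 100) are chosen for stable,
#' fast convergence of this architecture on a single CPU.
#'
#' @param nBlocks Number of conv blocks (1-5).
#' @param blockFilters Integer vector of filters per block.
#' @param kernelSize Convolution kernel width (bp).
#' @param poolSize Max-pooling width.
#' @param dropoutRate Dropout rate at the end of each block.
#' @param denseSizes Sizes of the dense layers before the output.
#' @param outputNodes Output nodes (2: nonDMR, DMR).
#' @param learningRate Adam learning rate.
#' @param batchSize Minibatch size.
#' @param maxEpochs Epoch cap.
#' @param earlyStopPatience Epochs without validation-loss improvement
#'   before stopping.
#' @param validationFraction Fraction of the training data held out
#'   (stratified) to monitor the validation loss.
#' @param classWeighting Weight each example by n_total / (2 n_class) to
#'   counter class imbalance.
#' @param seed Integer seed controlling initialization, shuffling,
#'   dropout and the validation split.
#' @return A \linkS4class{NetworkSpec}.
#' @examples
#' networkSpec()
#' networkSpec(nBlocks = 1L, blockFilters = 8L, kernelSize = 8L)
#' @export
networkSpec <- function(nBlocks = 2L, blockFilters = c(32L, 64L),
                        kernelSize = 20L, poolSize = 2L, dropoutRate = 0.4,
                        denseSizes = c(256L, 128L), outputNodes = 2L,
                        learningRate = 5e-4, batchSize = 64L,
                        maxEpochs = 100L, earlyStopPatience = 5L,
                        validationFraction = 0.1, classWeighting = TRUE,
                        seed = 1L) {
    new("NetworkSpec", nBlocks = as.integer(nBlocks),
        blockFilters = as.integer(blockFilters),
        kernelSize = as.integer(kernelSize),
        poolSize = as.integer(poolSize),
        dropoutRate = as.numeric(dropoutRate),
        denseSizes = as.integer(denseSizes),
        outputNodes = as.integer(outputNodes),
        learningRate = as.numeric(learningRate),
        batchSize = as.integer(batchSize),
        maxEpochs = as.integer(maxEpochs),
        earlyStopPatience = as.integer(earlyStopPatience),
        validationFraction = as.numeric(validationFraction),
        classWeighting = as.logical(classWeighting),
        seed = as.integer(seed))
}

#' Build an untrained network
#'
#' Instantiates the layer stack of a \linkS4class{NetworkSpec} for a given
#' input length, with variance-scaling (He) random initialization seeded
#' by \code{spec@seed}. The result is a \linkS4class{TrainedNetwork} with
#' an empty history; it is usable immediately (random features) or can be
#' passed to [trainNetwork()].
#'
#' @param spec A \linkS4class{NetworkSpec}.
#' @param inputLength Window length in bp (default 1000).
#' @return A \linkS4class{TrainedNetwork} with untrained weights.
#' @examples
#' net <- buildNetwork(networkSpec(), inputLength = 1000)
#' networkShapes(net)
#' @export
buildNetwork <- function(spec, inputLength = 1000L) {
    validObject(spec)
    set.seed(spec@seed)
    layers <- .buildLayers(spec, as.integer(inputLength))
    new("TrainedNetwork", spec = spec, layers = layers,
        inputLength = as.integer(inputLength),
        history = data.frame(epoch = integer(), loss = numeric(),
                             valLoss = numeric(), valAccuracy = numeric()))
}

#' Per-layer structural summary
#'
#' Returns the layer sequence with output shapes and trainable parameter
#' counts, for auditing the architecture (e.g. the first convolution of
#' the default spec has 32 kernels of receptive field 5 x 20 and
#' 32*5*20 + 32 = 3232 parameters, and an activation map of length
#' 1000 - 20 + 1 = 981).
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @return data.frame with columns \code{layer}, \code{type},
#'   \code{channels}, \code{length}, \code{nParams}.
#' @export
networkShapes <- function(network) {
    stopifnot(is(network, "TrainedNetwork"))
    C <- 5L; Tcur <- network@inputLength
    rows <- lapply(seq_along(network@layers), function(i) {
        ly <- network@layers[[i]]
        if (ly$type == "conv") {
            if (ly$pad == "valid") Tcur <<- Tcur - dim(ly$W)[3L] + 1L
            C <<- dim(ly$W)[1L]
        } else if (ly$type == "pool") {
            Tcur <<- Tcur %/% ly$size
        } else if (ly$type == "flatten") {
            C <<- C * Tcur; Tcur <<- 1L
        } else if (ly$type == "dense") {
            C <<- nrow(ly$W)
        }
        data.frame(layer = i, type = ly$type, channels = C, length = Tcur,
                   nParams = .layerParamCount(ly))
    })
    do.call(rbind, rows)
}

## Encode a LabeledWindows dataset once: one-hot array + class index (1 =
## nonDMR, 2 = DMR) + per-example weights.
.encodeDataset <- function(dataset, classWeighting) {
    X <- oneHotEncode(dataset)
    y <- as.integer(dataset@labels)          # 1 nonDMR, 2 DMR
    w <- rep(1, length(y))
    if (classWeighting) {
        tab <- tabulate(y, nbins = 2L)
        w <- length(y) / (2 * tab[y])
    }
    list(X = X, y = y, w = w)
}

## Stratified index split: returns validation indices.
.stratifiedHoldout <- function(y, fraction) {
    unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        nVal <- max(1L, round(fraction * length(idx)))
        sample(idx, nVal)
    }), use.names = FALSE)
}

#' Train the convolutional network
#'
#' Trains the network with minibatch Adam on softmax cross-entropy.
#' A stratified fraction of the data is held out to monitor the
#' validation loss; training stops when it has not improved for
#' \code{spec@earlyStopPatience} epochs (or at \code{maxEpochs}), and the
#' weights from the best-validation-loss epoch are restored. All
#' randomness (initialization, the split, shuffling, dropout) derives
#' from \code{seed}, so identical calls give identical histories.
#'
#' @param dataset A \linkS4class{LabeledWindows} with both classes.
#' @param spec A \linkS4class{NetworkSpec} (default [networkSpec()]).
#' @param network Optional pre-built \linkS4class{TrainedNetwork} to
#'   continue from; built from \code{spec} if NULL.
#' @param maxEpochs Optional override of \code{spec@maxEpochs}.
#' @param seed Optional override of \code{spec@seed}.
#' @param verbose Print per-epoch losses.
#' @return A \linkS4class{TrainedNetwork}.
#' @export
trainNetwork <- function(dataset, spec = networkSpec(), network = NULL,
                         maxEpochs = NULL, seed = NULL, verbose = FALSE) {
    stopifnot(is(dataset, "LabeledWindows"))
    if (nlevels(droplevels(dataset@labels)) < 2L)
        stop("dataset must contain both classes")
    if (is.null(seed)) seed <- spec@seed
    if (is.null(maxEpochs)) maxEpochs <- spec@maxEpochs
    set.seed(seed)
    if (is.null(network)) {
        layers <- .buildLayers(spec, windowSize(dataset))
    } else {
        stopifnot(is(network, "TrainedNetwork"))
        spec <- network@spec
        layers <- network@layers
    }
    enc <- .encodeDataset(dataset, spec@classWeighting)
    n <- length(enc$y)
    valIdx <- .stratifiedHoldout(enc$y, spec@validationFraction)
    trIdx <- setdiff(seq_len(n), valIdx)
    Xval <- enc$X[, , valIdx, drop = FALSE]
    yval <- enc$y[valIdx]
    wval <- enc$w[valIdx]

    state <- .adamInit(layers)
    bestLoss <- Inf
    bestLayers <- layers
    sinceBest <- 0L
    hist <- vector("list", maxEpochs)
    t <- 0L
    for (epoch in seq_len(maxEpochs)) {
        ord <- sample(trIdx)
        batchLoss <- 0
        nb <- 0L
        for (bStart in seq(1L, length(ord), by = spec@batchSize)) {
            bi <- ord[bStart:min(bStart + spec@batchSize - 1L, length(ord))]
            fw <- .nnForward(layers, enc$X[, , bi, drop = FALSE],
                             training = TRUE)
            layers <- fw$layers
            sl <- .softmaxLoss(fw$out, enc$y[bi], enc$w[bi])
            if (!is.finite(sl$loss))
                stop("non-finite training loss at epoch ", epoch)
            grads <- .nnBackward(layers, fw$caches, sl$dZ)
            t <- t + 1L
            ad <- .adamStep(layers, grads, state, spec@learningRate, t)
            layers <- ad$layers
            state <- ad$state
            batchLoss <- batchLoss + sl$loss
            nb <- nb + 1L
        }
        vf <- .nnForward(layers, Xval, training = FALSE)
        vl <- .softmaxLoss(vf$out, yval, wval)
        valAcc <- mean(apply(vf$out, 2L, which.max) == yval)
        hist[[epoch]] <- data.frame(epoch = epoch, loss = batchLoss / nb,
                                    valLoss = vl$loss, valAccuracy = valAcc)
        if (verbose)
            message(sprintf("epoch %d  loss %.4f  val %.4f  acc %.3f",
                            epoch, batchLoss / nb, vl$loss, valAcc))
        if (vl$loss < bestLoss) {
            bestLoss <- vl$loss
            bestLayers <- layers
            sinceBest <- 0L
        } else {
            sinceBest <- sinceBest + 1L
            if (sinceBest >= spec@earlyStopPatience) break
        }
    }
    new("TrainedNetwork", spec = spec, layers = bestLayers,
        inputLength = windowSize(dataset),
        history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
}

## Coerce predict inputs to a (5, T, B) array.
.asOneHotBatch <- function(x, inputLength) {
    if (is(x, "GenomeWindows")) x <- oneHotEncode(x)
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    if (!is.array(x) || length(dim(x)) != 3L || dim(x)[1L] != 5L)
        stop("input must be windows or a 5 x L (x n) one-hot array")
    if (dim(x)[2L] != inputLength)
        stop("input length ", dim(x)[2L], " does not match the network's ",
             inputLength)
    x
}

#' DMR probabilities from the network's softmax head
#'
#' Runs the network in inference mode (batchnorm running statistics, no
#' dropout) and returns the softmax probability of the DMR class per
#' window; the call is DMR when the probability is at least 0.5.
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @param x \linkS4class{GenomeWindows}, a 5 x L one-hot matrix, or a
#'   5 x L x n array.
#' @param batchSize Windows scored per forward pass.
#' @return Numeric vector of DMR probabilities.
#' @export
predictDL <- function(network, x, batchSize = 256L) {
    stopifnot(is(network, "TrainedNetwork"))
    X <- .asOneHotBatch(x, network@inputLength)
    n <- dim(X)[3L]
    probs <- numeric(n)
    for (bStart in seq(1L, n, by = batchSize)) {
        bi <- bStart:min(bStart + batchSize - 1L, n)
        fw <- .nnForward(network@layers, X[, , bi, drop = FALSE],
                         training = FALSE)
        probs[bi] <- .softmax(fw$out)[2L, ]
    }
    probs
}

#' First-convolution-layer kernels
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @return Array (5, kernelSize, nFilters): one 5 x kernelSize weight
#'   matrix per learned sequence detector, rows ordered A, C, G, T, N.
#' @export
conv1Kernels <- function(network) {
    stopifnot(is(network, "TrainedNetwork"))
    W <- network@layers[[1L]]$W                  # (F, 5, K)
    aperm(W, c(2L, 3L, 1L))
}
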