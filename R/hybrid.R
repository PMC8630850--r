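#' @include classifier.R
NULL

#' Train the full hybrid model
#'
#' Trains the convolutional network on the dataset, re-expresses every
#' window as pooled first-conv-layer features, and fits the boosted-tree
#' classifier on those features. The returned model makes its predictions
#' through the boosted stage (the hybrid path), not the network's softmax
#' head.
#'
#' @param dataset A \linkS4class{LabeledWindows} with both classes.
#' @param spec \linkS4class{NetworkSpec} for the network stage.
#' @param dlEpochs Optional epoch cap override for network training.
#' @param nrounds,xgbParams Passed to [trainClassifier()].
#' @param pooling Feature pooling ("mean", the default, or "max").
#' @param seed Seed for both stages.
#' @return A \linkS4class{HybridModel}.
#' @export
trainHybrid <- function(dataset, spec = networkSpec(), dlEpochs = NULL,
                        nrounds = 200L, xgbParams = list(),
                        pooling = "mean", seed = spec@seed) {
    network <- trainNetwork(dataset, spec = spec, maxEpochs = dlEpochs,
                            seed = seed)
    feats <- reexpress(network, dataset, pooling)
    booster <- trainClassifier(feats, dataset@labels, nrounds = nrounds,
                               params = xgbParams, seed = seed)
    new("HybridModel", network = network, booster = booster,
        pooling = pooling, featureNames = colnames(feats))
}

#' Predict DMR probabilities with the hybrid model
#'
#' Re-expresses the windows through the model's first convolution layer
#' and scores the pooled features with the boosted classifier.
#'
#' @param model A \linkS4class{HybridModel}.
#' @param windows \linkS4class{GenomeWindows} (or subclass) or a one-hot
#'   array.
#' @param batchSize Windows per forward pass.
#' @return Numeric vector of DMR probabilities in [0, 1].
#' @export
predictHybrid <- function(model, windows, batchSize = 256L) {
    stopifnot(is(model, "HybridModel"))
    feats <- reexpress(model@network, windows, model@pooling,
                       batchSize = batchSize)
    predictClassifier(model@booster, feats)
}
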