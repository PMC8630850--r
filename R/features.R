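#' @include network.R
NULL

## Index of the layer after which conv1 features are taken: the first
## convolution's batchnorm + ReLU output, before any pooling.
.conv1StopIndex <- function(layers) {
    stopifnot(layers[[1L]]$type == "conv", layers[[2L]]$type == "bn",
              layers[[3L]]$type == "relu")
    3L
}

#' First-convolution-layer activation maps
#'
#' Computes the output of the first convolution layer after its batch
#' normalization (inference statistics) and ReLU -- the layer whose
#' kernels define the extracted features -- before any pooling. For the
#' default spec on 1000 bp input the map is 32 kernels x 981 positions
#' (valid convolution: 1000 - 20 + 1) and all entries are non-negative.
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @param x A \linkS4class{GenomeWindows}, 5 x L one-hot matrix, or
#'   5 x L x n array.
#' @return A (nKernels, L - kernelSize + 1) matrix for a single window,
#'   or an array with a third dimension over windows.
#' @export
conv1Activations <- function(network, x) {
    stopifnot(is(network, "TrainedNetwork"))
    single <- is.matrix(x) ||
        (is(x, "GenomeWindows") && length(x) == 1L)
    X <- .asOneHotBatch(x, network@inputLength)
    fw <- .nnForward(network@layers, X, training = FALSE,
                     stopAfter = .conv1StopIndex(network@layers))
    A <- fw$out
    if (single) {
        d <- dim(A)
        dim(A) <- d[1:2]
    }
    A
}

#' Pool an activation map into one value per kernel
#'
#' Collapses per-position activations into a single feature per kernel.
#' The default, a global mean, reads as motif density over the window
#' and mirrors the average-output convention used to categorize detector
#' kernels; \code{"max"} reads as motif presence anywhere in the window
#' and is invariant to the motif's position. Mean is the default because
#' density is what separates the classes here (CpG-free negatives versus
#' CpG-bearing positives); a global maximum is an extreme-value statistic
#' over roughly a thousand positions and loses most of that signal.
#'
#' @param map A (nKernels, positions) activation matrix, or the 3-d batch
#'   form from [conv1Activations()].
#' @param method \code{"mean"} (default) or \code{"max"}.
#' @return Numeric vector of length nKernels (or a matrix
#'   windows x nKernels for batch input).
#' @export
poolFeatures <- function(map, method = c("mean", "max")) {
    method <- match.arg(method)
    f <- if (method == "max") max else mean
    if (is.matrix(map)) return(apply(map, 1L, f))
    stopifnot(length(dim(map)) == 3L)
    t(apply(map, c(1L, 3L), f))
}

#' Re-express windows as DL feature vectors
#'
#' Runs every window through the first convolution layer and pools each
#' kernel's activation map, yielding the feature matrix (one row per
#' window, one column per kernel, named f0..f31 for the default spec)
#' that the boosted classifier consumes. Deterministic given the trained
#' network; row order follows the input.
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @param windows A \linkS4class{GenomeWindows} (or subclass), or a one-hot
#'   array.
#' @param pooling \code{"mean"} (default) or \code{"max"}.
#' @param batchSize Windows per forward pass (bounds memory).
#' @return Numeric matrix n x nKernels; rownames are window keys when the
#'   input carries them.
#' @export
reexpress <- function(network, windows, pooling = c("mean", "max"),
                      batchSize = 256L) {
    pooling <- match.arg(pooling)
    stopifnot(is(network, "TrainedNetwork"))
    X <- .asOneHotBatch(windows, network@inputLength)
    n <- dim(X)[3L]
    nF <- dim(network@layers[[1L]]$W)[1L]
    out <- matrix(0, nrow = n, ncol = nF,
                  dimnames = list(NULL, paste0("f", seq_len(nF) - 1L)))
    stopIdx <- .conv1StopIndex(network@layers)
    for (bStart in seq(1L, n, by = batchSize)) {
        bi <- bStart:min(bStart + batchSize - 1L, n)
        fw <- .nnForward(network@layers, X[, , bi, drop = FALSE],
                         training = FALSE, stopAfter = stopIdx)
        out[bi, ] <- poolFeatures(fw$out, pooling)
    }
    if (is(windows, "GenomeWindows")) rownames(out) <- windowKeys(windows)
    out
}

#' Categorize kernels as DMR or non-DMR detectors
#'
#' For each first-layer kernel, computes the mean pooled activation over
#' the DMR examples minus the mean over the non-DMR examples. A kernel
#' with a positive difference fires preferentially on DMRs and is a
#' DMR detector; a negative difference marks a non-DMR detector (an exact
#' zero is assigned non-DMR with a note). Results are sorted by
#' decreasing activation difference.
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @param dataset A \linkS4class{LabeledWindows} with both classes.
#' @param pooling Pooling used for the per-window feature value.
#' @param features Optional precomputed feature matrix from
#'   [reexpress()] (rows aligned with \code{dataset}).
#' @return data.frame with columns \code{featureId} (0-based kernel
#'   index), \code{detectorClass} ("DMR-detector" or "nonDMR-detector"),
#'   \code{activationDifference}.
#' @export
classifyDetectors <- function(network, dataset,
                              pooling = c("mean", "max"),
                              features = NULL) {
    pooling <- match.arg(pooling)
    stopifnot(is(dataset, "LabeledWindows"))
    if (nlevels(droplevels(dataset@labels)) < 2L)
        stop("dataset must contain both classes")
    if (is.null(features))
        features <- reexpress(network, dataset, pooling)
    isDmr <- dataset@labels == "DMR"
    diff <- colMeans(features[isDmr, , drop = FALSE]) -
        colMeans(features[!isDmr, , drop = FALSE])
    if (any(diff == 0))
        message(sum(diff == 0), " kernel(s) with zero activation ",
                "difference assigned to the non-DMR class")
    out <- data.frame(
        featureId = seq_along(diff) - 1L,
        detectorClass = ifelse(diff > 0, "DMR-detector", "nonDMR-detector"),
        activationDifference = unname(diff),
        stringsAsFactors = FALSE)
    out[order(-out$activationDifference), , drop = FALSE]
}

#' Export a feature matrix as TSV
#'
#' @param features Matrix from [reexpress()].
#' @param path Output path.
#' @param labels Optional label factor appended as a final column.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTsv <- function(features, path, labels = NULL) {
    df <- data.frame(key = if (is.null(rownames(features)))
        seq_len(nrow(features)) else rownames(features),
        features, check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(labels)) df$label <- as.character(labels)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
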