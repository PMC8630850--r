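#' @include AllClasses.R
NULL

#' Accessors for window objects
#'
#' \code{windowRanges} returns the coordinates as a \code{GRanges};
#' \code{windowSeqs} the sequences as a \code{DNAStringSet};
#' \code{windowSize} the common width; \code{windowKeys} a character key
#' per window in 0-based half-open form (\code{"chrom:start-end"});
#' \code{windowLabels} the class factor and \code{classCounts} the tally
#' per class for labeled sets.
#'
#' @param x A \linkS4class{GenomeWindows} (or subclass) object.
#' @return See the per-function description.
#' @examples
#' gw <- tileWindows(Biostrings::DNAStringSet(c(chrT = paste(
#'     rep("ACGTA", 40), collapse = ""))), windowSize = 100)
#' windowKeys(gw)
#' @name window-accessors
#' @aliases windowRanges windowSeqs windowSize windowKeys windowLabels
#'   classCounts
NULL

#' @rdname window-accessors
#' @export
setGeneric("windowRanges", function(x) standardGeneric("windowRanges"))

#' @rdname window-accessors
#' @export
setGeneric("windowSeqs", function(x) standardGeneric("windowSeqs"))

#' @rdname window-accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname window-accessors
#' @export
setGeneric("windowKeys", function(x) standardGeneric("windowKeys"))

#' @rdname window-accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname window-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname window-accessors
setMethod("windowRanges", "GenomeWindows", function(x) x@ranges)

#' @rdname window-accessors
setMethod("windowSeqs", "GenomeWindows", function(x) x@seqs)

#' @rdname window-accessors
setMethod("windowSize", "GenomeWindows", function(x) x@windowSize)

#' @rdname window-accessors
setMethod("windowKeys", "GenomeWindows", function(x) {
    if (!length(x@ranges)) return(character())
    sprintf("%s:%d-%d", as.character(seqnames(x@ranges)),
            start(x@ranges) - 1L, end(x@ranges))
})

#' @rdname window-accessors
setMethod("windowLabels", "LabeledWindows", function(x) x@labels)

#' @rdname window-accessors
setMethod("classCounts", "LabeledWindows", function(x) {
    tab <- table(x@labels)
    c(nNonDmr = unname(tab["nonDMR"]), nDmr = unname(tab["DMR"]))
})

#' @export
setMethod("length", "GenomeWindows", function(x) length(x@ranges))

#' Subset windows
#'
#' @param x A \linkS4class{GenomeWindows} or \linkS4class{LabeledWindows}.
#' @param i Index vector (integer, logical, or window keys).
#' @param j,...,drop Ignored.
#' @return An object of the same class with the selected windows.
#' @export
setMethod("[", "GenomeWindows", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, windowKeys(x))
    initialize(x, ranges = x@ranges[i], seqs = x@seqs[i])
})

#' @rdname sub-GenomeWindows-ANY-ANY-ANY-method
#' @export
setMethod("[", "LabeledWindows", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, windowKeys(x))
    initialize(x, ranges = x@ranges[i], seqs = x@seqs[i],
               labels = x@labels[i])
})

setMethod("show", "GenomeWindows", function(object) {
    cat(class(object), "with", length(object), "windows of",
        object@windowSize, "bp on",
        length(unique(as.character(seqnames(object@ranges)))),
        "sequence(s)\n")
})

setMethod("show", "LabeledWindows", function(object) {
    cc <- classCounts(object)
    cat(class(object), "with", length(object), "windows of",
        object@windowSize, "bp:", cc["nDmr"], "DMR,",
        cc["nNonDmr"], "nonDMR\n")
})

setMethod("show", "NetworkSpec", function(object) {
    cat("NetworkSpec:", object@nBlocks, "conv block(s) [",
        paste(object@blockFilters, collapse = ", "),
        "filters ], kernel", object@kernelSize,
        ", pool", object@poolSize, ", dropout", object@dropoutRate, "\n")
    cat("  dense head:", paste(object@denseSizes, collapse = ", "),
        "->", object@outputNodes, "(softmax)\n")
    cat("  lr", object@learningRate, ", batch", object@batchSize,
        ", max", object@maxEpochs, "epochs, patience",
        object@earlyStopPatience, ", seed", object@seed, "\n")
})

setMethod("show", "TrainedNetwork", function(object) {
    cat("TrainedNetwork on", object@inputLength, "bp input;",
        nrow(object@history), "epoch(s) trained")
    if (nrow(object@history))
        cat("; best val loss", format(min(object@history$valLoss),
                                      digits = 4))
    cat("\n")
})

setMethod("show", "HybridModel", function(object) {
    cat("HybridModel:", object@network@spec@blockFilters[1L],
        "DL features (", object@pooling,
        "pooled) -> XGBoost classifier\n")
})

setMethod("show", "CVReport", function(object) {
    cat("CVReport over", nrow(object@perFold), "folds (",
        object@nDmr, "DMR /", object@nNonDmr, "nonDMR )\n")
    cat("  mean:", paste(sprintf("%s=%.4f", names(object@mean),
                                 object@mean), collapse = "  "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@nPerClass, "windows/class,",
        object@windowSize, "bp, motif(s)",
        paste(object@motifs, collapse = ","),
        "x", object@motifCopies,
        ", mutation rate", object@mutationRate,
        ", seed", object@seed, "\n")
})
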