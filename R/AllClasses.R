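#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet readDNAStringSet vcountPattern width
NULL

.WINDOW_ALPHABET <- c("A", "C", "G", "T", "N")
.CLASS_LEVELS <- c("nonDMR", "DMR")

#' GenomeWindows: fixed-width genomic windows with their sequence
#'
#' A set of equal-width, non-overlapping genomic windows, each carrying its
#' DNA sequence over the five-letter alphabet \{A,C,G,T,N\}. Coordinates are
#' stored as a \linkS4class{GRanges} (1-based, as is native to Bioconductor);
#' all text output (window keys, TSV, BED) uses 0-based half-open
#' coordinates.
#'
#' @slot ranges A \linkS4class{GRanges} of window coordinates.
#' @slot seqs A \linkS4class{DNAStringSet}, parallel to \code{ranges}; every
#'   sequence has width \code{windowSize} and uses only A, C, G, T, N.
#' @slot windowSize Integer scalar, the common window width in bp
#'   (default tiling uses 1000).
#'
#' @seealso [tileWindows()], [readGenomeFasta()], [oneHotEncode()],
#'   [cpgProfile()]
#' @exportClass GenomeWindows
setClass("GenomeWindows",
    slots = c(ranges = "GRanges", seqs = "DNAStringSet",
              windowSize = "integer"))

setValidity("GenomeWindows", function(object) {
    msg <- character()
    if (length(object@ranges) != length(object@seqs))
        msg <- c(msg, "ranges and seqs must have equal length")
    if (length(object@windowSize) != 1L || object@windowSize < 1L)
        msg <- c(msg, "windowSize must be a single positive integer")
    if (length(object@seqs)) {
        if (!all(Biostrings::width(object@seqs) == object@windowSize))
            msg <- c(msg, "all sequences must have width == windowSize")
        if (!all(width(object@ranges) == object@windowSize))
            msg <- c(msg, "all ranges must have width == windowSize")
        freq <- Biostrings::alphabetFrequency(object@seqs, baseOnly = FALSE)
        extra <- freq[, setdiff(colnames(freq), .WINDOW_ALPHABET), drop = FALSE]
        if (any(extra > 0))
            msg <- c(msg, "sequences may only contain A, C, G, T, N")
    }
    if (length(msg)) msg else TRUE
})

#' LabeledWindows: genome windows with DMR / non-DMR class labels
#'
#' Extends \linkS4class{GenomeWindows} with a per-window class label. The
#' label levels are fixed to \code{c("nonDMR", "DMR")}; \code{"DMR"} is the
#' positive class throughout the package.
#'
#' @slot labels Factor with levels \code{nonDMR}, \code{DMR}, parallel to
#'   the windows.
#'
#' @seealso [buildDataset()], [generateDataset()], [classCounts()]
#' @exportClass LabeledWindows
setClass("LabeledWindows", contains = "GenomeWindows",
    slots = c(labels = "factor"))

setValidity("LabeledWindows", function(object) {
    msg <- character()
    if (length(object@labels) != length(object@ranges))
        msg <- c(msg, "labels must be parallel to windows")
    if (!identical(levels(object@labels), .CLASS_LEVELS))
        msg <- c(msg, "label levels must be exactly c('nonDMR', 'DMR')")
    if (anyNA(object@labels))
        msg <- c(msg, "labels may not contain NA")
    if (length(msg)) msg else TRUE
})

#' SyntheticWindows: a generated dataset with its ground truth
#'
#' Extends \linkS4class{LabeledWindows} with the generator's ground truth:
#' the spec used, and per positive window the planted motif start offsets
#' (0-based within the window).
#'
#' @slot spec The \linkS4class{SyntheticSpec} the dataset was generated from.
#' @slot motifStarts Named list: for each positive window key, an integer
#'   vector of 0-based motif start offsets.
#'
#' @seealso [generateDataset()]
#' @exportClass SyntheticWindows
setClass("SyntheticWindows", contains = "LabeledWindows",
    slots = c(spec = "ANY", motifStarts = "list"))

#' NetworkSpec: hyperparameters of the convolutional network
#'
#' Architecture and training hyperparameters of the two-block convolutional
#' classifier. Defaults encode the published configuration: two blocks of
#' two convolutions (32 then 64 filters, kernel size 20, the first
#' convolution of each block unpadded, the second length-preserving), batch
#' normalization then ReLU after every convolution, max pooling of size 2
#' and dropout 0.4 at the end of each block, dense layers of 256 and 128
#' nodes, and a two-node softmax output trained with cross-entropy, the
#' Adam optimizer and early stopping with patience 5.
#'
#' @seealso [networkSpec()], [buildNetwork()], [trainNetwork()]
#' @exportClass NetworkSpec
setClass("NetworkSpec",
    slots = c(
        nBlocks = "integer", blockFilters = "integer",
        kernelSize = "integer", poolSize = "integer",
        dropoutRate = "numeric", denseSizes = "integer",
        outputNodes = "integer", learningRate = "numeric",
        batchSize = "integer", maxEpochs = "integer",
        earlyStopPatience = "integer", validationFraction = "numeric",
        classWeighting = "logical", seed = "integer"))

setValidity("NetworkSpec", function(object) {
    msg <- character()
    if (object@nBlocks < 1L || object@nBlocks > 5L)
        msg <- c(msg, "nBlocks must be between 1 and 5")
    if (length(object@blockFilters) != object@nBlocks)
        msg <- c(msg, "blockFilters must have one entry per block")
    if (any(c(object@blockFilters, object@kernelSize, object@poolSize,
              object@denseSizes, object@outputNodes, object@batchSize,
              object@maxEpochs) < 1L))
        msg <- c(msg, "all sizes must be positive")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (object@validationFraction <= 0 || object@validationFraction > 0.5)
        msg <- c(msg, "validationFraction must be in (0, 0.5]")
    if (length(msg)) msg else TRUE
})

#' TrainedNetwork: a fitted convolutional network
#'
#' Holds the fitted parameters of the network described by a
#' \linkS4class{NetworkSpec}, together with the per-epoch training history.
#' The first-convolution-layer kernels (the learned sequence detectors) are
#' available through [conv1Kernels()].
#'
#' @slot spec The \linkS4class{NetworkSpec} used.
#' @slot layers Internal list of layer parameter sets, in forward order.
#' @slot inputLength Window length the network was built for (bp).
#' @slot history data.frame with one row per trained epoch: \code{epoch},
#'   \code{loss}, \code{valLoss}, \code{valAccuracy}.
#'
#' @seealso [trainNetwork()], [predictDL()], [conv1Activations()]
#' @exportClass TrainedNetwork
setClass("TrainedNetwork",
    slots = c(spec = "NetworkSpec", layers = "list",
              inputLength = "integer", history = "data.frame"))

#' HybridModel: trained network plus boosted-tree classifier
#'
#' The full hybrid model: a \linkS4class{TrainedNetwork} whose first
#' convolution layer re-expresses each window as a pooled feature vector,
#' and an XGBoost ensemble trained on those features that makes the final
#' DMR / non-DMR call.
#'
#' @slot network The fitted \linkS4class{TrainedNetwork}.
#' @slot booster The fitted \code{xgb.Booster}.
#' @slot pooling Pooling used to collapse activation maps ("max" or "mean").
#' @slot featureNames Character vector of feature column names (f0, f1, ...).
#'
#' @seealso [trainHybrid()], [predictHybrid()], [scanGenome()]
#' @exportClass HybridModel
setClass("HybridModel",
    slots = c(network = "TrainedNetwork", booster = "ANY",
              pooling = "character", featureNames = "character"))

#' CVReport: fivefold cross-validation results
#'
#' Per-fold and mean evaluation metrics of the hybrid model under
#' stratified k-fold cross-validation, plus the fold assignment used (for
#' leakage auditing).
#'
#' @slot perFold data.frame with one row per fold: \code{fold},
#'   \code{accuracy}, \code{precision}, \code{recall}, \code{f1}.
#' @slot mean Named numeric: arithmetic mean of the per-fold metrics.
#' @slot nDmr,nNonDmr Class counts of the dataset.
#' @slot foldAssignments Integer vector, fold id per window (named by key).
#'
#' @seealso [crossValidate()], [summarizeChromosomeCv()]
#' @exportClass CVReport
setClass("CVReport",
    slots = c(perFold = "data.frame", mean = "numeric",
              nDmr = "integer", nNonDmr = "integer",
              foldAssignments = "integer"))

#' SyntheticSpec: parameters of the synthetic window generator
#'
#' Describes the synthetic study conditions: positives are background
#' sequence with planted, per-position-mutated copies of a consensus motif
#' and CpG dinucleotides injected at a target rate; negatives are
#' background sequence with every CpG destroyed, mirroring the CpG-free
#' definition of a non-DMR.
#'
#' @slot nPerClass Examples per class.
#' @slot windowSize Window width in bp.
#' @slot motifs Character vector of consensus motifs planted in positives.
#' @slot mutationRate Per-position substitution probability applied to each
#'   planted copy, in [0, 0.5].
#' @slot motifCopies Copies planted per positive window.
#' @slot posCpgRate Expected number of CpG dinucleotides injected per
#'   positive window (at least one is always present).
#' @slot backgroundProbs Named numeric over A, C, G, T; sums to 1.
#' @slot cpgMatchedNegatives If TRUE, negatives keep the positives' CpG
#'   rate instead of being CpG-free, forcing the model to rely on motifs.
#' @slot seed Integer RNG seed.
#'
#' @seealso [syntheticSpec()], [generateDataset()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    slots = c(nPerClass = "integer", windowSize = "integer",
              motifs = "character", mutationRate = "numeric",
              motifCopies = "integer", posCpgRate = "numeric",
              backgroundProbs = "numeric", cpgMatchedNegatives = "logical",
              seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nPerClass < 1L) msg <- c(msg, "nPerClass must be >= 1")
    if (any(nchar(object@motifs) > object@windowSize))
        msg <- c(msg, "motifs must fit inside the window")
    if (any(nchar(object@motifs) < 1L)) msg <- c(msg, "motifs must be non-empty")
    if (!all(strsplit(paste(object@motifs, collapse = ""), "")[[1]] %in%
             c("A", "C", "G", "T")))
        msg <- c(msg, "motifs must use only A, C, G, T")
    if (object@mutationRate < 0 || object@mutationRate > 0.5)
        msg <- c(msg, "mutationRate must be in [0, 0.5]")
    if (abs(sum(object@backgroundProbs) - 1) > 1e-8 ||
        !identical(names(object@backgroundProbs), c("A", "C", "G", "T")))
        msg <- c(msg, "backgroundProbs must be named A,C,G,T and sum to 1")
    if (object@motifCopies < 1L) msg <- c(msg, "motifCopies must be >= 1")
    if (length(msg)) msg else TRUE
})
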