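#' @include features.R
#' @importFrom xgboost xgb.DMatrix xgb.train xgb.importance
NULL

.defaultXgbParams <- function(nPos, nNeg) {
    list(objective = "binary:logistic", eval_metric = "logloss",
         max_depth = 6L, eta = 0.1,
         scale_pos_weight = if (nPos > 0) nNeg / nPos else 1,
         nthread = 1L)
}

#' Train the boosted-tree classifier on DL features
#'
#' Fits an XGBoost gradient-boosted decision-tree ensemble on the
#' re-expressed feature matrix. The positive (DMR) class is weighted by
#' n_nonDMR / n_DMR by default to counter class imbalance. Hyperparameters
#' not pinned down by the published configuration default to 200 trees of
#' depth 6 with learning rate 0.1.
#'
#' @param features Numeric matrix (windows x features) from [reexpress()].
#' @param labels Factor/character with levels nonDMR, DMR (or 0/1).
#' @param nrounds Number of boosting rounds (default 200).
#' @param params Named list merged over the defaults (xgboost parameters).
#' @param seed Integer seed.
#' @return A fitted \code{xgb.Booster}.
#' @export
trainClassifier <- function(features, labels, nrounds = 200L,
                            params = list(), seed = 1L) {
    if (!is.matrix(features) || nrow(features) == 0L)
        stop("features must be a non-empty matrix")
    y <- .asBinaryLabels(labels)
    if (length(unique(y)) < 2L) stop("labels must contain both classes")
    p <- utils::modifyList(.defaultXgbParams(sum(y == 1L), sum(y == 0L)),
                           params)
    p$seed <- as.integer(seed)
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(data = features, label = y,
                                   nthread = 1L)
    xgboost::xgb.train(params = p, data = dtrain,
                       nrounds = as.integer(nrounds), verbose = 0)
}

## labels -> 0/1 with DMR = 1
.asBinaryLabels <- function(labels) {
    if (is.logical(labels)) return(as.integer(labels))
    if (is.numeric(labels)) return(as.integer(labels != 0))
    out <- as.character(labels) %in% c("DMR", "TRUE", "1")
    if (!all(as.character(labels) %in% c("DMR", "nonDMR", "TRUE", "FALSE",
                                         "1", "0")))
        stop("labels must be DMR/nonDMR, logical, or 0/1")
    as.integer(out)
}

#' Predict DMR probabilities from a fitted booster
#'
#' @param booster An \code{xgb.Booster} from [trainClassifier()].
#' @param features Feature matrix aligned with the training columns.
#' @return Numeric vector of DMR probabilities.
#' @export
predictClassifier <- function(booster, features) {
    stats::predict(booster, xgboost::xgb.DMatrix(features, nthread = 1L))
}

#' Binary classification metrics with DMR as the positive class
#'
#' Computes accuracy, precision, recall and F1 from predicted and true
#' labels. Precision is TP / (TP + FP), recall TP / (TP + FN), and F1 the
#' harmonic mean 2PR / (P + R); an undefined ratio (zero denominator) is
#' reported as 0 with a note.
#'
#' @param yTrue,yPred Vectors of equal length: factors/characters with
#'   levels nonDMR/DMR, logicals, or 0/1 numerics (1 = DMR).
#' @return Named numeric: \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1}.
#' @examples
#' computeMetrics(c(1, 1, 0, 0), c(1, 0, 1, 0))  # all four are 0.5
#' @export
computeMetrics <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred))
        stop("yTrue and yPred must have equal length")
    if (!length(yTrue)) stop("need at least one example")
    yt <- .asBinaryLabels(yTrue)
    yp <- .asBinaryLabels(yPred)
    tp <- sum(yt == 1L & yp == 1L)
    fp <- sum(yt == 0L & yp == 1L)
    fn <- sum(yt == 1L & yp == 0L)
    tn <- sum(yt == 0L & yp == 0L)
    prec <- if (tp + fp > 0) tp / (tp + fp) else {
        message("no predicted positives; precision reported as 0"); 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else {
        message("no true positives; recall reported as 0"); 0 }
    f1 <- f1Score(prec, rec)
    c(accuracy = (tp + tn) / length(yt), precision = prec, recall = rec,
      f1 = f1)
}

#' Harmonic-mean F1 score
#'
#' \code{2 * precision * recall / (precision + recall)}, or 0 when both
#' are 0. This is the standard F1; it reproduces published per-chromosome
#' F1 values from their printed precision/recall, unlike a "one-half
#' times the product over the sum" reading, which yields half of it.
#'
#' @param precision,recall Numeric in [0, 1] (vectorized).
#' @return Numeric F1.
#' @export
f1Score <- function(precision, recall) {
    ifelse(precision + recall > 0,
           2 * precision * recall / (precision + recall), 0)
}

## Stratified fold assignment: returns integer fold id per example.
.stratifiedFolds <- function(y, k) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Stratified k-fold cross-validation of the hybrid model
#'
#' Partitions the dataset into k stratified folds (default 5). Within
#' each fold, \emph{both} stages -- the convolutional network and the
#' boosted classifier -- are trained only on that fold's training
#' partition, and metrics are computed on the held-out partition, so no
#' test window leaks into feature learning. The report carries per-fold
#' metrics, their arithmetic mean, and the fold assignment for auditing.
#'
#' @param dataset A \linkS4class{LabeledWindows}; each class must have at
#'   least k members.
#' @param k Number of folds (default 5).
#' @param spec \linkS4class{NetworkSpec} for the per-fold networks.
#' @param dlEpochs Optional epoch cap override for the per-fold network
#'   training (the boosted stage carries the classification, so a small
#'   number of epochs suffices for feature learning).
#' @param nrounds,xgbParams Passed to [trainClassifier()].
#' @param pooling Feature pooling ("mean" or "max").
#' @param seed Seed for fold assignment and per-fold training.
#' @param verbose Print per-fold progress.
#' @return A \linkS4class{CVReport}.
#' @export
crossValidate <- function(dataset, k = 5L, spec = networkSpec(),
                          dlEpochs = NULL, nrounds = 200L,
                          xgbParams = list(), pooling = "mean", seed = 1L,
                          verbose = FALSE) {
    stopifnot(is(dataset, "LabeledWindows"))
    cc <- table(dataset@labels)
    if (any(cc < k))
        stop("each class must have at least k = ", k, " examples")
    set.seed(seed)
    fold <- .stratifiedFolds(as.integer(dataset@labels), k)
    perFold <- vector("list", k)
    for (f in seq_len(k)) {
        if (verbose) message("fold ", f, "/", k)
        trainSet <- dataset[which(fold != f)]
        testSet <- dataset[which(fold == f)]
        model <- trainHybrid(trainSet, spec = spec, dlEpochs = dlEpochs,
                             nrounds = nrounds, xgbParams = xgbParams,
                             pooling = pooling, seed = seed + f)
        prob <- predictHybrid(model, testSet)
        m <- computeMetrics(testSet@labels, prob >= 0.5)
        perFold[[f]] <- data.frame(fold = f, t(m))
    }
    perFold <- do.call(rbind, perFold)
    names(fold) <- windowKeys(dataset)
    new("CVReport", perFold = perFold,
        mean = colMeans(perFold[, c("accuracy", "precision", "recall",
                                    "f1")]),
        nDmr = unname(as.integer(cc["DMR"])),
        nNonDmr = unname(as.integer(cc["nonDMR"])),
        foldAssignments = fold)
}

#' Gain-based feature importance ranking
#'
#' Ranks the DL features by their XGBoost gain. Features never used in a
#' split score 0; the result is a permutation of all feature columns in
#' descending importance.
#'
#' @param model A \linkS4class{HybridModel} or \code{xgb.Booster}.
#' @param featureNames Feature column names (taken from the model when it
#'   is a \linkS4class{HybridModel}).
#' @return data.frame with columns \code{featureId} (0-based),
#'   \code{feature}, \code{gain}, sorted by decreasing gain.
#' @export
featureImportance <- function(model, featureNames = NULL) {
    if (is(model, "HybridModel")) {
        featureNames <- model@featureNames
        model <- model@booster
    }
    if (is.null(featureNames))
        stop("featureNames required when passing a bare booster")
    imp <- tryCatch(xgboost::xgb.importance(model = model),
                    error = function(e) stop("model is not fitted: ",
                                             conditionMessage(e)))
    gain <- stats::setNames(rep(0, length(featureNames)), featureNames)
    if (!is.null(imp) && nrow(imp))
        gain[imp$Feature] <- imp$Gain
    out <- data.frame(featureId = seq_along(featureNames) - 1L,
                      feature = featureNames, gain = unname(gain),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$gain), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarize per-chromosome cross-validation reports
#'
#' Collects per-chromosome CV results into one table (columns mirroring
#' the usual report layout: #nonDMRs, #DMRs, accuracy, F1, precision,
#' recall) and computes the unweighted arithmetic mean of the
#' per-chromosome accuracies. Rows named "All"/"ALL" (a model trained on
#' the pooled genome) are kept in the table but excluded from the mean,
#' which summarizes the per-chromosome models.
#'
#' @param reports Named list of \linkS4class{CVReport} (names =
#'   chromosomes), or a data.frame with columns \code{chrom},
#'   \code{nNonDmr}, \code{nDmr}, \code{accuracy}, \code{f1},
#'   \code{precision}, \code{recall}.
#' @param path Optional TSV output path.
#' @return List with \code{table} (data.frame) and \code{meanAccuracy}
#'   (unweighted mean over chromosome rows).
#' @export
summarizeChromosomeCv <- function(reports, path = NULL) {
    if (is.list(reports) && !is.data.frame(reports)) {
        stopifnot(length(reports) >= 1L, !is.null(names(reports)))
        tab <- do.call(rbind, lapply(names(reports), function(ch) {
            r <- reports[[ch]]
            data.frame(chrom = ch, nNonDmr = r@nNonDmr, nDmr = r@nDmr,
                       accuracy = r@mean[["accuracy"]],
                       f1 = r@mean[["f1"]],
                       precision = r@mean[["precision"]],
                       recall = r@mean[["recall"]],
                       stringsAsFactors = FALSE)
        }))
    } else {
        tab <- as.data.frame(reports)
        need <- c("chrom", "accuracy")
        if (!all(need %in% names(tab)))
            stop("data.frame input needs at least columns chrom, accuracy")
    }
    chromRows <- !(toupper(tab$chrom) %in% "ALL")
    meanAcc <- mean(tab$accuracy[chromRows])
    if (!is.null(path))
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    list(table = tab, meanAccuracy = meanAcc)
}

#' Published per-chromosome reference metrics
#'
#' Loads the reference table of per-chromosome fivefold cross-validation
#' metrics for the rat transgenerational DMR prediction task (20
#' autosomes, X, Y, and a pooled "All" model), as shipped in
#' \code{inst/extdata/rat_cv_reference_metrics.tsv}. Used to validate the
#' metric arithmetic and the per-chromosome summary.
#'
#' @return data.frame with columns \code{chrom}, \code{nNonDmr},
#'   \code{nDmr}, \code{accuracy}, \code{f1}, \code{precision},
#'   \code{recall}.
#' @export
ratCvReference <- function() {
    path <- system.file("extdata", "rat_cv_reference_metrics.tsv",
                        package = "hybridDMR", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
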