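#' @include features.R
NULL

## Activation maps for all kernels of a batch, plus helper to walk a
## dataset in batches. fn(A, offset) is called with A = (F, To, B).
.conv1Walk <- function(network, X, batchSize, fn) {
    n <- dim(X)[3L]
    stopIdx <- .conv1StopIndex(network@layers)
    for (bStart in seq(1L, n, by = batchSize)) {
        bi <- bStart:min(bStart + batchSize - 1L, n)
        fw <- .nnForward(network@layers, X[, , bi, drop = FALSE],
                         training = FALSE, stopAfter = stopIdx)
        fn(fw$out, bStart - 1L)
    }
}

#' Subsequences that strongly activate a kernel
#'
#' Scans every position of every window and collects the
#' kernel-size-length subsequences whose activation (post batchnorm/ReLU)
#' is at least \code{thresholdFraction} times the kernel's maximum
#' activation over the whole dataset. At \code{thresholdFraction = 1}
#' only the argmax subsequence(s) are returned; lowering the fraction
#' can only grow the set. These subsequences are the raw material for the
#' kernel's position weight matrix.
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @param kernelId 0-based kernel index (matching \code{featureId}).
#' @param windows \linkS4class{GenomeWindows} (or subclass).
#' @param thresholdFraction Fraction of the dataset-wide maximum
#'   activation, in (0, 1].
#' @param batchSize Windows per forward pass.
#' @return Character vector of subsequences (possibly empty when the
#'   kernel never activates, with a warning).
#' @export
activatingSubsequences <- function(network, kernelId, windows,
                                   thresholdFraction = 0.5,
                                   batchSize = 256L) {
    stopifnot(is(network, "TrainedNetwork"),
              thresholdFraction > 0, thresholdFraction <= 1)
    nF <- dim(network@layers[[1L]]$W)[1L]
    if (kernelId < 0L || kernelId >= nF)
        stop("kernelId must be in [0, ", nF - 1L, "]")
    hits <- .activatingPositions(network, windows,
                                 kernelIds = kernelId,
                                 thresholdFraction = thresholdFraction,
                                 batchSize = batchSize)[[1L]]
    hits$subsequences
}

## Two-pass scan shared by activatingSubsequences and kernelMotifs:
## pass 1 finds each kernel's dataset-wide max activation, pass 2
## collects the subsequences at or above fraction * max.
.activatingPositions <- function(network, windows, kernelIds,
                                 thresholdFraction, batchSize = 256L) {
    X <- .asOneHotBatch(windows, network@inputLength)
    K <- dim(network@layers[[1L]]$W)[3L]
    rows <- kernelIds + 1L
    maxAct <- rep(-Inf, length(rows))
    env <- environment()
    .conv1Walk(network, X, batchSize, function(A, off) {
        m <- apply(A[rows, , , drop = FALSE], 1L, max)
        env$maxAct <- pmax(env$maxAct, m)
    })
    seqChars <- if (is(windows, "GenomeWindows"))
        as.character(windowSeqs(windows))
    else vapply(seq_len(dim(X)[3L]), function(i) decodeOneHot(X[, , i]),
                character(1))
    out <- vector("list", length(rows))
    for (j in seq_along(rows)) out[[j]] <- list(win = integer(),
                                                pos = integer())
    .conv1Walk(network, X, batchSize, function(A, off) {
        for (j in seq_along(rows)) {
            if (env$maxAct[j] <= 0) next
            hit <- which(A[rows[j], , , drop = FALSE] >=
                             thresholdFraction * env$maxAct[j],
                         arr.ind = TRUE)
            if (nrow(hit)) {
                o <- env$out[[j]]
                o$win <- c(o$win, hit[, 3L] + off)
                o$pos <- c(o$pos, hit[, 2L])
                env$out[[j]] <- o
            }
        }
    })
    lapply(seq_along(rows), function(j) {
        o <- out[[j]]
        if (maxAct[j] <= 0) {
            warning("kernel ", kernelIds[j], " never activates; ",
                    "no subsequences collected")
            subs <- character()
        } else {
            subs <- substring(seqChars[o$win], o$pos, o$pos + K - 1L)
        }
        list(kernelId = kernelIds[j], maxActivation = maxAct[j],
             subsequences = subs)
    })
}

#' Build a position weight matrix from subsequences
#'
#' Tallies the base at each position over the given subsequences and
#' normalizes by their number: entry (b, j) is the fraction of
#' subsequences with base b at position j. Rows are A, C, G, T, N and
#' every column sums to 1.
#'
#' @param subsequences Non-empty character vector of equal-length
#'   sequences over A, C, G, T, N.
#' @return 5 x width numeric matrix with attribute
#'   \code{nSubsequences}.
#' @examples
#' buildPwm(c("AC", "GC"))  # position 1: A/G 0.5 each; position 2: C 1
#' @export
buildPwm <- function(subsequences) {
    if (!length(subsequences))
        stop("cannot build a PWM from zero subsequences")
    w <- unique(nchar(subsequences))
    if (length(w) != 1L) stop("subsequences must have equal length")
    counts <- Biostrings::consensusMatrix(
        Biostrings::DNAStringSet(subsequences))
    pwm <- matrix(0, nrow = 5L, ncol = w,
                  dimnames = list(.WINDOW_ALPHABET, NULL))
    for (b in intersect(rownames(counts), .WINDOW_ALPHABET))
        pwm[b, ] <- counts[b, ]
    other <- setdiff(rownames(counts), .WINDOW_ALPHABET)
    if (length(other) && any(counts[other, , drop = FALSE] > 0))
        stop("subsequences contain letters outside A,C,G,T,N")
    pwm <- pwm / length(subsequences)
    attr(pwm, "nSubsequences") <- length(subsequences)
    pwm
}

#' Position weight matrices for every kernel
#'
#' For each first-layer kernel, collects its activating subsequences
#' (at \code{thresholdFraction} of the kernel's dataset-wide maximum,
#' over all examples) and tallies them into a PWM, carrying the kernel's
#' detector class and activation difference. Motifs are sorted DMR
#' detectors first, each class by decreasing absolute activation
#' difference, so the first motif of each class is its most biased.
#'
#' @param network A \linkS4class{TrainedNetwork}.
#' @param dataset A \linkS4class{LabeledWindows} with both classes.
#' @param thresholdFraction Activation threshold fraction (default 0.5).
#' @param pooling Pooling used for the detector classification.
#' @param batchSize Windows per forward pass.
#' @return List with one element per kernel (in sorted order), each a
#'   list: \code{kernelId}, \code{pwm}, \code{nSubsequences},
#'   \code{detectorClass}, \code{activationDifference}.
#' @export
kernelMotifs <- function(network, dataset, thresholdFraction = 0.5,
                         pooling = "mean", batchSize = 256L) {
    det <- classifyDetectors(network, dataset, pooling)
    nF <- nrow(det)
    hits <- .activatingPositions(network, dataset,
                                 kernelIds = seq_len(nF) - 1L,
                                 thresholdFraction = thresholdFraction,
                                 batchSize = batchSize)
    byId <- stats::setNames(hits, vapply(hits, `[[`, 0L, "kernelId"))
    ord <- det[order(det$detectorClass != "DMR-detector",
                     -abs(det$activationDifference)), , drop = FALSE]
    lapply(seq_len(nrow(ord)), function(i) {
        kid <- ord$featureId[i]
        h <- byId[[as.character(kid)]]
        pwm <- if (length(h$subsequences)) buildPwm(h$subsequences) else NULL
        list(kernelId = kid, pwm = pwm,
             nSubsequences = length(h$subsequences),
             detectorClass = ord$detectorClass[i],
             activationDifference = ord$activationDifference[i])
    })
}

#' Consensus sequence of a PWM
#'
#' Argmax base per column, excluding the N row (ties resolve to the
#' first base in A, C, G, T order).
#'
#' @param pwm A matrix from [buildPwm()].
#' @return Character string.
#' @export
pwmConsensus <- function(pwm) {
    core <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
    paste(rownames(core)[apply(core, 2L, which.max)], collapse = "")
}

#' Export kernel motifs
#'
#' \code{format = "meme"} writes MEME minimal motif format over the
#' four-letter alphabet (the N row's mass is redistributed uniformly over
#' A, C, G, T, since standard motif tools use ACGT), one MOTIF block per
#' kernel named \code{kernel<id>_<detectorClass>}, in the list's sort
#' order. \code{format = "tsv"} preserves all five rows, one row per
#' (kernel, position) with metadata columns.
#'
#' @param motifs List from [kernelMotifs()].
#' @param path Output path.
#' @param format "meme" or "tsv".
#' @return \code{path}, invisibly.
#' @export
exportMotifs <- function(motifs, path, format = c("meme", "tsv")) {
    format <- match.arg(format)
    motifs <- Filter(function(m) !is.null(m$pwm), motifs)
    if (format == "meme") {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                     "strands: + -", "",
                     "Background letter frequencies",
                     "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
        for (m in motifs) {
            p4 <- m$pwm[c("A", "C", "G", "T"), , drop = FALSE] +
                rep(m$pwm["N", ], each = 4L) / 4
            writeLines(sprintf("MOTIF kernel%02d_%s", m$kernelId,
                               sub("-detector", "", m$detectorClass)), con)
            writeLines(sprintf(
                "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                ncol(p4), m$nSubsequences), con)
            writeLines(apply(p4, 2L, function(col)
                paste(sprintf("%.6f", col), collapse = " ")), con)
            writeLines("", con)
        }
    } else {
        rows <- lapply(motifs, function(m) {
            data.frame(kernelId = m$kernelId,
                       detectorClass = m$detectorClass,
                       activationDifference = m$activationDifference,
                       nSubsequences = m$nSubsequences,
                       position = seq_len(ncol(m$pwm)),
                       A = m$pwm["A", ], C = m$pwm["C", ],
                       G = m$pwm["G", ], T = m$pwm["T", ],
                       N = m$pwm["N", ], stringsAsFactors = FALSE)
        })
        utils::write.table(do.call(rbind, rows), path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Parses motif blocks written by [exportMotifs()] (or any MEME minimal
#' file over ACGT) back into probability matrices.
#'
#' @param path MEME file path.
#' @return Named list of 4 x width matrices (rows A, C, G, T).
#' @export
readMemeMotifs <- function(path) {
    lines <- readLines(path)
    starts <- grep("^MOTIF ", lines)
    out <- list()
    for (s in starts) {
        name <- sub("^MOTIF +", "", lines[s])
        name <- sub(" .*$", "", name)
        hdr <- s + 1L
        while (hdr <= length(lines) &&
               !grepl("^letter-probability matrix", lines[hdr]))
            hdr <- hdr + 1L
        w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
        block <- lines[(hdr + 1L):(hdr + w)]
        vals <- t(vapply(strsplit(trimws(block), "[ \t]+"),
                         function(x) as.numeric(x), numeric(4)))
        m <- t(vals)
        rownames(m) <- c("A", "C", "G", "T")
        out[[name]] <- m
    }
    out
}
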