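#' @include dataset.R
NULL

.EXPOSURES <- c("vinclozolin", "DDT", "atrazine", "glyphosate",
                "pesticides", "dioxin", "jet fuel", "methoxychlor",
                "plastics")

#' Specify a synthetic dataset
#'
#' Describes the generated study conditions. Positives are background
#' sequence carrying mutated copies of a planted consensus motif plus
#' CpG dinucleotides injected at a target rate; negatives are background
#' sequence with every CpG destroyed, reproducing the defining confound
#' of the real task: CpG presence alone separates the classes. The
#' default consensus is a 20-mer (the kernel width), planted once per
#' positive with a 10% per-position mutation rate in 1000 bp windows,
#' 1000 windows per class, and roughly 10 CpGs per positive window --
#' about the genome-wide average density of CpG-bearing 1000 bp tiles.
#' Set \code{cpgMatchedNegatives = TRUE} for the harder variant where
#' negatives keep the positives' CpG rate and only the motif separates
#' the classes.
#'
#' @param nPerClass Windows per class (default 1000).
#' @param windowSize Window width in bp (default 1000).
#' @param motifs Consensus motif(s) over ACGT (default one 20-mer).
#' @param mutationRate Per-position substitution rate in [0, 0.5]
#'   (default 0.1).
#' @param motifCopies Copies planted per positive window (default 1).
#' @param posCpgRate Expected CpGs injected per positive window
#'   (default 10; at least one is always present).
#' @param backgroundProbs Named base probabilities (A, C, G, T), sum 1.
#' @param cpgMatchedNegatives Keep CpGs in negatives (default FALSE).
#' @param seed Integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nPerClass = 1000L, windowSize = 1000L,
                          motifs = "TCACGTGATTGACGTCAATG",
                          mutationRate = 0.1, motifCopies = 1L,
                          posCpgRate = 10,
                          backgroundProbs = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                          cpgMatchedNegatives = FALSE, seed = 1L) {
    new("SyntheticSpec", nPerClass = as.integer(nPerClass),
        windowSize = as.integer(windowSize), motifs = motifs,
        mutationRate = as.numeric(mutationRate),
        motifCopies = as.integer(motifCopies),
        posCpgRate = as.numeric(posCpgRate),
        backgroundProbs = backgroundProbs,
        cpgMatchedNegatives = as.logical(cpgMatchedNegatives),
        seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")

## Transition matrix of a first-order Markov chain with no C -> G
## transition whose stationary distribution equals the background exactly:
## from C the next base is drawn from the background restricted to
## {A, C, T}; from any other base, G is drawn at the inflated rate
## pG / (1 - pC) that restores its stationary frequency, and the rest of
## the mass is spread over A, C, T proportionally to the background.
.cpgFreeTransition <- function(probs) {
    p <- probs[.BASES]
    Q <- matrix(0, 4L, 4L, dimnames = list(.BASES, .BASES))
    Q["C", ] <- p / (1 - p["G"])
    Q["C", "G"] <- 0
    gRate <- p["G"] / (1 - p["C"])
    for (b in c("A", "G", "T")) {
        Q[b, ] <- p * (1 - gRate) / (1 - p["G"])
        Q[b, "G"] <- gRate
    }
    Q
}

## L x n character matrix of CpG-free sequence with background marginals.
.sampleCpgFreeMatrix <- function(L, n, probs) {
    Q <- .cpgFreeTransition(probs)
    cum <- t(apply(Q, 1L, cumsum))
    mat <- matrix("", nrow = L, ncol = n)
    curIdx <- sample.int(4L, n, replace = TRUE, prob = probs)
    mat[1L, ] <- .BASES[curIdx]
    for (j in 2:L) {
        u <- stats::runif(n)
        curIdx <- 1L + (u > cum[curIdx, 1L]) + (u > cum[curIdx, 2L]) +
            (u > cum[curIdx, 3L])
        mat[j, ] <- .BASES[curIdx]
    }
    mat
}

## Place `count` non-overlapping intervals of widths `widths` uniformly in
## [1, L], avoiding `blocked` positions. Returns start positions.
.placeNonOverlapping <- function(widths, L, blocked = integer()) {
    starts <- integer(0)
    occupied <- logical(L)
    occupied[blocked] <- TRUE
    for (w in widths) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
            s <- sample.int(L - w + 1L, 1L)
            span <- s:(s + w - 1L)
            if (!any(occupied[span])) {
                occupied[span] <- TRUE
                starts <- c(starts, s)
                ok <- TRUE
                break
            }
        }
        if (!ok) stop("could not place motif/CpG without overlap")
    }
    starts
}

#' Generate a labeled synthetic dataset
#'
#' Draws the dataset described by a \linkS4class{SyntheticSpec}, fully
#' seeded: identical specs give identical datasets. Positive windows are
#' background sequence with each motif copy placed uniformly at random
#' without overlap and mutated per position at the spec's rate, then CpG
#' dinucleotides injected (outside the motifs) until the window holds at
#' least \code{max(1, Poisson(posCpgRate))} CpGs. Negative windows are
#' CpG-free by construction: they are drawn from a first-order Markov
#' chain that forbids the C-to-G transition but whose stationary
#' distribution equals the background base composition exactly (unless
#' \code{cpgMatchedNegatives}, where negatives keep the positives' CpG
#' rate). Windows are laid out on the pseudo chromosome "synth" in
#' tiling order, positives first.
#'
#' @param spec A \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{SyntheticWindows}: labeled windows plus ground
#'   truth (motif start offsets per positive window).
#' @export
generateDataset <- function(spec) {
    validObject(spec)
    set.seed(spec@seed)
    n <- spec@nPerClass
    L <- spec@windowSize
    probs <- spec@backgroundProbs
    motifChars <- strsplit(spec@motifs, "")
    widths <- nchar(spec@motifs)

    posMat <- matrix(sample(.BASES, n * L, replace = TRUE, prob = probs),
                     nrow = L, ncol = n)
    motifStarts <- vector("list", n)
    for (i in seq_len(n)) {
        picks <- rep(seq_along(motifChars), length.out = spec@motifCopies)
        starts <- .placeNonOverlapping(widths[picks], L)
        blocked <- integer(0)
        for (j in seq_along(picks)) {
            m <- motifChars[[picks[j]]]
            mut <- stats::runif(length(m)) < spec@mutationRate
            if (any(mut))
                m[mut] <- vapply(m[mut], function(b)
                    sample(setdiff(.BASES, b), 1L), character(1))
            span <- starts[j]:(starts[j] + length(m) - 1L)
            posMat[span, i] <- m
            blocked <- c(blocked, span)
        }
        ## top up CpGs to the target rate, outside the planted motifs
        target <- max(1L, stats::rpois(1L, spec@posCpgRate))
        have <- sum(posMat[-L, i] == "C" & posMat[-1L, i] == "G")
        if (have < target) {
            cgStarts <- .placeNonOverlapping(
                rep(2L, target - have), L,
                blocked = unique(c(blocked, blocked - 1L)))
            for (s in cgStarts) posMat[s:(s + 1L), i] <- c("C", "G")
        }
        motifStarts[[i]] <- as.integer(starts - 1L)   # 0-based offsets
    }

    if (!spec@cpgMatchedNegatives) {
        negMat <- .sampleCpgFreeMatrix(L, n, probs)
    } else {
        negMat <- matrix(sample(.BASES, n * L, replace = TRUE,
                                prob = probs),
                         nrow = L, ncol = n)
        for (i in seq_len(n)) {
            target <- max(1L, stats::rpois(1L, spec@posCpgRate))
            have <- sum(negMat[-L, i] == "C" & negMat[-1L, i] == "G")
            if (have < target) {
                cgStarts <- .placeNonOverlapping(rep(2L, target - have), L)
                for (s in cgStarts) negMat[s:(s + 1L), i] <- c("C", "G")
            }
        }
    }

    seqs <- Biostrings::DNAStringSet(c(
        apply(posMat, 2L, paste, collapse = ""),
        apply(negMat, 2L, paste, collapse = "")))
    gr <- GRanges("synth", IRanges(start = (seq_len(2L * n) - 1L) * L + 1L,
                                   width = L))
    labels <- factor(rep(c("DMR", "nonDMR"), each = n),
                     levels = .CLASS_LEVELS)
    keys <- sprintf("synth:%d-%d", start(gr) - 1L, end(gr))
    new("SyntheticWindows", ranges = gr, seqs = seqs,
        windowSize = L, labels = labels, spec = spec,
        motifStarts = stats::setNames(motifStarts, keys[seq_len(n)]))
}

#' Generate a per-exposure statistics table for a synthetic dataset
#'
#' Emits the per-region p-value table the labeling step consumes: every
#' true positive gets a p-value below the DMR threshold (drawn from
#' Uniform(0, pLow)) under one randomly chosen exposure, every window
#' additionally gets non-significant rows (Uniform(pHigh, 1)) under other
#' exposures, so the union-over-exposures labeling rule is exercised.
#'
#' @param dataset A \linkS4class{SyntheticWindows} (or any
#'   \linkS4class{LabeledWindows}).
#' @param pLow Upper bound of the significant p-values; must be below
#'   1e-5.
#' @param pHigh Lower bound of the non-significant p-values; at least
#'   1e-5.
#' @param exposures Exposure names to draw from.
#' @param seed Integer seed.
#' @param path Optional TSV output path.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{exposure}, \code{p_value}.
#' @export
generateStatsTable <- function(dataset, pLow = 1e-6, pHigh = 0.1,
                               exposures = .EXPOSURES, seed = 1L,
                               path = NULL) {
    stopifnot(is(dataset, "LabeledWindows"), pLow < 1e-5, pHigh >= 1e-5)
    set.seed(seed)
    gr <- windowRanges(dataset)
    base <- data.frame(chrom = as.character(seqnames(gr)),
                       start = start(gr) - 1L, end = end(gr),
                       stringsAsFactors = FALSE)
    isPos <- windowLabels(dataset) == "DMR"
    rows <- list()
    sig <- base[isPos, , drop = FALSE]
    sig$exposure <- sample(exposures, nrow(sig), replace = TRUE)
    sig$p_value <- stats::runif(nrow(sig), 0, pLow)
    rows[[1L]] <- sig
    other <- base
    other$exposure <- sample(exposures, nrow(other), replace = TRUE)
    other$p_value <- stats::runif(nrow(other), pHigh, 1)
    ## avoid colliding with the significant row of the same exposure
    clash <- paste(other$chrom, other$start, other$exposure) %in%
        paste(sig$chrom, sig$start, sig$exposure)
    rows[[2L]] <- other[!clash, , drop = FALSE]
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$start, out$exposure), ]
    rownames(out) <- NULL
    if (!is.null(path))
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    out
}

#' Assemble a toy genome from a synthetic dataset
#'
#' Concatenates the dataset's windows in shuffled order into one or more
#' synthetic chromosomes, so that re-tiling the FASTA reproduces the
#' windows bit-exactly, and returns the matching per-window truth as a
#' \code{GRanges}. Used to exercise the genome-scan path end to end.
#'
#' @param dataset A \linkS4class{LabeledWindows}.
#' @param shuffleSeed Seed for the window order.
#' @param nChrom Number of chromosomes to spread the windows over.
#' @param fastaPath,truthBedPath Optional output paths (FASTA / BED with
#'   the class in the name field).
#' @return List with \code{genome} (\linkS4class{DNAStringSet}),
#'   \code{truth} (\code{GRanges} with a \code{label} column), and
#'   \code{windows} (the input dataset remapped onto the toy genome's
#'   coordinates, in tiling order).
#' @export
assembleToyGenome <- function(dataset, shuffleSeed = 1L, nChrom = 1L,
                              fastaPath = NULL, truthBedPath = NULL) {
    stopifnot(is(dataset, "LabeledWindows"))
    set.seed(shuffleSeed)
    n <- length(dataset)
    ord <- sample(n)
    L <- windowSize(dataset)
    chromOf <- rep(paste0("synthChr", seq_len(nChrom)),
                   each = ceiling(n / nChrom))[seq_len(n)]
    seqs <- as.character(windowSeqs(dataset))[ord]
    labs <- as.character(windowLabels(dataset))[ord]
    idxByChrom <- split(seq_len(n), factor(chromOf, unique(chromOf)))
    genome <- Biostrings::DNAStringSet(vapply(
        idxByChrom, function(ix) paste(seqs[ix], collapse = ""),
        character(1)))
    truth <- GRanges(chromOf,
                     IRanges(start = unlist(lapply(idxByChrom, function(ix)
                         (seq_along(ix) - 1L) * L + 1L),
                         use.names = FALSE),
                             width = L))
    mcols(truth)$label <- labs
    if (!is.null(fastaPath))
        Biostrings::writeXStringSet(genome, fastaPath)
    if (!is.null(truthBedPath)) {
        bed <- truth
        mcols(bed)$name <- labs
        mcols(bed)$label <- NULL
        rtracklayer::export.bed(bed, truthBedPath)
    }
    remapped <- new("LabeledWindows",
                    ranges = GRanges(seqnames(truth),
                                     IRanges(start(truth), end(truth))),
                    seqs = Biostrings::DNAStringSet(seqs),
                    windowSize = L,
                    labels = factor(labs, levels = .CLASS_LEVELS))
    list(genome = genome, truth = truth, windows = remapped)
}
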