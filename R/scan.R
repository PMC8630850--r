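#' @include hybrid.R
NULL

#' Scan a genome with a trained hybrid model
#'
#' Tiles every chromosome into windows of the model's input length, scores
#' each window through the hybrid path (first-conv features into the
#' boosted classifier), and returns one record per window. Chromosomes
#' are processed in chunks so memory stays bounded regardless of genome
#' length; chromosomes shorter than one window are skipped with a
#' message. All-N stretches are scored like any other sequence (they
#' simply produce valid probabilities).
#'
#' @param model A \linkS4class{HybridModel}.
#' @param genome A \linkS4class{DNAStringSet}, a FASTA path, or a
#'   \linkS4class{GenomeWindows} that is already tiled.
#' @param batchSize Windows scored per forward pass.
#' @param threshold Decision threshold on the DMR probability
#'   (default 0.5).
#' @return A \code{GRanges} with metadata columns \code{probability} and
#'   \code{call} ("DMR"/"nonDMR"), one range per scanned window.
#' @export
scanGenome <- function(model, genome, batchSize = 256L, threshold = 0.5) {
    stopifnot(is(model, "HybridModel"))
    ws <- model@network@inputLength
    if (is.character(genome)) genome <- readGenomeFasta(genome)
    if (is(genome, "GenomeWindows")) {
        if (windowSize(genome) != ws)
            stop("window size ", windowSize(genome),
                 " does not match the model input length ", ws)
        windows <- genome
    } else {
        short <- Biostrings::width(genome) < ws
        if (any(short))
            message("skipping ", sum(short),
                    " sequence(s) shorter than one window: ",
                    paste(utils::head(names(genome)[short], 5L),
                          collapse = ", "))
        windows <- tileWindows(genome[!short], windowSize = ws)
    }
    n <- length(windows)
    prob <- numeric(n)
    for (bStart in seq(1L, n, by = 4L * batchSize)) {
        bi <- bStart:min(bStart + 4L * batchSize - 1L, n)
        prob[bi] <- predictHybrid(model, windows[bi], batchSize = batchSize)
    }
    gr <- windowRanges(windows)
    mcols(gr)$probability <- prob
    mcols(gr)$call <- ifelse(prob >= threshold, "DMR", "nonDMR")
    gr
}

#' Summarize a genome scan
#'
#' Per chromosome and in total: the number of windows, predicted DMRs,
#' the percentage of windows called DMR (%Genome), the size and
#' percentage of the "maximum possible DMR" set (windows with 1-200 CpGs
#' per 1000 bp; predictions should sit well below this bound), and,
#' when training DMR keys are supplied, the recall of the training DMRs
#' (percent called DMR by the scan).
#'
#' @param records \code{GRanges} from [scanGenome()].
#' @param windows The scanned \linkS4class{GenomeWindows} (or the genome
#'   \code{DNAStringSet}/FASTA path to re-tile) -- needed for CpG counts.
#' @param trainingDmrKeys Optional character vector of training DMR
#'   window keys.
#' @param maxCpgDensityPct Island cutoff for the upper bound (default 20).
#' @return data.frame with one row per chromosome plus a "Total" row:
#'   \code{chrom}, \code{nWindows}, \code{nPredictedDmr},
#'   \code{pctGenome}, \code{nMaxPossible}, \code{pctMaxPossible},
#'   \code{pctRecallTrainingDmrs}.
#' @export
summarizeScan <- function(records, windows, trainingDmrKeys = NULL,
                          maxCpgDensityPct = 20) {
    if (is.character(windows)) windows <- readGenomeFasta(windows)
    if (is(windows, "DNAStringSet"))
        windows <- tileWindows(windows,
                               windowSize = unique(width(records)))
    keys <- windowKeys(windows)
    recKeys <- sprintf("%s:%d-%d", as.character(seqnames(records)),
                       start(records) - 1L, end(records))
    if (!setequal(keys, recKeys))
        stop("scan records and windows do not cover the same tiling")
    maxPoss <- maxPossibleDmrs(windows, maxCpgDensityPct)
    df <- data.frame(chrom = as.character(seqnames(records)),
                     key = recKeys,
                     dmr = mcols(records)$call == "DMR",
                     stringsAsFactors = FALSE)
    chromOf <- sub(":.*$", "", maxPoss)
    oneRow <- function(ch) {
        sub <- if (identical(ch, "Total")) df else df[df$chrom == ch, ]
        nMax <- if (identical(ch, "Total")) length(maxPoss)
                else sum(chromOf == ch)
        rec <- NA_real_
        if (!is.null(trainingDmrKeys)) {
            tk <- intersect(trainingDmrKeys, sub$key)
            if (length(tk))
                rec <- 100 * mean(sub$dmr[match(tk, sub$key)])
        }
        data.frame(chrom = ch, nWindows = nrow(sub),
                   nPredictedDmr = sum(sub$dmr),
                   pctGenome = 100 * sum(sub$dmr) / nrow(sub),
                   nMaxPossible = nMax,
                   pctMaxPossible = 100 * nMax / nrow(sub),
                   pctRecallTrainingDmrs = rec,
                   stringsAsFactors = FALSE)
    }
    do.call(rbind, lapply(c(unique(df$chrom), "Total"), oneRow))
}

#' Randomly sample predicted DMRs for visualization
#'
#' Draws a uniform random sample (without replacement) of the windows
#' called DMR, of size \code{round(fraction * n_predicted)}. The default
#' fraction, 0.02%, matches the sampling rate used for chromosome-level
#' visualization tracks.
#'
#' @param records \code{GRanges} from [scanGenome()].
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return \code{GRanges} of sampled DMR windows, sorted.
#' @export
sampleTrack <- function(records, fraction = 0.0002, seed = 1L) {
    stopifnot(fraction > 0, fraction <= 1)
    dmr <- records[mcols(records)$call == "DMR"]
    n <- round(fraction * length(dmr))
    set.seed(seed)
    GenomicRanges::sort(dmr[sample(length(dmr), n)], ignore.strand = TRUE)
}

#' Write scan records as BED6
#'
#' One line per record: chrom, 0-based start, exclusive end, the call as
#' the name, \code{round(1000 * probability)} as the score, and "." for
#' strand. Records must be coordinate-sorted; with \code{sort = TRUE}
#' (default) they are sorted on the way out, otherwise unsorted input is
#' an error.
#'
#' @param records \code{GRanges} from [scanGenome()] or [sampleTrack()].
#' @param path Output BED path.
#' @param sort Sort records before writing (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeScanBed <- function(records, path, sort = TRUE) {
    srt <- GenomicRanges::sort(records, ignore.strand = TRUE)
    if (!identical(as.character(seqnames(records)),
                   as.character(seqnames(srt))) ||
        !identical(start(records), start(srt))) {
        if (!sort) stop("records are not coordinate-sorted")
        records <- srt
    }
    out <- GRanges(seqnames(records),
                   IRanges(start(records), end(records)))
    mcols(out)$name <- mcols(records)$call
    mcols(out)$score <- round(1000 * mcols(records)$probability)
    rtracklayer::export.bed(out, path)
    invisible(path)
}
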