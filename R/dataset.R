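#' @include windows.R
NULL

#' Read a per-region differential-methylation statistics table
#'
#' Reads the TSV of per-window statistics the labeling step consumes: one
#' row per (window, exposure) with the probability that the window is
#' \emph{not} a DMR. Coordinates are 0-based half-open and must align with
#' the genome tiling.
#'
#' @param path TSV file with header columns \code{chrom}, \code{start},
#'   \code{end}, \code{exposure}, \code{p_value}.
#' @return data.frame with those columns plus a \code{key} column.
#' @export
readRegionStats <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "exposure", "p_value")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("stats table lacks column(s): ", paste(missing, collapse = ", "))
    if (any(!is.finite(df$p_value)) || any(df$p_value <= 0 | df$p_value > 1))
        stop("p_value must lie in (0, 1]")
    df$key <- sprintf("%s:%d-%d", df$chrom, as.integer(df$start),
                      as.integer(df$end))
    df
}

#' Label DMR windows from per-exposure p-values
#'
#' A window is a DMR if its p-value is strictly below \code{threshold}
#' (default 1e-5) for at least one exposure: labels are the union over
#' exposures, so a region significant only under, say, atrazine is still a
#' DMR. Duplicate (window, exposure) rows are collapsed to their minimum
#' p-value with a warning.
#'
#' @param stats data.frame as returned by [readRegionStats()] (a
#'   \code{key} column is derived if absent).
#' @param threshold Strict upper bound on the p-value, in (0, 1).
#' @return Character vector of DMR window keys.
#' @examples
#' stats <- data.frame(chrom = "chr1", start = c(0, 0, 1000),
#'                     end = c(1000, 1000, 2000),
#'                     exposure = c("atrazine", "DDT", "DDT"),
#'                     p_value = c(1e-6, 0.5, 1e-5))
#' labelDmrs(stats)  # chr1:0-1000 (union rule); 1e-5 exactly is NOT a DMR
#' @export
labelDmrs <- function(stats, threshold = 1e-5) {
    stopifnot(threshold > 0, threshold < 1)
    if (is.null(stats$key))
        stats$key <- sprintf("%s:%d-%d", stats$chrom,
                             as.integer(stats$start), as.integer(stats$end))
    dupKey <- paste(stats$key, stats$exposure, sep = "\r")
    if (anyDuplicated(dupKey)) {
        warning("duplicate (window, exposure) rows; keeping minimum p-value")
        stats <- stats[order(stats$p_value), ]
        stats <- stats[!duplicated(paste(stats$key, stats$exposure,
                                         sep = "\r")), ]
    }
    sort(unique(stats$key[stats$p_value < threshold]))
}

#' Select CpG-free windows as negatives
#'
#' Returns the keys of windows with zero CpG dinucleotides: without a CpG,
#' differential cytosine methylation is impossible, so these windows are
#' unambiguous non-DMRs. Any window that is simultaneously in the DMR set
#' (which should be impossible for a true DMR) is excluded with a warning.
#'
#' @param windows A \linkS4class{GenomeWindows} object.
#' @param dmrKeys Optional character vector of DMR window keys to audit
#'   against.
#' @return Character vector of non-DMR window keys.
#' @export
selectNonDmrs <- function(windows, dmrKeys = character()) {
    keys <- windowKeys(windows)[cpgCount(windows) == 0L]
    clash <- intersect(keys, dmrKeys)
    if (length(clash)) {
        warning("window(s) labeled DMR despite zero CpGs, excluded from ",
                "negatives: ", paste(utils::head(clash, 5L), collapse = ", "))
        keys <- setdiff(keys, clash)
    }
    sort(keys)
}

#' Windows that could possibly be DMRs
#'
#' The "maximum possible DMR" set: every window that is not trivially
#' non-DMR, i.e. has at least one CpG and at most
#' \code{maxCpgDensityPct}% CpGs (200 per 1000 bp window at the default
#' 20%; "more than 20%" is strict, so a window with exactly 200 CpGs is
#' included). The size of this set is an upper bound on the number of
#' windows any model could predict as DMRs.
#'
#' @param windows A \linkS4class{GenomeWindows} object.
#' @param maxCpgDensityPct CpG-island density cutoff in percent
#'   (default 20; 10 is the alternative island definition).
#' @return Character vector of window keys.
#' @export
maxPossibleDmrs <- function(windows, maxCpgDensityPct = 20) {
    counts <- cpgCount(windows)
    maxCount <- maxCpgDensityPct / 100 * windowSize(windows)
    sort(windowKeys(windows)[counts >= 1L & counts <= maxCount])
}

#' Build the labeled training dataset
#'
#' Combines the DMR labeling rule (p < threshold in any exposure) with the
#' CpG-free negative rule into a \linkS4class{LabeledWindows} dataset.
#' Windows that are neither (CpGs present but no significant p-value) are
#' left out: failing the p-value threshold does not make a window a
#' non-DMR. Optionally, CpG-island windows and/or high-p-value windows can
#' be added to the negatives; both are off by default since they
#' contribute on the order of 1-2% more negatives and have been observed
#' to diminish performance.
#'
#' @param windows A \linkS4class{GenomeWindows} tiling of the genome.
#' @param stats Optional data.frame of per-exposure statistics
#'   ([readRegionStats()]); NULL yields a negatives-only dataset.
#' @param threshold DMR p-value threshold (default 1e-5, strict).
#' @param chrom Restrict to one chromosome, or \code{"ALL"} (default).
#' @param includeCpgIslandNegatives Add windows above the island density
#'   cutoff to the negatives.
#' @param cpgIslandDensityPct Island density cutoff in percent (default 20).
#' @param includeHighPNegatives Add windows whose minimum p-value across
#'   exposures exceeds \code{highPThreshold} to the negatives.
#' @param highPThreshold Lower bound for the high-p negative rule.
#' @return A \linkS4class{LabeledWindows} object.
#' @export
buildDataset <- function(windows, stats = NULL, threshold = 1e-5,
                         chrom = "ALL",
                         includeCpgIslandNegatives = FALSE,
                         cpgIslandDensityPct = 20,
                         includeHighPNegatives = FALSE,
                         highPThreshold = 0.5) {
    stopifnot(is(windows, "GenomeWindows"))
    if (!identical(chrom, "ALL")) {
        keep <- as.character(seqnames(windows@ranges)) %in% chrom
        windows <- windows[which(keep)]
        if (!is.null(stats)) stats <- stats[stats$chrom %in% chrom, ]
    }
    keys <- windowKeys(windows)
    dmrKeys <- character()
    if (!is.null(stats) && nrow(stats)) {
        if (is.null(stats$key))
            stats$key <- sprintf("%s:%d-%d", stats$chrom,
                                 as.integer(stats$start),
                                 as.integer(stats$end))
        bad <- setdiff(unique(stats$key), keys)
        if (length(bad))
            stop("stats rows not aligned to the window tiling: ",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5L) sprintf(" (and %d more)",
                                               length(bad) - 5L))
        dmrKeys <- labelDmrs(stats, threshold)
    }
    negKeys <- selectNonDmrs(windows, dmrKeys)
    if (includeCpgIslandNegatives) {
        dens <- 100 * cpgCount(windows) / windowSize(windows)
        island <- keys[dens > cpgIslandDensityPct]
        negKeys <- union(negKeys, setdiff(island, dmrKeys))
    }
    if (includeHighPNegatives && !is.null(stats) && nrow(stats)) {
        minP <- tapply(stats$p_value, stats$key, min)
        highP <- names(minP)[minP > highPThreshold]
        negKeys <- union(negKeys, setdiff(highP, dmrKeys))
    }
    sel <- c(sort(dmrKeys), sort(setdiff(negKeys, dmrKeys)))
    lab <- factor(rep(c("DMR", "nonDMR"),
                      c(length(dmrKeys), length(sel) - length(dmrKeys))),
                  levels = .CLASS_LEVELS)
    sub <- windows[sel]
    new("LabeledWindows", ranges = sub@ranges, seqs = sub@seqs,
        windowSize = sub@windowSize, labels = lab)
}

#' Export window labels as BED
#'
#' Writes a BED file with the class label in the name field (0-based
#' half-open coordinates, as BED requires).
#'
#' @param x A \linkS4class{LabeledWindows} object.
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
exportLabelBed <- function(x, path) {
    stopifnot(is(x, "LabeledWindows"))
    gr <- x@ranges
    mcols(gr)$name <- as.character(x@labels)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    rtracklayer::export.bed(gr, path)
    invisible(path)
}
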