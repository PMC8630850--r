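#' @include AllClasses.R
NULL

## byte lookup table: ASCII code -> row index in the one-hot alphabet
.alphabetLut <- local({
    lut <- integer(256)
    lut[utf8ToInt("A") + 1L] <- 1L
    lut[utf8ToInt("C") + 1L] <- 2L
    lut[utf8ToInt("G") + 1L] <- 3L
    lut[utf8ToInt("T") + 1L] <- 4L
    lut[utf8ToInt("N") + 1L] <- 5L
    lut
})

#' Read a genome FASTA into normalized sequences
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file, uppercases the
#' sequences and maps every character outside A, C, G, T (IUPAC ambiguity
#' codes included) to N, so that downstream code sees exactly the
#' five-letter alphabet. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A \linkS4class{DNAStringSet} named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtR", ">chr2", "NNNNA"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    head <- readLines(path, n = 50L, warn = FALSE)
    nonEmpty <- which(nzchar(trimws(head)))
    if (!length(nonEmpty))
        stop("empty FASTA file: ", path)
    if (!startsWith(trimws(head[nonEmpty[1L]]), ">"))
        stop("malformed FASTA: line ", nonEmpty[1L],
             " of ", path, " does not start a '>' record")
    seqs <- Biostrings::readBStringSet(path)
    if (!length(seqs)) stop("no records in FASTA file: ", path)
    chars <- toupper(as.character(seqs))
    chars <- gsub("[^ACGTN]", "N", chars)
    out <- Biostrings::DNAStringSet(chars)
    names(out) <- sub("\\s.*$", "", names(seqs))
    out
}

#' Tile sequences into fixed-width windows
#'
#' Divides each sequence into consecutive non-overlapping windows of
#' \code{windowSize} bp, anchored at position 0. A trailing remainder
#' shorter than the window is dropped, so every emitted window has the
#' full width (the network input shape is fixed).
#'
#' @param seqs A \linkS4class{DNAStringSet} (e.g. from
#'   [readGenomeFasta()]), or a single character string.
#' @param windowSize Window width in bp (default 1000).
#' @param chrom Chromosome name used when \code{seqs} is a bare string.
#' @return A \linkS4class{GenomeWindows} object with
#'   \code{floor(length / windowSize)} windows per sequence.
#' @examples
#' gw <- tileWindows(paste(rep("ACGT", 625), collapse = ""),
#'                   windowSize = 1000, chrom = "chr1")
#' length(gw)  # 2: the trailing 500 bp are dropped
#' @export
tileWindows <- function(seqs, windowSize = 1000L, chrom = "seq1") {
    windowSize <- as.integer(windowSize)
    stopifnot(windowSize >= 1L)
    if (is.character(seqs) && is.null(names(seqs)))
        names(seqs) <- rep_len(chrom, length(seqs))
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)))
        names(seqs) <- paste0("seq", seq_along(seqs))
    grl <- lapply(seq_along(seqs), function(i) {
        n <- Biostrings::width(seqs)[i] %/% windowSize
        if (n == 0L) return(GRanges())
        GRanges(names(seqs)[i],
                IRanges(start = (seq_len(n) - 1L) * windowSize + 1L,
                        width = windowSize))
    })
    gr <- suppressWarnings(do.call(c, grl))
    if (!length(gr))
        return(new("GenomeWindows", ranges = GRanges(),
                   seqs = Biostrings::DNAStringSet(), windowSize = windowSize))
    ws <- Biostrings::subseq(seqs[as.character(seqnames(gr))],
                             start = start(gr), width = windowSize)
    names(ws) <- NULL
    new("GenomeWindows", ranges = gr, seqs = ws, windowSize = windowSize)
}

## character string -> 5 x L binary matrix (rows A,C,G,T,N)
.encodeOne <- function(s) {
    bytes <- as.integer(charToRaw(s))
    idx <- .alphabetLut[bytes + 1L]
    if (any(idx == 0L))
        stop("unexpected character in sequence: ",
             rawToChar(as.raw(bytes[which(idx == 0L)[1L]])))
    L <- length(idx)
    m <- matrix(0, nrow = 5L, ncol = L,
                dimnames = list(.WINDOW_ALPHABET, NULL))
    m[cbind(idx, seq_len(L))] <- 1
    m
}

#' One-hot encode windows
#'
#' Encodes each window as a 5 x width binary matrix with fixed row order
#' (A, C, G, T, N): column j has a single 1 in the row of base j. A set of
#' windows becomes a 3-dimensional array (5, width, n).
#'
#' @param x A \linkS4class{GenomeWindows} object or a character string.
#' @return A 5 x L matrix for a single sequence, or a 5 x L x n array.
#' @examples
#' oneHotEncode("ACGTN")  # the 5x5 identity under row order A,C,G,T,N
#' @export
oneHotEncode <- function(x) {
    if (is.character(x) && length(x) == 1L) return(.encodeOne(x))
    if (is(x, "GenomeWindows")) {
        chars <- as.character(x@seqs)
        L <- x@windowSize
    } else if (is.character(x)) {
        chars <- x
        L <- unique(nchar(x))
        if (length(L) != 1L) stop("sequences must have equal length")
    } else stop("cannot one-hot encode objects of class ", class(x))
    out <- array(0, dim = c(5L, L, length(chars)),
                 dimnames = list(.WINDOW_ALPHABET, NULL, NULL))
    for (i in seq_along(chars)) out[, , i] <- .encodeOne(chars[i])
    out
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [oneHotEncode()] for a single window: takes the row with the
#' maximum value in each column.
#'
#' @param m A 5 x L matrix with rownames A, C, G, T, N.
#' @return A character string of length L.
#' @export
decodeOneHot <- function(m) {
    stopifnot(is.matrix(m), nrow(m) == 5L)
    paste(.WINDOW_ALPHABET[apply(m, 2L, which.max)], collapse = "")
}

#' CpG content of windows
#'
#' Counts CG dinucleotides (a cytosine immediately followed by a guanine;
#' the substrate of cytosine methylation) per window. Dinucleotides
#' involving N never count. Density is expressed as a percentage of the
#' window size, the convention used for the CpG-island bound (a 1000 bp
#' window with more than 200 CpGs has density > 20%).
#'
#' @param x A \linkS4class{GenomeWindows} object.
#' @return data.frame with columns \code{key}, \code{cpgCount},
#'   \code{cpgDensityPct}.
#' @seealso [cpgCount()] for the bare counts.
#' @export
cpgProfile <- function(x) {
    stopifnot(is(x, "GenomeWindows"))
    counts <- cpgCount(x)
    data.frame(key = windowKeys(x), cpgCount = counts,
               cpgDensityPct = 100 * counts / x@windowSize,
               stringsAsFactors = FALSE)
}

#' @rdname cpgProfile
#' @return \code{cpgCount}: integer vector of CG dinucleotide counts.
#' @export
cpgCount <- function(x) {
    stopifnot(is(x, "GenomeWindows"))
    Biostrings::vcountPattern("CG", x@seqs, fixed = TRUE)
}

#' Write window coordinates as TSV
#'
#' Emits one row per window with 0-based half-open coordinates
#' (\code{chrom}, \code{start}, \code{end}), plus a \code{label} column for
#' labeled sets.
#'
#' @param x A \linkS4class{GenomeWindows} or \linkS4class{LabeledWindows}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeWindowTsv <- function(x, path) {
    df <- data.frame(chrom = as.character(seqnames(x@ranges)),
                     start = start(x@ranges) - 1L, end = end(x@ranges),
                     stringsAsFactors = FALSE)
    if (is(x, "LabeledWindows")) df$label <- as.character(x@labels)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
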