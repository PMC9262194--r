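# fread with transparent gzip support (no external decompression helper)
.readTable <- function(path) {
    if (grepl("\\.gz$", path)) {
        con <- gzfile(path, "r")
        on.exit(close(con))
        lines <- readLines(con)
        if (!length(lines))
            return(data.table::data.table())
        data.table::fread(text = lines, header = FALSE)
    } else {
        data.table::fread(path, header = FALSE)
    }
}

#' Read a HiC-Pro contact map (.matrix + _abs.bed)
#'
#' The bed file holds the binning (chrom, start, end, bin_id; 0-based
#' half-open), the matrix file the sparse triplets (bin_id_i, bin_id_j,
#' count). Gzip-compressed inputs are accepted transparently. The triplets
#' are normalized on load: pairs flipped to \code{bin1 < bin2}, duplicates
#' summed, self pairs dropped, zero counts removed.
#'
#' @param matrixPath path to the 3-column triplet file.
#' @param bedPath path to the 4+-column bins file.
#' @param binSize optional bin size in bp; inferred when NULL.
#' @return A \linkS4class{ContactMap}.
#' @export
readHicPro <- function(matrixPath, bedPath, binSize = NULL) {
    bed <- .readTable(bedPath)
    if (ncol(bed) < 4L)
        stop("bed file must have at least 4 columns (chrom, start, end, id)")
    bins <- GRanges(seqnames = as.character(bed[[1L]]),
                    ranges = IRanges(start = bed[[2L]] + 1L, end = bed[[3L]]))
    mcols(bins)$bin_id <- as.integer(bed[[4L]])
    mat <- .readTable(matrixPath)
    if (nrow(mat) == 0L)
        return(ContactMap(bins, data.frame(bin1 = integer(), bin2 = integer(),
                                           count = integer()),
                          binSize = binSize))
    if (ncol(mat) != 3L)
        stop("matrix file must have exactly 3 columns (i, j, count)")
    cnt <- mat[[3L]]
    if (any(cnt != round(cnt)))
        stop("non-integer count in matrix file at line ",
             which(cnt != round(cnt))[1L])
    ContactMap(bins, data.frame(bin1 = mat[[1L]], bin2 = mat[[2L]],
                                count = cnt),
               binSize = binSize)
}

#' Write a contact map as a HiC-Pro matrix/bed pair
#'
#' @param map \linkS4class{ContactMap}.
#' @param prefix output path prefix; writes \code{<prefix>.matrix} and
#'   \code{<prefix>_abs.bed}.
#' @return invisibly, the two file paths.
#' @export
writeHicPro <- function(map, prefix) {
    b <- map@bins
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
                      start = GenomicRanges::start(b) - 1L,
                      end = GenomicRanges::end(b),
                      id = mcols(b)$bin_id)
    bedPath <- paste0(prefix, "_abs.bed")
    matPath <- paste0(prefix, ".matrix")
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(interactions(map), matPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(c(matrix = matPath, bed = bedPath))
}

#' Read a BED file of intervals (baits, features)
#'
#' Minimal BED reader: first three columns chrom/start/end (0-based
#' half-open), converted to 1-based closed GRanges. Strand is ignored.
#'
#' @param path BED file path (optionally gzipped).
#' @return GRanges.
#' @export
readBedIntervals <- function(path) {
    bed <- .readTable(path)
    if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
    GRanges(seqnames = as.character(bed[[1L]]),
            ranges = IRanges(start = bed[[2L]] + 1L, end = bed[[3L]]))
}

#' Assign fragment-level read pairs to bins
#'
#' Each fragment end is assigned to the bin whose half-open interval contains
#' its midpoint \code{floor((start + end) / 2)} (0-based coordinates; a
#' midpoint equal to a bin start belongs to that bin). Pairs whose two ends
#' fall in the same bin are removed as self interactions; remaining pairs are
#' aggregated into counts. Midpoints beyond the last bin of their chromosome
#' are clamped to the terminal bin with a warning reporting how many reads
#' were clamped.
#'
#' @param pairs data.frame with columns chromA, startA, endA, chromB, startB,
#'   endB (0-based half-open fragment coordinates).
#' @param bins GRanges with \code{bin_id} metadata, covering the chromosomes
#'   referenced.
#' @return A \linkS4class{ContactMap}.
#' @export
binFragmentPairs <- function(pairs, bins) {
    bins <- .orderBins(bins)
    stopifnot(all(c("chromA", "startA", "endA", "chromB", "startB",
                    "endB") %in% names(pairs)))
    if (any(pairs$startA < 0 | pairs$startB < 0))
        stop("fragment coordinates must be non-negative")
    clamped <- 0L
    assign1 <- function(chrom, start, end) {
        mid <- floor((start + end) / 2)
        id <- rep(NA_integer_, length(mid))
        for (ch in unique(chrom)) {
            sel <- chrom == ch
            bsel <- as.character(GenomicRanges::seqnames(bins)) == ch
            if (!any(bsel))
                stop("no bins for chromosome ", ch)
            st0 <- GenomicRanges::start(bins)[bsel] - 1L
            en0 <- GenomicRanges::end(bins)[bsel]
            k <- findInterval(mid[sel], st0)
            if (any(k < 1L))
                stop("fragment midpoint before the first bin of ", ch)
            over <- mid[sel] >= en0[length(en0)]
            clamped <<- clamped + sum(over)
            k[over] <- length(st0)
            id[sel] <- mcols(bins)$bin_id[bsel][k]
        }
        id
    }
    iA <- assign1(as.character(pairs$chromA), pairs$startA, pairs$endA)
    iB <- assign1(as.character(pairs$chromB), pairs$startB, pairs$endB)
    if (clamped > 0L)
        warning(clamped, " read end(s) beyond the terminal bin were clamped")
    ContactMap(bins, data.frame(bin1 = iA, bin2 = iB, count = 1L))
}

# neg-log10 with minimal decimal formatting: at least one decimal place,
# trailing zeros trimmed ("12.0", "3.907411").
.fmtNegLog10 <- function(p) {
    v <- sprintf("%.6f", -log10(p))
    v <- sub("0+$", "", v)
    ifelse(grepl("\\.$", v), paste0(v, "0"), v)
}

#' Write scored interaction calls to a tab-delimited file
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, distance, observed,
#' expected, neg_log10_pvalue, class. Rows are sorted by P-value ascending
#' with coordinate tie-breaks; trans distances are written as "NA".
#'
#' @param records data.frame from [scoreInteractions()] (or a subset).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCalls <- function(records, path) {
    records <- .orderRecords(records)
    out <- data.frame(chrom1 = records$chrom1, start1 = records$start1,
                      end1 = records$end1, chrom2 = records$chrom2,
                      start2 = records$start2, end2 = records$end2,
                      distance = ifelse(is.na(records$distance), "NA",
                                        format(records$distance,
                                               scientific = FALSE,
                                               trim = TRUE)),
                      observed = records$observed,
                      expected = sprintf("%.6g", records$expected),
                      neg_log10_pvalue = .fmtNegLog10(records$pvalue),
                      class = records$class, stringsAsFactors = FALSE)
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write calls to ", path, ": ",
                          conditionMessage(ok))
    invisible(path)
}

#' Read back a calls file written by [writeCalls()]
#'
#' @param path calls file path.
#' @return data.frame with the file's columns plus a recovered \code{pvalue}.
#' @export
readCalls <- function(path) {
    x <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA")
    x$pvalue <- 10^(-x$neg_log10_pvalue)
    x
}
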