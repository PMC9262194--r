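.datatable.aware <- TRUE

#' Construct a ContactMap from bins and raw triplets
#'
#' Normalizes raw triplets: pairs are flipped so that \code{bin1 < bin2},
#' duplicate pairs are summed, self pairs (\code{i == j}) are dropped, and
#' zero-count rows are removed. The count mass removed with self pairs is
#' reported through the \code{"droppedSelfMass"} attribute.
#'
#' @param bins GRanges with a \code{bin_id} integer metadata column.
#' @param triplets data.frame-like with columns \code{bin1}, \code{bin2},
#'   \code{count} (any order of ids; duplicates allowed).
#' @param binSize bin width in bp; inferred from the most common bin width
#'   when NULL.
#' @return A \linkS4class{ContactMap}.
#' @export
ContactMap <- function(bins, triplets, binSize = NULL) {
    bins <- .orderBins(bins)
    tr <- data.frame(bin1 = as.integer(triplets$bin1),
                     bin2 = as.integer(triplets$bin2),
                     count = triplets$count)
    bad <- setdiff(unique(c(tr$bin1, tr$bin2)), mcols(bins)$bin_id)
    if (length(bad))
        stop("interaction refers to unknown bin id(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
    if (any(tr$count != round(tr$count)))
        stop("non-integer count at triplet row ",
             which(tr$count != round(tr$count))[1L])
    tr$count <- as.integer(round(tr$count))
    swap <- tr$bin1 > tr$bin2
    if (any(swap)) {
        tmp <- tr$bin1[swap]
        tr$bin1[swap] <- tr$bin2[swap]
        tr$bin2[swap] <- tmp
    }
    selfMass <- sum(tr$count[tr$bin1 == tr$bin2])
    tr <- tr[tr$bin1 != tr$bin2 & tr$count > 0L, , drop = FALSE]
    if (nrow(tr)) {
        dt <- data.table::as.data.table(tr)
        tr <- as.data.frame(dt[, list(count = sum(count)),
                               by = c("bin1", "bin2")])
        tr <- tr[order(tr$bin1, tr$bin2), , drop = FALSE]
        rownames(tr) <- NULL
    }
    if (is.null(binSize)) {
        w <- GenomicRanges::width(bins)
        binSize <- as.integer(names(sort(table(w), decreasing = TRUE))[1L])
    }
    out <- new("ContactMap", bins = bins, interactions = tr,
               binSize = as.integer(binSize))
    attr(out, "droppedSelfMass") <- selfMass
    out
}

.orderBins <- function(bins) {
    stopifnot(is(bins, "GRanges"))
    o <- order(as.character(GenomicRanges::seqnames(bins)),
               GenomicRanges::start(bins))
    bins <- bins[o]
    sp <- split(bins, droplevels(GenomicRanges::seqnames(bins)))
    for (g in sp) {
        if (length(g) > 1L &&
            any(GenomicRanges::start(g)[-1L] <=
                GenomicRanges::end(g)[-length(g)]))
            stop("bins within a chromosome must be non-overlapping")
    }
    bins
}

#' @rdname ContactMap-class
#' @aliases hicBins interactions binSize
#' @export
setMethod("hicBins", "ContactMap", function(x) x@bins)

#' @rdname ContactMap-class
#' @export
setMethod("interactions", "ContactMap", function(x) x@interactions)

#' @rdname ContactMap-class
#' @export
setMethod("binSize", "ContactMap", function(x) x@binSize)

setMethod("show", "ContactMap", function(object) {
    tr <- object@interactions
    cat("ContactMap:", length(object@bins), "bins of",
        object@binSize, "bp;", nrow(tr), "stored pairs; total reads",
        sum(tr$count), "\n")
    chr <- unique(as.character(GenomicRanges::seqnames(object@bins)))
    cat("  chromosomes:", paste(utils::head(chr, 6L), collapse = ", "),
        if (length(chr) > 6L) "..." else "", "\n")
})

# Per-triplet covariates used throughout the model layer: indices of the two
# ends into the bin vector, cis flag, genomic distance (midpoint difference)
# and powers of its natural log.
.covariates <- function(map) {
    b <- map@bins
    tr <- map@interactions
    id <- mcols(b)$bin_id
    i1 <- match(tr$bin1, id)
    i2 <- match(tr$bin2, id)
    chrom <- as.character(GenomicRanges::seqnames(b))
    mid <- (GenomicRanges::start(b) + GenomicRanges::end(b)) / 2
    cis <- chrom[i1] == chrom[i2]
    d <- ifelse(cis, abs(mid[i1] - mid[i2]), NA_real_)
    if (any(cis & d <= 0))
        stop("cis pair with non-positive distance; self pairs must be removed")
    L <- ifelse(cis, log(pmax(d, 1)), 0)
    list(i1 = i1, i2 = i2, x = as.numeric(tr$count), cis = cis, d = d,
         L = L, L2 = L^2, L3 = L^3, n = nrow(tr), nbins = length(b))
}

# Raw marginal totals s_i (sum of stored counts over pairs touching each bin).
.rawBinTotals <- function(map) {
    cv <- .covariates(map)
    s <- numeric(cv$nbins)
    t1 <- rowsum(cv$x, cv$i1)
    t2 <- rowsum(cv$x, cv$i2)
    s[as.integer(rownames(t1))] <- s[as.integer(rownames(t1))] + t1[, 1L]
    s[as.integer(rownames(t2))] <- s[as.integer(rownames(t2))] + t2[, 1L]
    s
}
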