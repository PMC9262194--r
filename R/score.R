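#' Score every stored bin pair under a trained model
#'
#' Produces one record per stored triplet with observed count, expected count
#' under the fitted background, the NB tail P-value, genomic distance (NA for
#' trans) and interaction class. A Benjamini-Hochberg \code{qvalue} column is
#' added for convenience; primary calls threshold the raw P-value.
#'
#' @param map \linkS4class{ContactMap}.
#' @param fit a \linkS4class{BackgroundFit} or
#'   \linkS4class{CaptureBackgroundFit}.
#' @param inclusive P-value convention: TRUE for \eqn{P(X \ge x)} (default),
#'   FALSE for the strict tail \eqn{P(X > x)}.
#' @return data.frame with columns chrom1, start1, end1, chrom2, start2, end2,
#'   bin1, bin2, distance, observed, expected, pvalue, qvalue, class. Start
#'   coordinates are 0-based half-open (BED convention).
#' @export
scoreInteractions <- function(map, fit, inclusive = TRUE) {
    cov <- .covariates(map)
    b <- map@bins
    if (is(fit, "CaptureBackgroundFit")) {
        mu <- .capturePairExpectations(cov, fit@binStats$s, fit@paramsByClass,
                                       fit@classes)
        r <- exp(unname(vapply(fit@paramsByClass,
                               function(p) log(p@dispersion), 0)))
        rvec <- r[as.integer(fit@classes)]
        p <- nbTailProb(cov$x, mu, rvec, inclusive = inclusive)
        cls <- paste(ifelse(cov$cis, "cis", "trans"),
                     as.character(fit@classes), sep = "/")
    } else {
        mu <- .pairExpectations(cov, fit@binStats$s, fit@params)
        p <- nbTailProb(cov$x, mu, fit@params@dispersion,
                        inclusive = inclusive)
        cls <- ifelse(cov$cis, "cis", "trans")
    }
    st <- GenomicRanges::start(b) - 1L
    en <- GenomicRanges::end(b)
    chr <- as.character(GenomicRanges::seqnames(b))
    data.frame(chrom1 = chr[cov$i1], start1 = st[cov$i1], end1 = en[cov$i1],
               chrom2 = chr[cov$i2], start2 = st[cov$i2], end2 = en[cov$i2],
               bin1 = interactions(map)$bin1, bin2 = interactions(map)$bin2,
               distance = cov$d, observed = interactions(map)$count,
               expected = mu, pvalue = p,
               qvalue = stats::p.adjust(p, method = "BH"),
               class = cls, stringsAsFactors = FALSE)
}

.orderRecords <- function(records) {
    records[order(records$pvalue, records$chrom1, records$start1,
                  records$chrom2, records$start2), , drop = FALSE]
}

#' Select significant interactions
#'
#' Subset of scored records with raw P-value strictly below the threshold,
#' sorted by P-value ascending with deterministic coordinate tie-breaks.
#'
#' @param records data.frame from [scoreInteractions()].
#' @param threshold P-value cutoff in (0, 1); the analysis default is 0.001.
#' @return sorted subset of \code{records}.
#' @export
callSignificant <- function(records, threshold = 0.001) {
    if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
        stop("threshold must be in (0, 1]")
    out <- .orderRecords(records[records$pvalue < threshold, , drop = FALSE])
    rownames(out) <- NULL
    out
}

#' Top-k interactions by P-value
#'
#' @param records data.frame from [scoreInteractions()].
#' @param k number of records to keep (k > nrow returns all).
#' @return the k best-P-value records, deterministic tie-breaks as in
#'   [callSignificant()].
#' @export
topInteractions <- function(records, k) {
    stopifnot(k >= 0)
    out <- .orderRecords(records)
    out <- utils::head(out, k)
    rownames(out) <- NULL
    out
}
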