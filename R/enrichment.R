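# GRanges of one end of the interaction records (records store 0-based
# starts; GRanges are 1-based closed).
.endRanges <- function(records, end = 1L) {
    GRanges(records[[paste0("chrom", end)]],
            IRanges(start = records[[paste0("start", end)]] + 1L,
                    end = records[[paste0("end", end)]]))
}

.fisherP <- function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L,
                              byrow = TRUE))$p.value
}

#' Region-based feature enrichment of significant interactions
#'
#' Enrichment = fraction of significant records with at least one end
#' overlapping the feature, divided by the same fraction over all records
#' (the genome-wide expectation). The P-value comes from Fisher's exact test
#' (two-sided) on the 2x2 table (significant overlap / significant
#' non-overlap / all overlap / all non-overlap).
#'
#' @param sig significant records (subset of \code{all}).
#' @param all all scored records.
#' @param feature GRanges of the feature intervals (>= 1 bp overlap counts;
#'   strand ignored). GWAS-SNP enrichment is this operation with point
#'   intervals.
#' @return list with \code{enrichment}, \code{pvalue}, \code{fractionSig},
#'   \code{fractionAll} and the 2x2 \code{table}.
#' @export
regionEnrichment <- function(sig, all, feature) {
    ovr <- function(rec) overlapsAny(.endRanges(rec, 1L), feature) |
        overlapsAny(.endRanges(rec, 2L), feature)
    .enrichFromFlags(ovr(sig), ovr(all))
}

#' Pair-based feature enrichment (both ends must overlap)
#'
#' As [regionEnrichment()] but a record counts only when one end overlaps
#' \code{featureA} and the other end overlaps \code{featureB} (order-free);
#' with \code{featureA == featureB} this is the "both sides overlap the
#' feature" analysis used for promoter-enhancer or CTCF-CTCF pairs.
#'
#' @param sig,all records as in [regionEnrichment()].
#' @param featureA,featureB GRanges.
#' @return as [regionEnrichment()].
#' @export
pairEnrichment <- function(sig, all, featureA, featureB = featureA) {
    ovr <- function(rec) {
        a1 <- overlapsAny(.endRanges(rec, 1L), featureA)
        a2 <- overlapsAny(.endRanges(rec, 2L), featureA)
        b1 <- overlapsAny(.endRanges(rec, 1L), featureB)
        b2 <- overlapsAny(.endRanges(rec, 2L), featureB)
        (a1 & b2) | (a2 & b1)
    }
    .enrichFromFlags(ovr(sig), ovr(all))
}

.enrichFromFlags <- function(ovSig, ovAll) {
    fS <- mean(ovSig)
    fA <- mean(ovAll)
    if (!is.finite(fA) || fA == 0) {
        warning("no overlap among all records; enrichment undefined")
        return(list(enrichment = NA_real_, pvalue = NA_real_,
                    fractionSig = fS, fractionAll = fA, table = NULL))
    }
    tab <- matrix(c(sum(ovSig), sum(!ovSig), sum(ovAll), sum(!ovAll)),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c("sig", "all"),
                                  c("overlap", "no_overlap")))
    list(enrichment = fS / fA,
         pvalue = .fisherP(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
         fractionSig = fS, fractionAll = fA, table = tab)
}

#' Permutation enrichment for capture Hi-C other ends
#'
#' For capture libraries the background expectation is built by permutation:
#' the observed overlap fraction of the significant bait-interacting bins is
#' divided by the mean overlap fraction of \code{nPerm} random draws (without
#' replacement, each of the same size) from a pool of bins with no target
#' interaction. The empirical P-value is
#' \eqn{(1 + \#\{perm \ge obs\}) / (nPerm + 1)}.
#'
#' @param sigOtherEnds GRanges of the significant other-end bins.
#' @param candidatePool GRanges of candidate bins (must exclude
#'   target-interacting bins and be at least as large as
#'   \code{sigOtherEnds}).
#' @param feature GRanges of the feature.
#' @param nPerm number of permutations.
#' @param seed RNG seed (fixed seed reproduces the result exactly).
#' @return list with \code{enrichment}, \code{pvalue},
#'   \code{observedFraction}, \code{permutationMean}.
#' @export
capturePermutationEnrichment <- function(sigOtherEnds, candidatePool,
                                         feature, nPerm = 1000L, seed = 1L) {
    nSig <- length(sigOtherEnds)
    if (length(candidatePool) < nSig)
        stop("candidate pool is smaller than the significant set")
    obs <- mean(overlapsAny(sigOtherEnds, feature))
    poolOv <- overlapsAny(candidatePool, feature)
    set.seed(seed)
    perm <- vapply(seq_len(nPerm),
                   function(i) mean(poolOv[sample.int(length(poolOv),
                                                      nSig)]), 0)
    pm <- mean(perm)
    enr <- if (pm == 0) {
        warning("permutation mean overlap is zero; enrichment undefined")
        NA_real_
    } else obs / pm
    list(enrichment = enr,
         pvalue = (1 + sum(perm >= obs)) / (nPerm + 1),
         observedFraction = obs, permutationMean = pm)
}

#' Overlap of interactions with eQTL SNP-gene pairs
#'
#' A record bridges an eQTL pair iff one end contains the SNP position and
#' the other end intersects the gene's promoter window (TSS +/-
#' \code{promoterHalfwidth}). With halfwidth 0 only ends containing the exact
#' TSS position count.
#'
#' @param records scored records.
#' @param eqtl data.frame with columns \code{chrom_snp}, \code{pos_snp},
#'   \code{chrom_gene}, \code{tss} (0-based positions).
#' @param promoterHalfwidth promoter half-width in bp (default 5000).
#' @return fraction of records bridging at least one eQTL pair.
#' @export
eqtlPairOverlap <- function(records, eqtl, promoterHalfwidth = 5000) {
    if (nrow(records) == 0L) return(NA_real_)
    snp <- GRanges(eqtl$chrom_snp,
                   IRanges(start = eqtl$pos_snp + 1L, width = 1L))
    prom <- GRanges(eqtl$chrom_gene,
                    IRanges(start = eqtl$tss - promoterHalfwidth + 1L,
                            end = eqtl$tss + promoterHalfwidth + 1L))
    e1 <- .endRanges(records, 1L)
    e2 <- .endRanges(records, 2L)
    pairHit <- function(endS, endP) {
        hS <- findOverlaps(endS, snp)
        hP <- findOverlaps(endP, prom)
        keyS <- paste(queryHits(hS), subjectHits(hS))
        keyP <- paste(queryHits(hP), subjectHits(hP))
        unique(queryHits(hS)[keyS %in% keyP])
    }
    hit <- union(pairHit(e1, e2), pairHit(e2, e1))
    length(hit) / nrow(records)
}

#' eQTL-pair enrichment of significant interactions
#'
#' @param sig,all records as in [regionEnrichment()].
#' @param eqtl,promoterHalfwidth see [eqtlPairOverlap()].
#' @return list with \code{fractionSig}, \code{fractionAll},
#'   \code{enrichment}.
#' @export
eqtlPairEnrichment <- function(sig, all, eqtl, promoterHalfwidth = 5000) {
    fS <- eqtlPairOverlap(sig, eqtl, promoterHalfwidth)
    fA <- eqtlPairOverlap(all, eqtl, promoterHalfwidth)
    list(fractionSig = fS, fractionAll = fA,
         enrichment = if (is.na(fA) || fA == 0) NA_real_ else fS / fA)
}
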