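# Shared fixtures: everything is built in code at test time.

library(GenomicRanges)

# n equal bins of `size` bp on one chromosome, ids 1..n
toyBins <- function(n, size = 10000L, chrom = "chrT", idOffset = 0L) {
    gr <- GRanges(chrom, IRanges(start = (seq_len(n) - 1L) * size + 1L,
                                 end = seq_len(n) * size))
    S4Vectors::mcols(gr)$bin_id <- seq_len(n) + idOffset
    gr
}

toyMap <- function(n = 5L, size = 10000L, triplets) {
    ContactMap(toyBins(n, size), triplets, binSize = size)
}

# deep-library truth used by recovery-style experiments: the expectation
# surface is scaled x40 so that almost no pair is zero-truncated
deepTruth <- function() simTruthParameters(depth = 40)

# truth expectation of given pairs (wrapper over the internal helper)
truthMu <- function(sim, bin1, bin2) {
    hicnb:::.truthMu(hicBins(sim$map), sim$truth, bin1, bin2)
}

# distance-stratified relative error of fitted vs truth expected counts
# over the map's stored pairs (the identified product scale)
decayMaxRelErr <- function(sim, fit, dmax = 1e7, nstr = 20L) {
    cov <- hicnb:::.covariates(sim$map)
    muh <- hicnb:::.pairExpectations(cov, binStats(fit)$s,
                                     modelParameters(fit))
    mut <- truthMu(sim, interactions(sim$map)$bin1,
                   interactions(sim$map)$bin2)
    br <- exp(seq(log(min(cov$d)) - 1e-9, log(dmax), length.out = nstr + 1L))
    str <- cut(cov$d, br)
    mh <- tapply(muh, str, mean)
    mt <- tapply(mut, str, mean)
    ok <- !is.na(mh) & !is.na(mt)
    max(abs(mh[ok] - mt[ok]) / mt[ok])
}
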