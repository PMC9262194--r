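# minimal scored-record builder on a toy genome
mkRecords <- function(n, chrom = "chrT", size = 10000L, gap = 3L,
                      offset = 0L) {
    i <- seq_len(n) + offset
    j <- i + gap
    data.frame(chrom1 = chrom, start1 = (i - 1L) * size, end1 = i * size,
               chrom2 = chrom, start2 = (j - 1L) * size, end2 = j * size,
               bin1 = i, bin2 = j, distance = gap * size,
               observed = 5L, expected = 2, pvalue = 0.5, qvalue = 0.5,
               class = "cis", stringsAsFactors = FALSE)
}

genomeWide <- GRanges("chrT", IRanges(1, 10^9))

# exact two-sided Fisher p by hypergeometric enumeration on the 2x2 table
enumFisherP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("region enrichment has exact trivial values and a Fisher oracle", {
    all <- mkRecords(100)
    sig <- all[1:10, ]
    expect_equal(regionEnrichment(sig, all, genomeWide)$enrichment, 1)
    expect_equal(regionEnrichment(all, all,
                                  GRanges("chrT",
                                          IRanges(1, 15000)))$enrichment, 1)
    # toy 4/10 sig vs 20/100 all -> enrichment 2, Fisher p from enumeration
    feat <- GRanges("chrT", IRanges((c(1:4, 11:20) - 1L) * 10000L + 1L,
                                    width = 50L))
    ov <- function(rec) (rec$bin1 %in% c(1:4, 11:20)) |
        (rec$bin2 %in% c(1:4, 11:20))
    res <- regionEnrichment(sig, all, feat)
    expect_equal(res$fractionSig, mean(ov(sig)))
    expect_equal(res$enrichment, mean(ov(sig)) / mean(ov(all)))
    tab <- res$table
    expect_equal(res$pvalue,
                 enumFisherP(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
    # no overlap among all records -> NA with a warning
    none <- GRanges("chrZ", IRanges(1, 10))
    expect_warning(r0 <- regionEnrichment(sig, all, none), "undefined")
    expect_true(is.na(r0$enrichment))
})

test_that("pair enrichment requires opposite ends to hit the two features", {
    all <- mkRecords(60)
    sig <- all[1:12, ]
    expect_equal(pairEnrichment(sig, all, genomeWide,
                                genomeWide)$enrichment, 1)
    # featureA on the sig end1 bins, featureB on the sig end2 bins
    featA <- GRanges("chrT", IRanges((sig$bin1 - 1L) * 10000L + 1L,
                                     width = 5L))
    featB <- GRanges("chrT", IRanges((sig$bin2 - 1L) * 10000L + 1L,
                                     width = 5L))
    res <- pairEnrichment(sig, all, featA, featB)
    # direct counting oracle (order-free end matching)
    a1 <- all$bin1 %in% sig$bin1; a2 <- all$bin2 %in% sig$bin1
    b1 <- all$bin1 %in% sig$bin2; b2 <- all$bin2 %in% sig$bin2
    ovAll <- (a1 & b2) | (a2 & b1)
    expect_equal(res$fractionSig, 1)
    expect_equal(res$enrichment, 1 / mean(ovAll))
    expect_warning(pairEnrichment(all[0, ], all,
                                  GRanges("chrZ", IRanges(1, 2)),
                                  GRanges("chrZ", IRanges(1, 2))),
                   "undefined")
})

test_that("capture permutation enrichment matches hypergeometric expectations", {
    pool <- toyBins(100)
    feat <- GRanges("chrT", IRanges((0:49) * 10000L + 1L, width = 10L))
    sigEnds <- pool[3:12]
    res <- capturePermutationEnrichment(sigEnds, pool, feat, nPerm = 1000,
                                        seed = 7)
    # permutation mean: hypergeometric mean 0.5 within 3 sigma of the
    # mean of 1000 draws of size 10
    sdDraw <- sqrt(0.5 * 0.5 * (100 - 10) / 99 / 10)
    expect_lt(abs(res$permutationMean - 0.5), 3 * sdDraw / sqrt(1000))
    # determinism
    res2 <- capturePermutationEnrichment(sigEnds, pool, feat, nPerm = 1000,
                                         seed = 7)
    expect_identical(res$enrichment, res2$enrichment)
    expect_identical(res$pvalue, res2$pvalue)
    # feature covering everything -> enrichment exactly 1, p ~ 1
    resAll <- capturePermutationEnrichment(sigEnds, pool, genomeWide,
                                           nPerm = 200, seed = 1)
    expect_equal(resAll$enrichment, 1)
    expect_equal(resAll$pvalue, 1)
    expect_error(capturePermutationEnrichment(pool, pool[1:3], feat),
                 "smaller")
})

test_that("permutation p-values are super-uniform under the null", {
    pool <- toyBins(120)
    sigEnds <- pool[1:20]
    set.seed(11)
    ps <- vapply(1:200, function(i) {
        hit <- sample.int(120, 40)
        feat <- GRanges("chrT", IRanges((hit - 1L) * 10000L + 1L,
                                        width = 10L))
        capturePermutationEnrichment(sigEnds, pool, feat, nPerm = 99,
                                     seed = i)$pvalue
    }, 0)
    expect_lte(mean(ps <= 0.05), 0.08)
})

test_that("eQTL pair bridging follows the SNP/promoter end rule", {
    rec <- mkRecords(3, gap = 5L)   # pairs (1,6),(2,7),(3,8)
    # SNP in bin 1, TSS in bin 6 -> record 1 bridges
    eq <- data.frame(chrom_snp = "chrT", pos_snp = 5000,
                     chrom_gene = "chrT", tss = 55000)
    expect_equal(eqtlPairOverlap(rec, eq), 1 / 3)
    # SNP and TSS in the same bin: no record has both ends there
    eqSame <- data.frame(chrom_snp = "chrT", pos_snp = 5000,
                         chrom_gene = "chrT", tss = 6000)
    expect_equal(eqtlPairOverlap(rec, eqSame), 0)
    # halfwidth 0: only the exact-TSS end counts
    eqEdge <- data.frame(chrom_snp = "chrT", pos_snp = 5000,
                         chrom_gene = "chrT", tss = 60005)
    expect_equal(eqtlPairOverlap(rec, eqEdge, promoterHalfwidth = 0), 0)
    eqIn <- data.frame(chrom_snp = "chrT", pos_snp = 5000,
                       chrom_gene = "chrT", tss = 59000)
    expect_equal(eqtlPairOverlap(rec, eqIn, promoterHalfwidth = 0), 1 / 3)
    # enrichment wrapper
    en <- eqtlPairEnrichment(rec[1, ], rec, eq)
    expect_equal(en$enrichment, 1 / (1 / 3))
})
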