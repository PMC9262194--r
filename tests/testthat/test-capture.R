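test_that("target flagging follows half-open overlap", {
    bins <- toyBins(4, 10000L)
    # bait equal to bin 2; bait spanning the 3/4 boundary
    baits <- GRanges("chrT", IRanges(start = c(10001, 29995),
                                     end = c(20000, 30005)))
    fl <- flagTargets(bins, baits)
    expect_equal(unname(fl), c(FALSE, TRUE, TRUE, TRUE))
    expect_equal(names(fl), as.character(1:4))
    # bait ending exactly at a bin start flags only the upstream bin
    ab <- GRanges("chrT", IRanges(start = 5001, end = 10000))
    expect_equal(unname(flagTargets(bins, ab)), c(TRUE, FALSE, FALSE, FALSE))
    far <- GRanges("chrZ", IRanges(1, 100))
    expect_error(flagTargets(bins, far), "no targets")
})

test_that("interaction classes partition the pairs symmetrically", {
    fl <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE), 1:4)
    expect_equal(as.character(interactionClass(1, 2, fl)), "TT")
    expect_equal(as.character(interactionClass(1, 3, fl)), "TO")
    expect_equal(as.character(interactionClass(3, 1, fl)), "TO")
    expect_equal(as.character(interactionClass(3, 4, fl)), "OO")
    # partition over a simulated capture map
    sim <- simulateBackground(nBins = 60, seed = 41, targetFraction = 0.2,
                              baitBoost = 4)
    fl2 <- stats::setNames(sim$truth$targetFlags, 1:60)
    tr <- interactions(sim$map)
    cls <- interactionClass(tr$bin1, tr$bin2, fl2)
    expect_equal(sum(table(cls)), nrow(tr))
})

test_that("TT conversion is Eq-consistent, linear, and identity on TT", {
    expect_equal(convertToTT(6, 2, 5), 15)
    expect_equal(convertToTT(6, 3, 3), 6)              # identity when mus equal
    x <- c(1, 4, 9)
    expect_equal(convertToTT(2 * x, 2, 5), 2 * convertToTT(x, 2, 5))
})

test_that("capture mode with baits over every bin equals the general model", {
    sim <- simulateBackground(nBins = 150, binSize = 20000,
                              params = deepTruth(), seed = 42)
    allBaits <- GenomicRanges::reduce(hicBins(sim$map))
    cfg <- trainingConfig(rounds = 2)
    gen <- fitBackground(sim$map, cfg)
    expect_warning(cap <- fitCaptureBackground(sim$map, allBaits, cfg,
                                               minClassPairs = 100),
                   "borrowing")
    expect_true(all(cap@classes == "TT"))
    rg <- scoreInteractions(sim$map, gen)
    rc <- scoreInteractions(sim$map, cap)
    expect_identical(rg$pvalue, rc$pvalue)
    expect_identical(rg$expected, rc$expected)
    expect_equal(rc$class, paste0(rg$class, "/TT"))
    # converted counts are exactly the observed counts (identity on TT)
    expect_equal(ttEquivalentCounts(sim$map, cap),
                 as.numeric(interactions(sim$map)$count))
})

test_that("per-class parameters recover class-wise backgrounds", {
    sim <- simulateBackground(nBins = 600, binSize = 20000,
                              params = deepTruth(), targetFraction = 0.1,
                              baitBoost = 10, seed = 43)
    baits <- hicBins(sim$map)[sim$truth$targetFlags]
    fit <- fitCaptureBackground(sim$map, baits, trainingConfig(rounds = 2))
    cov <- hicnb:::.covariates(sim$map)
    muh <- hicnb:::.capturePairExpectations(cov, binStats(fit)$s,
                                            fit@paramsByClass, fit@classes)
    mut <- truthMu(sim, interactions(sim$map)$bin1,
                   interactions(sim$map)$bin2)
    rvec <- vapply(fit@paramsByClass, function(p) p@dispersion,
                   0)[as.integer(fit@classes)]
    p <- nbTailProb(cov$x, muh, rvec)
    for (cl in c("TT", "TO", "OO")) {
        sel <- fit@classes == cl
        nstr <- max(4L, min(12L, floor(sum(sel) / 300)))
        br <- exp(seq(log(min(cov$d[sel])) - 1e-9, log(max(cov$d[sel])),
                      length.out = nstr + 1L))
        str <- cut(cov$d[sel], br)
        mh <- tapply(muh[sel], str, mean)
        mt <- tapply(mut[sel], str, mean)
        nst <- tapply(muh[sel], str, length)
        # compare only where a stratum has enough pairs to estimate a mean
        ok <- !is.na(mh) & !is.na(mt) & nst >= 100
        expect_lt(max(abs(mh[ok] - mt[ok]) / mt[ok]), 0.15)
        # per-class null call rate stays in the nominal range
        expect_lt(mean(p[sel] < 0.001), 0.01)
    }
})

test_that("dispersion can be pooled across capture classes", {
    sim <- simulateBackground(nBins = 200, binSize = 20000,
                              params = deepTruth(), targetFraction = 0.25,
                              baitBoost = 3, seed = 47)
    baits <- hicBins(sim$map)[sim$truth$targetFlags]
    fit <- fitCaptureBackground(sim$map, baits,
                                trainingConfig(rounds = 1),
                                shareDispersion = TRUE)
    rs <- vapply(fit@paramsByClass, function(p) p@dispersion, 0)
    expect_equal(unname(rs[1]), unname(rs[2]))
    expect_equal(unname(rs[2]), unname(rs[3]))
})
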