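test_that("analytic gradient matches central finite differences", {
    sim <- simulateBackground(nBins = 40, seed = 7)
    cov <- hicnb:::.covariates(sim$map)
    s <- hicnb:::.rawBinTotals(sim$map)
    keep <- seq_len(cov$n)
    norm <- hicnb:::.decayNorm(cov, keep)
    theta <- c(b = 0.9, bm = -5, lvb = log(0.02), c0 = 1.5, c1 = -2.1,
               c2 = 0.3, c3 = -0.05, lfc = log(0.3), lr = log(3))
    an <- hicnb:::.nllGrad(theta, cov, s, keep, 10, 0.5, norm)$grad
    num <- vapply(names(theta), function(nm) {
        h <- 1e-6 * max(1, abs(theta[[nm]]))
        tp <- theta; tp[[nm]] <- tp[[nm]] + h
        tm <- theta; tm[[nm]] <- tm[[nm]] - h
        (hicnb:::.nllGrad(tp, cov, s, keep, 10, 0.5, norm,
                          wantGrad = FALSE)$nll -
         hicnb:::.nllGrad(tm, cov, s, keep, 10, 0.5, norm,
                          wantGrad = FALSE)$nll) / (2 * h)
    }, 0)
    expect_equal(unname(an), unname(num), tolerance = 1e-5)
})

test_that("compiled likelihood kernel equals the R reference", {
    sim <- simulateBackground(nBins = 50, seed = 9)
    cov <- hicnb:::.covariates(sim$map)
    s <- hicnb:::.rawBinTotals(sim$map)
    keep <- which(cov$x > 0)
    norm <- hicnb:::.decayNorm(cov, keep)
    theta <- hicnb:::.thetaFromParams(
        hicnb:::.initParams(cov, s, keep, 10, 0.5), norm)
    ref <- hicnb:::.nllGrad(theta, cov, s, keep, 10, 0.5, norm)
    sub <- hicnb:::.subsetCov(cov, keep, norm)
    fast <- hicnb:::.nllGradCpp(theta, sub$i1, sub$i2, sub$xi, sub$ux,
                                sub$sumLgX1, sub$cis, sub$z, s, 10, 0.5)
    expect_equal(fast$nll, ref$nll, tolerance = 1e-10)
    expect_equal(unname(fast$grad), unname(ref$grad), tolerance = 1e-10)
})

test_that("negative log-likelihood sums pair terms", {
    p <- BackgroundParameters(biasExponent = 1, biasOffset = -3,
                              biasFloor = 1e-4, decay = c(4, -0.3, 0, 0),
                              transFloor = 0.5, dispersion = 3)
    map1 <- toyMap(triplets = data.frame(bin1 = 1, bin2 = 3, count = 4))
    bs <- data.frame(bin_id = 1:5, s = hicnb:::.rawBinTotals(map1))
    # single-term sum equals -nbLogPmf of that term
    cov <- hicnb:::.covariates(map1)
    mu <- hicnb:::.pairExpectations(cov, bs$s, p)
    expect_equal(negLogLikelihood(map1, p, bs), -nbLogPmf(4, mu, 3))
    # three-triplet map matches a hand-summed oracle
    map3 <- toyMap(triplets = data.frame(bin1 = c(1, 1, 2),
                                         bin2 = c(2, 4, 5),
                                         count = c(2, 7, 1)))
    bs3 <- data.frame(bin_id = 1:5, s = hicnb:::.rawBinTotals(map3))
    cov3 <- hicnb:::.covariates(map3)
    mu3 <- hicnb:::.pairExpectations(cov3, bs3$s, p)
    expect_equal(negLogLikelihood(map3, p, bs3),
                 -sum(nbLogPmf(c(2, 7, 1), mu3, 3)))
    # additivity: duplicating every pair as distinct pairs doubles the NLL
    map6 <- ContactMap(toyBins(10),
                       data.frame(bin1 = c(1, 1, 2, 6, 6, 7),
                                  bin2 = c(2, 4, 5, 7, 9, 10),
                                  count = c(2, 7, 1, 2, 7, 1)))
    bs6 <- data.frame(bin_id = 1:10, s = c(bs3$s, bs3$s))
    expect_equal(negLogLikelihood(map6, p, bs6),
                 2 * negLogLikelihood(map3, p, bs3))
})

test_that("a zero-iteration round returns the starting parameters", {
    sim <- simulateBackground(nBins = 30, seed = 2)
    p0 <- simTruthParameters()
    res <- fitRound(sim$map, p0, config = trainingConfig(maxIters = 0))
    expect_false(res$converged)
    expect_equal(modelParameters(fitBackground(
        sim$map, trainingConfig(rounds = 1, maxIters = 0),
        params0 = p0))@decay, p0@decay)
})

test_that("bin totals substitute masked pairs by their expectations", {
    map <- toyMap(triplets = data.frame(bin1 = c(1, 1, 2),
                                        bin2 = c(2, 3, 3),
                                        count = c(100, 3, 2)))
    p <- BackgroundParameters(biasExponent = 1, biasOffset = -2,
                              biasFloor = 1e-4, decay = c(1.5, 0, 0, 0),
                              transFloor = 0.5, dispersion = 2)
    raw <- recomputeBinTotals(map, masked = rep(FALSE, 3), p)
    expect_equal(raw$s, hicnb:::.rawBinTotals(map))
    # masking pair (1,2): both its ends drop by x - mu
    cov <- hicnb:::.covariates(map)
    mu <- hicnb:::.pairExpectations(cov, raw$s, p)
    one <- recomputeBinTotals(map, masked = c(TRUE, FALSE, FALSE), p,
                              binStats = raw)
    expect_equal(one$s[1:2], raw$s[1:2] - (100 - mu[1]))
    expect_equal(one$s[3], raw$s[3])
    # all pairs masked: totals equal marginal sums of expectations
    allm <- recomputeBinTotals(map, masked = rep(TRUE, 3), p,
                               binStats = raw)
    oracle <- c(mu[1] + mu[2], mu[1] + mu[3], mu[2] + mu[3], 0, 0)
    expect_equal(allm$s, oracle)
})

test_that("the fitted optimum is a fixed point of another round", {
    sim <- simulateBackground(nBins = 150, binSize = 20000,
                              params = deepTruth(), seed = 13)
    fit <- fitBackground(sim$map, trainingConfig(rounds = 1))
    # refit starting at the optimum: the fitted surface stays put
    # (raw cubic coefficients can trade off along near-flat directions,
    # so compare predictions and the objective, not raw coefficients)
    again <- fitRound(sim$map, modelParameters(fit),
                      config = trainingConfig())
    cov <- hicnb:::.covariates(sim$map)
    mu0 <- hicnb:::.pairExpectations(cov, binStats(fit)$s,
                                     modelParameters(fit))
    mu1 <- hicnb:::.pairExpectations(cov, binStats(fit)$s, again$params)
    expect_lt(max(abs(mu1 - mu0) / mu0), 0.03)
    expect_lte(utils::tail(again$nllTrace, 1),
               utils::tail(fit@nllTrace[[1]], 1) + 1)
})

test_that("NLL is non-increasing over the back half of a round", {
    sim <- simulateBackground(nBins = 150, binSize = 20000,
                              params = deepTruth(), seed = 17)
    fit <- fitBackground(sim$map, trainingConfig(rounds = 1))
    tr <- fit@nllTrace[[1]]
    half <- tr[seq(ceiling(length(tr) / 2), length(tr))]
    expect_true(all(diff(half) <= 1e-6 * abs(half[-length(half)])))
})

test_that("a single-round fit on deep background is near-nominally calibrated", {
    sim <- simulateBackground(nBins = 300, binSize = 20000,
                              params = deepTruth(), seed = 19)
    fit <- fitBackground(sim$map, trainingConfig(rounds = 1))
    rec <- scoreInteractions(sim$map, fit)
    for (t in c(0.01, 0.001)) {
        frac <- mean(rec$pvalue < t)
        expect_gt(frac, t / 3)
        expect_lt(frac, 3 * t)
    }
})

test_that("deep-background parameter recovery works from default init", {
    sim <- simulateBackground(nBins = 400, binSize = 20000,
                              params = deepTruth(), seed = 23)
    fit <- fitBackground(sim$map, trainingConfig(rounds = 1))
    p <- modelParameters(fit)
    expect_lt(abs(p@biasExponent - 1), 0.05)
    expect_lt(abs(log(p@dispersion) - log(4)), 0.15)
    expect_lt(decayMaxRelErr(sim, fit, dmax = 7.5e6), 0.1)
})

test_that("spiking loops never decreases the number of masked pairs", {
    sim <- simulateBackground(nBins = 250, binSize = 20000,
                              params = deepTruth(), seed = 29)
    cfg <- trainingConfig(rounds = 2)
    base <- sum(maskedPairs(fitBackground(sim$map, cfg)))
    ut <- which(upper.tri(matrix(0, 250, 250)), arr.ind = TRUE)
    d <- abs(ut[, 1] - ut[, 2]) * 20000
    cand <- which(d >= 40000 & d <= 2e6)
    set.seed(31)
    pick <- sample(cand, 25)
    sp <- spikeLoops(sim$map, data.frame(bin1 = ut[pick, 1],
                                         bin2 = ut[pick, 2], fold = 10),
                     sim$truth, seed = 37)
    withLoops <- sum(maskedPairs(fitBackground(sp$map, cfg)))
    expect_gte(withLoops, base)
})
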