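# Internal optimizer representation: all strictly positive parameters are
# optimized on the log scale so positivity is maintained automatically, and
# the decay cubic is optimized in a standardized log-distance basis
# z = (ln d - m0) / s0 so its four coefficients have comparable sensitivity
# (ADAM takes equal-sized per-coordinate steps; on the raw ln d basis the
# cubic coefficient multiplies ln(d)^3 ~ 4e3 and a single step destroys the
# curve). norm = c(m0, s0); the user-facing parameterization stays a0..a3 on
# natural-log distance.
.THETA <- c("b", "bm", "lvb", "c0", "c1", "c2", "c3", "lfc", "lr")

# cubic coefficients on ln d  ->  coefficients on z = (L - m0)/s0
.decayToC <- function(a, norm) {
    m0 <- norm[1]; s0 <- norm[2]
    c(a[1] + a[2] * m0 + a[3] * m0^2 + a[4] * m0^3,
      s0 * (a[2] + 2 * a[3] * m0 + 3 * a[4] * m0^2),
      s0^2 * (a[3] + 3 * a[4] * m0),
      s0^3 * a[4])
}

# inverse of .decayToC
.decayToA <- function(cc, norm) {
    m0 <- norm[1]; s0 <- norm[2]
    u <- 1 / s0; w <- -m0 / s0
    c(cc[1] + cc[2] * w + cc[3] * w^2 + cc[4] * w^3,
      cc[2] * u + 2 * cc[3] * u * w + 3 * cc[4] * u * w^2,
      cc[3] * u^2 + 3 * cc[4] * u^2 * w,
      cc[4] * u^3)
}

.thetaFromParams <- function(p, norm = c(0, 1)) {
    cc <- .decayToC(p@decay, norm)
    c(b = p@biasExponent, bm = p@biasOffset, lvb = log(p@biasFloor),
      c0 = cc[1], c1 = cc[2], c2 = cc[3], c3 = cc[4],
      lfc = log(p@transFloor), lr = log(p@dispersion))
}

.paramsFromTheta <- function(theta, k, baseE, norm = c(0, 1)) {
    BackgroundParameters(biasExponent = theta[["b"]],
                         biasOffset = theta[["bm"]],
                         biasFloor = exp(theta[["lvb"]]),
                         decay = .decayToA(unname(theta[c("c0", "c1", "c2",
                                                          "c3")]), norm),
                         transFloor = exp(theta[["lfc"]]),
                         dispersion = exp(theta[["lr"]]),
                         sharpness = k, baseExpectation = baseE)
}

# 0-based index/covariate subset handed to the C++ likelihood kernel;
# counts are factored into unique values so special functions are cached.
.subsetCov <- function(cov, keep, norm) {
    x <- cov$x[keep]
    ux <- sort(unique(x))
    list(i1 = cov$i1[keep] - 1L, i2 = cov$i2[keep] - 1L,
         xi = match(x, ux) - 1L, ux = ux, sumLgX1 = sum(lgamma(x + 1)),
         cis = cov$cis[keep],
         z = (cov$L[keep] - norm[1]) / norm[2])
}

# distance normalization constants from the kept cis pairs
.decayNorm <- function(cov, keep) {
    L <- cov$L[keep][cov$cis[keep]]
    if (length(L) < 2L) return(c(0, 1))
    c(mean(L), max(stats::sd(L), 1e-6))
}

# Negative log-likelihood of the kept triplets and its analytic gradient with
# respect to theta. The gradient flows through the soft maxima of Eqs for
# f(d) and mu; the hard maximum in the bias factor routes the gradient to
# (b, bm) where the power law is active and to v_base where the floor is.
.nllGrad <- function(theta, cov, s, keep, k, baseE, norm = c(0, 1),
                     wantGrad = TRUE) {
    b <- theta[["b"]]; bm <- theta[["bm"]]
    vbase <- exp(theta[["lvb"]])
    c0 <- theta[["c0"]]; c1 <- theta[["c1"]]
    c2 <- theta[["c2"]]; c3 <- theta[["c3"]]
    fc <- exp(theta[["lfc"]]); r <- exp(theta[["lr"]])

    lns <- ifelse(s > 0, log(s), 0)
    vraw <- ifelse(s > 0, exp(b * lns + bm), 0)
    v <- pmax(vraw, vbase)
    act <- vraw > vbase

    i1 <- cov$i1[keep]; i2 <- cov$i2[keep]
    x <- cov$x[keep]; cis <- cov$cis[keep]
    z <- (cov$L[keep] - norm[1]) / norm[2]
    z2 <- z * z; z3 <- z2 * z

    vi <- v[i1]; vj <- v[i2]
    fv <- exp(pmin(c3 * z3 + c2 * z2 + c1 * z + c0, 500))
    w1 <- stats::plogis(k * (fv - fc))
    g <- ifelse(cis, w1 * fv + (1 - w1) * fc, fc)
    P <- vi * vj * g
    w2 <- stats::plogis(k * (P - baseE))
    mu <- w2 * P + (1 - w2) * baseE

    ll <- stats::dnbinom(x, size = r, mu = mu, log = TRUE)
    nll <- -sum(ll)
    if (!is.finite(nll)) {
        bad <- which(!is.finite(ll))[1L]
        stop("non-finite likelihood term at pair index ", keep[bad])
    }
    if (!wantGrad) return(list(nll = nll, grad = NULL))

    A <- -(x / mu - (x + r) / (r + mu))        # d nll / d mu
    dmudP <- w2 + k * w2 * (1 - w2) * (P - baseE)
    B <- A * dmudP                              # d nll / d P
    C <- B * P
    ai <- act[i1]; aj <- act[i2]
    gb <- sum(C * (lns[i1] * ai + lns[i2] * aj))
    gbm <- sum(C * (ai + aj))
    glvb <- vbase * sum(B * g * (vj * (1 - ai) + vi * (1 - aj)))

    D <- B * vi * vj                            # d nll / d g
    dgdfv <- w1 + k * w1 * (1 - w1) * (fv - fc)
    dgdfc <- (1 - w1) - k * w1 * (1 - w1) * (fv - fc)
    Dc <- D[cis]; Ec <- (Dc * dgdfv[cis] * fv[cis])
    gc0 <- sum(Ec)
    gc1 <- sum(Ec * z[cis])
    gc2 <- sum(Ec * z2[cis])
    gc3 <- sum(Ec * z3[cis])
    glfc <- fc * (sum(Dc * dgdfc[cis]) + sum(D[!cis]))

    dnlldr <- -(digamma(x + r) - digamma(r) + log(r / (r + mu)) +
                1 - (r + x) / (r + mu))
    glr <- r * sum(dnlldr)

    list(nll = nll,
         grad = c(b = gb, bm = gbm, lvb = glvb, c0 = gc0, c1 = gc1,
                  c2 = gc2, c3 = gc3, lfc = glfc, lr = glr))
}

#' Negative log-likelihood of a contact map under the background model
#'
#' Sum of \code{-nbLogPmf(x, mu, r)} over unmasked stored pairs; cis pairs use
#' the distance expectation, trans pairs the constant \eqn{f_c}. Bias factors
#' are recomputed from \code{binStats$s} under \code{params}.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param params \linkS4class{BackgroundParameters}.
#' @param binStats data.frame with per-bin effective totals \code{s} in bin
#'   order; defaults to raw marginal totals.
#' @param masked logical per stored pair; masked pairs are excluded.
#' @return scalar negative log-likelihood.
#' @export
negLogLikelihood <- function(map, params, binStats = NULL, masked = NULL) {
    cov <- .covariates(map)
    s <- if (is.null(binStats)) .rawBinTotals(map) else binStats$s
    keep <- if (is.null(masked)) seq_len(cov$n) else which(!masked)
    .nllGrad(.thetaFromParams(params), cov, s, keep,
             params@sharpness, params@baseExpectation,
             wantGrad = FALSE)$nll
}

# ADAM with geometric learning-rate decay. Stops when every free parameter
# changed by less than tol since the previous iteration, or at maxIters
# (oscillation guard). Errors out if the NLL increases 50 iterations in a row.
.adamFit <- function(theta0, cov, s, keep, k, baseE, free, config,
                     norm = c(0, 1)) {
    theta <- theta0
    lr0 <- config$learningRate
    b1 <- config$adamBeta1; b2 <- config$adamBeta2; eps <- config$adamEps
    decay <- config$lrDecay
    m <- v <- numeric(length(theta))
    trace <- numeric(0)
    converged <- FALSE
    worse <- 0L
    lastNll <- Inf
    if (config$maxIters < 1L)
        return(list(theta = theta, trace = trace, converged = FALSE))
    batched <- !is.null(config$batchSize) &&
        config$batchSize < length(keep)
    sub <- if (batched) NULL else .subsetCov(cov, keep, norm)
    for (t in seq_len(config$maxIters)) {
        scale <- 1
        if (batched) {
            idx <- sample(keep, config$batchSize)
            scale <- length(keep) / config$batchSize
            sub <- .subsetCov(cov, idx, norm)
        }
        ng <- .nllGradCpp(theta, sub$i1, sub$i2, sub$xi, sub$ux,
                          sub$sumLgX1, sub$cis, sub$z, s, k, baseE)
        if (!is.finite(ng$nll))
            stop("non-finite likelihood term at pair index ",
                 if (batched) "(mini-batch)" else keep[ng$bad])
        g <- stats::setNames(ng$grad, .THETA) * scale
        g[!free] <- 0
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^t)
        vhat <- v / (1 - b2^t)
        step <- (lr0 * decay^t) * mhat / (sqrt(vhat) + eps)
        theta <- theta - step
        trace[t] <- ng$nll
        if (ng$nll > lastNll) worse <- worse + 1L else worse <- 0L
        lastNll <- ng$nll
        if (worse >= 50L)
            stop("optimization diverged: NLL increased for 50 consecutive ",
                 "iterations (last NLL ", signif(ng$nll, 8), ")")
        if (max(abs(step[free])) < config$tol) {
            converged <- TRUE
            break
        }
    }
    list(theta = theta, trace = trace, converged = converged)
}

# Data-driven initialization: b = 1; bm so the median bias factor is 1; decay
# coefficients from an OLS cubic of log stratified mean count vs log distance;
# f_c from trans counts (or the farthest stratum); r by method of moments on
# distance strata; v_base at the 1st percentile of the raw bias factors.
.initParams <- function(cov, s, keep, k, baseE) {
    lns <- log(pmax(s, 1))
    bm <- -stats::median(lns[s > 0])
    vraw <- ifelse(s > 0, exp(lns + bm), 0)
    vbase <- max(stats::quantile(vraw[vraw > 0], 0.01), 1e-6)

    ci <- keep[cov$cis[keep]]
    L <- cov$L[ci]; x <- cov$x[ci]
    nstr <- min(20L, max(3L, length(unique(round(L, 3))) %/% 2L))
    br <- seq(min(L), max(L), length.out = nstr + 1L)
    str <- cut(L, br, include.lowest = TRUE)
    mx <- tapply(x, str, mean)
    vx <- tapply(x, str, stats::var)
    mL <- tapply(L, str, mean)
    ok <- is.finite(mx) & mx > 0
    co <- tryCatch(stats::coef(stats::lm(log(mx[ok]) ~ stats::poly(mL[ok], 3,
                                                                   raw = TRUE))),
                   error = function(e) c(log(mean(x)), 0, 0, 0))
    co[!is.finite(co)] <- 0

    tri <- keep[!cov$cis[keep]]
    fc <- if (length(tri) >= 100L) mean(cov$x[tri])
          else max(mx[ok][which.max(mL[ok])], 0.05)

    rr <- (mx^2 / pmax(vx - mx, 1e-8))[ok & is.finite(vx) & vx > mx]
    r <- if (length(rr)) stats::median(rr) else 2
    r <- min(max(r, 0.1), 1e4)

    BackgroundParameters(biasExponent = 1, biasOffset = bm,
                         biasFloor = vbase, decay = unname(co),
                         transFloor = fc, dispersion = r,
                         sharpness = k, baseExpectation = baseE)
}

#' Training configuration for the background model
#'
#' @param rounds training rounds (an unmasked fit counts as round 1).
#' @param sigThreshold P-value below which pairs are masked between rounds.
#' @param tol per-parameter convergence delta on the optimization scale.
#' @param maxIters ADAM iteration cap per round (oscillation guard).
#' @param learningRate,adamBeta1,adamBeta2,adamEps ADAM constants.
#' @param lrDecay geometric learning-rate decay per iteration; makes the
#'   parameter-change stopping rule attainable.
#' @param includeTrans include trans pairs in the likelihood (they inform
#'   \eqn{f_c} and the bias factors).
#' @param freezeBiasFloor keep \eqn{v_{base}} at its initial value instead of
#'   learning it.
#' @param batchSize optional mini-batch size; NULL = full batch
#'   (deterministic given the initialization).
#' @param seed RNG seed used only when \code{batchSize} is set.
#' @return list of class settings passed to [fitBackground()].
#' @export
trainingConfig <- function(rounds = 4L, sigThreshold = 0.001, tol = 1e-4,
                           maxIters = 1000L, learningRate = 0.01,
                           adamBeta1 = 0.9, adamBeta2 = 0.999,
                           adamEps = 1e-8, lrDecay = 0.995,
                           includeTrans = TRUE, freezeBiasFloor = FALSE,
                           batchSize = NULL, seed = 1L) {
    stopifnot(rounds >= 1L, sigThreshold > 0, sigThreshold < 1, tol > 0)
    list(rounds = as.integer(rounds), sigThreshold = sigThreshold, tol = tol,
         maxIters = as.integer(maxIters), learningRate = learningRate,
         adamBeta1 = adamBeta1, adamBeta2 = adamBeta2, adamEps = adamEps,
         lrDecay = lrDecay, includeTrans = includeTrans,
         freezeBiasFloor = freezeBiasFloor, batchSize = batchSize,
         seed = as.integer(seed))
}

#' Recompute effective bin totals with masked pairs replaced by expectations
#'
#' For every bin, \eqn{s_i} is the sum of observed counts over unmasked pairs
#' touching it plus the model-expected counts of masked pairs touching it —
#' the counts the masked (putative real) interactions would have shown had
#' they been background.
#'
#' @param map \linkS4class{ContactMap}.
#' @param masked logical per stored pair.
#' @param params \linkS4class{BackgroundParameters} used for the expectations.
#' @param binStats data.frame with the current effective totals \code{s}
#'   (used to compute bias factors of the masked pairs); NULL = raw totals.
#' @return data.frame with \code{bin_id}, \code{s}, \code{v}.
#' @export
recomputeBinTotals <- function(map, masked, params, binStats = NULL) {
    cov <- .covariates(map)
    sCur <- if (is.null(binStats)) .rawBinTotals(map) else binStats$s
    contrib <- cov$x
    if (any(masked)) {
        mu <- .pairExpectations(cov, sCur, params)
        contrib[masked] <- mu[masked]
    }
    s <- numeric(cov$nbins)
    t1 <- rowsum(contrib, cov$i1)
    t2 <- rowsum(contrib, cov$i2)
    s[as.integer(rownames(t1))] <- s[as.integer(rownames(t1))] + t1[, 1L]
    s[as.integer(rownames(t2))] <- s[as.integer(rownames(t2))] + t2[, 1L]
    data.frame(bin_id = mcols(map@bins)$bin_id, s = s,
               v = biasFactor(s, params))
}

# Expected count per stored pair under params with bias from totals s.
.pairExpectations <- function(cov, s, params) {
    v <- biasFactor(s, params)
    fd <- ifelse(cov$cis,
                 distanceExpectation(pmax(cov$d, 1), params),
                 params@transFloor)
    expectedCount(v[cov$i1], v[cov$i2], fd, params)
}

#' Fit one round of the background model
#'
#' Runs full-batch ADAM on the analytic gradient of the NB negative
#' log-likelihood over the unmasked pairs, starting from \code{params0}.
#' Iterations stop when every free parameter's absolute change drops below
#' \code{config$tol} on its optimization scale, or at \code{config$maxIters}.
#'
#' @param map \linkS4class{ContactMap}.
#' @param params0 starting \linkS4class{BackgroundParameters}.
#' @param masked logical per stored pair (TRUE = excluded from the objective).
#' @param config a [trainingConfig()] list.
#' @param binStats data.frame with effective totals \code{s}; NULL = raw.
#' @return list with \code{params}, \code{nllTrace}, \code{converged}.
#' @export
fitRound <- function(map, params0, masked = NULL, config = trainingConfig(),
                     binStats = NULL) {
    cov <- .covariates(map)
    s <- if (is.null(binStats)) .rawBinTotals(map) else binStats$s
    keep <- seq_len(cov$n)
    if (!is.null(masked)) keep <- keep[!masked]
    if (!config$includeTrans) keep <- keep[cov$cis[keep]]
    free <- stats::setNames(rep(TRUE, length(.THETA)), .THETA)
    if (config$freezeBiasFloor) free["lvb"] <- FALSE
    if (!is.null(config$batchSize)) set.seed(config$seed)
    norm <- .decayNorm(cov, keep)
    res <- .adamFit(.thetaFromParams(params0, norm), cov, s, keep,
                    params0@sharpness, params0@baseExpectation, free, config,
                    norm)
    list(params = .paramsFromTheta(res$theta, params0@sharpness,
                                   params0@baseExpectation, norm),
         nllTrace = res$trace, converged = res$converged)
}

#' Fit the background model in multiple masking rounds
#'
#' In each round the model is fitted by maximum likelihood on the unmasked
#' pairs and every stored pair is scored; pairs with P-value below
#' \code{config$sigThreshold} become the new mask (recomputed from scratch,
#' not accumulated). Before each subsequent round the effective bin totals
#' are recomputed with masked counts replaced by their expectations and the
#' round is re-initialized from the refreshed data, so the reported model
#' and bin statistics are mutually consistent (the last round's fit used
#' exactly the reported totals).
#'
#' @param map \linkS4class{ContactMap}.
#' @param config a [trainingConfig()] list.
#' @param params0 optional starting parameters; a data-driven initialization
#'   is used when NULL.
#' @param sharpness,baseExpectation the fixed smoothing hyperparameters used
#'   when \code{params0} is NULL.
#' @param verbose print a per-round summary line.
#' @return A \linkS4class{BackgroundFit}.
#' @export
fitBackground <- function(map, config = trainingConfig(), params0 = NULL,
                          sharpness = 10, baseExpectation = 0.5,
                          verbose = FALSE) {
    cov <- .covariates(map)
    if (cov$n == 0L) stop("contact map has no stored pairs")
    sRaw <- .rawBinTotals(map)
    keep0 <- seq_len(cov$n)
    if (!config$includeTrans) keep0 <- keep0[cov$cis]
    if (is.null(params0))
        params0 <- .initParams(cov, sRaw, keep0, sharpness, baseExpectation)
    binStats <- data.frame(bin_id = mcols(map@bins)$bin_id, s = sRaw,
                           v = biasFactor(sRaw, params0))
    masked <- rep(FALSE, cov$n)
    params <- params0
    traces <- vector("list", config$rounds)
    conv <- logical(config$rounds)
    prevMasked <- masked
    for (rd in seq_len(config$rounds)) {
        if (rd > 1L) {
            # refresh totals with the previous round's model (masked counts
            # substituted by expectations), then re-derive the data-driven
            # initialization: the refreshed totals can shift the optimum
            # further than one round of ADAM travels from a warm start
            binStats <- recomputeBinTotals(map, masked, params, binStats)
            keepRd <- keep0[!masked[keep0]]
            params <- .initParams(cov, binStats$s, keepRd,
                                  params@sharpness, params@baseExpectation)
        }
        fit <- fitRound(map, params, masked = masked, config = config,
                        binStats = binStats)
        params <- fit$params
        traces[[rd]] <- fit$nllTrace
        conv[rd] <- fit$converged
        mu <- .pairExpectations(cov, binStats$s, params)
        p <- nbTailProb(cov$x, mu, params@dispersion)
        prevMasked <- masked
        masked <- p < config$sigThreshold
        if (verbose)
            message(sprintf(
                "round %d: nll %.2f after %d iters (converged=%s), %d masked",
                rd, utils::tail(fit$nllTrace, 1L), length(fit$nllTrace),
                fit$converged, sum(masked)))
    }
    binStats$v <- biasFactor(binStats$s, params)
    if (config$rounds > 1L &&
        sum(masked != prevMasked) > 0.01 * cov$n)
        warning("masked set still changed by >1% of pairs in the last round")
    new("BackgroundFit", params = params, binStats = binStats,
        masked = masked, nllTrace = traces, converged = conv,
        config = config)
}

#' @rdname BackgroundFit-class
#' @param ... unused.
#' @export
setMethod("modelParameters", "BackgroundFit", function(object, ...)
    object@params)

#' @rdname BackgroundFit-class
#' @export
setMethod("binStats", "BackgroundFit", function(object) object@binStats)

#' @rdname BackgroundFit-class
#' @export
setMethod("maskedPairs", "BackgroundFit", function(object) object@masked)

setMethod("show", "BackgroundFit", function(object) {
    cat("BackgroundFit:", length(object@converged), "round(s);",
        sum(object@masked), "pairs masked as significant in the final round\n")
    show(object@params)
})
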