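#' Flag bins overlapping capture baits
#'
#' A bin is a target iff it overlaps at least one bait interval by >= 1 bp
#' (half-open convention: a bait ending exactly where a bin starts does not
#' flag that bin).
#'
#' @param bins GRanges of bins with \code{bin_id} metadata.
#' @param baits GRanges of bait/target intervals (same assembly).
#' @return named logical vector (names = bin ids), TRUE for target bins.
#' @export
flagTargets <- function(bins, baits) {
    fl <- overlapsAny(bins, baits)
    if (!any(fl))
        stop("capture mode with no targets: no bin overlaps any bait")
    stats::setNames(fl, mcols(bins)$bin_id)
}

#' Interaction class of a bin pair in capture mode
#'
#' Symmetric in its two ends: both targets = TT, one = TO, none = OO.
#'
#' @param bin1,bin2 bin ids.
#' @param targetFlags named logical from [flagTargets()].
#' @return factor with levels TT, TO, OO.
#' @export
interactionClass <- function(bin1, bin2, targetFlags) {
    t1 <- targetFlags[as.character(bin1)]
    t2 <- targetFlags[as.character(bin2)]
    n <- t1 + t2
    factor(c("OO", "TO", "TT")[n + 1L], levels = c("TT", "TO", "OO"))
}

#' Convert an observed count to its Target-Target equivalent
#'
#' \eqn{x^{TT} = x \cdot \mu^{TT} / \mu^{own}}: linear in \eqn{x} and the
#' identity for TT pairs (where the two expectations coincide). Used so bin
#' totals are comparable across the differently enriched capture classes.
#'
#' @param x observed count(s).
#' @param muOwn expected count under the pair's own class parameters.
#' @param muTT expected count under the TT parameters (same covariates).
#' @return real-valued TT-equivalent count(s).
#' @export
convertToTT <- function(x, muOwn, muTT) {
    stopifnot(all(muOwn > 0), all(muTT > 0))
    x * muTT / muOwn
}

# mu per pair, each pair under the parameter set of the class in `classes`
# (or a single fixed class for every pair via `as`).
.capturePairExpectations <- function(cov, s, paramsByClass, classes,
                                     as = NULL) {
    mu <- numeric(cov$n)
    for (cl in levels(classes)) {
        sel <- which(classes == cl)
        if (!length(sel)) next
        p <- paramsByClass[[if (is.null(as)) cl else as]]
        v <- biasFactor(s, p)
        fd <- ifelse(cov$cis[sel],
                     distanceExpectation(pmax(cov$d[sel], 1), p),
                     p@transFloor)
        mu[sel] <- expectedCount(v[cov$i1[sel]], v[cov$i2[sel]], fd, p)
    }
    mu
}

#' TT-equivalent counts of all stored pairs under a capture fit
#'
#' @param map \linkS4class{ContactMap}.
#' @param fit \linkS4class{CaptureBackgroundFit}.
#' @return numeric vector of converted counts, one per stored pair.
#' @export
ttEquivalentCounts <- function(map, fit) {
    cov <- .covariates(map)
    muOwn <- .capturePairExpectations(cov, fit@binStats$s, fit@paramsByClass,
                                      fit@classes)
    muTT <- .capturePairExpectations(cov, fit@binStats$s, fit@paramsByClass,
                                     fit@classes, as = "TT")
    convertToTT(cov$x, muOwn, muTT)
}

#' Fit the capture Hi-C background model
#'
#' Same multi-round masking scheme as [fitBackground()], but every stored
#' pair belongs to one of the classes TT/TO/OO induced by the bait file, each
#' class has its own full parameter set fitted only on its own pairs, and
#' effective bin totals are accumulated from TT-equivalent converted counts
#' (masked pairs contribute their converted expectations). Scoring uses each
#' pair's own class parameters. A class with fewer than \code{minClassPairs}
#' pairs is not fitted; it borrows the nearest class's parameters
#' (TT and OO borrow from TO; TO borrows from TT, then OO) with a warning.
#'
#' @param map \linkS4class{ContactMap} of the capture library.
#' @param baits GRanges of bait intervals.
#' @param config a [trainingConfig()] list.
#' @param sharpness,baseExpectation fixed smoothing hyperparameters, shared
#'   across the three classes.
#' @param minClassPairs minimum pairs for a class to get its own fit.
#' @param shareDispersion if TRUE the NB dispersion is pooled across classes
#'   (pair-weighted mean of the per-class log dispersions after each round).
#' @param verbose print per-round summaries.
#' @return A \linkS4class{CaptureBackgroundFit}.
#' @export
fitCaptureBackground <- function(map, baits, config = trainingConfig(),
                                 sharpness = 10, baseExpectation = 0.5,
                                 minClassPairs = 1000L,
                                 shareDispersion = FALSE, verbose = FALSE) {
    flags <- flagTargets(map@bins, baits)
    cov <- .covariates(map)
    if (cov$n == 0L) stop("contact map has no stored pairs")
    tr <- interactions(map)
    classes <- interactionClass(tr$bin1, tr$bin2, flags)
    clNames <- levels(classes)
    nPerClass <- table(classes)
    fitted <- nPerClass >= minClassPairs
    if (!any(fitted))
        stop("no capture class has at least ", minClassPairs, " pairs")
    if (!all(fitted))
        warning("class(es) ",
                paste(clNames[!fitted], collapse = ", "),
                " have < ", minClassPairs,
                " pairs; borrowing parameters from the nearest class")

    s <- .rawBinTotals(map)
    keepAll <- seq_len(cov$n)
    if (!config$includeTrans) keepAll <- keepAll[cov$cis]

    params <- stats::setNames(vector("list", 3L), clNames)
    for (cl in clNames[fitted]) {
        kcl <- keepAll[classes[keepAll] == cl]
        params[[cl]] <- .initParams(cov, s, kcl, sharpness, baseExpectation)
    }
    .fillBorrowed <- function(params) {
        borrow <- list(TT = c("TO", "OO"), TO = c("TT", "OO"),
                       OO = c("TO", "TT"))
        for (cl in clNames[!fitted]) {
            src <- borrow[[cl]][fitted[borrow[[cl]]]][1L]
            params[[cl]] <- params[[src]]
        }
        params
    }
    params <- .fillBorrowed(params)

    masked <- rep(FALSE, cov$n)
    traces <- vector("list", config$rounds)
    conv <- matrix(FALSE, config$rounds, 3L,
                   dimnames = list(NULL, clNames))
    free <- stats::setNames(rep(TRUE, length(.THETA)), .THETA)
    if (config$freezeBiasFloor) free["lvb"] <- FALSE
    binIds <- mcols(map@bins)$bin_id

    for (rd in seq_len(config$rounds)) {
        if (rd > 1L) {
            # refresh totals on the TT-equivalent scale with the previous
            # round's model: converted observed counts for unmasked pairs,
            # converted expectations for masked ones
            muOwn <- .capturePairExpectations(cov, s, params, classes)
            muTT <- .capturePairExpectations(cov, s, params, classes,
                                             as = "TT")
            contrib <- convertToTT(cov$x, muOwn, muTT)
            contrib[masked] <- muTT[masked]
            s <- numeric(cov$nbins)
            t1 <- rowsum(contrib, cov$i1)
            t2 <- rowsum(contrib, cov$i2)
            s[as.integer(rownames(t1))] <-
                s[as.integer(rownames(t1))] + t1[, 1L]
            s[as.integer(rownames(t2))] <-
                s[as.integer(rownames(t2))] + t2[, 1L]
        }
        rdTrace <- list()
        for (cl in clNames[fitted]) {
            kcl <- keepAll[classes[keepAll] == cl & !masked[keepAll]]
            norm <- .decayNorm(cov, kcl)
            if (rd > 1L)    # fresh per-round init; see fitBackground
                params[[cl]] <- .initParams(cov, s, kcl, sharpness,
                                            baseExpectation)
            res <- .adamFit(.thetaFromParams(params[[cl]], norm), cov, s,
                            kcl, sharpness, baseExpectation, free, config,
                            norm)
            params[[cl]] <- .paramsFromTheta(res$theta, sharpness,
                                             baseExpectation, norm)
            rdTrace[[cl]] <- res$trace
            conv[rd, cl] <- res$converged
        }
        params <- .fillBorrowed(params)
        if (shareDispersion) {
            w <- as.numeric(nPerClass[clNames[fitted]])
            lr <- vapply(params[clNames[fitted]],
                         function(p) log(p@dispersion), 0)
            rShared <- exp(sum(w * lr) / sum(w))
            for (cl in clNames) params[[cl]]@dispersion <- rShared
        }
        traces[[rd]] <- rdTrace
        muOwn <- .capturePairExpectations(cov, s, params, classes)
        rvec <- vapply(params, function(p) p@dispersion,
                       0)[as.integer(classes)]
        p <- nbTailProb(cov$x, muOwn, rvec)
        masked <- p < config$sigThreshold
        if (verbose)
            message(sprintf("capture round %d: %d masked", rd, sum(masked)))
    }
    binStats <- data.frame(bin_id = binIds, s = s,
                           v_TT = biasFactor(s, params$TT),
                           v_TO = biasFactor(s, params$TO),
                           v_OO = biasFactor(s, params$OO))
    new("CaptureBackgroundFit", paramsByClass = params,
        targetFlags = unname(flags), binStats = binStats, classes = classes,
        masked = masked, nllTrace = traces, converged = conv, config = config)
}

#' @rdname CaptureBackgroundFit-class
#' @param object,... see generic.
#' @param class which class's parameters to return.
#' @export
setMethod("modelParameters", "CaptureBackgroundFit",
    function(object, class = c("TT", "TO", "OO"), ...)
        object@paramsByClass[[match.arg(class)]])

#' @rdname CaptureBackgroundFit-class
#' @export
setMethod("binStats", "CaptureBackgroundFit", function(object)
    object@binStats)

#' @rdname CaptureBackgroundFit-class
#' @export
setMethod("maskedPairs", "CaptureBackgroundFit", function(object)
    object@masked)

setMethod("show", "CaptureBackgroundFit", function(object) {
    cat("CaptureBackgroundFit:", nrow(object@converged), "round(s);",
        sum(object@targetFlags), "target bins;",
        paste(names(table(object@classes)), as.integer(table(object@classes)),
              sep = "=", collapse = " "), "pairs;",
        sum(object@masked), "masked\n")
})
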