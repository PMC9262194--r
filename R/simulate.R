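#' Default ground-truth parameters for the simulator
#'
#' At \code{depth = 1}, a shallow single-chromosome library typical of
#' fine-binned Hi-C: the distance term spans ~55 reads at 10 kb and ~30
#' reads at 20 kb, declining to the background-ligation floor
#' \eqn{f_c = 0.2} reads by 10 Mb; dispersion \eqn{r = 4}. \code{depth}
#' scales the whole expectation surface (both the cubic and the floor) to
#' emulate deeper sequencing or coarser bins without changing the decay
#' shape; parameter-recovery experiments use a deep setting because the
#' latent parameters are only identifiable when few pairs are
#' zero-truncated.
#'
#' Per-bin biases are drawn separately (see [simulateBackground()]); the
#' bias exponent recorded as truth is 1 because a generator that draws
#' per-bin multipliers makes bin totals proportional to them, which is the
#' only self-consistent power law (see the methods vignette).
#'
#' @param depth multiplicative sequencing-depth factor (>= 1).
#' @param transFloor,dispersion,sharpness,baseExpectation overrides of the
#'   defaults above (the default \code{transFloor} already includes
#'   \code{depth}).
#' @return A \linkS4class{BackgroundParameters} truth object.
#' @export
simTruthParameters <- function(depth = 1, transFloor = 0.2 * depth,
                               dispersion = 4,
                               sharpness = 10, baseExpectation = 0.5) {
    BackgroundParameters(
        biasExponent = 1, biasOffset = 0, biasFloor = 1e-3,
        decay = c(21.728215165 + log(depth), -3.443982826, 0.2199448125,
                  -0.0059625353),
        transFloor = transFloor, dispersion = dispersion,
        sharpness = sharpness, baseExpectation = baseExpectation)
}

.simBins <- function(nBins, binSize, nChrom) {
    per <- rep(nBins %/% nChrom, nChrom)
    if (nBins %% nChrom) per[seq_len(nBins %% nChrom)] <-
        per[seq_len(nBins %% nChrom)] + 1L
    chrom <- rep(paste0("chrS", seq_len(nChrom)), per)
    off <- unlist(lapply(per, function(n) seq_len(n) - 1L))
    bins <- GRanges(chrom, IRanges(start = off * binSize + 1L,
                                   end = (off + 1L) * binSize))
    mcols(bins)$bin_id <- seq_len(nBins)
    bins
}

#' Simulate a background contact map with known truth
#'
#' Generative twin of the background model: per-bin bias multipliers are
#' drawn lognormal, every cis (and, with more than one chromosome, trans)
#' bin pair gets an expected count through the model's own expectation
#' pipeline, observed counts are drawn NB(\eqn{\mu}, r), and only pairs with
#' at least one read are stored — emulating the zero-truncated input the real
#' pipeline sees. The dropped-zero fraction is reported in the truth so
#' calibration checks can condition on it.
#'
#' With \code{targetFraction > 0} a random subset of bins is flagged as
#' capture targets and their bias multipliers are scaled by
#' \code{baitBoost}, producing the TT/TO/OO enrichment structure of a capture
#' library.
#'
#' @param nBins total number of bins (>= 10).
#' @param binSize bin width in bp.
#' @param params truth \linkS4class{BackgroundParameters}; defaults to
#'   [simTruthParameters()].
#' @param biasLogSd sd of the per-bin log bias multipliers.
#' @param nChrom number of chromosomes the bins are split over (> 1 adds
#'   trans pairs).
#' @param targetFraction fraction of bins flagged as capture targets.
#' @param baitBoost per-end bias multiplier applied to target bins.
#' @param seed RNG seed; same seed and settings give a byte-identical map.
#' @return list with \code{map} (a \linkS4class{ContactMap}) and \code{truth}
#'   (list: params, bias, targetFlags, droppedFraction, seed, loops).
#' @export
simulateBackground <- function(nBins = 500L, binSize = 10000L,
                               params = simTruthParameters(),
                               biasLogSd = 0.25, nChrom = 1L,
                               targetFraction = 0, baitBoost = 1,
                               seed = 1L) {
    stopifnot(nBins >= 10L)
    set.seed(seed)
    bins <- .simBins(nBins, binSize, nChrom)
    v <- exp(stats::rnorm(nBins, 0, biasLogSd))
    flags <- rep(FALSE, nBins)
    if (targetFraction > 0) {
        flags[sample.int(nBins, max(1L, round(targetFraction * nBins)))] <-
            TRUE
        v <- v * ifelse(flags, baitBoost, 1)
        mcols(bins)$is_target <- flags
    }
    ut <- which(upper.tri(matrix(0, nBins, nBins)), arr.ind = TRUE)
    i <- ut[, 1L]; j <- ut[, 2L]
    chrom <- as.character(GenomicRanges::seqnames(bins))
    mid <- (GenomicRanges::start(bins) + GenomicRanges::end(bins)) / 2
    cis <- chrom[i] == chrom[j]
    d <- abs(mid[i] - mid[j])
    fd <- ifelse(cis, distanceExpectation(pmax(d, 1), params),
                 params@transFloor)
    mu <- expectedCount(v[i], v[j], fd, params)
    x <- stats::rnbinom(length(mu), size = params@dispersion, mu = mu)
    keep <- x >= 1L
    map <- ContactMap(bins, data.frame(bin1 = i[keep], bin2 = j[keep],
                                       count = x[keep]),
                      binSize = binSize)
    list(map = map,
         truth = list(params = params, bias = v, biasLogSd = biasLogSd,
                      targetFlags = flags, mu = NULL,
                      droppedFraction = 1 - mean(keep), seed = seed,
                      loops = NULL))
}

# Truth expectation of one or more bin pairs (by bin index = bin_id).
.truthMu <- function(bins, truth, bin1, bin2) {
    chrom <- as.character(GenomicRanges::seqnames(bins))
    mid <- (GenomicRanges::start(bins) + GenomicRanges::end(bins)) / 2
    cis <- chrom[bin1] == chrom[bin2]
    d <- abs(mid[bin1] - mid[bin2])
    p <- truth$params
    fd <- ifelse(cis, distanceExpectation(pmax(d, 1), p), p@transFloor)
    expectedCount(truth$bias[bin1], truth$bias[bin2], fd, p)
}

#' Spike true loops into a simulated map
#'
#' Redraws the listed bin pairs with mean \code{fold} times their background
#' expectation (fold = 1 leaves the distribution unchanged). The spiked pairs
#' and their folds are recorded in the returned truth.
#'
#' @param map \linkS4class{ContactMap} from [simulateBackground()].
#' @param loops data.frame with columns \code{bin1}, \code{bin2},
#'   \code{fold} (folds >= 1; self pairs are an error).
#' @param truth the truth list paired with \code{map}.
#' @param seed RNG seed for the redraw.
#' @return list with the modified \code{map} and updated \code{truth}.
#' @export
spikeLoops <- function(map, loops, truth, seed = 1L) {
    if (nrow(loops) == 0L) return(list(map = map, truth = truth))
    stopifnot(all(loops$fold >= 1))
    if (any(loops$bin1 == loops$bin2))
        stop("loop at a self pair is not allowed")
    b1 <- pmin(loops$bin1, loops$bin2)
    b2 <- pmax(loops$bin1, loops$bin2)
    set.seed(seed)
    mu <- .truthMu(map@bins, truth, b1, b2)
    x <- stats::rnbinom(length(mu), size = truth$params@dispersion,
                        mu = loops$fold * mu)
    tr <- interactions(map)
    drop <- paste(tr$bin1, tr$bin2) %in% paste(b1, b2)
    tr <- rbind(tr[!drop, , drop = FALSE],
                data.frame(bin1 = b1, bin2 = b2, count = x)[x >= 1L, ,
                                                            drop = FALSE])
    newMap <- ContactMap(map@bins, tr, binSize = map@binSize)
    truth$loops <- data.frame(bin1 = b1, bin2 = b2, fold = loops$fold,
                              mu = mu)
    list(map = newMap, truth = truth)
}

#' Write a simulation's truth to JSON
#'
#' @param truth truth list from [simulateBackground()] / [spikeLoops()].
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
writeSimTruth <- function(truth, path) {
    p <- truth$params
    out <- list(params = list(biasExponent = p@biasExponent,
                              biasOffset = p@biasOffset,
                              biasFloor = p@biasFloor,
                              decay = p@decay, transFloor = p@transFloor,
                              dispersion = p@dispersion,
                              sharpness = p@sharpness,
                              baseExpectation = p@baseExpectation),
                bias = truth$bias, biasLogSd = truth$biasLogSd,
                targetFlags = truth$targetFlags,
                droppedFraction = truth$droppedFraction, seed = truth$seed,
                loops = truth$loops)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}
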