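#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' ContactMap: a binned Hi-C contact map
#'
#' Holds the genome binning and the sparse upper-triangular observed counts of
#' one Hi-C (or capture Hi-C) library at a fixed bin size. Bins are a
#' \link[GenomicRanges]{GRanges} with an integer \code{bin_id} metadata column
#' (and, in capture mode, a logical \code{is_target} column). Interactions are
#' stored as triplets \code{(bin1, bin2, count)} with \code{bin1 < bin2} by
#' bin id, no self pairs and strictly positive integer counts, matching the
#' convention that only bin pairs supported by at least one read enter the
#' model.
#'
#' Coordinates follow the 0-based half-open BED convention on disk; in memory
#' bins are ordinary 1-based closed \code{GRanges}.
#'
#' @slot bins GRanges of genome bins with metadata column \code{bin_id}.
#' @slot interactions data.frame with integer columns \code{bin1},
#'   \code{bin2}, \code{count}.
#' @slot binSize integer, nominal bin width in bp.
#' @export
setClass("ContactMap",
    slots = c(bins = "GRanges", interactions = "data.frame",
              binSize = "integer"))

setValidity("ContactMap", function(object) {
    msg <- character()
    b <- object@bins
    tr <- object@interactions
    if (is.null(mcols(b)$bin_id))
        msg <- c(msg, "bins must carry a 'bin_id' metadata column")
    else {
        id <- mcols(b)$bin_id
        if (anyDuplicated(id)) msg <- c(msg, "bin_ids must be unique")
    }
    need <- c("bin1", "bin2", "count")
    if (!all(need %in% names(tr)))
        msg <- c(msg, "interactions must have columns bin1, bin2, count")
    else if (nrow(tr)) {
        if (any(tr$bin1 >= tr$bin2))
            msg <- c(msg, "interactions must satisfy bin1 < bin2 (no self pairs)")
        if (any(tr$count < 1))
            msg <- c(msg, "all stored counts must be >= 1")
        if (!all(tr$bin1 %in% mcols(b)$bin_id) ||
            !all(tr$bin2 %in% mcols(b)$bin_id))
            msg <- c(msg, "interaction bin ids must exist in bins")
        if (anyDuplicated(tr[, c("bin1", "bin2")]))
            msg <- c(msg, "duplicate (bin1, bin2) pairs are not allowed")
    }
    if (length(object@binSize) != 1L || object@binSize < 1L)
        msg <- c(msg, "binSize must be a single positive integer")
    if (length(msg)) msg else TRUE
})

#' BackgroundParameters: all scalars of the background model
#'
#' The learned scalars of the negative binomial background model together with
#' its two fixed smoothing hyperparameters.
#'
#' The expected count of a cis bin pair at distance \eqn{d} is
#' \deqn{\mu_{ij} = \mathrm{softmax}_k(v_i v_j f(d),\; \mathrm{base}_e)}
#' with bias factors \eqn{v_i = \max(s_i^{b} e^{b_m}, v_{base})}, decay
#' \eqn{f(d) = \mathrm{softmax}_k(\exp(a_3 \ln^3 d + a_2 \ln^2 d + a_1 \ln d +
#' a_0),\; f_c)} and, for trans pairs, \eqn{f = f_c}. Observed counts are
#' modelled as \eqn{x_{ij} \sim \mathrm{NB}(\mu_{ij}, r)} with variance
#' \eqn{\mu + \mu^2/r}.
#'
#' @slot biasExponent numeric, the power \eqn{b} relating bias to bin totals.
#' @slot biasOffset numeric, the log-space offset \eqn{b_m}.
#' @slot biasFloor numeric > 0, the floor \eqn{v_{base}} of the bias factor.
#' @slot decay numeric(4), cubic coefficients \code{c(a0, a1, a2, a3)} in
#'   natural-log distance.
#' @slot transFloor numeric > 0, the constant background-ligation expectation
#'   \eqn{f_c} (reads), used for trans pairs and as the far-cis floor.
#' @slot dispersion numeric > 0, the shared NB dispersion \eqn{r}.
#' @slot sharpness numeric > 0, soft-maximum sharpness \eqn{k} (fixed).
#' @slot baseExpectation numeric > 0, expected-count floor \eqn{base_e}
#'   in reads (fixed).
#' @export
setClass("BackgroundParameters",
    slots = c(biasExponent = "numeric", biasOffset = "numeric",
              biasFloor = "numeric", decay = "numeric",
              transFloor = "numeric", dispersion = "numeric",
              sharpness = "numeric", baseExpectation = "numeric"))

setValidity("BackgroundParameters", function(object) {
    msg <- character()
    if (length(object@decay) != 4L)
        msg <- c(msg, "decay must have 4 coefficients (a0..a3)")
    for (nm in c("biasFloor", "transFloor", "dispersion", "sharpness",
                 "baseExpectation"))
        if (!isTRUE(slot(object, nm) > 0))
            msg <- c(msg, paste0(nm, " must be strictly positive"))
    if (length(msg)) msg else TRUE
})

#' BackgroundFit: result of fitting the background model
#'
#' @slot params the fitted \linkS4class{BackgroundParameters}.
#' @slot binStats data.frame with \code{bin_id}, effective total reads
#'   \code{s} and bias factor \code{v} per bin (masked pairs contribute their
#'   expected counts to \code{s}).
#' @slot masked logical vector, one element per stored interaction, TRUE for
#'   pairs masked as putative real interactions in the final round.
#' @slot nllTrace list of numeric vectors, negative log-likelihood per ADAM
#'   iteration for each training round.
#' @slot converged logical, per-round convergence of the parameter-change rule.
#' @slot config list, the training configuration used.
#' @export
setClass("BackgroundFit",
    slots = c(params = "BackgroundParameters", binStats = "data.frame",
              masked = "logical", nllTrace = "list", converged = "logical",
              config = "list"))

#' CaptureBackgroundFit: capture Hi-C fit with per-class parameters
#'
#' Capture Hi-C bins are partitioned by a bait (target) BED file and each
#' interaction falls in exactly one of the classes target-target (TT),
#' target-other (TO) or other-other (OO). A separate parameter set is fitted
#' per class; bin totals are accumulated on the TT-equivalent count scale.
#'
#' @slot paramsByClass named list (TT, TO, OO) of
#'   \linkS4class{BackgroundParameters}.
#' @slot targetFlags logical per bin (same order as the map's bins).
#' @slot binStats data.frame with \code{bin_id}, \code{s} (TT-equivalent
#'   totals) and per-class bias columns \code{v_TT}, \code{v_TO}, \code{v_OO}.
#' @slot classes factor per stored interaction with levels TT/TO/OO.
#' @slot masked logical per stored interaction.
#' @slot nllTrace list of per-round, per-class traces.
#' @slot converged logical matrix rounds x classes.
#' @slot config list.
#' @export
setClass("CaptureBackgroundFit",
    slots = c(paramsByClass = "list", targetFlags = "logical",
              binStats = "data.frame", classes = "factor", masked = "logical",
              nllTrace = "list", converged = "matrix", config = "list"))
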