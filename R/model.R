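#' Default background model parameters
#'
#' @param biasExponent power \eqn{b} of the bias/total-reads relation.
#' @param biasOffset log-space offset \eqn{b_m}.
#' @param biasFloor floor \eqn{v_{base}} of the bias factor.
#' @param decay cubic coefficients \code{c(a0, a1, a2, a3)} in
#'   \eqn{\ln d}.
#' @param transFloor constant background-ligation expectation \eqn{f_c}
#'   (reads).
#' @param dispersion NB dispersion \eqn{r} (variance \eqn{\mu + \mu^2/r}).
#' @param sharpness soft-maximum sharpness \eqn{k}; fixed hyperparameter.
#' @param baseExpectation expected-count floor \eqn{base_e} (reads); fixed
#'   hyperparameter.
#' @return A \linkS4class{BackgroundParameters} object.
#' @export
BackgroundParameters <- function(biasExponent = 1, biasOffset = 0,
                                 biasFloor = 0.05,
                                 decay = c(3, 0, 0, 0),
                                 transFloor = 0.2, dispersion = 2,
                                 sharpness = 10, baseExpectation = 0.5) {
    new("BackgroundParameters",
        biasExponent = as.numeric(biasExponent),
        biasOffset = as.numeric(biasOffset),
        biasFloor = as.numeric(biasFloor),
        decay = as.numeric(decay),
        transFloor = as.numeric(transFloor),
        dispersion = as.numeric(dispersion),
        sharpness = as.numeric(sharpness),
        baseExpectation = as.numeric(baseExpectation))
}

setMethod("show", "BackgroundParameters", function(object) {
    cat("BackgroundParameters\n")
    cat(sprintf("  bias: v = max(s^%.4g * e^%.4g, %.4g)\n",
                object@biasExponent, object@biasOffset, object@biasFloor))
    cat(sprintf("  decay: a0..a3 = %s; trans/far-cis floor f_c = %.4g\n",
                paste(signif(object@decay, 4), collapse = ", "),
                object@transFloor))
    cat(sprintf("  dispersion r = %.4g; k = %.4g; base_e = %.4g\n",
                object@dispersion, object@sharpness, object@baseExpectation))
})

#' Soft maximum of two values
#'
#' Differentiable surrogate for \code{max} used in the expectation function:
#' \eqn{\tau = \gamma_\alpha \alpha + \gamma_\beta \beta} with weights
#' \eqn{\gamma_\alpha = e^{k\alpha} / (e^{k\alpha} + e^{k\beta})}. The largest
#' exponent is subtracted before exponentiating so the function is total for
#' finite inputs. Bounded by \code{min(alpha, beta)} and
#' \code{max(alpha, beta)}; converges to the hard maximum as \code{k} grows.
#'
#' @param alpha,beta numeric vectors (recycled).
#' @param k sharpness, > 0.
#' @return numeric vector of soft maxima.
#' @export
softMaximum <- function(alpha, beta, k) {
    stopifnot(k > 0)
    m <- pmax(alpha, beta)
    wa <- exp(k * (alpha - m))
    wb <- exp(k * (beta - m))
    (wa * alpha + wb * beta) / (wa + wb)
}

#' Per-bin bias factor
#'
#' \eqn{v_i = \max(s_i^{b} e^{b_m}, v_{base})}: a power law of the bin's
#' effective total read count with a hard floor that stops sparsely covered
#' bins from distorting the model or yielding spuriously significant calls.
#' \code{s = 0} maps to the floor (0^b defined as 0).
#'
#' @param s effective total read count(s), >= 0.
#' @param params \linkS4class{BackgroundParameters}.
#' @return bias factor(s), always >= \code{biasFloor}.
#' @export
biasFactor <- function(s, params) {
    stopifnot(all(s >= 0))
    raw <- ifelse(s > 0,
                  exp(params@biasExponent * log(s) + params@biasOffset), 0)
    pmax(raw, params@biasFloor)
}

#' Expected read count as a function of genomic distance
#'
#' \eqn{f(d) = \mathrm{softmax}_k(f_v(d), f_c)} with
#' \eqn{f_v(d) = \exp(a_3 \ln^3 d + a_2 \ln^2 d + a_1 \ln d + a_0)}. The
#' constant \eqn{f_c} models random background collisions and dominates at
#' large distances; trans pairs use \eqn{f_c} directly (same constant as
#' observed for distant cis interactions).
#'
#' @param d genomic distance(s) in bp, > 0 (cis only).
#' @param params \linkS4class{BackgroundParameters}.
#' @return expected count(s) at distance \code{d}.
#' @export
distanceExpectation <- function(d, params) {
    if (any(d <= 0))
        stop("distance must be positive; self pairs must be removed upstream")
    L <- log(d)
    a <- params@decay
    fv <- exp(pmin(((a[4] * L + a[3]) * L + a[2]) * L + a[1], 500))
    softMaximum(fv, params@transFloor, params@sharpness)
}

#' Expected count of a bin pair
#'
#' \eqn{\mu_{ij} = \mathrm{softmax}_k(v_i v_j f(d_{ij}), base_e)}: the product
#' of the two bias factors and the distance term, floored (softly) at
#' \eqn{base_e} so that near-empty bin pairs cannot pull the parameters down.
#'
#' @param vi,vj bias factors of the two ends, > 0.
#' @param fd distance expectation \eqn{f(d)} (or \eqn{f_c} for trans), > 0.
#' @param params \linkS4class{BackgroundParameters}.
#' @return strictly positive expected count(s).
#' @export
expectedCount <- function(vi, vj, fd, params) {
    softMaximum(vi * vj * fd, params@baseExpectation, params@sharpness)
}

#' Negative binomial log pmf (mean-dispersion parameterization)
#'
#' Log of \eqn{P(X = x)} for \eqn{X \sim NB(\mu, r)} with mean \eqn{\mu} and
#' variance \eqn{\mu + \mu^2/r}; evaluated through log-gamma terms (never
#' factorials). Non-integer counts are an error.
#'
#' @param x non-negative integer count(s).
#' @param mu mean(s), > 0.
#' @param r dispersion, > 0.
#' @return log-probability vector.
#' @export
nbLogPmf <- function(x, mu, r) {
    if (any(x != round(x)) || any(x < 0))
        stop("x must be non-negative integers")
    stopifnot(all(mu > 0), all(r > 0))
    stats::dnbinom(x, size = r, mu = mu, log = TRUE)
}

#' Negative binomial tail probability of an observed count
#'
#' \eqn{P(X \ge x)} by default (inclusive tail, the conservative discrete
#' convention), computed through the numerically stable survival function.
#' With \code{inclusive = FALSE} returns the strict tail \eqn{P(X > x)}.
#'
#' @param x observed count(s), non-negative integers.
#' @param mu expected count(s), > 0.
#' @param r dispersion, > 0.
#' @param inclusive logical; include the observed count in the tail.
#' @return tail probabilities in (0, 1].
#' @export
nbTailProb <- function(x, mu, r, inclusive = TRUE) {
    if (any(x != round(x)) || any(x < 0))
        stop("x must be non-negative integers")
    q <- if (inclusive) x - 1 else x
    stats::pnbinom(q, size = r, mu = mu, lower.tail = FALSE)
}
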