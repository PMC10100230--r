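#' Rule-of-thumb smoothing bandwidth
#'
#' The classical normal-reference rule `1.06 * sd(v) * n^(-1/5)` used for the
#' Nadaraya-Watson conditioning variable, with the usual `n - 1` denominator
#' in the standard deviation.
#'
#' @param v numeric vector of length at least 2.
#' @return positive bandwidth.
#' @examples
#' silvermanBandwidth(rnorm(100))
#' @export
silvermanBandwidth <- function(v) {
    n <- length(v)
    if (n < 2L) stop("silvermanBandwidth() needs at least 2 observations")
    s <- sd(v)
    if (!is.finite(s) || s == 0)
        stop("degenerate input: zero-variance conditioning variable ",
             "(constant features should be filtered out upstream)")
    1.06 * s * n^(-1 / 5)
}

#' Kaplan-Meier CDF transform of right-censored times
#'
#' Estimates the distribution function `F_T` of the latent event time by the
#' product-limit (Kaplan-Meier) estimator, `F_T(t) = 1 - S_KM(t)`, and
#' evaluates it at every observed time, censored observations included. At a
#' distinct event time with `d` events out of `r` at risk the survival curve
#' drops by the factor `1 - d/r`; with no censoring this reduces exactly to
#' the empirical CDF, tied times included.
#'
#' @param y observed times `min(T, C)`, positive.
#' @param delta event indicators (1 = event, 0 = censored).
#' @return list with components `cdf` (a right-continuous step function of
#'   `t`) and `u` (the transform `F_T(y_i)` at each observation).
#' @examples
#' km <- kmCDF(c(2, 1, 3), c(1, 0, 1))
#' km$u          # 0.5, 0, 1
#' km$cdf(2.5)   # 0.5
#' @export
kmCDF <- function(y, delta) {
    checkSurvival(y, delta)
    evTimes <- sort(unique(y[delta == 1]))
    if (length(evTimes)) {
        d <- vapply(evTimes, function(u) sum(y == u & delta == 1), numeric(1))
        r <- vapply(evTimes, function(u) sum(y >= u), numeric(1))
        surv <- cumprod(1 - d / r)
    } else {
        surv <- numeric(0)  # no events: F identically 0
    }
    cdf <- function(t) {
        vapply(t, function(tt) {
            if (tt < 0) return(0)
            k <- sum(evTimes <= tt)
            if (k == 0L) 0 else 1 - surv[k]
        }, numeric(1))
    }
    list(cdf = cdf, u = cdf(y))
}

#' Empirical CDF (rank) transform
#'
#' Maps each entry to the fraction of entries less than or equal to it,
#' `F_n(x_i) = #\{x_j <= x_i\} / n`. Invariant under strictly increasing
#' transforms of the input, which is what makes downstream screening robust
#' to heavy tails and outliers.
#'
#' @param x numeric vector.
#' @return vector in `(0, 1]`, same length as `x`.
#' @examples
#' ecdfTransform(c(5, 1, 3))  # 1, 1/3, 2/3
#' @export
ecdfTransform <- function(x) {
    if (!length(x)) stop("empty input")
    if (anyNA(x)) stop("missing values in input")
    rank(x, ties.method = "max") / length(x)
}

#' Characteristic-kernel Gram matrix
#'
#' Gaussian: `K(u, u') = exp(-(u - u')^2 / (2 sigma^2))`. Laplacian:
#' `K(u, u') = exp(-|u - u'| / sigma)`. Both have unit diagonal.
#'
#' @param u numeric vector.
#' @param config a [KernelConfig-class]; its `sigma`, if `NA`, is resolved by
#'   [medianHeuristic()] on `u`.
#' @return symmetric positive semidefinite `n x n` matrix.
#' @export
kernelMatrix <- function(u, config = kernelConfig()) {
    sigma <- resolveSigma(u, config)
    D <- outer(u, u, "-")
    switch(config@characteristicKernel,
        gaussian = exp(-D^2 / (2 * sigma^2)),
        laplacian = exp(-abs(D) / sigma))
}

#' Median-heuristic kernel scale
#'
#' Median of the nonzero pairwise absolute differences of `u`; the default,
#' scale-adaptive choice for the characteristic-kernel scale when none is
#' given.
#'
#' @param u numeric vector with at least two distinct values.
#' @return positive scalar.
#' @export
medianHeuristic <- function(u) {
    d <- abs(outer(u, u, "-"))
    d <- d[upper.tri(d)]
    d <- d[d > 0]
    if (!length(d))
        stop("degenerate input: all values equal, cannot resolve kernel scale")
    median(d)
}

resolveSigma <- function(u, config) {
    if (is.na(config@sigma)) medianHeuristic(u) else config@sigma
}

resolveBandwidth <- function(v, config) {
    if (identical(config@bandwidthRule, "fixed")) config@bandwidth
    else silvermanBandwidth(v)
}

## Config with data-dependent choices filled in, for result snapshots.
resolveConfig <- function(u, v, config) {
    config@sigma <- resolveSigma(u, config)
    config@bandwidth <- resolveBandwidth(v, config)
    config@bandwidthRule <- "fixed"
    validObject(config)
    config
}

#' Nadaraya-Watson weight matrix
#'
#' Row-normalized Gaussian smoothing weights
#' `A[t, s] = G_h(v_t - v_s) / sum_l G_h(v_t - v_l)`; row `t` holds the
#' weights of the local average estimating a conditional expectation at
#' `V = v_t`. The `h^(-q)` normalization of `G_h` cancels in the ratio.
#'
#' @param v conditioning variable.
#' @param h positive bandwidth.
#' @return row-stochastic `n x n` matrix with entries in `(0, 1]`.
#' @export
smoothingWeights <- function(v, h) {
    if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
        stop("bandwidth h must be a positive number")
    W <- exp(-outer(v, v, "-")^2 / (2 * h^2))
    rs <- rowSums(W)
    if (any(rs == 0))  # unreachable for a Gaussian kernel with h > 0
        stop("numeric degeneracy: a smoothing-weight row summed to zero")
    W / rs
}

checkSurvival <- function(y, delta) {
    if (length(y) != length(delta))
        stop("times and event indicators have different lengths")
    if (!length(y)) stop("empty survival data")
    if (anyNA(y) || anyNA(delta)) stop("missing values in survival data")
    if (any(y <= 0)) stop("observed times must be positive")
    if (!all(delta %in% c(0, 1))) stop("event indicators must be 0 or 1")
    invisible(TRUE)
}
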