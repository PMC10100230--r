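#' Simulate censored survival data with a known active gene set
#'
#' Generates the canonical screening test bed: an equicorrelated Gaussian
#' expression matrix, latent event times driven by a small active gene set
#' through one of three outcome models, and independent exponential censoring
#' calibrated to a target censoring fraction. Because the censoring time is
#' drawn independently of everything else, the independent-censoring
#' assumption `(T, X) independent of C` holds by construction.
#'
#' Outcome models (`lambda0` is the baseline hazard giving a 24-month median
#' at a null linear predictor, typical of intermediate-prognosis carcinoma
#' cohorts):
#' \describe{
#'   \item{`cox_linear`}{proportional hazards,
#'     `h(t|X) = lambda0 * exp(sum_j beta_j X_j)` over the active set, with
#'     `beta_j = effectSize` and alternating sign.}
#'   \item{`cox_nonlinear`}{proportional hazards with nonlinear single-gene
#'     effects, `h(t|X) = lambda0 * exp(effectSize * sum_j f_j(X_j))`, the
#'     `f_j` cycling through `x^2`, `sin(pi x)`, `|x|`, each centered and
#'     scaled to unit variance under the standard normal so every active
#'     gene contributes equal signal variance to the log hazard.}
#'   \item{`non_ph`}{a log-normal accelerated-failure-time model,
#'     `log T = log(24) - effectSize * s(X) + 0.5 * eps` with `s` the
#'     standardized active-gene sum — a monotone function of the active score
#'     plus noise, violating proportional hazards.}
#' }
#'
#' Reproducibility: one seed governs everything through fixed sub-streams
#' (design, outcome noise, censoring, calibration pilot), and the expression
#' matrix is filled column-major, so enlarging `p` leaves the first columns
#' unchanged.
#'
#' @param n number of samples.
#' @param p number of genes.
#' @param activeSize number of truly active genes (the first `activeSize`
#'   columns).
#' @param model outcome model, see Details.
#' @param effectSize per-gene effect magnitude on the log-hazard (or
#'   log-time) scale, applied to a unit-variance (standardized) single-gene
#'   effect; the default 2.5 is the strong-signal regime customary in
#'   sure-screening simulation studies.
#' @param censorFrac target fraction of censored samples in `[0, 1)`.
#' @param rhoX pairwise correlation of the equicorrelated gene design, in
#'   `[0, 1)`.
#' @param seed integer seed; sub-seeds are derived from it.
#' @return a `SummarizedExperiment` (genes x samples, assay `"expression"`)
#'   with `colData` columns `time` (= `min(T, C)`, months), `status`
#'   (`I(T <= C)`), `trueTime`, `censTime`, and metadata entries `active`
#'   (true active indices) and `descriptor` (model, parameters, seed).
#' @examples
#' sim <- simulateScreeningData(n = 100, p = 50, seed = 1)
#' table(SummarizedExperiment::colData(sim)$status)
#' activeGenes(sim)
#' @export
simulateScreeningData <- function(n, p, activeSize = 4L,
                                  model = c("cox_linear", "cox_nonlinear",
                                            "non_ph"),
                                  effectSize = 2.5, censorFrac = 0.5,
                                  rhoX = 0.2, seed = 1L) {
    model <- match.arg(model)
    if (activeSize > p) stop("activeSize cannot exceed p")
    if (censorFrac < 0 || censorFrac >= 1) stop("censorFrac must be in [0, 1)")
    if (rhoX < 0 || rhoX >= 1) stop("rhoX must be in [0, 1)")
    seed <- as.integer(seed)
    if (abs(seed) > .Machine$integer.max - 10L)
        stop("seed too large to derive sub-seeds")

    set.seed(seed)                       # design sub-stream
    z0 <- rnorm(n)
    X <- sqrt(rhoX) * z0 + sqrt(1 - rhoX) * matrix(rnorm(n * p), n, p)
    active <- seq_len(activeSize)

    set.seed(seed + 1L)                  # outcome sub-stream
    lambda0 <- log(2) / 24
    if (model == "cox_linear") {
        beta <- effectSize * (-1)^(seq_len(activeSize) + 1)
        eta <- as.vector(X[, active, drop = FALSE] %*% beta)
        tt <- -log(runif(n)) / (lambda0 * exp(eta))
    } else if (model == "cox_nonlinear") {
        eta <- effectSize * nonlinearScore(X[, active, drop = FALSE])
        beta <- rep(effectSize, activeSize)
        tt <- -log(runif(n)) / (lambda0 * exp(eta))
    } else {
        s <- rowSums(X[, active, drop = FALSE]) / sqrt(activeSize)
        beta <- rep(effectSize, activeSize)
        tt <- exp(log(24) - effectSize * s + 0.5 * rnorm(n))
    }
    tt <- pmax(tt, .Machine$double.eps)

    if (censorFrac == 0) {
        cc <- rep(Inf, n)
    } else {
        set.seed(seed + 3L)              # calibration pilot sub-stream
        pilotT <- simulateLatentTimes(model, activeSize, effectSize, rhoX,
                                      m = 5000L, lambda0 = lambda0)
        rate <- calibrateCensoringRate(pilotT, censorFrac)
        set.seed(seed + 2L)              # censoring sub-stream
        cc <- rexp(n, rate = rate)
    }
    y <- pmin(tt, cc)
    delta <- as.integer(tt <= cc)

    sampleIds <- sprintf("s%04d", seq_len(n))
    geneIds <- sprintf("gene%04d", seq_len(p))
    expr <- t(X)
    dimnames(expr) <- list(geneIds, sampleIds)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expression = expr),
        colData = S4Vectors::DataFrame(time = y, status = delta,
                                       trueTime = tt, censTime = cc,
                                       row.names = sampleIds),
        metadata = list(
            active = active,
            descriptor = list(model = model, n = n, p = p,
                              activeSize = activeSize, beta = beta,
                              effectSize = effectSize,
                              censorFrac = censorFrac, rhoX = rhoX,
                              seed = seed)))
}

## Nonlinear single-gene effects, cycling x^2, sin(pi x), |x|, each centered
## and scaled to unit variance under N(0,1) so active genes contribute equal
## signal variance.
nonlinearScore <- function(Xa) {
    fs <- list(
        function(x) (x^2 - 1) / sqrt(2),
        function(x) sin(pi * x) / sqrt(0.5 * (1 - exp(-2 * pi^2))),
        function(x) (abs(x) - sqrt(2 / pi)) / sqrt(1 - 2 / pi))
    rowSums(vapply(seq_len(ncol(Xa)), function(j)
        fs[[(j - 1L) %% 3L + 1L]](Xa[, j]), numeric(nrow(Xa))))
}

## Fresh latent event times under the current RNG state (pilot draws for
## censoring calibration use their own equicorrelated design of size m).
simulateLatentTimes <- function(model, activeSize, effectSize, rhoX, m,
                                lambda0) {
    z0 <- rnorm(m)
    Xa <- sqrt(rhoX) * z0 +
        sqrt(1 - rhoX) * matrix(rnorm(m * activeSize), m, activeSize)
    if (model == "cox_linear") {
        beta <- effectSize * (-1)^(seq_len(activeSize) + 1)
        eta <- as.vector(Xa %*% beta)
        -log(runif(m)) / (lambda0 * exp(eta))
    } else if (model == "cox_nonlinear") {
        eta <- effectSize * nonlinearScore(Xa)
        -log(runif(m)) / (lambda0 * exp(eta))
    } else {
        s <- rowSums(Xa) / sqrt(activeSize)
        exp(log(24) - effectSize * s + 0.5 * rnorm(m))
    }
}

## Exponential censoring rate such that P(C < T) matches the target, solved
## on a pilot sample of latent times by monotone root finding.
calibrateCensoringRate <- function(pilotT, censorFrac) {
    f <- function(r) mean(1 - exp(-r * pilotT)) - censorFrac
    lo <- 1e-12
    hi <- 1
    it <- 0L
    while (f(hi) < 0 && it < 60L) { hi <- hi * 2; it <- it + 1L }
    if (f(hi) < 0 || f(lo) > 0)
        stop("censoring calibration infeasible for the requested fraction")
    uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' True active gene indices of a simulated dataset
#'
#' @param se a `SummarizedExperiment` from [simulateScreeningData()].
#' @return integer vector of active gene indices.
#' @export
activeGenes <- function(se) {
    a <- S4Vectors::metadata(se)$active
    if (is.null(a)) stop("no active-set metadata on this object")
    a
}

#' Minimum model size of a screening run
#'
#' The smallest screening size `d` at which the top-`d` set (under the
#' deterministic ranking of [selectTop()]) covers every truly active gene —
#' the standard yardstick for sure-screening power.
#'
#' @param scores per-gene score vector.
#' @param active indices of the truly active genes.
#' @return positive integer.
#' @export
minimumModelSize <- function(scores, active) {
    if (!length(active)) stop("active set must be nonempty")
    if (any(active < 1 | active > length(scores)))
        stop("active indices out of range")
    ranking <- order(-scores, seq_along(scores))
    max(match(active, ranking))
}
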