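#' Literal quintuple-sum estimator of H^2_K(U|V) (correctness oracle)
#'
#' Direct transcription of the Nadaraya-Watson plug-in estimator as a nested
#' sum over five indices,
#' \deqn{\frac{1}{n^5}\sum_{t_1,\dots,t_5}
#'   \frac{G_{t_1t_2} G_{t_1t_3}\, d_{t_2t_3t_4t_5}}
#'        {\frac{1}{n^2}\sum_{s_1,s_2} G_{t_1s_1}G_{t_1s_2}},}
#' with \eqn{d_{t_2t_3t_4t_5} = K_{t_2t_3}-K_{t_2t_4}-K_{t_3t_5}+K_{t_4t_5}};
#' the denominator is local to each \eqn{t_1}. Cost is O(n^5), so this is an
#' oracle for testing [h2Cond()], refused above a small `n`.
#'
#' @param u,v numeric vectors of equal length.
#' @param config a [KernelConfig-class].
#' @param cap largest `n` accepted.
#' @return the estimate of `H^2_K(U|V)`.
#' @export
h2CondNaive <- function(u, v, config = kernelConfig(), cap = 12L) {
    n <- length(u)
    if (length(v) != n) stop("u and v must have equal length")
    if (n > cap) stop("h2CondNaive() is an O(n^5) oracle; n exceeds the cap")
    h <- resolveBandwidth(v, config)
    K <- kernelMatrix(u, config)
    G <- exp(-outer(v, v, "-")^2 / (2 * h^2))  # h^-q factor cancels
    total <- 0
    for (t1 in seq_len(n)) {
        denom <- sum(outer(G[t1, ], G[t1, ])) / n^2
        for (t2 in seq_len(n)) for (t3 in seq_len(n))
            for (t4 in seq_len(n)) for (t5 in seq_len(n)) {
                d <- K[t2, t3] - K[t2, t4] - K[t3, t5] + K[t4, t5]
                total <- total + G[t1, t2] * G[t1, t3] * d / denom
            }
    }
    total / n^5
}

#' Nadaraya-Watson plug-in estimator of H^2_K(U|V)
#'
#' Algebraically reduced form of the same estimator as [h2CondNaive()]: with
#' the row-stochastic weight matrix `A` from [smoothingWeights()], kernel row
#' sums `R` and grand sum `Q`, the two free indices of the quintuple sum
#' collapse and the estimate is
#' `mean_t [ (A K A')_tt - (2/n) (A R)_t + Q / n^2 ]`.
#' Agreement with the literal sum to 1e-10 is enforced in the test suite.
#' The finite-sample value may be slightly negative under independence and is
#' not clamped.
#'
#' @inheritParams h2CondNaive
#' @return the estimate of `H^2_K(U|V)`.
#' @export
h2Cond <- function(u, v, config = kernelConfig()) {
    n <- length(u)
    if (length(v) != n) stop("u and v must have equal length")
    A <- smoothingWeights(v, resolveBandwidth(v, config))
    K <- kernelMatrix(u, config)
    h2CondFromMatrices(K, A)
}

## Shared core: K characteristic Gram matrix, A row-stochastic NW weights.
h2CondFromMatrices <- function(K, A) {
    n <- nrow(K)
    R <- rowSums(K)
    Q <- sum(R)
    B <- A %*% K
    mean(rowSums(B * A) - (2 / n) * as.vector(A %*% R) + Q / n^2)
}

#' Plug-in estimator of the self term H^2_K(U|U)
#'
#' `mean_i K(u_i, u_i) - mean_{i1,i2} K(u_i1, u_i2)`; for a unit-diagonal
#' kernel this is one minus the mean of the Gram matrix. Nonnegative, and
#' zero exactly when all entries of `u` coincide.
#'
#' @inheritParams h2CondNaive
#' @return nonnegative scalar.
#' @export
h2Self <- function(u, config = kernelConfig()) {
    if (!length(u)) stop("empty input")
    if (length(unique(u)) == 1L) return(0)
    K <- kernelMatrix(u, config)
    mean(diag(K)) - mean(K)
}

#' ECCFIC correlation between two variables
#'
#' The normalized kernel dependence measure
#' `rho_K(U|V) = H^2_K(U|V) / H^2_K(U|U)`, estimated by the plug-in
#' Nadaraya-Watson forms. The population value lies in `[0, 1]`, equals 0
#' iff `U` and `V` are independent and 1 iff `U` is a function of `V`;
#' finite-sample estimates are reported raw (no clamping).
#'
#' @inheritParams h2CondNaive
#' @return an [EccficResult-class].
#' @examples
#' set.seed(1)
#' v <- runif(200)
#' eccficCorr(sin(2 * pi * v) + rnorm(200, sd = 0.1), v)
#' @export
eccficCorr <- function(u, v, config = kernelConfig()) {
    n <- length(u)
    if (length(v) != n) stop("u and v must have equal length")
    if (length(unique(u)) == 1L)
        stop("degenerate outcome: H^2_K(U|U) = 0 (constant u), ",
             "the ECCFIC correlation is undefined")
    resolved <- resolveConfig(u, v, config)
    self <- h2Self(u, resolved)
    cond <- h2Cond(u, v, resolved)
    new("EccficResult", h2Cond = cond, h2Self = self, rho = cond / self,
        n = as.integer(n), config = resolved)
}
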