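#' Per-gene ECCFIC screening scores
#'
#' Transforms the observed survival times by the Kaplan-Meier CDF and every
#' gene column by its empirical CDF, then scores gene `j` by the ECCFIC
#' correlation between the transformed outcome and the transformed column.
#' The characteristic-kernel Gram matrix and the self term depend only on the
#' outcome and are computed once; the Nadaraya-Watson bandwidth is resolved
#' per gene from its transformed column (Silverman rule by default).
#'
#' Constant columns cannot be scored: their score is set to the sentinel
#' `-Inf`, they are reported in the `"flagged"` attribute, and a warning is
#' raised. They are never silently dropped.
#'
#' @param X numeric matrix, samples in rows and genes in columns.
#' @param y,delta observed times and event indicators, aligned to rows of `X`.
#' @param config a [KernelConfig-class].
#' @return numeric vector of length `ncol(X)`, named by column names when
#'   present, with attribute `"flagged"` listing degenerate columns.
#' @seealso [esisScreen()] for the full screen returning a
#'   [ScreeningResult-class].
#' @export
esisScores <- function(X, y, delta, config = kernelConfig()) {
    X <- as.matrix(X)
    checkSurvival(y, delta)
    if (nrow(X) != length(y))
        stop("number of rows of X must match the survival data")
    n <- nrow(X)
    u <- kmCDF(y, delta)$u
    if (length(unique(u)) == 1L)
        stop("degenerate outcome: Kaplan-Meier transform is constant ",
             "(no events?)")
    cfg <- config
    cfg@sigma <- resolveSigma(u, config)
    K <- kernelMatrix(u, cfg)
    self <- mean(diag(K)) - mean(K)
    R <- rowSums(K)
    Q <- sum(R)
    scores <- vapply(seq_len(ncol(X)), function(j) {
        v <- X[, j]
        if (length(unique(v)) == 1L) return(-Inf)
        v <- ecdfTransform(v)
        A <- smoothingWeights(v, resolveBandwidth(v, cfg))
        B <- A %*% K
        mean(rowSums(B * A) - (2 / n) * as.vector(A %*% R) + Q / n^2) / self
    }, numeric(1))
    names(scores) <- colnames(X)
    flagged <- which(is.infinite(scores))
    if (length(flagged))
        warning(length(flagged), " constant gene column(s) flagged with a ",
                "-Inf sentinel score")
    attr(scores, "flagged") <- as.integer(unname(flagged))
    scores
}

#' Default screening sizes
#'
#' The usual hard-threshold choices for the number of genes to retain:
#' `floor(n / log n)`, twice or three times that, or `n - 1` (natural
#' logarithm throughout).
#'
#' @param n sample size, at least 2.
#' @param rule one of `"n_over_logn"`, `"two_n_over_logn"`,
#'   `"three_n_over_logn"`, `"n_minus_1"`.
#' @return a positive integer screening size.
#' @examples
#' defaultD(379, "n_minus_1")   # 378
#' defaultD(100, "n_over_logn") # 21
#' @export
defaultD <- function(n, rule = c("n_over_logn", "two_n_over_logn",
                                 "three_n_over_logn", "n_minus_1")) {
    rule <- match.arg(rule)
    if (n < 2) stop("n must be at least 2")
    d <- switch(rule,
        n_over_logn = floor(n / log(n)),
        two_n_over_logn = floor(2 * n / log(n)),
        three_n_over_logn = floor(3 * n / log(n)),
        n_minus_1 = n - 1)
    d <- as.integer(d)
    if (d < 1L) stop("screening size rule gave d < 1 for n = ", n)
    d
}

#' Rank scores and keep the top d
#'
#' Deterministic selection: sort scores in decreasing order, breaking ties by
#' ascending column index, and retain the first `d`.
#'
#' @param scores numeric score vector (may contain `-Inf` sentinels).
#' @param d number of genes to keep, `1 <= d <= length(scores)`.
#' @param geneIds identifiers aligned to `scores`; defaults to names or
#'   `g<j>`.
#' @return a [ScreeningResult-class].
#' @export
selectTop <- function(scores, d, geneIds = NULL) {
    p <- length(scores)
    if (d < 1 || d > p) stop("d must lie between 1 and the number of genes")
    if (is.null(geneIds))
        geneIds <- if (!is.null(names(scores))) names(scores)
                   else paste0("g", seq_len(p))
    if (length(geneIds) != p) stop("geneIds must match scores in length")
    flagged <- attr(scores, "flagged")
    ranking <- order(-scores, seq_len(p))  # ties: ascending column index
    new("ScreeningResult",
        scores = as.numeric(scores),
        ranking = as.integer(ranking),
        selected = as.integer(ranking[seq_len(d)]),
        d = as.integer(d),
        geneIds = as.character(geneIds),
        flagged = if (is.null(flagged)) integer(0) else as.integer(flagged))
}

#' Sure independence screen of an expression matrix against survival
#'
#' The full ESIS pipeline: Kaplan-Meier transform of the outcome, empirical
#' CDF transform of every gene, ECCFIC correlation scores, and retention of
#' the top `d` genes. Methods exist for a plain samples-by-genes matrix with
#' explicit survival vectors and for a `SummarizedExperiment` (genes in rows)
#' whose `colData` carries `time` and `status` columns.
#'
#' @param x expression data: matrix (samples x genes) or
#'   `SummarizedExperiment` (genes x samples).
#' @param ... passed on to methods.
#' @return a [ScreeningResult-class].
#' @examples
#' sim <- simulateScreeningData(n = 60, p = 30, seed = 7)
#' res <- esisScreen(sim, dRule = "n_over_logn")
#' selectedGenes(res)
#' @export
setGeneric("esisScreen", function(x, ...) standardGeneric("esisScreen"))

#' @describeIn esisScreen matrix interface.
#' @param y,delta observed times and event indicators (matrix method).
#' @param d explicit screening size; overrides `dRule` when given.
#' @param dRule screening-size rule, see [defaultD()].
#' @param config a [KernelConfig-class].
#' @export
setMethod("esisScreen", "matrix",
    function(x, y, delta, d = NULL, dRule = "n_over_logn",
             config = kernelConfig()) {
        scores <- esisScores(x, y, delta, config)
        if (is.null(d)) d <- defaultD(nrow(x), dRule)
        selectTop(scores, d)
    })

#' @describeIn esisScreen `SummarizedExperiment` interface; uses the first
#'   assay (genes x samples) and the `time`/`status` columns of `colData`.
#' @export
setMethod("esisScreen", "SummarizedExperiment",
    function(x, d = NULL, dRule = "n_over_logn", config = kernelConfig()) {
        surv <- survivalData(x)
        esisScreen(t(SummarizedExperiment::assay(x)),
                   y = surv$time, delta = surv$status,
                   d = d, dRule = dRule, config = config)
    })

#' Extract the survival table of an expression experiment
#'
#' @param se a `SummarizedExperiment` whose `colData` has `time` and `status`.
#' @return data.frame with `sample_id`, `time`, `status`.
#' @export
survivalData <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    if (!all(c("time", "status") %in% colnames(cd)))
        stop("colData must contain 'time' and 'status' columns")
    data.frame(sample_id = colnames(se), time = cd$time, status = cd$status,
               row.names = NULL)
}
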