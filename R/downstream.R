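#' Stratified train/test split on censoring status
#'
#' Splits samples into training and testing sets with randomization
#' stratified on the event indicator, so the censoring fraction is preserved
#' in both sets. Within each stratum the test set gets `floor` of its share
#' and the remainder goes to training, which reproduces splits such as
#' 379/94 from 473 samples with 207 events at a 4:1 ratio.
#'
#' @param y,delta observed times and event indicators.
#' @param trainFrac fraction of each stratum assigned to training (default
#'   0.8, i.e. a 4:1 split).
#' @param seed integer seed making the split reproducible.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(y, delta, trainFrac = 0.8, seed = 1L) {
    checkSurvival(y, delta)
    if (trainFrac <= 0 || trainFrac >= 1) stop("trainFrac must be in (0, 1)")
    strata <- list(which(delta == 1), which(delta == 0))
    if (any(vapply(strata, length, integer(1)) < 2L))
        stop("each censoring stratum needs at least 2 samples")
    set.seed(as.integer(seed))
    test <- integer(0)
    for (idx in strata) {
        # epsilon guards against 1 - trainFrac landing just below a round
        # fraction in floating point (e.g. 10 * (1 - 0.8) = 1.9999...)
        nTest <- floor(length(idx) * (1 - trainFrac) + 1e-9)
        if (nTest > 0)
            test <- c(test, sort(sample(idx, nTest)))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(y), test), test = test)
}

#' Dichotomize risk scores at a cutoff
#'
#' Labels a sample high-risk iff its score strictly exceeds the cutoff (ties
#' go to the low-risk group). With the cutoff at the median of the scores
#' being labelled, the two groups differ in size by at most one when scores
#' are distinct. The training-derived cutoff is applied unchanged to any
#' external cohort, where the groups need not balance.
#'
#' @param scores numeric risk scores (linear predictors).
#' @param cutoff threshold; defaults to `median(scores)`.
#' @param source label recording which cohort defined the cutoff.
#' @return a [RiskStratification-class].
#' @export
dichotomize <- function(scores, cutoff = median(scores), source = "training") {
    if (anyNA(scores) || any(!is.finite(scores)))
        stop("risk scores must be finite")
    groups <- factor(ifelse(scores > cutoff, "high", "low"),
                     levels = c("low", "high"))
    new("RiskStratification", riskScores = as.numeric(scores),
        cutoff = as.numeric(cutoff), groups = groups,
        source = as.character(source))
}

#' Two-sample log-rank test
#'
#' The classical log-rank statistic: at every distinct event time the
#' observed number of events in group 1 is compared with its hypergeometric
#' expectation given the margins of the at-risk table, and the standardized
#' squared sum is referred to a chi-square distribution with one degree of
#' freedom. Implemented natively (it is the evaluation statistic of record
#' for risk stratification here); agreement with `survival::survdiff` is
#' enforced in the test suite.
#'
#' @param y,delta observed times and event indicators.
#' @param groups a two-level factor (or coercible) of group labels.
#' @return list with `statistic` (chi-square), `p.value`, and the per-group
#'   observed and expected event counts.
#' @examples
#' y <- c(2, 4, 5, 7, 9, 11, 3, 8); d <- c(1, 1, 0, 1, 1, 0, 1, 1)
#' g <- rep(c("a", "b"), each = 4)
#' logrankTest(y, d, g)
#' @export
logrankTest <- function(y, delta, groups) {
    checkSurvival(y, delta)
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("logrankTest() requires exactly two groups")
    if (length(groups) != length(y))
        stop("groups must align with the survival data")
    if (sum(delta) == 0) stop("no events: log-rank test undefined")
    g1 <- groups == levels(groups)[1]
    evTimes <- sort(unique(y[delta == 1]))
    firstEvent <- min(evTimes)
    if (!any(g1 & y >= firstEvent) || !any(!g1 & y >= firstEvent))
        stop("degenerate design: a group has no samples at risk at any ",
             "event time")
    obs <- exp1 <- varSum <- 0
    obsByGroup <- expByGroup <- c(0, 0)
    for (tk in evTimes) {
        atRisk <- y >= tk
        nk <- sum(atRisk)
        n1k <- sum(atRisk & g1)
        dk <- sum(y == tk & delta == 1)
        d1k <- sum(y == tk & delta == 1 & g1)
        ek <- dk * n1k / nk
        obs <- obs + d1k
        exp1 <- exp1 + ek
        obsByGroup <- obsByGroup + c(d1k, dk - d1k)
        expByGroup <- expByGroup + c(ek, dk - ek)
        if (nk > 1)
            varSum <- varSum +
                dk * (n1k / nk) * (1 - n1k / nk) * (nk - dk) / (nk - 1)
    }
    stat <- if (varSum == 0) 0 else (obs - exp1)^2 / varSum
    names(obsByGroup) <- names(expByGroup) <- levels(groups)
    list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         observed = obsByGroup, expected = expByGroup)
}

#' Penalized Cox risk model (adapter around glmnet)
#'
#' Thin wrapper fitting an L1-penalized proportional-hazards model to the
#' screened gene set via `glmnet::cv.glmnet` (partial-likelihood deviance,
#' 10-fold cross-validation by default) and returning the coefficients at
#' the deviance-minimizing penalty together with the per-sample linear
#' predictor — the risk score used for stratification. The solver is
#' established methodology; only this adapter is under test here.
#'
#' @param X samples-by-genes matrix of the screened (reduced) gene set.
#' @param y,delta observed times and event indicators.
#' @param nfolds number of cross-validation folds.
#' @param seed seed fixing the fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation when given.
#' @return list with `coefficients` (named, sparse-as-dense numeric),
#'   `riskScores`, `lambda`, and the underlying fit object.
#' @export
fitPenalizedCox <- function(X, y, delta, nfolds = 10L, seed = 1L,
                            lambda = NULL) {
    X <- as.matrix(X)
    checkSurvival(y, delta)
    surv <- survival::Surv(y, delta)
    if (is.null(lambda)) {
        set.seed(as.integer(seed))
        foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
        cvfit <- glmnet::cv.glmnet(X, surv, family = "cox", foldid = foldid)
        lambda <- cvfit$lambda.min
        fit <- cvfit$glmnet.fit
    } else {
        fit <- glmnet::glmnet(X, surv, family = "cox", lambda = lambda)
    }
    beta <- as.numeric(stats::coef(fit, s = lambda))
    names(beta) <- colnames(X)
    list(coefficients = beta,
         riskScores = as.vector(X %*% beta),
         lambda = lambda,
         fit = fit)
}

#' Naive variance screening baseline
#'
#' Ranks genes by sample variance and keeps the top `topK` — the common
#' quick-and-dirty pre-filter used as a baseline against dependence-based
#' screening. Ties break by ascending column index.
#'
#' @param X samples-by-genes matrix.
#' @param topK number of genes to keep.
#' @return integer indices of the retained columns, in rank order.
#' @export
naiveVarianceScreen <- function(X, topK) {
    X <- as.matrix(X)
    if (topK < 1 || topK > ncol(X)) stop("topK must lie in 1..p")
    v <- apply(X, 2, var)
    order(-v, seq_len(ncol(X)))[seq_len(topK)]
}

#' Screen, fit, stratify and test in one call
#'
#' The post-screening application pipeline: stratified train/test split,
#' ESIS on the training set, penalized Cox fit on the retained genes,
#' risk-score dichotomization at the training median, and log-rank
#' comparison of the two risk groups in training and test cohorts.
#'
#' @param se `SummarizedExperiment` with expression and `time`/`status`.
#' @param trainFrac training fraction for the stratified split.
#' @param d,dRule screening size (explicit or rule), see [esisScreen()].
#' @param config a [KernelConfig-class].
#' @param seed seed for the split and the cross-validation folds.
#' @param screen set `FALSE` to skip screening and use all genes.
#' @return list with the split, the screening result, the penalized fit,
#'   the training/test stratifications and their log-rank results.
#' @export
evaluatePipeline <- function(se, trainFrac = 0.8, d = NULL,
                             dRule = "n_over_logn",
                             config = kernelConfig(), seed = 1L,
                             screen = TRUE) {
    surv <- survivalData(se)
    X <- t(SummarizedExperiment::assay(se))
    split <- stratifiedSplit(surv$time, surv$status, trainFrac, seed)
    tr <- split$train; te <- split$test
    if (screen) {
        scr <- esisScreen(X[tr, , drop = FALSE], surv$time[tr],
                          surv$status[tr], d = d, dRule = dRule,
                          config = config)
        keep <- selectedIndices(scr)
    } else {
        scr <- NULL
        keep <- seq_len(ncol(X))
    }
    fit <- fitPenalizedCox(X[tr, keep, drop = FALSE], surv$time[tr],
                           surv$status[tr], seed = seed)
    cutoff <- median(fit$riskScores)
    trainStrat <- dichotomize(fit$riskScores, cutoff, source = "training")
    testScores <- as.vector(X[te, keep, drop = FALSE] %*% fit$coefficients)
    testStrat <- dichotomize(testScores, cutoff, source = "training")
    trainTest <- tryCatch(
        logrankTest(surv$time[tr], surv$status[tr], riskGroups(trainStrat)),
        error = function(e) NULL)
    testTest <- tryCatch(
        logrankTest(surv$time[te], surv$status[te], riskGroups(testStrat)),
        error = function(e) NULL)
    list(split = split, screening = scr, fit = fit, cutoff = cutoff,
         train = trainStrat, test = testStrat,
         trainLogrank = trainTest, testLogrank = testTest)
}
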