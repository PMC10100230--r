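test_that("stratifiedSplit preserves censoring strata at the given ratio", {
    y <- rep(1:20, length.out = 20) + 0.5
    delta <- rep(c(1, 0), each = 10)
    sp <- stratifiedSplit(y, delta, trainFrac = 0.8, seed = 3)
    expect_length(sp$train, 16)
    expect_length(sp$test, 4)
    expect_equal(sum(delta[sp$train]), 8)
    expect_equal(sum(delta[sp$test]), 2)
    expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
    expect_identical(sp, stratifiedSplit(y, delta, trainFrac = 0.8, seed = 3))
})

test_that("per-stratum floor rounding reproduces a 379/94 style split", {
    # 473 samples with 207 events at 4:1
    set.seed(61)
    y <- runif(473, 1, 100)
    delta <- c(rep(1, 207), rep(0, 266))
    sp <- stratifiedSplit(y, delta, trainFrac = 0.8, seed = 8)
    expect_length(sp$train, 379)
    expect_length(sp$test, 94)
    expect_equal(sum(delta[sp$test]), floor(207 * 0.2))
    expect_error(stratifiedSplit(c(1, 2, 3), c(1, 1, 0)), "at least 2")
})

test_that("dichotomize labels high only above the cutoff", {
    strat <- dichotomize(c(1, 2, 3, 4), cutoff = 10)
    expect_true(all(riskGroups(strat) == "low"))
    set.seed(71)
    sc <- rnorm(21)
    atMedian <- dichotomize(sc)
    tab <- table(riskGroups(atMedian))
    expect_lte(abs(tab[["high"]] - tab[["low"]]), 1)
    expect_equal(atMedian@cutoff, median(sc))
    # external cohort keeps the training cutoff; balance not guaranteed
    ext <- dichotomize(sc + 5, cutoff = atMedian@cutoff, source = "training")
    expect_true(all(riskGroups(ext) == "high"))
    expect_output(show(ext), "cutoff")
})

test_that("log-rank statistic is zero for two identical groups", {
    y <- c(2, 5, 8, 11)
    d <- c(1, 0, 1, 1)
    res <- logrankTest(c(y, y), c(d, d), rep(c("a", "b"), each = 4))
    expect_equal(res$statistic, 0)
    expect_equal(res$p.value, 1)
})

test_that("log-rank matches the hand-built observed-expected table", {
    # two groups of four; events at t = 2, 3, 4, 7, 8, 9
    y <- c(2, 4, 5, 7, 3, 8, 9, 11)
    d <- c(1, 1, 0, 1, 1, 1, 1, 0)
    g <- rep(c("a", "b"), each = 4)
    # hand accumulation of O - E and hypergeometric variances for group a:
    # t=2: E=4/8, V=1*(4/8)(4/8)(7/7); t=3: E=3/7, V=(3/7)(4/7)
    # t=4: E=3/6, V=(3/6)(3/6); t=7: E=1/4, V=(1/4)(3/4); t=8,9: E=V=0
    expObs <- 3
    expE <- 4 / 8 + 3 / 7 + 3 / 6 + 1 / 4
    expV <- (4 / 8) * (4 / 8) + (3 / 7) * (4 / 7) + (3 / 6) * (3 / 6) +
        (1 / 4) * (3 / 4)
    res <- logrankTest(y, d, g)
    expect_equal(res$observed[["a"]], expObs)
    expect_equal(res$expected[["a"]], expE)
    expect_equal(res$statistic, (expObs - expE)^2 / expV)
})

test_that("log-rank agrees with survival::survdiff on random instances", {
    set.seed(81)
    for (i in 1:25) {
        n <- sample(20:60, 1)
        s <- randomSurvival(n, runif(1, 0.1, 0.5))
        g <- factor(sample(c("a", "b"), n, replace = TRUE))
        if (min(table(g)) < 2) next
        ref <- survival::survdiff(survival::Surv(s$y, s$delta) ~ g)
        expect_equal(logrankTest(s$y, s$delta, g)$statistic,
                     unname(ref$chisq), tolerance = 1e-8)
    }
})

test_that("log-rank rejects degenerate designs", {
    expect_error(logrankTest(c(1, 2, 3, 4), c(1, 1, 0, 0),
                             rep("a", 4)), "two groups")
    expect_error(logrankTest(c(1, 2, 3, 4), c(0, 0, 0, 0),
                             rep(c("a", "b"), 2)), "no events")
    # group b leaves the risk set before the first event
    expect_error(logrankTest(c(5, 6, 1, 2), c(1, 1, 0, 0),
                             rep(c("a", "b"), each = 2)), "at risk")
})

test_that("fitPenalizedCox recovers a strong gene and honors the penalty", {
    set.seed(91)
    n <- 150
    X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("g", 1:6)))
    tt <- -log(runif(n)) / (0.05 * exp(1.5 * X[, 1]))
    cc <- rexp(n, 0.02)
    y <- pmin(tt, cc)
    delta <- as.integer(tt <= cc)
    fit <- fitPenalizedCox(X, y, delta, seed = 7)
    expect_gt(fit$coefficients[["g1"]], 0)
    expect_equal(which.max(abs(fit$coefficients)), c(g1 = 1L))
    expect_equal(fit$riskScores, as.vector(X %*% fit$coefficients))
    # determinism under a fixed fold seed
    fit2 <- fitPenalizedCox(X, y, delta, seed = 7)
    expect_identical(fit$coefficients, fit2$coefficients)
    # heavy penalty on pure noise: no coefficient survives
    Xn <- matrix(rnorm(n * 5), n)
    sn <- randomSurvival(n, 0.3)
    heavy <- fitPenalizedCox(Xn, sn$y, sn$delta, lambda = 5)
    expect_true(all(heavy$coefficients == 0))
    expect_equal(var(heavy$riskScores), 0)
})

test_that("naiveVarianceScreen ranks columns by variance", {
    X <- cbind(a = c(0, 6, 0, 6), b = c(1, 2, 1, 2), c = c(0, 3, 0, 3))
    expect_identical(naiveVarianceScreen(X, 2), c(1L, 3L))
    expect_identical(sort(naiveVarianceScreen(X, 3)), 1:3)
    set.seed(101)
    M <- matrix(rnorm(200), 20)
    expect_identical(naiveVarianceScreen(M, 4),
                     order(-apply(M, 2, var))[1:4])
    expect_error(naiveVarianceScreen(M, 11), "topK")
})

test_that("evaluatePipeline stratifies and tests end to end", {
    sim <- simulateScreeningData(n = 120, p = 40, activeSize = 2,
                                 model = "cox_linear", effectSize = 2,
                                 censorFrac = 0.3, seed = 12)
    res <- evaluatePipeline(sim, d = 10, seed = 12)
    expect_s4_class(res$train, "RiskStratification")
    tab <- table(riskGroups(res$train))
    expect_lte(abs(tab[["high"]] - tab[["low"]]), 1)
    expect_equal(res$cutoff, median(riskScores(res$train)))
    expect_false(is.null(res$testLogrank))
    expect_true(res$trainLogrank$p.value <= 1 && res$trainLogrank$p.value >= 0)
})
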