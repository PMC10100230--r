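test_that("silvermanBandwidth reproduces the 1.06 sd n^(-1/5) rule", {
    set.seed(11)
    v <- rnorm(100)
    expect_equal(silvermanBandwidth(v), 1.06 * sd(v) * 100^(-0.2))
    # sd exactly 1 at n = 2 isolates the printed constant up to n^(-1/5)
    v2 <- c(-0.5, 0.5) * sqrt(2)
    expect_equal(silvermanBandwidth(v2), 1.06 * 2^(-0.2))
    expect_error(silvermanBandwidth(rep(3, 10)), "zero-variance")
    expect_error(silvermanBandwidth(1), "at least 2")
})

test_that("kmCDF without censoring equals the empirical CDF, ties included", {
    set.seed(21)
    y <- sample(c(1.5, 2, 2, 3, 7, 7, 7, 10), 8)
    km <- kmCDF(y, rep(1, 8))
    expect_equal(km$u, ecdfTransform(y))
    grid <- c(0.5, 1.5, 2, 2.5, 7, 9, 10, 12)
    expect_equal(km$cdf(grid),
                 vapply(grid, function(t) mean(y <= t), numeric(1)))
})

test_that("kmCDF with no events is identically zero", {
    km <- kmCDF(c(3, 1, 4), c(0, 0, 0))
    expect_equal(km$u, c(0, 0, 0))
    expect_equal(km$cdf(c(0, 2, 100)), c(0, 0, 0))
})

test_that("kmCDF matches a hand-computed product-limit estimate", {
    # Y = (2, 1, 3), delta = (1, 0, 1): risk sets 2 and 1 at event times 2, 3
    km <- kmCDF(c(2, 1, 3), c(1, 0, 1))
    expect_equal(km$u, c(1 - (1 - 1 / 2), 0, 1 - (1 - 1 / 2) * (1 - 1 / 1)))
    expect_equal(km$cdf(2.5), 0.5)
})

test_that("kmCDF agrees with the survival-package estimator", {
    set.seed(31)
    for (i in 1:20) {
        n <- sample(5:40, 1)
        s <- randomSurvival(n, censorFrac = runif(1, 0, 0.6))
        s$y <- round(s$y, 1) + 0.1  # force some ties, keep positive
        km <- kmCDF(s$y, s$delta)
        expect_equal(km$u, survfitCDF(s$y, s$delta, s$y), tolerance = 1e-12)
    }
})

test_that("kmCDF transform is non-decreasing, right-continuous and bounded", {
    set.seed(41)
    s <- randomSurvival(60, 0.4)
    km <- kmCDF(s$y, s$delta)
    grid <- sort(c(0, s$y, s$y + 1e-9, max(s$y) + 5))
    vals <- km$cdf(grid)
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(km$cdf(0), 0)
})

test_that("ecdfTransform gives ranks over n and is monotone-invariant", {
    expect_equal(ecdfTransform(c(5, 1, 3)), c(1, 1 / 3, 2 / 3))
    expect_equal(ecdfTransform(rep(2.2, 4)), rep(1, 4))
    set.seed(51)
    x <- rnorm(50)
    expect_identical(ecdfTransform(x), ecdfTransform(exp(x)))
    expect_identical(ecdfTransform(x), ecdfTransform(x^3 + 10 * x))
})

test_that("kernelMatrix matches the scalar closed forms elementwise", {
    set.seed(61)
    u <- rnorm(6)
    for (kern in c("gaussian", "laplacian")) {
        sigma <- runif(1, 0.2, 2)
        K <- kernelMatrix(u, kernelConfig(kern, sigma = sigma))
        ref <- outer(u, u, function(a, b)
            if (kern == "gaussian") exp(-(a - b)^2 / (2 * sigma^2))
            else exp(-abs(a - b) / sigma))
        expect_equal(K, ref, tolerance = 1e-12)
        expect_true(isSymmetric(K))
        expect_equal(diag(K), rep(1, 6))
        expect_true(min(eigen(K, symmetric = TRUE,
                              only.values = TRUE)$values) > -1e-10)
    }
    expect_equal(kernelMatrix(c(0, 1), kernelConfig(sigma = 1))[1, 2],
                 exp(-1 / 2))
    expect_equal(kernelMatrix(rep(0.7, 4), kernelConfig(sigma = 2)),
                 matrix(1, 4, 4))
    expect_error(kernelConfig(sigma = -1), "positive")
})

test_that("smoothingWeights rows are stochastic and flatten as h grows", {
    set.seed(71)
    v <- rnorm(20)
    for (h in c(0.05, 0.5, 5)) {
        A <- smoothingWeights(v, h)
        expect_equal(rowSums(A), rep(1, 20), tolerance = 1e-12)
        expect_true(all(A >= 0 & A <= 1))  # far pairs may underflow to 0
        expect_true(all(diag(A) > 0))
    }
    expect_equal(smoothingWeights(3.2, 1), matrix(1, 1, 1))
    expect_equal(smoothingWeights(v, 1e8), matrix(1 / 20, 20, 20),
                 tolerance = 1e-10)
    expect_error(smoothingWeights(v, 0), "positive")
})

test_that("medianHeuristic is the median nonzero pairwise gap", {
    u <- c(0, 1, 3)
    expect_equal(medianHeuristic(u), median(c(1, 3, 2)))
    expect_error(medianHeuristic(rep(1, 5)), "degenerate")
})
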