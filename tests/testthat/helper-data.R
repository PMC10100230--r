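## Small fixtures built in code.

## Random right-censored sample with roughly the requested censoring.
randomSurvival <- function(n, censorFrac = 0.3) {
    tt <- rexp(n, rate = 1 / 20)
    cc <- if (censorFrac > 0) rexp(n, rate = censorFrac / ((1 - censorFrac) * 20))
          else rep(Inf, n)
    list(y = pmin(tt, cc), delta = as.integer(tt <= cc))
}

## Fully resolved config with random scales, for oracle comparisons.
randomConfig <- function(kernel = sample(c("gaussian", "laplacian"), 1)) {
    kernelConfig(characteristicKernel = kernel,
                 sigma = runif(1, 0.3, 2),
                 bandwidthRule = "fixed",
                 bandwidth = runif(1, 0.1, 1))
}

## Kaplan-Meier CDF via the survival package, evaluated at given times —
## independent oracle for kmCDF().
survfitCDF <- function(y, delta, at) {
    fit <- survival::survfit(survival::Surv(y, delta) ~ 1)
    s <- summary(fit, times = at, extend = TRUE)
    1 - s$surv[match(at, s$time)]
}
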