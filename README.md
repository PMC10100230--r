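# esis

Model-free sure independence screening for high-dimensional right-censored
survival data.

## What it is for

Prognostic-gene discovery in cancer cohorts starts from a matrix with
thousands of genes and a few hundred patients whose outcome — overall or
disease-free survival — is right-censored. Before any interpretable model
can be fitted, the gene set has to be screened down to fewer genes than
samples, and a screen based on linear correlation silently discards genes
whose effect on the hazard is nonlinear or non-monotone. `esis` ranks genes
by a kernel dependence measure that detects *any* form of dependence, makes
no assumption about the model linking expression to survival, and handles
censoring through a Kaplan-Meier transform of the observed times.

## The statistic

For random variables `U`, `V` and a characteristic positive definite kernel
`K` (Gaussian or Laplacian), the ECCFIC correlation is

    ρ_K(U|V) = H²_K(U|V) / H²_K(U|U),
    H²_K(U|V) = E_V E_{U|v,U'|v} K(U,U') − E_{U,U'} K(U,U'),

with `ρ_K(U|V) ∈ [0,1]`, `= 0` iff `U ⫫ V` and `= 1` iff `U` is a function
of `V` — a nonlinear generalization of R². Gene `j` is scored by

    ŵ_j = ρ̂_K( F̂_T(Y) | F̂_Xj(X_j) ),

where `F̂_T` is the Kaplan-Meier CDF of the event time evaluated at the
observed (possibly censored) times and `F̂_Xj` is the per-gene empirical
CDF; the conditional term is estimated with a Nadaraya-Watson smoother
(Gaussian weights, `1.06·sd·n^(−1/5)` bandwidth). The screen keeps the `d`
highest-scoring genes (`⌊n/log n⌋` by default). Scores are exactly
invariant under monotone transforms of expression, and the estimator is
covered by a literal brute-force oracle of its defining multi-index sum in
the test suite.

A downstream stage reproduces the standard signature workflow: stratified
4:1 split, LASSO-penalized Cox fit (via glmnet) on the screened genes,
risk-score dichotomization at the training median, and a log-rank
comparison of the resulting risk groups.

## Worked example

```r
library(esis)

sim <- simulateScreeningData(n = 150, p = 300, activeSize = 3,
                             model = "cox_nonlinear", censorFrac = 0.4,
                             seed = 42)
res <- esisScreen(sim, dRule = "n_over_logn")
res
#> ScreeningResult: 29 of 300 genes selected
#>   top genes: gene0003 (0.0771), gene0002 (0.0592), gene0263 (0.0369), gene0207 (0.0349), gene0001 (0.0347)
match(activeGenes(sim), res@ranking)
#> [1] 5 2 1
```

The three truly active genes — one with a quadratic, one with a sinusoidal
and one with a `|x|`-shaped effect on the log hazard — rank 5th, 2nd and
1st among 300, so all of them survive the `d = 29` cut; a Pearson screen
would miss the symmetric ones. Scores (here 0.03–0.08) are estimated ECCFIC
correlations: near 0 for noise genes, larger for dependent ones.

On a linear design the full pipeline separates risk groups out of sample:

```r
simLin <- simulateScreeningData(n = 150, p = 300, activeSize = 3,
                                model = "cox_linear", censorFrac = 0.4,
                                seed = 42)
pipe <- evaluatePipeline(simLin, seed = 42)
pipe$testLogrank[c("statistic", "p.value")]
#> $statistic
#> [1] 12.98345
#> $p.value
#> [1] 0.0003142567
```

i.e. the median-dichotomized risk score built on the screened genes yields
a test-cohort log-rank χ² of 13.0 (p ≈ 3e-4).

A command-line interface wrapping the same functions ships with the
package (`system.file("cli", "esis.R", package = "esis")`) with
`simulate`, `screen` and `evaluate` subcommands reading/writing TSV
expression matrices, CSV survival tables and JSON summaries.

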