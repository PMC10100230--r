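#' @import methods
#' @importFrom stats median sd var rnorm runif rexp uniroot pchisq setNames
#'   IQR coef
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Kernel configuration for the ECCFIC dependence measure
#'
#' Bundles the characteristic kernel acting on the (transformed) outcome, the
#' smoothing kernel used by the Nadaraya-Watson conditional-mean estimator,
#' and the bandwidth rule for the conditioning variable. The conditioning
#' variable is always scalar here (`q = 1`).
#'
#' @slot characteristicKernel `"gaussian"` or `"laplacian"`; both are bounded,
#'   positive definite and characteristic on the unit interval, so the induced
#'   dependence measure detects any departure from independence.
#' @slot sigma positive scale of the characteristic kernel, or `NA_real_` to
#'   resolve it from the data by the median heuristic (median of the nonzero
#'   pairwise absolute differences of the outcome variable).
#' @slot smoothingKernel currently only `"gaussian"`.
#' @slot bandwidthRule `"silverman"` (the 1.06 sd n^(-1/5) rule, resolved per
#'   conditioning variable) or `"fixed"`.
#' @slot bandwidth the fixed bandwidth `h > 0` when `bandwidthRule = "fixed"`,
#'   otherwise `NA_real_`.
#'
#' @seealso [kernelConfig()] for the user-facing constructor.
#' @exportClass KernelConfig
setClass("KernelConfig",
    representation(
        characteristicKernel = "character",
        sigma = "numeric",
        smoothingKernel = "character",
        bandwidthRule = "character",
        bandwidth = "numeric"
    ),
    prototype(
        characteristicKernel = "gaussian",
        sigma = NA_real_,
        smoothingKernel = "gaussian",
        bandwidthRule = "silverman",
        bandwidth = NA_real_
    )
)

setValidity("KernelConfig", function(object) {
    msg <- character()
    if (!object@characteristicKernel %in% c("gaussian", "laplacian"))
        msg <- c(msg, "characteristicKernel must be 'gaussian' or 'laplacian'")
    if (!identical(object@smoothingKernel, "gaussian"))
        msg <- c(msg, "smoothingKernel must be 'gaussian'")
    if (!object@bandwidthRule %in% c("silverman", "fixed"))
        msg <- c(msg, "bandwidthRule must be 'silverman' or 'fixed'")
    if (!is.na(object@sigma) && object@sigma <= 0)
        msg <- c(msg, "sigma must be positive")
    if (identical(object@bandwidthRule, "fixed") &&
        (is.na(object@bandwidth) || object@bandwidth <= 0))
        msg <- c(msg, "a fixed bandwidthRule requires bandwidth > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a kernel configuration
#'
#' @param characteristicKernel kernel on the outcome variable: `"gaussian"`
#'   (default) or `"laplacian"`.
#' @param sigma positive kernel scale, or `NA` (default) to use the median
#'   heuristic on the outcome at estimation time.
#' @param smoothingKernel smoothing kernel for the Nadaraya-Watson weights;
#'   only `"gaussian"`.
#' @param bandwidthRule `"silverman"` (default) or `"fixed"`.
#' @param bandwidth fixed bandwidth, required iff `bandwidthRule = "fixed"`.
#'
#' @return a [KernelConfig-class] object.
#' @examples
#' kernelConfig()
#' kernelConfig("laplacian", sigma = 0.5)
#' kernelConfig(bandwidthRule = "fixed", bandwidth = 0.1)
#' @export
kernelConfig <- function(characteristicKernel = c("gaussian", "laplacian"),
                         sigma = NA_real_,
                         smoothingKernel = "gaussian",
                         bandwidthRule = c("silverman", "fixed"),
                         bandwidth = NA_real_) {
    new("KernelConfig",
        characteristicKernel = match.arg(characteristicKernel),
        sigma = as.numeric(sigma),
        smoothingKernel = smoothingKernel,
        bandwidthRule = match.arg(bandwidthRule),
        bandwidth = as.numeric(bandwidth))
}

setMethod("show", "KernelConfig", function(object) {
    cat("KernelConfig\n")
    cat("  characteristic kernel:", object@characteristicKernel,
        if (is.na(object@sigma)) "(sigma: median heuristic)"
        else sprintf("(sigma = %g)", object@sigma), "\n")
    cat("  smoothing kernel:     ", object@smoothingKernel, "\n")
    cat("  bandwidth rule:       ", object@bandwidthRule,
        if (identical(object@bandwidthRule, "fixed"))
            sprintf("(h = %g)", object@bandwidth) else "", "\n")
    invisible(NULL)
})

#' ECCFIC estimate for one variable pair
#'
#' Holds the plug-in estimates of the conditional dependence term
#' `H^2_K(U|V)`, the self term `H^2_K(U|U)` and their ratio, the ECCFIC
#' correlation. The ratio is reported raw: finite-sample estimates may fall
#' slightly outside `[0, 1]` and are deliberately not clamped.
#'
#' @slot h2Cond Nadaraya-Watson estimate of `H^2_K(U|V)`.
#' @slot h2Self estimate of `H^2_K(U|U)`; nonnegative.
#' @slot rho `h2Cond / h2Self`.
#' @slot n sample size.
#' @slot config the resolved [KernelConfig-class] snapshot (sigma and, for a
#'   fixed rule, the bandwidth filled in).
#' @exportClass EccficResult
setClass("EccficResult",
    representation(h2Cond = "numeric", h2Self = "numeric", rho = "numeric",
                   n = "integer", config = "KernelConfig"))

setMethod("show", "EccficResult", function(object) {
    cat(sprintf("EccficResult (n = %d)\n", object@n))
    cat(sprintf("  H^2(U|V) = %.6g   H^2(U|U) = %.6g   rho = %.6g\n",
                object@h2Cond, object@h2Self, object@rho))
    invisible(NULL)
})

#' Result of a sure-independence screen
#'
#' @slot scores per-gene ECCFIC correlation scores, `-Inf` for genes flagged
#'   as degenerate (constant columns).
#' @slot ranking permutation of gene indices by decreasing score, ties broken
#'   by ascending column index.
#' @slot selected indices of the `d` top-ranked genes.
#' @slot d screening size.
#' @slot geneIds identifiers aligned to the score vector.
#' @slot flagged indices of genes whose score is a degeneracy sentinel.
#' @exportClass ScreeningResult
setClass("ScreeningResult",
    representation(scores = "numeric", ranking = "integer",
                   selected = "integer", d = "integer",
                   geneIds = "character", flagged = "integer"))

setValidity("ScreeningResult", function(object) {
    p <- length(object@scores)
    msg <- character()
    if (length(object@geneIds) != p)
        msg <- c(msg, "geneIds length must match scores")
    if (!identical(sort(object@ranking), seq_len(p)))
        msg <- c(msg, "ranking must be a permutation of 1..p")
    if (object@d > p || object@d < 1L)
        msg <- c(msg, "d must lie in 1..p")
    if (!identical(object@selected, object@ranking[seq_len(object@d)]))
        msg <- c(msg, "selected must equal the first d entries of ranking")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ScreeningResult", function(object) {
    p <- length(object@scores)
    cat(sprintf("ScreeningResult: %d of %d genes selected\n", object@d, p))
    k <- min(5L, object@d)
    top <- object@ranking[seq_len(k)]
    cat("  top genes:",
        paste(sprintf("%s (%.4f)", object@geneIds[top], object@scores[top]),
              collapse = ", "), "\n")
    if (length(object@flagged))
        cat("  flagged degenerate columns:", length(object@flagged), "\n")
    invisible(NULL)
})

#' @describeIn ScreeningResult-class per-gene scores, named by gene id.
#' @param object a `ScreeningResult`.
#' @export
setGeneric("screeningScores", function(object) standardGeneric("screeningScores"))
setMethod("screeningScores", "ScreeningResult", function(object)
    setNames(object@scores, object@geneIds))

#' @describeIn ScreeningResult-class ids of the selected (top-`d`) genes, in
#'   rank order.
#' @export
setGeneric("selectedGenes", function(object) standardGeneric("selectedGenes"))
setMethod("selectedGenes", "ScreeningResult", function(object)
    object@geneIds[object@selected])

#' @describeIn ScreeningResult-class integer indices of the selected genes,
#'   in rank order.
#' @export
setGeneric("selectedIndices", function(object) standardGeneric("selectedIndices"))
setMethod("selectedIndices", "ScreeningResult", function(object) object@selected)

#' @describeIn ScreeningResult-class the screening size `d`.
#' @export
setGeneric("screeningSize", function(object) standardGeneric("screeningSize"))
setMethod("screeningSize", "ScreeningResult", function(object) object@d)

#' Risk-group assignment from a fitted risk score
#'
#' @slot riskScores linear predictor per sample.
#' @slot cutoff dichotomization threshold (the training-cohort median).
#' @slot groups factor with levels `low`, `high`; `high` iff score strictly
#'   exceeds the cutoff.
#' @slot source label of the cohort that defined the cutoff.
#' @exportClass RiskStratification
setClass("RiskStratification",
    representation(riskScores = "numeric", cutoff = "numeric",
                   groups = "factor", source = "character"))

setMethod("show", "RiskStratification", function(object) {
    tab <- table(object@groups)
    cat(sprintf("RiskStratification (cutoff %.4g from %s cohort)\n",
                object@cutoff, object@source))
    cat(sprintf("  low: %d   high: %d\n", tab[["low"]], tab[["high"]]))
    invisible(NULL)
})

#' @describeIn RiskStratification-class the risk-group factor.
#' @param object a `RiskStratification`.
#' @export
setGeneric("riskGroups", function(object) standardGeneric("riskGroups"))
setMethod("riskGroups", "RiskStratification", function(object) object@groups)

#' @describeIn RiskStratification-class the numeric risk scores.
#' @export
setGeneric("riskScores", function(object) standardGeneric("riskScores"))
setMethod("riskScores", "RiskStratification", function(object) object@riskScores)
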