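#' Read an expression matrix from delimited text
#'
#' Reads a TSV with a header row and an identifier column, in either
#' orientation, into a `SummarizedExperiment` (assay `"expression"`, genes in
#' rows). Genes with zero interquartile range (completely missing or
#' constant, hence unscoreable) are dropped with a message reporting the
#' count; missing or non-numeric cells are rejected with their location.
#'
#' @param path TSV file; first column holds identifiers.
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`.
#' @param dropZeroIQR drop constant genes (default `TRUE`).
#' @return `SummarizedExperiment` with genes in rows.
#' @export
readExpression <- function(path,
                           orientation = c("genes_by_samples",
                                           "samples_by_genes"),
                           dropZeroIQR = TRUE) {
    orientation <- match.arg(orientation)
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2L) stop("expression table needs an id column plus data")
    ids <- tab[[1]]
    if (anyDuplicated(ids))
        stop("duplicate row identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(colnames(tab)[-1]))
        stop("duplicate column identifiers: ",
             paste(unique(colnames(tab)[-1][duplicated(colnames(tab)[-1])]),
                   collapse = ", "))
    suppressWarnings(num <- vapply(tab[-1], as.numeric,
                                   numeric(nrow(tab))))
    num <- matrix(num, nrow = nrow(tab),
                  dimnames = list(ids, colnames(tab)[-1]))
    bad <- which(is.na(num), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric or missing cells, e.g. row '",
             rownames(num)[bad[1, 1]], "' column '",
             colnames(num)[bad[1, 2]], "' (", nrow(bad), " in total)")
    expr <- if (orientation == "samples_by_genes") t(num) else num
    if (dropZeroIQR) {
        iqr0 <- apply(expr, 1, function(x) stats::IQR(x) == 0)
        if (any(iqr0)) {
            message(sum(iqr0), " gene(s) excluded due to zero ",
                    "interquartile range")
            expr <- expr[!iqr0, , drop = FALSE]
        }
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expression = expr))
}

#' Write an expression experiment as TSV (genes by samples)
#'
#' @param se `SummarizedExperiment` with an expression assay.
#' @param path output TSV path.
#' @export
writeExpression <- function(se, path) {
    expr <- SummarizedExperiment::assay(se)
    tab <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a survival table
#'
#' CSV with columns `sample_id`, `time`, `event`. Times must be positive and
#' events 0/1; offending samples are named in errors.
#'
#' @param path CSV path.
#' @return data.frame with `sample_id`, `time`, `event`.
#' @export
readSurvival <- function(path) {
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    need <- c("sample_id", "time", "event")
    if (!all(need %in% colnames(tab)))
        stop("survival table must have columns: ",
             paste(need, collapse = ", "))
    tab$sample_id <- as.character(tab$sample_id)
    if (anyDuplicated(tab$sample_id))
        stop("duplicate sample ids in survival table")
    bad <- which(!is.finite(tab$time) | tab$time <= 0)
    if (length(bad))
        stop("nonpositive or missing times for sample(s): ",
             paste(tab$sample_id[bad], collapse = ", "))
    bad <- which(!tab$event %in% c(0, 1))
    if (length(bad))
        stop("event indicator not in {0,1} for sample(s): ",
             paste(tab$sample_id[bad], collapse = ", "))
    tab[need]
}

#' Write a survival table as CSV
#'
#' @param surv data.frame with `sample_id`, `time`, `event`.
#' @param path output CSV path.
#' @export
writeSurvival <- function(surv, path) {
    utils::write.csv(surv[c("sample_id", "time", "event")], path,
                     row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Attach survival data to an expression experiment
#'
#' Aligns a survival table to the samples of an expression
#' `SummarizedExperiment` by id (any order) and stores `time` and `status`
#' in `colData`. Samples present in one input but not the other are an
#' error, with the offenders listed.
#'
#' @param se `SummarizedExperiment`, genes in rows.
#' @param surv data.frame as from [readSurvival()].
#' @return the experiment with `time` and `status` columns in `colData`.
#' @export
attachSurvival <- function(se, surv) {
    ids <- colnames(se)
    missingIds <- setdiff(ids, surv$sample_id)
    extraIds <- setdiff(surv$sample_id, ids)
    if (length(missingIds) || length(extraIds))
        stop("sample ids do not match; missing from survival table: [",
             paste(missingIds, collapse = ", "), "], not in expression: [",
             paste(extraIds, collapse = ", "), "]")
    m <- match(ids, surv$sample_id)
    SummarizedExperiment::colData(se)$time <- surv$time[m]
    SummarizedExperiment::colData(se)$status <- as.integer(surv$event[m])
    se
}

#' Write a screening result as a ranked TSV
#'
#' Columns: `gene_id`, `score`, `rank`, `selected` (0/1), ordered by rank.
#'
#' @param res a [ScreeningResult-class].
#' @param path output TSV path.
#' @export
writeScreeningResult <- function(res, path) {
    ord <- res@ranking
    tab <- data.frame(gene_id = res@geneIds[ord],
                      score = res@scores[ord],
                      rank = seq_along(ord),
                      selected = as.integer(seq_along(ord) <= res@d))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
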