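#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the identical distribution of
#' values: the reference distribution is the vector of row-wise means of the
#' column-sorted matrix, and each column's values are replaced by the
#' reference values at their within-column ranks, with ties receiving the
#' mean of the reference values they span. Rank order within each column is
#' preserved.
#'
#' @param x numeric matrix (genes x samples, at least two columns) or a
#'   [ResistanceExperiment].
#' @return object of the same class with normalized expression.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(6, 4, 8)))
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
    if (ncol(x) < 2L)
        stop("quantile normalization needs at least two samples")
    if (any(!is.finite(x)))
        stop("expression matrix must be complete and finite")
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "ResistanceExperiment", function(x) {
    SummarizedExperiment::assay(x) <-
        quantileNormalize(SummarizedExperiment::assay(x))
    x
})

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values controlling the false discovery rate:
#' elementwise at least the input, capped at 1, monotone over the order
#' statistics.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must be finite and lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
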