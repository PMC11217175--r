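## Median-split, pathway association and progression/survival analysis.
## Kaplan-Meier curves and log-rank tests delegate to the survival package
## (product-limit estimator; hypergeometric log-rank variance with the
## (n - d)/(n - 1) tie factor), wrapped behind the module surface used by
## the pipeline.

#' Split samples at the median expression of a gene
#'
#' Samples strictly above the across-sample median are labelled `"high"`;
#' values equal to the median go to `"low"` (so the high group strictly
#' exceeds the median).
#'
#' @param x expression matrix or [ResistanceExperiment].
#' @param gene gene id present in `x`.
#' @return named character vector (`"high"`/`"low"`) over the samples.
#' @examples
#' m <- matrix(1:4, 1, 4, dimnames = list("G1", paste0("s", 1:4)))
#' medianSplit(m, "G1")
#' @export
medianSplit <- function(x, gene) {
    x <- .exprMatrix(x)
    if (!gene %in% rownames(x))
        stop(sprintf("gene '%s' absent from the expression matrix", gene))
    v <- x[gene, ]
    if (length(v) < 2L) stop("median split needs at least two samples")
    if (max(v) == min(v))
        stop(sprintf("gene '%s' is constant; median split undefined", gene))
    stats::setNames(ifelse(v > stats::median(v), "high", "low"), colnames(x))
}

#' Associate a gene with pathway activity scores
#'
#' Either compares pathway scores between the gene's median-split high and
#' low sample groups (rank-sum test plus median difference) or correlates
#' the gene's expression with each pathway score (Pearson r with t-transform
#' p), over the samples shared by the expression matrix and the score
#' matrix.
#'
#' @param x expression matrix or [ResistanceExperiment].
#' @param gene candidate gene id.
#' @param scores pathway enrichment matrix (pathways x samples) from
#'   [ssgseaScore()].
#' @param mode `"median_split"` or `"correlation"`.
#' @return data.frame with one row per pathway: `pathway`, `estimate`
#'   (median score difference high - low, or Pearson r), `p_value`, `mode`.
#' @export
pathwayAssociation <- function(x, gene, scores,
                               mode = c("median_split", "correlation")) {
    mode <- match.arg(mode)
    x <- .exprMatrix(x)
    shared <- intersect(colnames(x), colnames(scores))
    if (length(shared) < 3L)
        stop("fewer than three shared samples between expression and scores")
    if (mode == "correlation") {
        out <- hubCellCorrelation(x[, shared, drop = FALSE], gene,
                                  scores[, shared, drop = FALSE])
        return(data.frame(pathway = out$cell_type, estimate = out$r,
                          p_value = out$p, mode = mode,
                          stringsAsFactors = FALSE))
    }
    split <- medianSplit(x[, shared, drop = FALSE], gene)
    hi <- shared[split == "high"]
    lo <- shared[split == "low"]
    rows <- lapply(rownames(scores), function(s) {
        a <- scores[s, hi]; b <- scores[s, lo]
        rt <- .rankTest(a, b, paired = FALSE)
        data.frame(pathway = s,
                   estimate = stats::median(a) - stats::median(b),
                   p_value = rt$p, mode = mode, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Kaplan-Meier product-limit fit
#'
#' Product-limit estimate of the survival function per group: at every
#' event time `S(t)` is multiplied by `1 - d/n`; censored subjects leave the
#' risk set after their time, with events processed before censorings tied
#' at the same time.
#'
#' @param times non-negative event/censoring times (days).
#' @param events logical (or 0/1) event indicators.
#' @param labels optional group labels (one curve per group).
#' @return a [survival::survfit] object.
#' @examples
#' fit <- kmFit(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' summary(fit)$surv  # 2/3, 1/3, 0
#' @export
kmFit <- function(times, events, labels = NULL) {
    times <- as.numeric(times)
    events <- as.logical(events)
    stopifnot(length(times) == length(events))
    if (any(!is.finite(times)) || any(times < 0))
        stop("times must be finite and non-negative")
    if (is.null(labels)) {
        survival::survfit(survival::Surv(times, events) ~ 1)
    } else {
        stopifnot(length(labels) == length(times))
        grp <- factor(labels)
        survival::survfit(survival::Surv(times, events) ~ grp)
    }
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each distinct
#' event time the observed events in group 1 are compared with their
#' hypergeometric expectation given the risk sets; the squared standardized
#' sum is chi-square with 1 degree of freedom.
#'
#' @param times non-negative event/censoring times (days).
#' @param events logical (or 0/1) event indicators.
#' @param labels group labels taking exactly two values, both non-empty.
#' @return list of class `logrankTest`: `chi_square`, `p_value`, `n`,
#'   `observed` and `expected` per group.
#' @export
logrankTest <- function(times, events, labels) {
    times <- as.numeric(times)
    events <- as.logical(events)
    grp <- factor(labels)
    stopifnot(length(times) == length(events),
              length(labels) == length(times))
    if (any(!is.finite(times)) || any(times < 0))
        stop("times must be finite and non-negative")
    if (nlevels(grp) != 2L || any(table(grp) == 0L))
        stop("exactly two non-empty groups are required")
    if (!any(events))
        stop("log-rank statistic undefined without any event")
    sd_ <- survival::survdiff(survival::Surv(times, events) ~ grp)
    structure(list(chi_square = unname(sd_$chisq),
                   p_value = stats::pchisq(sd_$chisq, df = 1,
                                           lower.tail = FALSE),
                   n = stats::setNames(as.integer(sd_$n), levels(grp)),
                   observed = stats::setNames(sd_$obs, levels(grp)),
                   expected = stats::setNames(sd_$exp, levels(grp))),
              class = "logrankTest")
}

#' @export
print.logrankTest <- function(x, ...) {
    cat(sprintf("Log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
                x$chi_square, x$p_value))
    tab <- rbind(n = x$n, observed = x$observed, expected = x$expected)
    print(tab)
    invisible(x)
}
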