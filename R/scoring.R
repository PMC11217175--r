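## Single-sample gene-set scoring and score comparisons. The score is the
## rank-weighted single-sample enrichment statistic that underlies
## signature-based cell-type scoring: per sample, genes are ranked by
## decreasing expression (ties broken by gene id), the in-set cumulative
## fraction weights the gene at rank i by (N - i + 1)^alpha normalized over
## in-set weights, the out-set cumulative fraction steps by 1/(N - |S|), and
## the score is the sum over all ranks of their difference. It is a pure
## rank statistic: invariant to strictly monotone transforms of a sample.

.resolveSets <- function(sets) {
    if (is(sets, "GeneSetCollection")) geneSets(sets)
    else if (is.list(sets) && !is.null(names(sets))) sets
    else stop("'sets' must be a GeneSetCollection or a named list")
}

.exprMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
    else if (is.matrix(x)) x
    else stop("expected a matrix or SummarizedExperiment")
}

#' Single-sample gene-set enrichment scores
#'
#' @param x numeric expression matrix (genes x samples, unique gene
#'   rownames) or [ResistanceExperiment].
#' @param sets a [GeneSetCollection] or named list of gene id vectors. Each
#'   set is intersected with the matrix genes and must remain a non-empty
#'   proper subset of them.
#' @param alpha rank-weight exponent (default 0.25; `alpha = 0` weights all
#'   ranks equally).
#' @param normalize divide the whole score matrix by its range
#'   (`max - min`).
#'
#' @return numeric matrix of scores, sets in rows, samples in columns.
#' @examples
#' x <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
#' ssgseaScore(x, list(top = "A"))  # 1.5
#' @export
ssgseaScore <- function(x, sets, alpha = 0.25, normalize = FALSE) {
    x <- .exprMatrix(x)
    sets <- .resolveSets(sets)
    if (alpha < 0) stop("alpha must be non-negative")
    genes <- rownames(x)
    if (is.null(genes) || anyDuplicated(genes))
        stop("expression matrix needs unique gene rownames")
    n <- nrow(x)
    member <- lapply(names(sets), function(nm) {
        m <- genes %in% sets[[nm]]
        k <- sum(m)
        if (k == 0L)
            stop(sprintf("gene set '%s' has no overlap with the expression genes", nm))
        if (k == n)
            stop(sprintf("gene set '%s' covers the whole gene universe (empty out-set)", nm))
        m
    })
    names(member) <- names(sets)
    rankWeight <- (n:1)^alpha
    scores <- matrix(NA_real_, length(sets), ncol(x),
                     dimnames = list(names(sets), colnames(x)))
    for (j in seq_len(ncol(x))) {
        ord <- order(-x[, j], genes)
        for (i in seq_along(member)) {
            ind <- member[[i]][ord]
            wIn <- rankWeight * ind
            inCum <- cumsum(wIn) / sum(wIn)
            outCum <- cumsum(!ind) / (n - sum(ind))
            scores[i, j] <- sum(inCum - outCum)
        }
    }
    if (normalize) {
        rng <- max(scores) - min(scores)
        if (rng > 0) scores <- scores / rng
    }
    scores
}

#' Composite immune, stromal and microenvironment scores
#'
#' Summarizes an enrichment-score matrix into per-sample composites:
#' `immune` is the mean of the named immune signature scores, `stromal` the
#' mean of the stromal signature scores, and `microenvironment` their sum.
#'
#' @param scores enrichment matrix from [ssgseaScore()] (sets x samples).
#' @param immuneSets,stromalSets non-empty character vectors of set names
#'   present in `scores`.
#' @return data.frame with `sample_id`, `immune`, `stromal`,
#'   `microenvironment`.
#' @export
compositeScores <- function(scores, immuneSets, stromalSets) {
    if (!length(immuneSets) || !length(stromalSets))
        stop("immuneSets and stromalSets must be non-empty")
    missing <- setdiff(c(immuneSets, stromalSets), rownames(scores))
    if (length(missing))
        stop(sprintf("set(s) absent from the score matrix: %s",
                     paste(missing, collapse = ", ")))
    imm <- colMeans(scores[immuneSets, , drop = FALSE])
    str <- colMeans(scores[stromalSets, , drop = FALSE])
    data.frame(sample_id = colnames(scores), immune = unname(imm),
               stromal = unname(str), microenvironment = unname(imm + str),
               stringsAsFactors = FALSE, row.names = NULL)
}

## internal: two-sided rank-sum (unpaired) or signed-rank (paired) test.
## Exact p when the combined sample is small (<= 12) and untied; otherwise
## the continuity-corrected normal approximation with tie-adjusted variance
## (as implemented by stats::wilcox.test).
.rankTest <- function(a, b, paired = FALSE) {
    if (paired) {
        d <- a - b
        if (all(d == 0))
            return(list(statistic = NA_real_, p = 1, flagged = TRUE))
        exact <- length(d) <= 12L && !any(d == 0) && !anyDuplicated(abs(d))
        ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                  exact = exact,
                                                  correct = TRUE))
    } else {
        exact <- (length(a) + length(b)) <= 12L &&
            !anyDuplicated(c(a, b))
        ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                  correct = TRUE))
    }
    list(statistic = unname(ht$statistic), p = ht$p.value, flagged = FALSE)
}

#' Compare enrichment scores between two sample groups
#'
#' For each gene set, compares score distributions between two labelled
#' sample groups with a two-sided Mann-Whitney rank-sum test (unpaired
#' design) or Wilcoxon signed-rank test (paired design, pairing by patient).
#' Exact p-values are used for small untied samples (combined n <= 12),
#' otherwise the tie-adjusted continuity-corrected normal approximation.
#'
#' @param scores enrichment matrix (sets x samples) from [ssgseaScore()].
#' @param se the [ResistanceExperiment] the scores were computed from.
#' @param labels two combined `group_timepoint` labels (see
#'   [sampleLabels()]), e.g. `c("PR_pre", "AR_pre")` or
#'   `c("AR_pre", "AR_post")`; the first label is group A.
#' @param design `"unpaired"` or `"paired"` (paired requires both labels to
#'   cover complete patient pairs).
#'
#' @return data.frame with one row per set: `set_name`, `statistic` (U for
#'   unpaired, V for paired), `p_value`, `median_a`, `median_b`, `direction`
#'   (sign of `median_a - median_b`), `flagged` (paired comparisons whose
#'   differences are all zero get `p = 1` and a flag).
#' @export
compareGroups <- function(scores, se, labels,
                          design = c("unpaired", "paired")) {
    design <- match.arg(design)
    stopifnot(length(labels) == 2L)
    lab <- sampleLabels(se)
    names(lab) <- colnames(se)
    lab <- lab[colnames(scores)]
    selA <- which(lab == labels[1L])
    selB <- which(lab == labels[2L])
    if (!length(selA) || !length(selB))
        stop(sprintf("no samples carry label(s): %s",
                     paste(labels[c(!length(selA), !length(selB))], collapse = ", ")))
    if (design == "paired") {
        patients <- patientIds(se)[match(colnames(scores),
                                         colnames(se))]
        pa <- patients[selA]; pb <- patients[selB]
        if (!setequal(pa, pb) || anyDuplicated(pa) || anyDuplicated(pb))
            stop("paired design requires complete patient pairs across the two labels")
        selB <- selB[match(pa, pb)]
    } else if (length(selA) < 2L || length(selB) < 2L) {
        stop("unpaired design needs at least two samples per group")
    }
    rows <- lapply(rownames(scores), function(s) {
        a <- scores[s, selA]; b <- scores[s, selB]
        rt <- .rankTest(a, b, paired = design == "paired")
        ma <- stats::median(a); mb <- stats::median(b)
        data.frame(set_name = s, statistic = rt$statistic, p_value = rt$p,
                   median_a = ma, median_b = mb,
                   direction = ifelse(ma > mb, "up",
                                      ifelse(ma < mb, "down", "none")),
                   flagged = rt$flagged, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
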