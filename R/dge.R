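## Differential expression for the two designs the cohort supports: a paired
## pre/post contrast (one-sample t on within-patient differences) and a
## two-group contrast at a fixed timepoint (pooled-variance two-sample t).
## moderation = "empirical_bayes" shrinks the per-gene variances toward a
## prior fitted across genes (limma); moderation = "none" is the plain
## textbook t kept as a hand-checkable path.

.rowSds <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (n - 1L))
}

#' Call differentially expressed genes
#'
#' @param se a [ResistanceExperiment] (normalize first; see
#'   [quantileNormalize()]).
#' @param contrast `"paired_pre_post"`: within-patient post minus pre,
#'   one-sample t on the differences; `"group_pre_vs_pre"`: `groupA` minus
#'   `groupB` at the pre timepoint, pooled-variance two-sample t.
#' @param moderation `"empirical_bayes"` (default; limma-style variance
#'   shrinkage) or `"none"`.
#' @param pThreshold significance threshold, applied inclusively (`<=`) to
#'   the BH-adjusted p-value (or to the raw p when `useAdjusted = FALSE`).
#' @param fcThreshold absolute log2 fold-change bound, applied strictly
#'   (`>`).
#' @param useAdjusted compare `pThreshold` against BH-adjusted p-values
#'   (default) or raw p-values.
#' @param subsetGroup optionally restrict a paired contrast to one
#'   resistance group (e.g. `"AR"` for the acquired-resistance pre/post
#'   contrast).
#' @param groupA,groupB group labels for `"group_pre_vs_pre"`; the log2 fold
#'   change is `mean(groupA) - mean(groupB)`.
#'
#' @return data.frame, one row per gene in input order: `gene_id`, `log2fc`,
#'   `t_stat`, `df`, `p_value`, `adj_p`, `is_deg`, `direction`
#'   (`"up"` iff `log2fc > 0`) and `zero_variance` (genes with no residual
#'   variance; under `moderation = "none"` these get `t = NA`, `p = 1` and
#'   are never called).
#' @examples
#' cohort <- simulateCohort(simConfig(nGenes = 100, seed = 1,
#'   deSpec = data.frame(gene = 1:5, delta = 2, contrast = "pre_vs_post")))
#' deg <- diffExpr(quantileNormalize(cohort$experiment))
#' head(deg[deg$is_deg, ])
#' @export
diffExpr <- function(se,
                     contrast = c("paired_pre_post", "group_pre_vs_pre"),
                     moderation = c("empirical_bayes", "none"),
                     pThreshold = 0.05, fcThreshold = 0.3,
                     useAdjusted = TRUE, subsetGroup = NULL,
                     groupA = "PR", groupB = "AR") {
    contrast <- match.arg(contrast)
    moderation <- match.arg(moderation)
    x <- SummarizedExperiment::assay(se)
    meta <- as.data.frame(SummarizedExperiment::colData(se))

    if (contrast == "paired_pre_post") {
        if (!is.null(subsetGroup)) {
            keep <- meta$group %in% subsetGroup
            meta <- meta[keep, , drop = FALSE]
            x <- x[, keep, drop = FALSE]
        }
        pre <- meta$sample_id[meta$timepoint == "pre"]
        post <- meta$sample_id[meta$timepoint == "post"]
        prePat <- meta$patient_id[match(pre, meta$sample_id)]
        postPat <- meta$patient_id[match(post, meta$sample_id)]
        incomplete <- c(setdiff(prePat, postPat), setdiff(postPat, prePat))
        if (length(incomplete))
            stop(sprintf("paired contrast: patient(s) missing a timepoint: %s",
                         paste(sort(incomplete), collapse = ", ")))
        if (length(prePat) < 2L)
            stop("paired contrast needs at least two complete pairs")
        d <- x[, post[order(postPat)], drop = FALSE] -
            x[, pre[order(prePat)], drop = FALSE]
        n <- ncol(d)
        log2fc <- rowMeans(d)
        if (moderation == "none") {
            s <- .rowSds(d)
            zv <- s == 0
            tt <- ifelse(zv, NA_real_, log2fc / (s / sqrt(n)))
            df <- rep(n - 1L, nrow(d))
            p <- ifelse(zv, 1, 2 * stats::pt(-abs(tt), df))
        } else {
            fit <- limma::eBayes(limma::lmFit(d, design = matrix(1, n, 1L)))
            tt <- fit$t[, 1L]
            df <- fit$df.total
            p <- fit$p.value[, 1L]
            log2fc <- fit$coefficients[, 1L]
            zv <- .rowSds(d) == 0
        }
    } else {
        keep <- meta$timepoint == "pre" & meta$group %in% c(groupA, groupB)
        meta <- meta[keep, , drop = FALSE]
        x <- x[, keep, drop = FALSE]
        isA <- meta$group == groupA
        nA <- sum(isA); nB <- sum(!isA)
        if (nA < 2L || nB < 2L)
            stop("two-group contrast needs at least two samples per group")
        xa <- x[, isA, drop = FALSE]
        xb <- x[, !isA, drop = FALSE]
        log2fc <- rowMeans(xa) - rowMeans(xb)
        if (moderation == "none") {
            ssA <- rowSums((xa - rowMeans(xa))^2)
            ssB <- rowSums((xb - rowMeans(xb))^2)
            sp2 <- (ssA + ssB) / (nA + nB - 2L)
            zv <- sp2 == 0
            tt <- ifelse(zv, NA_real_,
                         log2fc / sqrt(sp2 * (1 / nA + 1 / nB)))
            df <- rep(nA + nB - 2L, nrow(x))
            p <- ifelse(zv, 1, 2 * stats::pt(-abs(tt), df))
        } else {
            design <- cbind(intercept = 1, grp = as.numeric(isA))
            fit <- limma::eBayes(limma::lmFit(x, design = design))
            tt <- fit$t[, "grp"]
            df <- fit$df.total
            p <- fit$p.value[, "grp"]
            log2fc <- fit$coefficients[, "grp"]
            ssA <- rowSums((xa - rowMeans(xa))^2)
            ssB <- rowSums((xb - rowMeans(xb))^2)
            zv <- (ssA + ssB) == 0
        }
    }

    adj <- bhAdjust(p)
    crit <- if (useAdjusted) adj else p
    isDeg <- crit <= pThreshold & abs(log2fc) > fcThreshold & !is.na(crit)
    data.frame(
        gene_id = rownames(se),
        log2fc = unname(log2fc),
        t_stat = unname(tt),
        df = unname(df),
        p_value = unname(p),
        adj_p = unname(adj),
        is_deg = unname(isDeg),
        direction = ifelse(log2fc > 0, "up", "down"),
        zero_variance = unname(zv),
        stringsAsFactors = FALSE, row.names = NULL)
}
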