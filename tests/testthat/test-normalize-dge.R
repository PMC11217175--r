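test_that("quantile normalization matches the hand-worked reference", {
    x <- cbind(s1 = c(1, 2, 3), s2 = c(6, 4, 8))
    rownames(x) <- paste0("G", 1:3)
    out <- quantileNormalize(x)
    expect_equal(unname(out[, "s1"]), c(2.5, 4, 5.5))
    expect_equal(unname(out[, "s2"]), c(4, 2.5, 5.5))
})

test_that("quantile normalization fixed points and defining property hold", {
    x <- matrix(rep(c(5, 1, 3), 3), 3, 3,
                dimnames = list(paste0("G", 1:3), paste0("s", 1:3)))
    expect_equal(quantileNormalize(x), x)
    set.seed(1)
    y <- matrix(rnorm(60, 8), 10, 6,
                dimnames = list(paste0("G", 1:10), paste0("s", 1:6)))
    out <- quantileNormalize(y)
    sorted <- apply(out, 2L, sort)
    expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1, 1)],
                 ignore_attr = TRUE)
    ## rank order preserved within columns
    expect_equal(apply(out, 2L, rank), apply(y, 2L, rank))
})

test_that("quantile normalization refuses a single-sample matrix", {
    x <- matrix(1:3, 3, 1, dimnames = list(paste0("G", 1:3), "s1"))
    expect_error(quantileNormalize(x), "two samples")
})

test_that("paired t without moderation matches the textbook computation", {
    ## three patients with post - pre differences 1, 1, 2
    x <- pairedMatrix(c(5, 6, 5, 6, 5, 7), nGenes = 1L)
    se <- makePairedSE(x)
    deg <- diffExpr(se, moderation = "none")
    expect_equal(deg$log2fc, 4 / 3)
    expect_equal(deg$t_stat, 4)
    expect_equal(deg$df, 2)
    expect_equal(deg$p_value, 2 * pt(-4, 2))
})

test_that("the DEG thresholds are inclusive on p and strict on fold change", {
    ## gene 1: diffs 0.25/0.5/0.75 -> log2fc exactly at the bound, small p
    ## -> not a DEG (strict >); gene 2 exceeds the bound -> DEG
    ## (binary-exact values so "exactly at the bound" is exact)
    x <- pairedMatrix(rep(0, 12), nGenes = 2L)
    x[1L, ] <- c(5, 5.4375, 5, 5.5, 5, 5.5625)
    x[2L, ] <- c(5, 5.5, 5, 5.625, 5, 5.75)
    se <- makePairedSE(x)
    deg <- diffExpr(se, moderation = "none", useAdjusted = FALSE,
                    fcThreshold = 0.5)
    expect_identical(deg$log2fc[1L], 0.5)
    expect_true(deg$p_value[1L] <= 0.05)
    expect_false(deg$is_deg[1L])
    expect_true(deg$is_deg[2L])
})

test_that("zero-variance genes are flagged with p = 1, never called", {
    x <- pairedMatrix(rep(c(5, 6), 3), nGenes = 1L)  # all diffs exactly 1
    deg <- diffExpr(makePairedSE(x), moderation = "none")
    expect_true(deg$zero_variance)
    expect_equal(deg$p_value, 1)
    expect_true(is.na(deg$t_stat))
    expect_false(deg$is_deg)
    ## a constant null gene is likewise never a DEG
    x0 <- pairedMatrix(rep(5, 6), nGenes = 1L)
    deg0 <- diffExpr(makePairedSE(x0), moderation = "none")
    expect_equal(deg0$log2fc, 0)
    expect_false(deg0$is_deg)
})

test_that("paired mode errors list patients missing a timepoint", {
    cohort <- simulateCohort(simConfig(nGenes = 10, seed = 1))
    se <- cohort$experiment
    drop <- colnames(se) != "P03_post"
    expect_error(diffExpr(se[, drop]), "P03")
})

test_that("the two-group contrast is oriented groupA minus groupB", {
    cfg <- simConfig(nGenes = 30, seed = 4, deSpec = data.frame(
        gene = 1L, delta = 4, contrast = "PRpre_vs_ARpre"))
    se <- simulateCohort(cfg)$experiment
    deg <- diffExpr(se, contrast = "group_pre_vs_pre",
                    groupA = "PR", groupB = "AR", moderation = "none")
    expect_gt(deg$log2fc[1L], 2)
    degFlip <- diffExpr(se, contrast = "group_pre_vs_pre",
                        groupA = "AR", groupB = "PR", moderation = "none")
    expect_equal(degFlip$log2fc, -deg$log2fc)
    expect_equal(degFlip$p_value, deg$p_value)
})

test_that("consistently permuting samples leaves every record unchanged", {
    cohort <- simulateCohort(simConfig(nGenes = 50, seed = 6))
    se <- cohort$experiment
    set.seed(1)
    perm <- sample(ncol(se))
    for (ctr in c("paired_pre_post", "group_pre_vs_pre"))
        expect_equal(diffExpr(se[, perm], contrast = ctr),
                     diffExpr(se, contrast = ctr))
})

test_that("moderated t converges to the plain t with many pairs", {
    ## heterogeneous per-gene variances (so the fitted prior df is finite
    ## and the shrinkage weight d0 / (d0 + d) vanishes as pairs grow)
    set.seed(7)
    nGenes <- 300L; nPat <- 200L
    sdg <- sqrt(4 / rchisq(nGenes, 4))
    x <- matrix(8, nGenes, 2L * nPat,
                dimnames = list(sprintf("G%03d", seq_len(nGenes)), NULL))
    post <- seq(2L, 2L * nPat, by = 2L)
    x[, post] <- 8 + matrix(rnorm(nGenes * nPat), nGenes) * sdg
    colnames(x) <- paste(rep(sprintf("P%03d", seq_len(nPat)), each = 2L),
                         c("pre", "post"), sep = "_")
    md <- data.frame(sample_id = colnames(x),
                     patient_id = rep(sprintf("P%03d", seq_len(nPat)),
                                      each = 2L),
                     timepoint = rep(c("pre", "post"), nPat),
                     group = "AR")
    se <- ResistanceExperiment(x, md)
    eb <- diffExpr(se, moderation = "empirical_bayes")
    un <- diffExpr(se, moderation = "none")
    rel <- abs(eb$t_stat - un$t_stat) / pmax(abs(un$t_stat), 1e-8)
    expect_lt(stats::median(rel), 0.01)
})

test_that("BH adjustment matches hand examples and defining properties", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.123), 0.123)
    set.seed(2)
    p <- runif(100)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
})
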