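test_that("the default cohort matches the study design", {
    cohort <- simulateCohort(simConfig(nGenes = 40, seed = 3))
    se <- cohort$experiment
    expect_identical(ncol(se), 34L)
    expect_identical(length(unique(patientIds(se))), 17L)
    md <- as.data.frame(SummarizedExperiment::colData(se))
    expect_identical(sum(md$group == "PR" & md$timepoint == "pre"), 5L)
    expect_identical(sum(md$group == "AR" & md$timepoint == "pre"), 12L)
    ## progression outcome is patient-level: identical on a patient's samples
    pd <- tapply(md$progression_days, md$patient_id,
                 function(v) length(unique(v)))
    expect_true(all(pd == 1L))
})

test_that("identical seeds reproduce the cohort bit-for-bit; seeds differ", {
    a <- simulateCohort(simConfig(nGenes = 30, seed = 5))
    b <- simulateCohort(simConfig(nGenes = 30, seed = 5))
    c_ <- simulateCohort(simConfig(nGenes = 30, seed = 6))
    expect_identical(SummarizedExperiment::assay(a$experiment),
                     SummarizedExperiment::assay(b$experiment))
    expect_identical(
        as.data.frame(SummarizedExperiment::colData(a$experiment)),
        as.data.frame(SummarizedExperiment::colData(b$experiment)))
    expect_false(identical(SummarizedExperiment::assay(a$experiment),
                           SummarizedExperiment::assay(c_$experiment)))
})

test_that("planted effects land in the stated contrast arm", {
    cfg <- simConfig(nGenes = 50, seed = 8, deSpec = data.frame(
        gene = c(1L, 2L), delta = c(3, -3),
        contrast = c("pre_vs_post", "PRpre_vs_ARpre")))
    se <- simulateCohort(cfg)$experiment
    x <- SummarizedExperiment::assay(se)
    post <- timepoints(se) == "post"
    expect_gt(mean(x[1L, post]) - mean(x[1L, !post]), 1.5)
    prpre <- sampleLabels(se) == "PR_pre"
    arpre <- sampleLabels(se) == "AR_pre"
    expect_lt(mean(x[2L, prpre]) - mean(x[2L, arpre]), -1.5)
})

test_that("module leaf-hub correlations converge to rho in large cohorts", {
    cfg <- simConfig(nPR = 125L, nAR = 125L, nGenes = 20, seed = 9,
                     moduleSpec = data.frame(hub = 1L, nLeaves = 9L,
                                             rho = 0.9))
    cohort <- simulateCohort(cfg)
    x <- SummarizedExperiment::assay(cohort$experiment)
    hub <- cohort$truth$hubGenes
    leaves <- cohort$truth$modules[[hub]]
    rs <- vapply(leaves, function(l) cor(x[hub, ], x[l, ]), 0)
    expect_true(all(abs(rs - 0.9) < 0.05))
})

test_that("invalid simulator configurations are rejected", {
    expect_error(simConfig(nGenes = 10, moduleSpec = data.frame(
        hub = 8L, nLeaves = 5L, rho = 0.9)), "budget")
    expect_error(simConfig(nGenes = 100, moduleSpec = data.frame(
        hub = c(1L, 5L), nLeaves = 5L, rho = 0.9)), "overlaps")
    expect_error(simConfig(moduleSpec = data.frame(
        hub = 1L, nLeaves = 4L, rho = 0.9)), "nLeaves")
    expect_error(simConfig(moduleSpec = data.frame(
        hub = 1L, nLeaves = 5L, rho = 1)), "rho")
    expect_error(simConfig(nGenes = 100, seed = 1, deSpec = data.frame(
        gene = 5L, delta = 1, contrast = "pre_vs_post"),
        moduleSpec = data.frame(hub = 3L, nLeaves = 5L, rho = 0.5)),
        "overlaps")
})

test_that("recovery report arithmetic follows its definitions", {
    cfg <- simConfig(nGenes = 30, seed = 2, deSpec = data.frame(
        gene = 1:10, delta = 2, contrast = "pre_vs_post"))
    truth <- simulateCohort(cfg)$truth
    genes <- truth$geneUniverse
    deg <- data.frame(gene_id = genes,
                      is_deg = genes %in% genes[c(1:8, 21, 22)])
    r <- truthRecoveryReport(truth, deg = deg)
    expect_equal(r$deSensitivity, 0.8)
    expect_equal(r$deFdp, 0.2)
    ## perfect recovery
    deg$is_deg <- genes %in% genes[1:10]
    r <- truthRecoveryReport(truth, deg = deg)
    expect_equal(r$deSensitivity, 1)
    expect_equal(r$deFdp, 0)
    ## nothing planted, nothing called
    truth0 <- simulateCohort(simConfig(nGenes = 30, seed = 2))$truth
    r0 <- truthRecoveryReport(truth0,
                              deg = data.frame(gene_id = genes,
                                               is_deg = FALSE))
    expect_true(is.na(r0$deSensitivity))
    expect_equal(r0$deFdp, 0)
    ## mismatched universes
    expect_error(truthRecoveryReport(truth,
        deg = data.frame(gene_id = "other", is_deg = FALSE)),
        "universe")
})

test_that("DEG-stage sensitivity is monotone in the planted effect size", {
    deltas <- c(0.5, 1.0, 1.5, 2.0)
    set.seed(20)
    sens <- vapply(deltas, function(d) {
        mean(replicate(50, {
            s <- sample.int(2^30, 1)
            ch <- simulateCohort(simConfig(nGenes = 200, seed = s,
                deSpec = data.frame(gene = 1:20, delta = d,
                                    contrast = "pre_vs_post")))
            deg <- diffExpr(ch$experiment)
            truthRecoveryReport(ch$truth, deg = deg)$deSensitivity
        }))
    }, 0)
    expect_true(all(diff(sens) > -0.02))
    expect_gt(sens[4L], sens[1L])
})

test_that("under the global null the DEG filter makes almost no calls", {
    set.seed(30)
    frac <- replicate(200, {
        s <- sample.int(2^30, 1)
        ch <- simulateCohort(simConfig(nGenes = 1000, seed = s))
        mean(diffExpr(ch$experiment)$is_deg)
    })
    expect_lt(mean(frac), 0.005)
})

test_that("with no survival effect the median-split log-rank is calibrated", {
    set.seed(40)
    rej <- replicate(2000, {
        s <- sample.int(2^30, 1)
        ch <- simulateCohort(simConfig(nGenes = 10, seed = s, survBeta = 0,
            moduleSpec = data.frame(hub = 1L, nLeaves = 5L, rho = 0.5)))
        se <- ch$experiment
        md <- as.data.frame(SummarizedExperiment::colData(se))
        pre <- md[md$timepoint == "pre", ]
        sp <- medianSplit(SummarizedExperiment::assay(se)[
            , pre$sample_id, drop = FALSE], ch$truth$survGene)
        logrankTest(pre$progression_days, pre$progression_event,
                    sp)$p_value < 0.05
    })
    expect_lt(abs(mean(rej) - 0.05), 0.02)
})
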