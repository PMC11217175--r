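## Seeded generator for paired pre/post expression cohorts with planted
## differential expression, planted hub-centered co-expression modules, and
## progression outcomes whose hazard depends on hub expression. Emulates a
## microarray-style study: Gaussian log2 intensities around a baseline of 8,
## a per-gene patient random intercept shared by a patient's two samples,
## and additive log2 effect sizes.

#' Configuration of a synthetic resistance cohort
#'
#' Defaults mirror the study design the package targets: 5 primary-resistance
#' (PR) and 12 acquired-resistance (AR) patients, each with one pre- and one
#' post-treatment sample (34 samples), 2000 genes, unit log2-scale residual
#' noise around a baseline intensity of 8, and a patient random intercept of
#' sd 0.5 shared by a patient's two samples.
#'
#' @param nPR,nAR number of PR / AR patients.
#' @param nGenes total number of genes.
#' @param noiseSd residual standard deviation on the log2 scale.
#' @param patientSd sd of the per-gene patient random intercept.
#' @param deSpec `NULL` or data.frame with columns `gene` (index), `delta`
#'   (log2 effect) and `contrast` (`"pre_vs_post"`: added to every
#'   post-treatment sample; `"PRpre_vs_ARpre"`: added to PR pre-treatment
#'   samples).
#' @param moduleSpec `NULL` or data.frame with columns `hub` (gene index),
#'   `nLeaves` (>= 5) and `rho` (leaf-on-hub loading in (0, 1)). Leaves
#'   occupy the indices immediately following the hub and are generated as
#'   `rho * hub + sqrt(1 - rho^2) * noise`, so each leaf-hub correlation has
#'   expectation `rho` (star topology: the hub is the unique within-module
#'   connector).
#' @param survBeta log-hazard slope per SD of the first planted hub's
#'   standardized pre-treatment expression (0 = outcome independent of
#'   expression).
#' @param baselineHazard baseline progression hazard, events/day.
#' @param censorRate fraction of patients administratively censored.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#'
#' @return a `simConfig` list, validated.
#' @seealso [simulateCohort()]
#' @export
simConfig <- function(nPR = 5L, nAR = 12L, nGenes = 2000L,
                      noiseSd = 1.0, patientSd = 0.5,
                      deSpec = NULL, moduleSpec = NULL,
                      survBeta = 0, baselineHazard = 0.004,
                      censorRate = 0.1, seed = 1L) {
    cfg <- list(nPR = as.integer(nPR), nAR = as.integer(nAR),
                nGenes = as.integer(nGenes), noiseSd = noiseSd,
                patientSd = patientSd, deSpec = deSpec,
                moduleSpec = moduleSpec, survBeta = survBeta,
                baselineHazard = baselineHazard, censorRate = censorRate,
                seed = as.integer(seed))
    if (cfg$nPR < 0L || cfg$nAR < 0L || cfg$nPR + cfg$nAR < 2L)
        stop("at least two patients are required")
    if (cfg$nGenes < 1L) stop("nGenes must be positive")
    if (cfg$noiseSd <= 0 || cfg$patientSd < 0)
        stop("noiseSd must be positive and patientSd non-negative")
    if (cfg$censorRate < 0 || cfg$censorRate >= 1)
        stop("censorRate must lie in [0, 1)")
    if (cfg$baselineHazard <= 0) stop("baselineHazard must be positive")
    deGenes <- integer(0)
    if (!is.null(cfg$deSpec)) {
        ds <- as.data.frame(cfg$deSpec)
        stopifnot(all(c("gene", "delta", "contrast") %in% colnames(ds)))
        if (!all(ds$contrast %in% c("pre_vs_post", "PRpre_vs_ARpre")))
            stop("deSpec contrast must be 'pre_vs_post' or 'PRpre_vs_ARpre'")
        if (any(ds$gene < 1L | ds$gene > cfg$nGenes))
            stop("deSpec gene index outside 1..nGenes")
        if (anyDuplicated(ds$gene))
            stop("deSpec gene indices must be distinct")
        deGenes <- as.integer(ds$gene)
        cfg$deSpec <- ds
    }
    if (!is.null(cfg$moduleSpec)) {
        ms <- as.data.frame(cfg$moduleSpec)
        stopifnot(all(c("hub", "nLeaves", "rho") %in% colnames(ms)))
        if (any(ms$nLeaves < 5L))
            stop("each module needs nLeaves >= 5")
        if (any(ms$rho <= 0 | ms$rho >= 1))
            stop("module rho must lie strictly in (0, 1)")
        used <- deGenes
        for (i in seq_len(nrow(ms))) {
            idx <- ms$hub[i] + 0:ms$nLeaves[i]
            if (max(idx) > cfg$nGenes)
                stop(sprintf("configuration error: module at hub %d exceeds the nGenes budget",
                             ms$hub[i]))
            if (any(idx %in% used))
                stop(sprintf("configuration error: module at hub %d overlaps other planted genes",
                             ms$hub[i]))
            used <- c(used, idx)
        }
        cfg$moduleSpec <- ms
    }
    class(cfg) <- "simConfig"
    cfg
}

#' Simulate a paired pre/post resistance cohort with planted truth
#'
#' Generates log2-scale expression for `2 * (nPR + nAR)` samples: background
#' genes are `8 + b[gene, patient] + e[gene, sample]` with the patient
#' intercept `b ~ N(0, patientSd^2)` shared by the patient's pre and post
#' samples and `e ~ N(0, noiseSd^2)`; planted modules replace leaf rows by
#' `rho`-loadings on their hub; planted differential-expression effects are
#' added to the stated contrast arm. Progression times are exponential with
#' log hazard `log(baselineHazard) + survBeta * z`, where `z` is the
#' standardized pre-treatment expression of the first planted hub (0 when no
#' module is planted); a `censorRate` fraction of patients is administratively
#' censored before their event.
#'
#' @param config a [simConfig()].
#' @return list with elements `experiment` (a [ResistanceExperiment] carrying
#'   expression and metadata including `progression_days`/`progression_event`)
#'   and `truth` (a `PlantedTruth` list with `deGenes`, `hubGenes`, `modules`,
#'   `survGene`, `survBeta`).
#' @examples
#' cohort <- simulateCohort(simConfig(nGenes = 50, seed = 7))
#' dim(cohort$experiment)  # 50 x 34
#' @export
simulateCohort <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    npat <- config$nPR + config$nAR
    patients <- sprintf("P%02d", seq_len(npat))
    groups <- rep(c("PR", "AR"), c(config$nPR, config$nAR))
    meta <- data.frame(
        sample_id = paste(rep(patients, each = 2L),
                          rep(c("pre", "post"), npat), sep = "_"),
        patient_id = rep(patients, each = 2L),
        timepoint = rep(c("pre", "post"), npat),
        group = rep(groups, each = 2L),
        stringsAsFactors = FALSE)
    genes <- sprintf("G%04d", seq_len(config$nGenes))
    nSamp <- nrow(meta)
    patIdx <- match(meta$patient_id, patients)

    b <- matrix(stats::rnorm(config$nGenes * npat, sd = config$patientSd),
                config$nGenes, npat)
    x <- 8 + b[, patIdx, drop = FALSE] +
        matrix(stats::rnorm(config$nGenes * nSamp, sd = config$noiseSd),
               config$nGenes, nSamp)
    dimnames(x) <- list(genes, meta$sample_id)

    modules <- list()
    hubGenes <- character(0)
    sigma <- sqrt(config$patientSd^2 + config$noiseSd^2)
    if (!is.null(config$moduleSpec)) {
        ms <- config$moduleSpec
        for (i in seq_len(nrow(ms))) {
            hub <- ms$hub[i]
            leaves <- hub + seq_len(ms$nLeaves[i])
            rho <- ms$rho[i]
            hubC <- x[hub, ] - 8
            for (l in leaves)
                x[l, ] <- 8 + rho * hubC +
                    sqrt(1 - rho^2) * stats::rnorm(nSamp, sd = sigma)
            modules[[genes[hub]]] <- genes[leaves]
            hubGenes <- c(hubGenes, genes[hub])
        }
    }

    deGenes <- data.frame(gene_id = character(0), delta = numeric(0),
                          contrast = character(0), stringsAsFactors = FALSE)
    if (!is.null(config$deSpec)) {
        ds <- config$deSpec
        for (i in seq_len(nrow(ds))) {
            g <- ds$gene[i]
            arm <- if (ds$contrast[i] == "pre_vs_post") {
                meta$timepoint == "post"
            } else {
                meta$group == "PR" & meta$timepoint == "pre"
            }
            x[g, arm] <- x[g, arm] + ds$delta[i]
        }
        deGenes <- data.frame(gene_id = genes[ds$gene], delta = ds$delta,
                              contrast = ds$contrast, stringsAsFactors = FALSE)
    }

    ## progression outcome, one draw per patient, copied to both samples
    survGene <- if (length(hubGenes)) hubGenes[1L] else NA_character_
    preCols <- meta$sample_id[meta$timepoint == "pre"][order(
        match(meta$patient_id[meta$timepoint == "pre"], patients))]
    z <- rep(0, npat)
    if (!is.na(survGene)) {
        hp <- x[survGene, preCols]
        if (stats::sd(hp) > 0) z <- as.numeric(scale(hp))
    }
    rate <- config$baselineHazard * exp(config$survBeta * z)
    tEvent <- stats::rexp(npat, rate = rate)
    event <- rep(TRUE, npat)
    nCens <- round(config$censorRate * npat)
    if (nCens > 0L) {
        cens <- sample.int(npat, nCens)
        tEvent[cens] <- stats::runif(nCens, 0, tEvent[cens])
        event[cens] <- FALSE
    }
    meta$progression_days <- tEvent[patIdx]
    meta$progression_event <- event[patIdx]

    truth <- structure(
        list(deGenes = deGenes, hubGenes = hubGenes, modules = modules,
             survGene = survGene, survBeta = config$survBeta,
             geneUniverse = genes, config = config),
        class = "PlantedTruth")
    list(experiment = ResistanceExperiment(x, meta), truth = truth)
}

#' @export
print.PlantedTruth <- function(x, ...) {
    cat(sprintf("PlantedTruth: %d DE gene(s), %d hub module(s); survBeta = %g (gene %s)\n",
                nrow(x$deGenes), length(x$hubGenes), x$survBeta,
                ifelse(is.na(x$survGene), "none", x$survGene)))
    invisible(x)
}

#' Score recovery of planted truth by the analysis stages
#'
#' Compares a differential-expression call set and/or a hub report against
#' the ground truth planted by [simulateCohort()].
#'
#' @param truth `PlantedTruth` from [simulateCohort()].
#' @param deg optional [diffExpr()] table (columns `gene_id`, `is_deg`); its
#'   gene universe must contain every planted DE gene.
#' @param hubs optional [findHubs()] report (columns `gene`, `is_hub`).
#' @param contrast optional contrast to restrict the planted DE genes to.
#'
#' @return list with `deSensitivity` (recovered/planted, `NA` when nothing
#'   was planted), `deFdp` (false-discovery proportion among calls, 0 for an
#'   empty call set) and `hubRecovery` (fraction of planted hubs called).
#' @export
truthRecoveryReport <- function(truth, deg = NULL, hubs = NULL,
                                contrast = NULL) {
    stopifnot(inherits(truth, "PlantedTruth"))
    out <- list(deSensitivity = NA_real_, deFdp = NA_real_,
                hubRecovery = NA_real_)
    if (!is.null(deg)) {
        planted <- truth$deGenes
        if (!is.null(contrast))
            planted <- planted[planted$contrast == contrast, , drop = FALSE]
        if (!all(planted$gene_id %in% deg$gene_id))
            stop("mismatched gene universes: planted DE gene(s) absent from the DEG table")
        called <- deg$gene_id[deg$is_deg]
        out$deSensitivity <- if (nrow(planted) == 0L) NA_real_
                             else mean(planted$gene_id %in% called)
        out$deFdp <- if (length(called) == 0L) 0
                     else mean(!(called %in% planted$gene_id))
    }
    if (!is.null(hubs)) {
        calledHubs <- hubs$gene[hubs$is_hub]
        out$hubRecovery <- if (length(truth$hubGenes) == 0L) NA_real_
                           else mean(truth$hubGenes %in% calledHubs)
    }
    out
}
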