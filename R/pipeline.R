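## End-to-end orchestration: validate a flat key-value (YAML) config, run
## every stage in order with START/END logging, write all intermediates as
## headered TSV, and emit a manifest (file names, row counts, config echo).
## All randomness flows from the single pipeline seed through a fixed
## per-stage offset, so identical config + seed reproduce identical files.

.CONFIG_DEFAULTS <- list(
    synthetic = TRUE,
    expression = NULL, metadata = NULL, panel = NULL,
    signatures = NULL, pathways = NULL,
    sim_n_pr = 5L, sim_n_ar = 12L, sim_n_genes = 2000L,
    sim_noise_sd = 1.0, sim_patient_sd = 0.5,
    sim_surv_beta = 1.0, sim_baseline_hazard = 0.004,
    sim_censor_rate = 0.1,
    beta = 6L, min_weight = 0.01, top_frac = 0.30, degree_gt = 4L,
    p_threshold = 0.05, fc_threshold = 0.3, alpha = 0.25,
    moderation = "empirical_bayes", use_adjusted = TRUE,
    immune_sets = NULL, stromal_sets = NULL)

.PATH_KEYS <- c("expression", "metadata", "panel", "signatures", "pathways")

#' Validate a pipeline configuration
#'
#' Reads a flat key-value YAML file (or takes an equivalent named list),
#' rejects unknown keys and out-of-range values, fills defaults (soft power
#' 6, edge floor 0.01, top fraction 0.30, hub degree bound 4, adjusted
#' p <= 0.05, |log2FC| > 0.3, rank-weight exponent 0.25), and enforces that
#' exactly one input mode is configured: either the five real-data paths
#' (`expression`, `metadata`, `panel`, `signatures`, `pathways`, all of
#' which must exist) or synthetic mode (`synthetic: true`, the default when
#' no path is given) with its `sim_*` generator settings.
#'
#' @param config path to a YAML file, a named list, or `NULL` for the fully
#'   defaulted synthetic configuration.
#' @return a validated `PipelineConfig` list.
#' @seealso [runPipeline()]
#' @export
validateConfig <- function(config = NULL) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            stop(sprintf("config file '%s' does not exist", config))
        config <- yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
    if (!is.list(config)) stop("config must be a file path or a named list")
    unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
    if (length(unknown))
        stop(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")))
    cfg <- utils::modifyList(.CONFIG_DEFAULTS, config, keep.null = TRUE)
    paths <- !vapply(cfg[.PATH_KEYS], is.null, TRUE)
    explicitSynthetic <- isTRUE(config$synthetic)
    if (any(paths) && explicitSynthetic)
        stop("config must use either real input paths or synthetic mode, not both")
    cfg$synthetic <- !any(paths)
    if (!cfg$synthetic) {
        missingKeys <- .PATH_KEYS[!paths]
        if (length(missingKeys))
            stop(sprintf("real-data mode needs all input paths; missing: %s",
                         paste(missingKeys, collapse = ", ")))
        for (k in .PATH_KEYS)
            if (!file.exists(cfg[[k]]))
                stop(sprintf("config key '%s': file '%s' does not exist",
                             k, cfg[[k]]))
    }
    .checkRange <- function(key, lo, hi, loOpen = FALSE, hiOpen = FALSE) {
        v <- cfg[[key]]
        bad <- !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
            (if (loOpen) v <= lo else v < lo) ||
            (if (hiOpen) v >= hi else v > hi)
        if (bad)
            stop(sprintf("config key '%s' = %s outside the permitted range %s%g, %g%s",
                         key, format(v), if (loOpen) "(" else "[", lo, hi,
                         if (hiOpen) ")" else "]"))
    }
    .checkRange("top_frac", 0, 1, loOpen = TRUE)
    .checkRange("min_weight", 0, 1, hiOpen = TRUE)
    .checkRange("p_threshold", 0, 1, loOpen = TRUE)
    .checkRange("fc_threshold", 0, Inf, hiOpen = TRUE)
    .checkRange("alpha", 0, Inf, hiOpen = TRUE)
    .checkRange("beta", 1, 50)
    .checkRange("degree_gt", 0, Inf, hiOpen = TRUE)
    .checkRange("sim_censor_rate", 0, 1, hiOpen = TRUE)
    .checkRange("sim_noise_sd", 0, Inf, loOpen = TRUE, hiOpen = TRUE)
    if (!cfg$moderation %in% c("empirical_bayes", "none"))
        stop("config key 'moderation' must be 'empirical_bayes' or 'none'")
    if (cfg$synthetic && cfg$sim_n_genes < 600L)
        stop("synthetic mode needs sim_n_genes >= 600 (room for the planted demo panel)")
    class(cfg) <- "PipelineConfig"
    cfg
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## synthetic-mode demo inputs: planted DE genes for both resistance
## contrasts, two hub-centred modules inside the gene panel, and block
## signatures / pathway sets over background genes.
.syntheticInputs <- function(cfg, seed) {
    deSpec <- data.frame(
        gene = c(101:140, 141:160, 201:230, 231:240),
        delta = c(rep(1.5, 40), rep(-1.5, 20), rep(2.5, 30), rep(-2.5, 10)),
        contrast = c(rep("pre_vs_post", 60), rep("PRpre_vs_ARpre", 40)),
        stringsAsFactors = FALSE)
    moduleSpec <- data.frame(hub = c(301L, 311L), nLeaves = 9L, rho = 0.9)
    sc <- simConfig(nPR = cfg$sim_n_pr, nAR = cfg$sim_n_ar,
                    nGenes = cfg$sim_n_genes, noiseSd = cfg$sim_noise_sd,
                    patientSd = cfg$sim_patient_sd, deSpec = deSpec,
                    moduleSpec = moduleSpec, survBeta = cfg$sim_surv_beta,
                    baselineHazard = cfg$sim_baseline_hazard,
                    censorRate = cfg$sim_censor_rate, seed = seed)
    cohort <- simulateCohort(sc)
    genes <- rownames(cohort$experiment)
    panel <- genes[c(201:240, 301:320, 401:440)]
    sigs <- GeneSetCollection(list(
        Immune_Bcell = genes[501:530],
        Immune_CD4T = genes[531:560],
        Immune_NK = genes[561:590],
        Stromal_Fibroblast = genes[591:595],
        Stromal_Endothelial = genes[c(596:599, 301:310)]),
        description = "synthetic signature")
    paths_ <- GeneSetCollection(stats::setNames(
        lapply(0:4, function(i) genes[101:125 + 25 * i]),
        paste0("Pathway_", 1:5)), description = "synthetic pathway set")
    list(cohort = cohort, panel = panel, signatures = sigs,
         pathways = paths_,
         immuneSets = c("Immune_Bcell", "Immune_CD4T", "Immune_NK"),
         stromalSets = c("Stromal_Fibroblast", "Stromal_Endothelial"))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (synthetic simulation or file
#' loading), quantile normalization, the three differential-expression
#' contrasts (paired pre/post over all patients; PR_pre vs AR_pre;
#' paired pre/post within AR), signature scoring with composite
#' immune/stromal/microenvironment scores and group comparisons,
#' co-expression network construction / two-stage filtering / spanning
#' forest / hub calling for the primary- and acquired-resistance contrasts,
#' hub-vs-cell-score correlation, hub-vs-pathway association, and
#' median-split Kaplan-Meier log-rank progression analysis per hub. Every
#' intermediate is written as a headered TSV and listed, with its row
#' count, in `manifest.yaml` alongside the config echo. Identical config
#' and seed reproduce byte-identical outputs.
#'
#' The network stage uses the panel genes called differentially expressed
#' in the corresponding contrast; when fewer than 10 survive, the full
#' panel is used (logged). When no gene exceeds the hub degree bound, the
#' three genes of highest tree degree are carried downstream as flagged
#' candidates so the association stages still produce output.
#'
#' @param config a `PipelineConfig` from [validateConfig()] (or anything
#'   [validateConfig()] accepts).
#' @param outDir output directory, created if needed.
#' @param seed integer seed feeding every stochastic stage.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = NULL, outDir, seed = 1L) {
    cfg <- if (inherits(config, "PipelineConfig")) config
           else validateConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    note <- function(name, rows)
        files[[length(files) + 1L]] <<- list(file = name, rows = as.integer(rows))
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        message(sprintf("START %s", name))
        res <- tryCatch(force(expr), error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
        message(sprintf("END %s (%.2fs)", name,
                        proc.time()[["elapsed"]] - t0))
        res
    }

    inputs <- stage("input", {
        if (cfg$synthetic) {
            syn <- .syntheticInputs(cfg, seed = as.integer(seed) + 101L)
            writeExpression(SummarizedExperiment::assay(syn$cohort$experiment),
                            file.path(outDir, "expression.tsv"))
            note("expression.tsv", nrow(syn$cohort$experiment))
            md <- as.data.frame(SummarizedExperiment::colData(syn$cohort$experiment))
            writeMetadata(md, file.path(outDir, "metadata.tsv"))
            note("metadata.tsv", nrow(md))
            writeLines(syn$panel, file.path(outDir, "panel.txt"))
            note("panel.txt", length(syn$panel))
            writeGMT(syn$signatures, file.path(outDir, "signatures.gmt"))
            note("signatures.gmt", length(syn$signatures))
            writeGMT(syn$pathways, file.path(outDir, "pathways.gmt"))
            note("pathways.gmt", length(syn$pathways))
            yaml::write_yaml(list(
                de_genes = syn$cohort$truth$deGenes,
                hub_genes = syn$cohort$truth$hubGenes,
                surv_gene = syn$cohort$truth$survGene,
                surv_beta = syn$cohort$truth$survBeta),
                file.path(outDir, "truth.yaml"))
            note("truth.yaml", nrow(syn$cohort$truth$deGenes))
            syn
        } else {
            x <- readExpression(cfg$expression)
            md <- readMetadata(cfg$metadata)
            se <- ResistanceExperiment(x, md)
            list(cohort = list(experiment = se, truth = NULL),
                 panel = readLines(cfg$panel),
                 signatures = readGMT(cfg$signatures),
                 pathways = readGMT(cfg$pathways),
                 immuneSets = cfg$immune_sets,
                 stromalSets = cfg$stromal_sets)
        }
    })
    se <- inputs$cohort$experiment

    se <- stage("normalize", {
        nse <- quantileNormalize(se)
        writeExpression(SummarizedExperiment::assay(nse),
                        file.path(outDir, "expression_normalized.tsv"))
        note("expression_normalized.tsv", nrow(nse))
        nse
    })

    ncfg <- networkConfig(beta = cfg$beta, minWeight = cfg$min_weight,
                          topFrac = cfg$top_frac,
                          hubDegreeGt = cfg$degree_gt)
    degArgs <- list(moderation = cfg$moderation,
                    pThreshold = cfg$p_threshold,
                    fcThreshold = cfg$fc_threshold,
                    useAdjusted = cfg$use_adjusted)
    degs <- stage("dge", {
        out <- list(
            paired_pre_post = do.call(diffExpr, c(list(se,
                contrast = "paired_pre_post"), degArgs)),
            pr_pre_vs_ar_pre = do.call(diffExpr, c(list(se,
                contrast = "group_pre_vs_pre", groupA = "PR",
                groupB = "AR"), degArgs)),
            ar_paired_pre_post = do.call(diffExpr, c(list(se,
                contrast = "paired_pre_post", subsetGroup = "AR"), degArgs)))
        for (nm in names(out)) {
            tab <- out[[nm]][order(out[[nm]]$adj_p, out[[nm]]$gene_id), ]
            .writeTsv(tab, file.path(outDir, sprintf("deg_%s.tsv", nm)))
            note(sprintf("deg_%s.tsv", nm), nrow(tab))
        }
        out
    })

    cellScores <- stage("scores", {
        sc <- ssgseaScore(se, inputs$signatures, alpha = cfg$alpha)
        .writeTsv(data.frame(set_name = rownames(sc), sc,
                             check.names = FALSE),
                  file.path(outDir, "cell_scores.tsv"))
        note("cell_scores.tsv", nrow(sc))
        if (!is.null(inputs$immuneSets) && !is.null(inputs$stromalSets)) {
            comp <- compositeScores(sc, inputs$immuneSets, inputs$stromalSets)
            .writeTsv(comp, file.path(outDir, "composite_scores.tsv"))
            note("composite_scores.tsv", nrow(comp))
        } else message("no immune/stromal set names configured; composite scores skipped")
        cmpU <- compareGroups(sc, se, c("PR_pre", "AR_pre"), "unpaired")
        .writeTsv(cmpU, file.path(outDir, "score_compare_PRpre_vs_ARpre.tsv"))
        note("score_compare_PRpre_vs_ARpre.tsv", nrow(cmpU))
        cmpP <- compareGroups(sc, se, c("AR_post", "AR_pre"), "paired")
        .writeTsv(cmpP, file.path(outDir, "score_compare_ARpost_vs_ARpre.tsv"))
        note("score_compare_ARpost_vs_ARpre.tsv", nrow(cmpP))
        sc
    })

    pathScores <- stage("pathway_scores", {
        ps <- ssgseaScore(se, inputs$pathways, alpha = cfg$alpha)
        .writeTsv(data.frame(set_name = rownames(ps), ps,
                             check.names = FALSE),
                  file.path(outDir, "pathway_scores.tsv"))
        note("pathway_scores.tsv", nrow(ps))
        ps
    })

    hubSets <- list()
    for (ctr in c("pr_pre_vs_ar_pre", "ar_paired_pre_post")) {
        hubSets[[ctr]] <- stage(sprintf("network_%s", ctr), {
            called <- degs[[ctr]]$gene_id[degs[[ctr]]$is_deg]
            genes <- intersect(inputs$panel, called)
            if (length(genes) < 10L) {
                message(sprintf(
                    "only %d DEG(s) intersect the panel; using the full panel",
                    length(genes)))
                genes <- inputs$panel
            }
            graph <- filterNetwork(buildAdjacency(se, genes, ncfg), ncfg)
            .writeTsv(networkEdges(graph),
                      file.path(outDir, sprintf("network_%s.tsv", ctr)))
            note(sprintf("network_%s.tsv", ctr), nrow(networkEdges(graph)))
            forest <- spanningForest(graph)
            .writeTsv(networkEdges(forest),
                      file.path(outDir, sprintf("forest_%s.tsv", ctr)))
            note(sprintf("forest_%s.tsv", ctr), nrow(networkEdges(forest)))
            hubs <- findHubs(forest, ncfg)
            .writeTsv(hubs, file.path(outDir, sprintf("hubs_%s.tsv", ctr)))
            note(sprintf("hubs_%s.tsv", ctr), nrow(hubs))
            cand <- hubs$gene[hubs$is_hub]
            flagged <- FALSE
            if (!length(cand)) {
                cand <- utils::head(hubs$gene, 3L)
                flagged <- TRUE
                message(sprintf(
                    "no gene exceeds tree degree %d; carrying top-degree candidates downstream",
                    ncfg$hubDegreeGt))
            }
            list(candidates = cand, flagged = flagged)
        })
    }

    stage("hub_associations", {
        for (ctr in names(hubSets)) {
            cand <- hubSets[[ctr]]$candidates
            if (!length(cand)) next
            cc <- hubCellCorrelation(se, cand, cellScores)
            cc$candidate_only <- hubSets[[ctr]]$flagged
            .writeTsv(cc, file.path(outDir,
                                    sprintf("hub_cell_correlation_%s.tsv", ctr)))
            note(sprintf("hub_cell_correlation_%s.tsv", ctr), nrow(cc))
            pa <- do.call(rbind, lapply(cand, function(g) {
                out <- rbind(pathwayAssociation(se, g, pathScores, "correlation"),
                             pathwayAssociation(se, g, pathScores, "median_split"))
                cbind(gene = g, out, stringsAsFactors = FALSE)
            }))
            .writeTsv(pa, file.path(outDir,
                                    sprintf("hub_pathway_association_%s.tsv", ctr)))
            note(sprintf("hub_pathway_association_%s.tsv", ctr), nrow(pa))
        }
        NULL
    })

    stage("survival", {
        md <- as.data.frame(SummarizedExperiment::colData(se))
        hasOutcome <- all(c("progression_days", "progression_event") %in%
                          colnames(md))
        if (!hasOutcome)
            message("metadata carries no progression outcome; survival stage skipped")
        pre <- md[md$timepoint == "pre", , drop = FALSE]
        rows <- list()
        curves <- list()
        for (ctr in if (hasOutcome) names(hubSets) else character(0)) {
            for (g in hubSets[[ctr]]$candidates) {
                split <- medianSplit(SummarizedExperiment::assay(se)[
                    , pre$sample_id, drop = FALSE], g)
                res <- tryCatch({
                    lr <- logrankTest(pre$progression_days,
                                      pre$progression_event, split)
                    fit <- kmFit(pre$progression_days,
                                 pre$progression_event, split)
                    sm <- summary(fit)
                    curves[[length(curves) + 1L]] <- data.frame(
                        contrast = ctr, gene = g,
                        group = sub("^grp=", "", as.character(sm$strata)),
                        time = sm$time, n_risk = sm$n.risk,
                        n_event = sm$n.event, surv = sm$surv,
                        stringsAsFactors = FALSE)
                    data.frame(contrast = ctr, gene = g,
                               chi_square = lr$chi_square,
                               p_value = lr$p_value,
                               n_high = sum(split == "high"),
                               n_low = sum(split == "low"),
                               flagged = FALSE, stringsAsFactors = FALSE)
                }, error = function(e) data.frame(
                    contrast = ctr, gene = g, chi_square = NA_real_,
                    p_value = NA_real_, n_high = sum(split == "high"),
                    n_low = sum(split == "low"), flagged = TRUE,
                    stringsAsFactors = FALSE))
                rows[[length(rows) + 1L]] <- res
            }
        }
        if (length(rows)) {
            tab <- do.call(rbind, rows)
            .writeTsv(tab, file.path(outDir, "survival_logrank.tsv"))
            note("survival_logrank.tsv", nrow(tab))
        }
        if (length(curves)) {
            cv <- do.call(rbind, curves)
            .writeTsv(cv, file.path(outDir, "survival_curves.tsv"))
            note("survival_curves.tsv", nrow(cv))
        }
        NULL
    })

    manifest <- list(seed = as.integer(seed),
                     config = unclass(cfg)[order(names(unclass(cfg)))],
                     files = files)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    message("pipeline complete")
    invisible(manifest)
}
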