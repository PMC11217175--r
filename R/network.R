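## Correlation-based co-expression network over a gene panel, the two-stage
## edge filter (absolute weight floor, then per-gene top-fraction retention
## with union semantics), the maximum-weight spanning forest (Kruskal on
## distance 1 - weight with deterministic tie-breaking), and hub calling by
## tree degree. All tie-breaks are lexicographic on node ids so identical
## inputs yield identical networks on any platform.

#' Co-expression network parameters
#'
#' Bundles the network-stage thresholds: the soft-threshold power applied to
#' the correlation, the edge-weight retention floor (strict `>`), the
#' per-gene retained fraction of strongest edges, and the tree-degree bound
#' (strict `>`) above which a gene is called a hub.
#'
#' @param beta positive integer soft-threshold power (default 6).
#' @param signed use the signed adjacency `((1 + r) / 2)^beta` instead of
#'   the unsigned `|r|^beta`.
#' @param minWeight edge retention floor in \[0, 1); edges with weight
#'   strictly greater survive (default 0.01).
#' @param topFrac per-gene retained fraction in (0, 1\]; each gene marks its
#'   strongest `ceiling(topFrac * k)` of `k` incident edges and an edge
#'   survives if either endpoint marks it (default 0.30).
#' @param hubDegreeGt hub threshold: a gene is a hub when its spanning-tree
#'   degree strictly exceeds this (default 4).
#' @return a validated `networkConfig` list.
#' @export
networkConfig <- function(beta = 6L, signed = FALSE, minWeight = 0.01,
                          topFrac = 0.30, hubDegreeGt = 4L) {
    cfg <- list(beta = as.integer(beta), signed = isTRUE(signed),
                minWeight = minWeight, topFrac = topFrac,
                hubDegreeGt = as.integer(hubDegreeGt))
    if (cfg$beta < 1L) stop("beta must be a positive integer")
    if (cfg$minWeight < 0 || cfg$minWeight >= 1)
        stop("minWeight must lie in [0, 1)")
    if (cfg$topFrac <= 0 || cfg$topFrac > 1)
        stop("topFrac must lie in (0, 1]")
    if (cfg$hubDegreeGt < 0L) stop("hubDegreeGt must be non-negative")
    class(cfg) <- "networkConfig"
    cfg
}

#' Build the soft-thresholded correlation adjacency over a gene panel
#'
#' Pairwise Pearson correlations over the samples, raised to the
#' soft-threshold power: unsigned weight `|r|^beta` or signed
#' `((1 + r) / 2)^beta`. Produces the complete weighted graph on the panel
#' (no self-loops).
#'
#' @param x expression matrix (genes x samples) or [ResistanceExperiment].
#' @param panel character vector of panel gene ids, all present in `x`, none
#'   with zero variance.
#' @param config a [networkConfig()].
#' @return a [CoexpressionNetwork].
#' @export
buildAdjacency <- function(x, panel, config = networkConfig()) {
    x <- .exprMatrix(x)
    stopifnot(inherits(config, "networkConfig"))
    missing <- setdiff(panel, rownames(x))
    if (length(missing))
        stop(sprintf("panel gene(s) absent from the expression matrix: %s",
                     paste(missing, collapse = ", ")))
    if (anyDuplicated(panel)) stop("panel contains duplicated gene ids")
    if (ncol(x) < 3L) stop("at least three samples are required")
    sub <- x[panel, , drop = FALSE]
    sds <- .rowSds(sub)
    if (any(sds == 0))
        stop(sprintf("zero-variance panel gene(s): %s",
                     paste(panel[sds == 0], collapse = ", ")))
    r <- stats::cor(t(sub))
    w <- if (config$signed) ((1 + r) / 2)^config$beta else abs(r)^config$beta
    w <- pmin(w, 1)
    ut <- which(upper.tri(w), arr.ind = TRUE)
    edges <- data.frame(from = panel[ut[, 1L]], to = panel[ut[, 2L]],
                        weight = w[ut], stringsAsFactors = FALSE)
    CoexpressionNetwork(panel, edges)
}

#' Apply the two-stage edge filter
#'
#' Stage 1 removes every edge whose weight is not strictly greater than
#' `minWeight`. Stage 2, on the surviving graph, lets every node mark its
#' strongest `ceiling(topFrac * k)` incident edges (ties broken by
#' lexicographic partner id) and keeps an edge if at least one endpoint
#' marked it. Nodes are never removed; genes left without edges stay in the
#' node set as isolated nodes.
#'
#' @param graph a [CoexpressionNetwork].
#' @param config a [networkConfig()].
#' @return the filtered [CoexpressionNetwork].
#' @export
filterNetwork <- function(graph, config = networkConfig()) {
    stopifnot(is(graph, "CoexpressionNetwork"),
              inherits(config, "networkConfig"))
    e <- networkEdges(graph)
    e <- e[e$weight > config$minWeight, , drop = FALSE]
    if (nrow(e)) {
        marked <- rep(FALSE, nrow(e))
        incident <- c(split(seq_len(nrow(e)), e$from),
                      split(seq_len(nrow(e)), e$to))
        ## a node may appear once as 'from' key and once as 'to' key
        for (v in unique(names(incident))) {
            idx <- unlist(incident[names(incident) == v], use.names = FALSE)
            partner <- ifelse(e$from[idx] == v, e$to[idx], e$from[idx])
            ord <- idx[order(-e$weight[idx], partner)]
            k <- ceiling(config$topFrac * length(idx))
            marked[ord[seq_len(k)]] <- TRUE
        }
        e <- e[marked, , drop = FALSE]
    }
    rownames(e) <- NULL
    CoexpressionNetwork(networkNodes(graph), e)
}

#' Spanning forest of maximal co-expression weight
#'
#' Computes, per connected component, the spanning tree minimizing total
#' edge distance `1 - weight` (equivalently maximizing total weight) with
#' Kruskal's algorithm and deterministic tie-breaking by (distance,
#' lexicographic node pair).
#'
#' @param graph a [CoexpressionNetwork].
#' @return a [SpanningForest] (empty input gives an empty forest).
#' @export
spanningForest <- function(graph) {
    stopifnot(is(graph, "CoexpressionNetwork"))
    nodes <- networkNodes(graph)
    e <- networkEdges(graph)
    keep <- logical(nrow(e))
    if (nrow(e)) {
        ord <- order(1 - e$weight, e$from, e$to)
        uf <- .unionFind(nodes)
        for (i in ord)
            keep[i] <- uf$union(e$from[i], e$to[i])
    }
    sel <- e[keep, , drop = FALSE]
    rownames(sel) <- NULL
    deg <- table(factor(c(sel$from, sel$to), levels = nodes))
    new("SpanningForest", nodes = nodes, edges = sel,
        degree = stats::setNames(as.integer(deg), nodes))
}

#' Call hub genes from a spanning forest
#'
#' A gene is a hub when its tree degree strictly exceeds the configured
#' bound (`hubDegreeGt`, default 4).
#'
#' @param forest a [SpanningForest].
#' @param config a [networkConfig()].
#' @return data.frame sorted by decreasing degree then gene id: `gene`,
#'   `degree`, `is_hub`.
#' @export
findHubs <- function(forest, config = networkConfig()) {
    stopifnot(is(forest, "SpanningForest"),
              inherits(config, "networkConfig"))
    deg <- treeDegree(forest)
    out <- data.frame(gene = names(deg), degree = unname(deg),
                      is_hub = unname(deg) > config$hubDegreeGt,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Correlate hub-gene expression with cell-type scores
#'
#' Pearson correlation between each hub gene's expression and each
#' enrichment-score row over the shared samples, with the two-sided p-value
#' from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom; `|r| = 1` is reported with `p = 0`. Zero-variance
#' vectors give a flagged record with missing correlation.
#'
#' @param x expression matrix or [ResistanceExperiment].
#' @param hubs character vector of hub gene ids present in `x`.
#' @param scores enrichment matrix (sets x samples) from [ssgseaScore()].
#' @return data.frame: `gene`, `cell_type`, `r`, `p`, `n`, `flagged`.
#' @export
hubCellCorrelation <- function(x, hubs, scores) {
    x <- .exprMatrix(x)
    missing <- setdiff(hubs, rownames(x))
    if (length(missing))
        stop(sprintf("hub gene(s) absent from the expression matrix: %s",
                     paste(missing, collapse = ", ")))
    shared <- intersect(colnames(x), colnames(scores))
    if (length(shared) < 3L)
        stop("fewer than three shared samples between expression and scores")
    n <- length(shared)
    rows <- list()
    for (g in hubs) {
        gx <- x[g, shared]
        for (s in rownames(scores)) {
            sy <- scores[s, shared]
            if (stats::sd(gx) == 0 || stats::sd(sy) == 0) {
                rows[[length(rows) + 1L]] <-
                    data.frame(gene = g, cell_type = s, r = NA_real_,
                               p = NA_real_, n = n, flagged = TRUE,
                               stringsAsFactors = FALSE)
                next
            }
            r <- stats::cor(gx, sy)
            p <- if (abs(r) >= 1 - 1e-12) 0 else {
                tt <- r * sqrt((n - 2) / (1 - r^2))
                2 * stats::pt(-abs(tt), n - 2)
            }
            rows[[length(rows) + 1L]] <-
                data.frame(gene = g, cell_type = s, r = r, p = p, n = n,
                           flagged = FALSE, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
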