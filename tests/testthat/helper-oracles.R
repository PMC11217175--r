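## Independent brute-force oracles and tiny fixture builders used across the
## suite. These deliberately avoid the code paths they check.

## Benjamini-Hochberg by explicit min over the tail of p * m / rank.
bhBrute <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    adj <- numeric(m)
    for (k in seq_len(m))
        adj[k] <- min(1, min(ps[k:m] * m / (k:m)))
    out <- numeric(m)
    out[ord] <- adj
    out
}

## Exact two-sided Mann-Whitney p by enumeration of all group-A subsets,
## using the same sidedness rule as stats::wilcox.test (double the tail the
## observed U falls in, capped at 1). Untied data only.
mwExactP <- function(a, b) {
    pool <- c(a, b)
    na <- length(a)
    rk <- rank(pool)
    uOf <- function(idx) sum(rk[idx]) - na * (na + 1) / 2
    obs <- uOf(seq_len(na))
    us <- combn(length(pool), na, uOf)
    p <- if (obs > na * length(b) / 2) 2 * mean(us >= obs)
         else 2 * mean(us <= obs)
    min(p, 1)
}

## Minimum spanning-forest total distance by exhaustive enumeration of
## (n - 1)-edge subsets (connected graphs only).
mstBrute <- function(nodes, edges) {
    n <- length(nodes)
    m <- nrow(edges)
    best <- Inf
    for (sel in asplit(combn(m, n - 1L), 2L)) {
        parent <- seq_len(n)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        ok <- TRUE
        for (j in sel) {
            ra <- find(match(edges$from[j], nodes))
            rb <- find(match(edges$to[j], nodes))
            if (ra == rb) { ok <- FALSE; break }
            parent[ra] <- rb
        }
        if (ok) best <- min(best, sum(1 - edges$weight[sel]))
    }
    best
}

## Random connected graph on n nodes: a random spanning tree plus extra
## edges, at most maxEdges edges in total, weights uniform.
randomConnectedGraph <- function(n, maxEdges = 14L) {
    nodes <- sprintf("N%02d", seq_len(n))
    perm <- sample(n)
    from <- to <- character(0)
    for (i in 2:n) {
        j <- sample(i - 1L, 1L)
        from <- c(from, nodes[perm[j]])
        to <- c(to, nodes[perm[i]])
    }
    all <- t(combn(nodes, 2L))
    key <- paste(pmin(from, to), pmax(from, to))
    pool <- which(!(paste(all[, 1L], all[, 2L]) %in% key))
    extra <- sample(pool, min(length(pool), max(0L, maxEdges - (n - 1L))))
    edges <- data.frame(
        from = c(pmin(from, to), all[extra, 1L]),
        to = c(pmax(from, to), all[extra, 2L]),
        stringsAsFactors = FALSE)
    edges$weight <- round(runif(nrow(edges)), 2)
    CoexpressionNetwork(nodes, edges)
}

## Small paired cohort container from an explicit expression matrix; one
## pre and one post sample per patient, all AR unless stated.
makePairedSE <- function(x, groups = NULL, progression = NULL) {
    npat <- ncol(x) / 2L
    pats <- sprintf("P%02d", seq_len(npat))
    if (is.null(groups)) groups <- rep("AR", npat)
    md <- data.frame(
        sample_id = colnames(x),
        patient_id = rep(pats, each = 2L),
        timepoint = rep(c("pre", "post"), npat),
        group = rep(groups, each = 2L),
        stringsAsFactors = FALSE)
    if (!is.null(progression)) {
        md$progression_days <- progression$days[rep(seq_len(npat), each = 2L)]
        md$progression_event <- progression$event[rep(seq_len(npat), each = 2L)]
    }
    ResistanceExperiment(x, md)
}

## Expression matrix whose column names follow the P<i>_pre/post scheme.
pairedMatrix <- function(values, nGenes = 1L, genes = NULL) {
    npat <- length(values) / (2L * nGenes)
    cn <- paste(rep(sprintf("P%02d", seq_len(npat)), each = 2L),
                c("pre", "post"), sep = "_")
    matrix(values, nGenes, 2L * npat,
           dimnames = list(genes %||% sprintf("G%03d", seq_len(nGenes)), cn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
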