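#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

.TIMEPOINTS <- c("pre", "post")
.GROUPS <- c("PR", "AR")
.META_REQUIRED <- c("sample_id", "patient_id", "timepoint", "group")

## internal: validate a sample metadata data.frame against the shared
## invariants (vocabulary, one sample per patient/timepoint, group constant
## within patient). Returns character(0) when clean.
.checkMetadata <- function(meta) {
    msg <- character(0)
    missing <- setdiff(.META_REQUIRED, colnames(meta))
    if (length(missing))
        return(sprintf("metadata lacks required column(s): %s",
                       paste(missing, collapse = ", ")))
    bad <- setdiff(unique(meta$timepoint), .TIMEPOINTS)
    if (length(bad))
        msg <- c(msg, sprintf("unknown timepoint value(s): %s",
                              paste(bad, collapse = ", ")))
    bad <- setdiff(unique(meta$group), .GROUPS)
    if (length(bad))
        msg <- c(msg, sprintf("unknown group value(s): %s",
                              paste(bad, collapse = ", ")))
    if (anyDuplicated(meta$sample_id))
        msg <- c(msg, sprintf("duplicated sample_id: %s",
                              paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                                    collapse = ", ")))
    key <- paste(meta$patient_id, meta$timepoint, sep = "\r")
    if (anyDuplicated(key)) {
        dup <- unique(meta$patient_id[duplicated(key)])
        msg <- c(msg, sprintf("patient(s) with a repeated timepoint: %s",
                              paste(dup, collapse = ", ")))
    }
    ngrp <- tapply(meta$group, meta$patient_id, function(g) length(unique(g)))
    if (any(ngrp > 1))
        msg <- c(msg, sprintf("group is not constant within patient(s): %s",
                              paste(names(ngrp)[ngrp > 1], collapse = ", ")))
    if ("progression_days" %in% colnames(meta)) {
        pd <- meta$progression_days
        if (any(!is.na(pd) & pd < 0))
            msg <- c(msg, "progression_days must be non-negative")
    }
    msg
}

#' Container for a resistance-stratified paired expression cohort
#'
#' `ResistanceExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with validity rules for the
#' paired pre/post, primary-/acquired-resistance design: the column data must
#' carry `sample_id`, `patient_id`, `timepoint` (`"pre"`/`"post"`) and `group`
#' (`"PR"`/`"AR"`); each patient contributes at most one sample per timepoint;
#' the resistance group is constant within a patient; and the (log2-scale)
#' expression assay is finite with unique gene and sample identifiers.
#' Optional outcome columns (`progression_days`, `progression_event`,
#' `survival_days`, `survival_event`) drive the survival stage.
#'
#' @param exprs numeric matrix of log2-scale expression, genes in rows
#'   (unique rownames), samples in columns (unique colnames).
#' @param metadata data.frame of per-sample annotations containing at least
#'   `sample_id`, `patient_id`, `timepoint`, `group`; `sample_id` must match
#'   `colnames(exprs)` one-to-one (order is taken from the matrix).
#'
#' @return A `ResistanceExperiment` object.
#' @examples
#' x <- matrix(rnorm(8, 8), 2, 4,
#'             dimnames = list(c("G1", "G2"),
#'                             c("P1_pre", "P1_post", "P2_pre", "P2_post")))
#' md <- data.frame(sample_id = colnames(x),
#'                  patient_id = rep(c("P1", "P2"), each = 2),
#'                  timepoint = rep(c("pre", "post"), 2),
#'                  group = rep(c("PR", "AR"), each = 2))
#' se <- ResistanceExperiment(x, md)
#' resistanceGroups(se)
#' @export
ResistanceExperiment <- function(exprs, metadata) {
    if (!is.matrix(exprs) || !is.numeric(exprs))
        stop("'exprs' must be a numeric matrix")
    metadata <- as.data.frame(metadata)
    if (is.null(colnames(exprs)) || is.null(rownames(exprs)))
        stop("'exprs' must have gene rownames and sample colnames")
    if (!setequal(metadata$sample_id, colnames(exprs)) ||
        nrow(metadata) != ncol(exprs))
        stop("metadata sample_id set does not match expression columns")
    metadata <- metadata[match(colnames(exprs), metadata$sample_id), ,
                         drop = FALSE]
    se <- SummarizedExperiment(
        assays = list(exprs = exprs),
        colData = DataFrame(metadata, row.names = metadata$sample_id))
    new("ResistanceExperiment", se)
}

#' @rdname ResistanceExperiment
#' @export
setClass("ResistanceExperiment",
         contains = "SummarizedExperiment")

setValidity("ResistanceExperiment", function(object) {
    msg <- character(0)
    if (length(SummarizedExperiment::assays(object)) < 1L)
        return("an expression assay is required")
    x <- assay(object)
    if (anyDuplicated(rownames(x)))
        msg <- c(msg, "duplicated gene identifiers")
    if (anyDuplicated(colnames(x)))
        msg <- c(msg, "duplicated sample identifiers")
    if (any(!is.finite(x)))
        msg <- c(msg, "expression values must all be finite")
    meta <- as.data.frame(colData(object))
    msg <- c(msg, .checkMetadata(meta))
    if (!length(msg)) TRUE else msg
})

#' @describeIn ResistanceExperiment patient identifier per sample.
#' @param x a `ResistanceExperiment`.
#' @export
patientIds <- function(x) as.character(colData(x)$patient_id)

#' @describeIn ResistanceExperiment timepoint (`"pre"`/`"post"`) per sample.
#' @export
timepoints <- function(x) as.character(colData(x)$timepoint)

#' @describeIn ResistanceExperiment resistance group (`"PR"`/`"AR"`) per
#'   sample.
#' @export
resistanceGroups <- function(x) as.character(colData(x)$group)

#' @describeIn ResistanceExperiment combined `group_timepoint` label per
#'   sample (e.g. `"AR_pre"`), the grouping used throughout the pipeline.
#' @export
sampleLabels <- function(x) paste(resistanceGroups(x), timepoints(x), sep = "_")

setMethod("show", "ResistanceExperiment", function(object) {
    cat(sprintf("ResistanceExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    lab <- table(paste(colData(object)$group, colData(object)$timepoint,
                       sep = "_"))
    cat("  samples:", paste(sprintf("%s=%d", names(lab), lab),
                            collapse = ", "), "\n")
})

#' Collection of named gene sets
#'
#' Lightweight container for GMT-style gene-set collections: uniquely named
#' sets of at least one gene each, with a free-text description per set.
#' Gene identifiers are opaque case-sensitive strings.
#'
#' @param sets named list of character vectors (set members).
#' @param description character vector of per-set descriptions, recycled to
#'   the number of sets.
#'
#' @return A `GeneSetCollection` object.
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' names(gsc)
#' gsc[["S2"]]
#' @export
GeneSetCollection <- function(sets, description = rep("", length(sets))) {
    new("GeneSetCollection", sets = sets,
        description = rep_len(as.character(description), length(sets)))
}

#' @rdname GeneSetCollection
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character(0)
    nm <- names(object@sets)
    if (length(object@sets) && (is.null(nm) || any(!nzchar(nm))))
        msg <- c(msg, "every gene set must be named")
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicated set name(s): %s",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (any(lengths(object@sets) < 1L))
        msg <- c(msg, "every gene set needs at least one member")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "gene sets must not contain duplicated members")
    if (length(object@description) != length(object@sets))
        msg <- c(msg, "one description per set is required")
    if (!length(msg)) TRUE else msg
})

#' @describeIn GeneSetCollection the sets as a plain named list.
#' @param x a `GeneSetCollection`.
#' @export
geneSets <- function(x) {
    if (is(x, "GeneSetCollection")) x@sets else as.list(x)
}

#' @describeIn GeneSetCollection per-set descriptions, named by set.
#' @export
setDescriptions <- function(x) stats::setNames(x@description, names(x@sets))

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection of %d set(s)\n", length(object@sets)))
    n <- min(5L, length(object@sets))
    if (n) {
        sz <- lengths(object@sets)[seq_len(n)]
        cat("  ", paste(sprintf("%s (%d)", names(object@sets)[seq_len(n)], sz),
                        collapse = ", "),
            if (length(object@sets) > n) ", ..." else "", "\n", sep = "")
    }
})

#' Weighted co-expression network
#'
#' Undirected weighted graph over a gene panel: nodes are gene identifiers,
#' edges are unordered pairs stored in canonical form (`from` before `to` in
#' lexicographic order) with adjacency weights in \[0, 1\]. Isolated nodes are
#' retained in the node set.
#'
#' @param nodes character vector of unique gene identifiers.
#' @param edges data.frame with columns `from`, `to`, `weight`.
#'
#' @return A `CoexpressionNetwork` object.
#' @seealso [buildAdjacency()], [filterNetwork()], [spanningForest()]
#' @export
CoexpressionNetwork <- function(nodes,
                                edges = data.frame(from = character(0),
                                                   to = character(0),
                                                   weight = numeric(0))) {
    edges <- as.data.frame(edges)
    if (nrow(edges)) {
        swap <- edges$from > edges$to
        tmp <- edges$from[swap]
        edges$from[swap] <- edges$to[swap]
        edges$to[swap] <- tmp
        edges <- edges[order(edges$from, edges$to), , drop = FALSE]
        rownames(edges) <- NULL
    }
    new("CoexpressionNetwork", nodes = as.character(nodes), edges = edges)
}

#' @rdname CoexpressionNetwork
#' @export
setClass("CoexpressionNetwork",
         representation(nodes = "character", edges = "data.frame"))

setValidity("CoexpressionNetwork", function(object) {
    msg <- character(0)
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% colnames(e)))
        return("edges need columns from, to, weight")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicated node identifiers")
    if (nrow(e)) {
        if (any(e$from == e$to))
            msg <- c(msg, "self-loops are not allowed")
        if (any(e$from > e$to))
            msg <- c(msg, "edges must be stored with from < to")
        if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
            msg <- c(msg, "duplicated edges")
        if (any(!(c(e$from, e$to) %in% object@nodes)))
            msg <- c(msg, "edge endpoint outside the node set")
        if (any(e$weight < 0 | e$weight > 1))
            msg <- c(msg, "edge weights must lie in [0, 1]")
    }
    if (!length(msg)) TRUE else msg
})

#' @describeIn CoexpressionNetwork node identifiers.
#' @param x a `CoexpressionNetwork` or `SpanningForest`.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn CoexpressionNetwork edge table (`from`, `to`, `weight`).
#' @export
networkEdges <- function(x) x@edges

setMethod("show", "CoexpressionNetwork", function(object) {
    cat(sprintf("CoexpressionNetwork: %d node(s), %d edge(s)\n",
                length(object@nodes), nrow(object@edges)))
})

#' Spanning forest of a co-expression network
#'
#' Result of [spanningForest()]: for each connected component of the source
#' graph, the spanning tree of minimum total distance (distance = 1 - weight,
#' i.e. the maximum-total-weight tree), plus the tree degree of every node.
#'
#' @slot nodes node identifiers (including isolated nodes, degree 0).
#' @slot edges retained edges with `from`, `to`, `weight`.
#' @slot degree named integer vector of per-node forest degree.
#' @seealso [findHubs()]
#' @export
setClass("SpanningForest",
         representation(nodes = "character", edges = "data.frame",
                        degree = "integer"))

setValidity("SpanningForest", function(object) {
    msg <- character(0)
    e <- object@edges
    deg <- table(factor(c(e$from, e$to), levels = object@nodes))
    if (!identical(as.integer(deg[object@nodes]),
                   unname(object@degree[object@nodes])))
        msg <- c(msg, "degree map inconsistent with edges")
    ## acyclic: every component of the edge set must satisfy |E| = |V| - 1
    if (nrow(e)) {
        comp <- .unionFind(object@nodes)
        for (i in seq_len(nrow(e)))
            if (!comp$union(e$from[i], e$to[i]))
                msg <- c(msg, "forest contains a cycle")
    }
    if (!length(msg)) TRUE else msg
})

#' @describeIn SpanningForest named per-node tree degree.
#' @param x a `SpanningForest`.
#' @export
treeDegree <- function(x) x@degree

setMethod("show", "SpanningForest", function(object) {
    ncomp <- length(object@nodes) - nrow(object@edges)
    cat(sprintf("SpanningForest: %d node(s), %d edge(s), %d component(s)\n",
                length(object@nodes), nrow(object@edges), ncomp))
})

## internal: tiny union-find over string keys; union() returns FALSE when the
## two keys were already connected.
.unionFind <- function(keys) {
    parent <- stats::setNames(seq_along(keys), keys)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    list(
        union = function(a, b) {
            ra <- find(match(a, keys))
            rb <- find(match(b, keys))
            if (ra == rb) return(FALSE)
            parent[ra] <<- rb
            TRUE
        },
        components = function() {
            roots <- vapply(seq_along(keys), find, 0L)
            length(unique(roots))
        })
}
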