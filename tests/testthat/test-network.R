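# three genes over three samples with pairwise correlations +0.5, -0.5, -1
exactCorMatrix <- function() {
    matrix(c(1, 0, -1,
             0, 1, -1,
             0, -1, 1),
           3, 3, byrow = TRUE,
           dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:3)))
}

test_that("adjacency weights follow the soft-threshold power", {
    g <- buildAdjacency(exactCorMatrix(), c("g1", "g2", "g3"))
    e <- networkEdges(g)
    w <- function(a, b) e$weight[e$from == a & e$to == b]
    expect_equal(w("g1", "g2"), 0.5^6)          # r = +0.5
    expect_equal(w("g1", "g3"), 0.5^6)          # r = -0.5, absolute value
    expect_equal(w("g2", "g3"), 1)              # r = -1 -> |r|^beta = 1
    gs <- buildAdjacency(exactCorMatrix(), c("g1", "g2"),
                         networkConfig(signed = TRUE))
    expect_equal(networkEdges(gs)$weight, 0.75^6)
})

test_that("adjacency preconditions are enforced by name", {
    x <- exactCorMatrix()
    expect_error(buildAdjacency(x, c("g1", "gX")), "gX")
    x2 <- rbind(x, flat = c(2, 2, 2))
    expect_error(buildAdjacency(x2, c("g1", "flat")), "flat")
    expect_error(buildAdjacency(x[, 1:2], c("g1", "g2")), "three samples")
})

test_that("stage 1 removes weights at exactly the floor (strict >)", {
    g <- CoexpressionNetwork(c("A", "B", "C"),
        data.frame(from = c("A", "A"), to = c("B", "C"),
                   weight = c(0.01, 0.0100001)))
    f <- filterNetwork(g, networkConfig(topFrac = 1))
    expect_identical(networkEdges(f)$to, "C")
    expect_identical(networkNodes(f), c("A", "B", "C"))  # nodes retained
})

test_that("top-fraction marking uses ceil, lexicographic ties, union", {
    ## complete graph on 4 nodes, equal weights: each node marks 1 edge
    ## (its lexicographically smallest partner) -> star on A
    nodes <- c("A", "B", "C", "D")
    pairs <- t(combn(nodes, 2))
    g <- CoexpressionNetwork(nodes, data.frame(
        from = pairs[, 1], to = pairs[, 2], weight = 0.5))
    f <- filterNetwork(g, networkConfig(topFrac = 0.30))
    e <- networkEdges(f)
    expect_identical(nrow(e), 3L)
    expect_true(all(e$from == "A"))
    ## no-op configuration returns the graph unchanged
    f2 <- filterNetwork(g, networkConfig(topFrac = 1, minWeight = 0))
    expect_equal(networkEdges(f2), networkEdges(g))
})

test_that("thresholding runs before per-gene top-fraction selection", {
    ## sub-floor edges at A must not inflate A's incident count: with the
    ## correct order A keeps only A-C; reversing the stages would also
    ## keep A-B
    g <- CoexpressionNetwork(c("A", "B", "C", "D", "E", "F"), data.frame(
        from = c("A", "A", "A", "A", "B"),
        to = c("C", "B", "D", "E", "F"),
        weight = c(0.5, 0.3, 0.005, 0.005, 0.5)))
    f <- filterNetwork(g, networkConfig(topFrac = 0.30))
    e <- networkEdges(f)
    expect_identical(paste(e$from, e$to), c("A C", "B F"))
})

test_that("filtering returns a subset of the input edges", {
    set.seed(8)
    for (rep in 1:5) {
        g <- randomConnectedGraph(sample(5:8, 1))
        f <- filterNetwork(g, networkConfig(minWeight = 0.2,
                                            topFrac = 0.4))
        keyIn <- paste(networkEdges(g)$from, networkEdges(g)$to)
        keyOut <- paste(networkEdges(f)$from, networkEdges(f)$to)
        expect_true(all(keyOut %in% keyIn))
    }
})

test_that("the spanning forest solves the tiny triangle by enumeration", {
    g <- CoexpressionNetwork(c("A", "B", "C"), data.frame(
        from = c("A", "B", "A"), to = c("B", "C", "C"),
        weight = 1 - c(0.1, 0.2, 0.3)))
    f <- spanningForest(g)
    e <- networkEdges(f)
    expect_identical(paste(e$from, e$to), c("A B", "B C"))
    expect_equal(sum(1 - e$weight), 0.3)
})

test_that("forest structure: n - 1 edges when connected, components kept", {
    set.seed(9)
    g <- randomConnectedGraph(7)
    f <- spanningForest(g)
    expect_identical(nrow(networkEdges(f)), 6L)
    g2 <- CoexpressionNetwork(c("A", "B", "C", "D"), data.frame(
        from = c("A", "C"), to = c("B", "D"), weight = c(0.9, 0.8)))
    f2 <- spanningForest(g2)
    expect_identical(nrow(networkEdges(f2)), 2L)
    f0 <- spanningForest(CoexpressionNetwork(character(0)))
    expect_identical(nrow(networkEdges(f0)), 0L)
})

test_that("forest total weight agrees with igraph's MST", {
    skip_if_not_installed("igraph")
    set.seed(10)
    for (rep in 1:20) {
        g <- randomConnectedGraph(sample(5:9, 1), maxEdges = 20L)
        e <- networkEdges(g)
        f <- spanningForest(g)
        ig <- igraph::graph_from_data_frame(e, directed = FALSE)
        mst <- igraph::mst(ig, weights = 1 - e$weight)
        expect_equal(sum(1 - networkEdges(f)$weight),
                     sum(1 - igraph::edge_attr(mst, "weight")))
    }
})

test_that("hub calling is strict in the degree threshold", {
    star <- CoexpressionNetwork(c("H", paste0("L", 1:6)), data.frame(
        from = "H", to = paste0("L", 1:6), weight = 0.9))
    h <- findHubs(spanningForest(star))
    expect_identical(h$gene[h$is_hub], "H")
    expect_identical(h$degree[1L], 6L)
    star4 <- CoexpressionNetwork(c("H", paste0("L", 1:4)), data.frame(
        from = "H", to = paste0("L", 1:4), weight = 0.9))
    h4 <- findHubs(spanningForest(star4))
    expect_false(any(h4$is_hub))   # degree exactly 4 is not a hub
    path <- CoexpressionNetwork(paste0("N", 1:6), data.frame(
        from = paste0("N", 1:5), to = paste0("N", 2:6), weight = 0.9))
    expect_false(any(findHubs(spanningForest(path))$is_hub))
})

test_that("end-to-end network construction is deterministic", {
    ch <- simulateCohort(simConfig(nGenes = 60, seed = 11,
        moduleSpec = data.frame(hub = 1L, nLeaves = 9L, rho = 0.9)))
    panel <- rownames(ch$experiment)[1:50]
    run <- function() {
        f <- spanningForest(filterNetwork(
            buildAdjacency(ch$experiment, panel)))
        findHubs(f)
    }
    expect_identical(run(), run())
})

test_that("hub/cell-score correlations match the hand Pearson formula", {
    x <- matrix(c(1, 2, 3, 4), 1, 4,
                dimnames = list("hub", paste0("s", 1:4)))
    e <- rbind(ct = c(1, 2, 3, 5))
    colnames(e) <- paste0("s", 1:4)
    out <- hubCellCorrelation(x, "hub", e)
    expect_equal(out$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
    ## self-correlation r = 1, p = 0
    self <- hubCellCorrelation(x, "hub", rbind(hubscore = x[1, ]))
    expect_equal(self$r, 1)
    expect_equal(self$p, 0)
})

test_that("correlation edge cases: r = 0 gives p = 1; degenerate input", {
    x <- matrix(c(1, 2, 3, 4, 5), 1, 5,
                dimnames = list("hub", paste0("s", 1:5)))
    e0 <- rbind(ct = c(1, -2, 0, 2, -1))   # orthogonal to centered x
    colnames(e0) <- paste0("s", 1:5)
    out <- hubCellCorrelation(x, "hub", e0)
    expect_equal(out$r, 0)
    expect_equal(out$p, 1)
    eFlat <- rbind(ct = rep(2, 5))
    colnames(eFlat) <- paste0("s", 1:5)
    flat <- hubCellCorrelation(x, "hub", eFlat)
    expect_true(flat$flagged)
    expect_true(is.na(flat$r))
    expect_error(hubCellCorrelation(x[, 1:2, drop = FALSE], "hub",
                                    e0[, 1:2, drop = FALSE]), "three")
})
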