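test_that("pairwise association computes Gaussian MI from correlations", {
    set.seed(1)
    n <- 500
    x <- rnorm(n)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)   # rho ~ 0.8
    z <- rnorm(n)                              # rho ~ 0
    m <- rbind(gx = x, gy = y, gz = z)
    colnames(m) <- sprintf("s%03d", seq_len(n))
    a <- pairwiseAssociation(m)
    expect_equal(a$mi["gx", "gy"],
                 -0.5 * log(1 - a$rho["gx", "gy"]^2))
    expect_equal(a$mi["gx", "gy"], 0.5108, tolerance = 0.15)  # closed form at rho=0.8
    expect_lt(a$mi["gx", "gz"], 0.01)
    # MI invariant to affine rescaling
    m2 <- m; m2["gy", ] <- 3 - 5 * m2["gy", ]
    a2 <- pairwiseAssociation(m2)
    expect_equal(abs(a2$mi["gx", "gy"]), abs(a$mi["gx", "gy"]))
    # perfect correlation clamps instead of overflowing
    m3 <- rbind(g1 = x, g2 = 2 * x + 1)
    colnames(m3) <- colnames(m)
    expect_true(is.finite(pairwiseAssociation(m3)$mi["g1", "g2"]))
    # zero-variance gene is a named error
    m4 <- rbind(m, flat = rep(1, n))
    expect_error(pairwiseAssociation(m4), "flat")
})

test_that("likelihood spanning tree matches brute force on 4 genes", {
    genes <- c("a", "b", "c", "d")
    set.seed(7)
    for (rep in 1:50) {
        L <- matrix(rnorm(16), 4)
        sigma <- crossprod(L) + diag(4) * 0.1
        m <- t(MASS::mvrnorm(60, rep(0, 4), sigma))
        rownames(m) <- genes; colnames(m) <- sprintf("s%02d", 1:60)
        a <- pairwiseAssociation(m)
        tree <- likelihoodSpanningTree(a)
        expect_identical(nrow(graphEdges(tree)), 3L)
        best <- max(vapply(allSpanningTrees4(genes), treeWeight,
                           numeric(1), mi = a$mi))
        expect_equal(treeWeight(graphEdges(tree), a$mi), best,
                     tolerance = 1e-12)
    }
})

test_that("two genes yield the single edge; p < 2 errors", {
    m <- toyMatrix(2, 10, seed = 2)
    tree <- likelihoodSpanningTree(pairwiseAssociation(m))
    expect_identical(nrow(graphEdges(tree)), 1L)
    expect_setequal(as.vector(graphEdges(tree)), rownames(m))
    m1 <- toyMatrix(1, 10, seed = 2)
    a1 <- list(genes = rownames(m1), mi = matrix(NA, 1, 1),
               rho = matrix(1, 1, 1), n = 10)
    class(a1) <- "AssociationMatrix"
    expect_error(likelihoodSpanningTree(a1), ">= 2 genes")
})

test_that("chordality test agrees with trivial cases", {
    # any tree is chordal
    m <- toyMatrix(8, 25, seed = 4)
    tree <- likelihoodSpanningTree(pairwiseAssociation(m))
    expect_true(isDecomposable(tree))
    # chordless 4-cycle is not
    sq <- list(genes = c("a", "b", "c", "d"),
               edges = rbind(c("a", "b"), c("b", "c"),
                             c("c", "d"), c("d", "a")))
    expect_false(isDecomposable(sq))
    # adding a chord fixes it
    sq$edges <- rbind(sq$edges, c("a", "c"))
    expect_true(isDecomposable(sq))
})

test_that("forward search adds no edge when genes are independent", {
    set.seed(21)
    m <- matrix(rnorm(12 * 80), 12, 80,
                dimnames = list(sprintf("g%02d", 1:12),
                                sprintf("s%02d", 1:80)))
    tree <- likelihoodSpanningTree(pairwiseAssociation(m))
    out <- forwardEdgeSearch(tree, m, candidates = "exhaustive")
    expect_identical(nrow(graphEdges(out)), nrow(graphEdges(tree)))
})

test_that("forward search output is chordal with strictly decreasing BIC
           and local deltas equal to global BIC differences", {
    set.seed(11)
    for (rep in 1:5) {
        L <- matrix(rnorm(25), 5)
        sigma <- crossprod(L) + diag(5) * 0.05
        m <- t(MASS::mvrnorm(80, rep(0, 5), sigma))
        rownames(m) <- sprintf("g%d", 1:5)
        colnames(m) <- sprintf("s%02d", 1:80)
        tree <- likelihoodSpanningTree(pairwiseAssociation(m))
        out <- forwardEdgeSearch(tree, m, candidates = "exhaustive")
        expect_true(isDecomposable(out))
        trace <- attr(out, "bicTrace")
        if (length(trace) > 1) expect_true(all(diff(trace) < 0))
        expect_lte(bicValue(out), bicValue(tree))
        # the trace's final entry equals the independent global recompute
        expect_equal(trace[length(trace)], graphBIC(out, m),
                     tolerance = 1e-8)
        # never removes tree edges
        treeKeys <- paste(pmin(graphEdges(tree)[, 1], graphEdges(tree)[, 2]),
                          pmax(graphEdges(tree)[, 1], graphEdges(tree)[, 2]))
        outKeys <- paste(pmin(graphEdges(out)[, 1], graphEdges(out)[, 2]),
                         pmax(graphEdges(out)[, 1], graphEdges(out)[, 2]))
        expect_true(all(treeKeys %in% outKeys))
    }
})

test_that("junction-tree bookkeeping stays consistent with the graph", {
    set.seed(31)
    m <- toyMatrix(10, 60, seed = 31)
    g <- forwardEdgeSearch(likelihoodSpanningTree(pairwiseAssociation(m)),
                           m, candidates = "exhaustive", maxEdges = 8)
    cl <- graphCliques(g)
    expect_setequal(unique(unlist(cl)), geneIds(g))
    # every separator is an intersection of two cliques
    for (s in graphSeparators(g))
        expect_true(any(vapply(seq_along(cl), function(i)
            all(s %in% cl[[i]]), logical(1))))
    # |cliques| - |separators| = number of connected components (here 1)
    expect_identical(length(cl) - length(graphSeparators(g)), 1L)
})

test_that("branch splitting cuts a 10-path into two 5-branches", {
    genes <- sprintf("g%02d", 1:10)
    edges <- cbind(genes[-10], genes[-1])
    g <- layerscope:::newDecomposableGraph(genes, edges)
    nodes <- splitIntoBranches(g, targetCount = 2, minSize = 2, maxSize = 5)
    expect_identical(length(nodes), 2L)
    sizes <- sort(vapply(nodes, function(n) length(n$genes), integer(1)))
    expect_identical(unname(sizes), c(5L, 5L))
    # partition property
    expect_setequal(unlist(lapply(nodes, `[[`, "genes")), genes)

    # graph already in target components: identity partition
    e2 <- rbind(c("a", "b"), c("c", "d"))
    g2 <- layerscope:::newDecomposableGraph(c("a", "b", "c", "d"), e2)
    nodes2 <- splitIntoBranches(g2, targetCount = 2, minSize = 2, maxSize = 4)
    expect_identical(length(nodes2), 2L)
    expect_error(splitIntoBranches(g2, targetCount = 9), "exceeds")
})

test_that("node activities are gene-order invariant means", {
    m <- rbind(g1 = c(1, 5), g2 = c(3, 7), g3 = c(10, 20))
    colnames(m) <- c("s1", "s2")
    nd <- functionalNode("pair", c("g1", "g2"))
    act <- nodeActivity(m, nd)
    expect_equal(unname(act["pair", ]), c(2, 6))
    # single-gene node equals the gene's row
    expect_equal(unname(nodeActivity(m, functionalNode("solo", "g3"))[1, ]),
                 unname(m["g3", ]))
    # gene order irrelevant
    act2 <- nodeActivity(m, functionalNode("pair", c("g2", "g1")))
    expect_equal(act, act2, ignore_attr = TRUE)
    # main-function subset mode
    nd3 <- functionalNode("sub", c("g1", "g2", "g3"), mainGenes = c("g1"))
    expect_equal(unname(nodeActivity(m, nd3, useMainSubset = TRUE)[1, ]),
                 unname(m["g1", ]))
    expect_error(nodeActivity(m, functionalNode("bad", "g9")), "absent")
})
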