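# Shared fixture builders; everything is generated in code at test time.

# Small deterministic expression matrix with named dims.
toyMatrix <- function(p = 6, n = 4, seed = 1) {
    set.seed(seed)
    matrix(rnorm(p * n, 7, 1), p, n,
           dimnames = list(sprintf("g%02d", seq_len(p)),
                           sprintf("s%02d", seq_len(n))))
}

toyCohort <- function(p = 6, n = 4, seed = 1, batch = "b1") {
    CohortExperiment(toyMatrix(p, n, seed), batch = batch)
}

# Planted 2-cluster matrix: `pInf` informative genes shifted by `delta` in
# the second half of the samples, rest pure noise.
plantedTwoCluster <- function(pInf = 20, pNoise = 180, n = 60, delta = 2,
                              seed = 1) {
    set.seed(seed)
    grp <- rep(1:2, each = n / 2)
    m <- matrix(rnorm((pInf + pNoise) * n), pInf + pNoise, n)
    m[seq_len(pInf), grp == 2] <- m[seq_len(pInf), grp == 2] + delta
    dimnames(m) <- list(sprintf("g%03d", seq_len(pInf + pNoise)),
                        sprintf("s%03d", seq_len(n)))
    list(m = m, grp = grp, informative = rownames(m)[seq_len(pInf)])
}

# Random labeled graph on `p` vertices with edge probability `prob`,
# as genes/edges lists compatible with isDecomposable().
randomGraph <- function(p, prob) {
    genes <- sprintf("v%02d", seq_len(p))
    pairs <- t(utils::combn(genes, 2))
    keep <- stats::runif(nrow(pairs)) < prob
    list(genes = genes,
         edges = matrix(pairs[keep, ], ncol = 2))
}

# Brute-force chordality: no induced cycle of length >= 4 (feasible for
# p <= 6). A vertex subset induces a chordless cycle iff the induced
# subgraph is connected and 2-regular.
bruteChordal <- function(g) {
    adj <- matrix(FALSE, length(g$genes), length(g$genes),
                  dimnames = list(g$genes, g$genes))
    if (nrow(g$edges))
        for (r in seq_len(nrow(g$edges))) {
            adj[g$edges[r, 1], g$edges[r, 2]] <- TRUE
            adj[g$edges[r, 2], g$edges[r, 1]] <- TRUE
        }
    p <- length(g$genes)
    for (k in 4:p) {
        if (k > p) break
        subsets <- utils::combn(p, k)
        for (col in seq_len(ncol(subsets))) {
            sub <- adj[subsets[, col], subsets[, col]]
            deg <- rowSums(sub)
            if (all(deg == 2) && isConnected(sub)) return(FALSE)
        }
    }
    TRUE
}

isConnected <- function(adj) {
    n <- nrow(adj)
    seen <- logical(n); seen[1] <- TRUE
    repeat {
        new <- (adj %*% seen > 0) & !seen
        if (!any(new)) break
        seen <- seen | new
    }
    all(seen)
}

# All 16 labeled spanning trees on 4 vertices via Pruefer decoding.
pruferDecode <- function(pr, n) {
    degree <- rep(1L, n)
    for (x in pr) degree[x] <- degree[x] + 1L
    edges <- matrix(integer(), ncol = 2)
    for (x in pr) {
        leaf <- min(which(degree == 1L))
        edges <- rbind(edges, c(leaf, x))
        degree[leaf] <- degree[leaf] - 1L
        degree[x] <- degree[x] - 1L
    }
    rbind(edges, which(degree == 1L))
}

allSpanningTrees4 <- function(genes) {
    stopifnot(length(genes) == 4)
    out <- list()
    for (a in 1:4) for (b in 1:4) {
        e <- pruferDecode(c(a, b), 4L)
        out[[length(out) + 1L]] <-
            matrix(genes[e], ncol = 2)
    }
    out
}

# Sum of MI weights over a tree's edges.
treeWeight <- function(edges, mi) {
    sum(vapply(seq_len(nrow(edges)), function(r)
        mi[edges[r, 1], edges[r, 2]], numeric(1)))
}

# Independent oracle for the tiny exhaustive instance: recompute d, the
# enumerated permutation null, and the Delta/FDR machinery from scratch
# with plain loops (two-class, fixed s0).
oracleSam <- function(m, labels, s0, fdrTarget = 0.05) {
    lv <- sort(unique(labels))
    dOf <- function(lab) {
        g1 <- m[, lab == lv[1], drop = FALSE]
        g2 <- m[, lab == lv[2], drop = FALSE]
        n1 <- ncol(g1); n2 <- ncol(g2)
        num <- rowMeans(g2) - rowMeans(g1)
        ss <- rowSums((g1 - rowMeans(g1))^2) + rowSums((g2 - rowMeans(g2))^2)
        se <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
        num / (se + s0)
    }
    d <- dOf(labels)
    n1 <- sum(labels == lv[1])
    sets <- utils::combn(length(labels), n1)
    perm <- matrix(NA_real_, nrow(m), ncol(sets))
    for (j in seq_len(ncol(sets))) {
        lab <- rep(lv[2], length(labels))
        lab[sets[, j]] <- lv[1]
        perm[, j] <- sort(dOf(lab))
    }
    dExp <- rowMeans(perm)
    dSort <- sort(d)
    diffs <- dSort - dExp
    B <- ncol(perm)
    gateP <- (1 + sum(apply(abs(perm - dExp), 2, max) >= max(abs(diffs)))) /
        (B + 1)
    best <- NULL
    if (gateP <= fdrTarget / 2) {
        for (delta in sort(unique(round(abs(diffs), 12)))) {
            up <- which(diffs >= delta & dSort >= 0)
            lo <- which(diffs <= -delta & dSort <= 0)
            cutUp <- if (length(up)) dSort[min(up)] else Inf
            cutLo <- if (length(lo)) dSort[max(lo)] else -Inf
            called <- sum(d >= cutUp | d <= cutLo)
            false <- colSums(perm >= cutUp) + colSums(perm <= cutLo)
            fdr <- if (called) min(mean(false) / called, 1) else 0
            if (fdr <= fdrTarget) {
                best <- list(delta = delta, cutUp = cutUp, cutLo = cutLo,
                             fdr = fdr,
                             sig = rownames(m)[d >= cutUp | d <= cutLo])
                break
            }
        }
    }
    if (is.null(best))
        best <- list(delta = Inf, cutUp = Inf, cutLo = -Inf, fdr = 0,
                     sig = character(0))
    c(best, list(d = d, dExp = dExp, nPerms = B))
}

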