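#' Pairwise Pearson correlation and Gaussian mutual information
#'
#' For jointly Gaussian variables the mutual information is a monotone
#' function of the correlation, \eqn{MI = -\frac{1}{2}\ln(1-\rho^2)} (nats),
#' which makes the maximum-likelihood spanning tree a maximum-weight
#' spanning tree under MI weights (Chow-Liu). Perfect correlations are
#' clamped so that MI is capped at `-0.5 * log(1e-12)` (~13.8 nats).
#'
#' @param x [CohortExperiment-class] or genes x samples matrix with >=3
#'   samples and no zero-variance gene.
#' @return an `AssociationMatrix` list: `rho`, `mi` (gene x gene matrices,
#'   `NA` diagonal for `mi`), `genes`, `n`.
#' @export
pairwiseAssociation <- function(x) {
    m <- asExprMatrix(x)
    if (ncol(m) < 3L) stop("need >= 3 samples")
    sds <- rowSds(m)
    if (any(sds == 0))
        stop("zero-variance gene(s): ",
             paste(rownames(m)[sds == 0], collapse = ", "))
    rho <- stats::cor(t(m))
    rho2 <- pmin(rho^2, 1 - 1e-12)
    mi <- -0.5 * log1p(-rho2)
    diag(mi) <- NA_real_
    structure(list(rho = rho, mi = mi, genes = rownames(m), n = ncol(m)),
              class = "AssociationMatrix")
}

# Kruskal maximum-weight spanning tree with a deterministic tie-break:
# edges sorted by decreasing weight, then lexicographically by endpoint
# names. Returns a 2-column character matrix.
kruskalMaxTree <- function(genes, weight) {
    p <- length(genes)
    idx <- which(upper.tri(weight), arr.ind = TRUE)
    a <- genes[idx[, 1L]]; b <- genes[idx[, 2L]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    w <- weight[idx]
    ord <- order(-w, lo, hi, method = "radix")
    parent <- seq_len(p)
    find <- function(i) {           # with path compression via <<-
        root <- i
        while (parent[root] != root) root <- parent[root]
        while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
        root
    }
    edges <- matrix(character(), ncol = 2L)
    taken <- 0L
    for (e in ord) {
        ri <- find(idx[e, 1L]); rj <- find(idx[e, 2L])
        if (ri != rj) {
            parent[ri] <- rj
            edges <- rbind(edges, c(lo[e], hi[e]))
            taken <- taken + 1L
            if (taken == p - 1L) break
        }
    }
    edges
}

#' Maximum-likelihood spanning tree over genes
#'
#' First modeling step: the spanning tree maximizing the Gaussian
#' likelihood, equivalently the maximum-weight spanning tree under mutual
#' information edge weights (Chow-Liu). Ties break deterministically on
#' lexicographic edge order.
#'
#' @param assoc an `AssociationMatrix` from [pairwiseAssociation()].
#' @return a [DecomposableGraph-class] with `p - 1` edges and its BIC.
#' @export
likelihoodSpanningTree <- function(assoc) {
    genes <- assoc$genes
    if (length(genes) < 2L) stop("need >= 2 genes")
    edges <- kruskalMaxTree(genes, assoc$mi)
    g <- newDecomposableGraph(genes, edges)
    scoreGraph(g, assoc$rho, assoc$n)
}

# Build the S4 object, deriving cliques and junction-tree separators.
newDecomposableGraph <- function(genes, edges) {
    edges <- matrix(as.character(edges), ncol = 2L)
    jt <- junctionTree(genes, edges)
    new("DecomposableGraph", genes = genes, edges = edges,
        cliques = jt$cliques, separators = jt$separators,
        bic = NA_real_, n = NA_integer_)
}

asIgraph <- function(genes, edges) {
    igraph::graph_from_data_frame(
        d = as.data.frame(edges, stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = genes, stringsAsFactors = FALSE))
}

# Maximal cliques plus junction-forest separators (max-weight spanning
# forest of the clique graph under |intersection| weights).
junctionTree <- function(genes, edges) {
    if (!nrow(edges))
        return(list(cliques = as.list(genes), separators = list()))
    ig <- asIgraph(genes, edges)
    cl <- lapply(igraph::max_cliques(ig), function(v)
        sort(names(v)))
    cl <- cl[order(vapply(cl, paste, character(1), collapse = "\r"))]
    nc <- length(cl)
    if (nc == 1L) return(list(cliques = cl, separators = list()))
    w <- matrix(0L, nc, nc)
    for (i in seq_len(nc - 1L))
        for (j in (i + 1L):nc)
            w[i, j] <- w[j, i] <- length(intersect(cl[[i]], cl[[j]]))
    te <- kruskalMaxTree(sprintf("c%05d", seq_len(nc)), w)
    seps <- lapply(seq_len(nrow(te)), function(r) {
        i <- as.integer(sub("c", "", te[r, 1L]))
        j <- as.integer(sub("c", "", te[r, 2L]))
        intersect(cl[[i]], cl[[j]])
    })
    # separators between different connected components are empty: drop them
    seps <- seps[vapply(seps, length, integer(1)) > 0L]
    list(cliques = cl, separators = seps)
}

#' Is a graph decomposable (chordal)?
#'
#' True iff every cycle of length >= 4 has a chord, tested via maximum
#' cardinality search (perfect elimination ordering).
#'
#' @param g a [DecomposableGraph-class], or a list with `genes` and `edges`.
#' @return logical.
#' @export
isDecomposable <- function(g) {
    genes <- if (is(g, "DecomposableGraph")) g@genes else g$genes
    edges <- if (is(g, "DecomposableGraph")) g@edges else g$edges
    igraph::is_chordal(asIgraph(genes, edges))$chordal
}

# -2 logLik + params log n for a decomposable Gaussian model on
# standardized data, from clique/separator correlation determinants.
# params = p (variances/means on standardized scale) + #edges.
graphBIC_ <- function(cliques, separators, nEdges, rho, n) {
    p <- nrow(rho)
    ldet <- function(vs) {
        if (length(vs) < 2L) return(0)
        determinant(rho[vs, vs, drop = FALSE], logarithm = TRUE)$modulus[1L]
    }
    dev <- n * (p * log(2 * pi) + p +
                sum(vapply(cliques, ldet, numeric(1))) -
                sum(vapply(separators, ldet, numeric(1))))
    dev + (p + nEdges) * log(n)
}

#' Global BIC of a decomposable graph on expression data
#'
#' Recomputes the model BIC from scratch using the junction-tree clique and
#' separator correlation determinants (data standardized per gene).
#'
#' @param g [DecomposableGraph-class].
#' @param x [CohortExperiment-class] or matrix (genes x samples) containing
#'   at least the graph's genes.
#' @return numeric BIC.
#' @export
graphBIC <- function(g, x) {
    m <- asExprMatrix(x)[g@genes, , drop = FALSE]
    rho <- stats::cor(t(m))
    graphBIC_(g@cliques, g@separators, nrow(g@edges), rho, ncol(m))
}

scoreGraph <- function(g, rho, n) {
    rho <- rho[g@genes, g@genes]
    g@bic <- graphBIC_(g@cliques, g@separators, nrow(g@edges), rho, n)
    g@n <- as.integer(n)
    g
}

# Minimal u,v-separator in a chordal graph: the neighbors of u with a
# neighbor in (or equal to a member of) the component of v in
# G - ({u} union N(u)).
minimalSeparator <- function(ig, u, v) {
    nu <- names(igraph::neighbors(ig, u))
    drop <- c(u, nu)
    sub <- igraph::delete_vertices(ig, drop)
    comp <- igraph::components(sub)
    cv <- names(comp$membership)[comp$membership == comp$membership[[v]]]
    keep <- vapply(nu, function(w)
        any(names(igraph::neighbors(ig, w)) %in% cv), logical(1))
    sort(nu[keep])
}

partialCorrelation <- function(rho, u, v, S) {
    vs <- c(u, v, S)
    P <- solve(rho[vs, vs, drop = FALSE])
    -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

#' Greedy forward edge search minimizing BIC over decomposable graphs
#'
#' Starting from a decomposable graph (typically the likelihood spanning
#' tree), repeatedly scores every candidate non-edge whose addition keeps
#' the graph chordal by
#' \deqn{\Delta BIC = n \ln(1 - r^2_{uv\cdot S}) + \ln(n)}
#' where \eqn{r_{uv\cdot S}} is the partial correlation of the endpoints
#' given the minimal separator S created by the addition, adds the edge with
#' the most negative \eqn{\Delta BIC}, and stops when no candidate improves
#' or `maxEdges` additions were accepted. The recorded BIC strictly
#' decreases at every accepted step.
#'
#' @param g0 decomposable [DecomposableGraph-class] start.
#' @param x [CohortExperiment-class] or matrix; genes must cover `g0`.
#' @param maxEdges maximum number of edges to add (`Inf` = until no gain).
#' @param candidates `"local"` scans vertex pairs at graph distance <= 2
#'   (a speed heuristic rescanned after every addition); `"exhaustive"`
#'   scans all non-adjacent pairs.
#' @return [DecomposableGraph-class] with updated edges, cliques,
#'   separators and BIC; attribute `"bicTrace"` holds the BIC after the
#'   start and each accepted addition.
#' @export
forwardEdgeSearch <- function(g0, x, maxEdges = Inf,
                              candidates = c("local", "exhaustive")) {
    candidates <- match.arg(candidates)
    if (!isDecomposable(g0)) stop("g0 must be decomposable")
    m <- asExprMatrix(x)[g0@genes, , drop = FALSE]
    n <- ncol(m)
    rho <- stats::cor(t(m))
    genes <- g0@genes
    edges <- g0@edges
    ig <- asIgraph(genes, edges)
    cur <- scoreGraph(g0, rho, n)
    trace <- cur@bic
    added <- 0L
    repeat {
        if (added >= maxEdges) break
        pool <- candidatePairs(ig, genes, candidates)
        if (!nrow(pool)) break
        best <- NULL; bestDelta <- 0
        for (r in seq_len(nrow(pool))) {
            u <- pool[r, 1L]; v <- pool[r, 2L]
            ig2 <- igraph::add_edges(ig, c(u, v))
            if (!igraph::is_chordal(ig2)$chordal) next
            S <- minimalSeparator(ig, u, v)
            pc <- partialCorrelation(rho, u, v, S)
            delta <- n * log(max(1 - pc^2, 1e-300)) + log(n)
            if (delta < bestDelta - 1e-12) {
                bestDelta <- delta; best <- c(u, v)
            }
        }
        if (is.null(best)) break
        edges <- rbind(edges, best)
        ig <- igraph::add_edges(ig, best)
        added <- added + 1L
        trace <- c(trace, trace[length(trace)] + bestDelta)
    }
    out <- newDecomposableGraph(genes, edges)
    out <- scoreGraph(out, rho, n)
    attr(out, "bicTrace") <- trace
    out
}

# Non-adjacent vertex pairs, either all or restricted to graph distance 2,
# in deterministic lexicographic order.
candidatePairs <- function(ig, genes, scope) {
    adj <- igraph::as_adjacency_matrix(ig, sparse = FALSE)[genes, genes]
    if (scope == "exhaustive") {
        cand <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
    } else {
        two <- (adj %*% adj) > 0      # share a neighbor
        cand <- which(upper.tri(adj) & adj == 0 & two, arr.ind = TRUE)
    }
    if (!length(cand)) return(matrix(character(), ncol = 2L))
    out <- cbind(genes[cand[, 1L]], genes[cand[, 2L]])
    out <- cbind(pmin(out[, 1L], out[, 2L]), pmax(out[, 1L], out[, 2L]))
    out[order(out[, 1L], out[, 2L], method = "radix"), , drop = FALSE]
}
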