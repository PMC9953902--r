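#' Create a functional node
#'
#' A named gene subset of the graphical model, optionally with a
#' "main-function" sub-subset (the genes annotated with the node's dominant
#' biological function) used when computing activities in subset mode.
#'
#' @param name node label.
#' @param genes member genes.
#' @param mainGenes optional subset of `genes`.
#' @return an S3 `FunctionalNode`.
#' @export
functionalNode <- function(name, genes, mainGenes = NULL) {
    stopifnot(length(genes) > 0)
    if (!is.null(mainGenes) && !all(mainGenes %in% genes))
        stop("mainGenes must be a subset of genes")
    structure(list(name = name, genes = genes, mainGenes = mainGenes),
              class = "FunctionalNode")
}

#' @export
print.FunctionalNode <- function(x, ...) {
    cat(sprintf("FunctionalNode '%s': %d genes%s\n", x$name, length(x$genes),
                if (is.null(x$mainGenes)) ""
                else sprintf(" (%d main-function)", length(x$mainGenes))))
    invisible(x)
}

#' Split a decomposable graph into functional-node branches
#'
#' Partitions the vertex set into connected branches: components larger
#' than `maxSize` are cut recursively at the edge of highest
#' edge-betweenness (ties broken on lexicographic edge order); cutting also
#' continues while there are fewer than `targetCount` branches. Components
#' smaller than `minSize` are then merged back into the neighboring
#' component attached by the lexicographically smallest original edge.
#' The procedure is deterministic given the graph.
#'
#' @param g [DecomposableGraph-class].
#' @param targetCount desired number of branches (default scales the 13
#'   nodes / 1700 genes granularity used for CRC cohorts).
#' @param minSize,maxSize branch size bounds; `maxSize` defaults to 150%
#'   of the even split.
#' @return list of [functionalNode()] objects named `node01`, `node02`, ...
#'   partitioning the vertex set.
#' @export
splitIntoBranches <- function(g, targetCount = max(2L, round(length(g@genes) / 130)),
                              minSize = 5L,
                              maxSize = ceiling(1.5 * length(g@genes) / targetCount)) {
    genes <- g@genes
    if (targetCount > length(genes))
        stop("targetCount exceeds the number of vertices")
    ig <- asIgraph(genes, g@edges)
    repeat {
        comp <- igraph::components(ig)
        sizes <- comp$csize
        if (max(sizes) <= maxSize && comp$no >= targetCount) break
        # cut inside the largest component (ties: first index)
        big <- which.max(sizes)
        vs <- names(comp$membership)[comp$membership == big]
        sub <- igraph::induced_subgraph(ig, vs)
        if (igraph::ecount(sub) == 0L) break       # singletons only; stop
        eb <- igraph::edge_betweenness(sub)
        el <- igraph::as_edgelist(sub)
        el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
        pick <- order(-eb, el[, 1L], el[, 2L], method = "radix")[1L]
        ig <- igraph::delete_edges(
            ig, igraph::get_edge_ids(ig, el[pick, ]))
    }
    comp <- igraph::components(ig)
    member <- comp$membership[genes]
    # merge undersized components back along original edges
    orig <- g@edges
    repeat {
        sizes <- table(member)
        small <- names(sizes)[sizes < minSize]
        if (!length(small) || length(sizes) <= 1L) break
        cid <- small[1L]
        inSmall <- names(member)[member == cid]
        touching <- orig[orig[, 1L] %in% inSmall | orig[, 2L] %in% inSmall, ,
                         drop = FALSE]
        other <- touching[!(touching[, 1L] %in% inSmall &
                            touching[, 2L] %in% inSmall), , drop = FALSE]
        if (!nrow(other)) {                        # isolated: fold into
            member[inSmall] <- names(sizes)[which.max(sizes)]  # largest
            next
        }
        key <- cbind(pmin(other[, 1L], other[, 2L]),
                     pmax(other[, 1L], other[, 2L]))
        pick <- order(key[, 1L], key[, 2L], method = "radix")[1L]
        ends <- other[pick, ]
        target <- member[[setdiff(ends, inSmall)[1L]]]
        member[inSmall] <- target
    }
    ids <- sort(unique(member))
    nodes <- lapply(seq_along(ids), function(i)
        functionalNode(sprintf("node%02d", i),
                       sort(names(member)[member == ids[i]])))
    stats::setNames(nodes, vapply(nodes, `[[`, character(1), "name"))
}

#' Functional-node activity: mean expression of the node's genes
#'
#' The activity of a node in a sample is the unweighted mean log2
#' expression of its member genes (or of the annotated main-function subset
#' when `useMainSubset = TRUE` and one is defined). A single-gene node's
#' activity equals that gene's expression row.
#'
#' @param x [CohortExperiment-class] or matrix containing the node genes.
#' @param nodes one [functionalNode()] or a list of them.
#' @param useMainSubset use the main-function subset when available.
#' @return numeric matrix, nodes x samples.
#' @export
nodeActivity <- function(x, nodes, useMainSubset = FALSE) {
    if (inherits(nodes, "FunctionalNode")) nodes <- list(nodes)
    m <- asExprMatrix(x)
    act <- t(vapply(nodes, function(nd) {
        gs <- if (useMainSubset && !is.null(nd$mainGenes)) nd$mainGenes
              else nd$genes
        if (!length(gs)) stop("empty gene set in node ", nd$name)
        absent <- setdiff(gs, rownames(m))
        if (length(absent))
            stop("node ", nd$name, " gene(s) absent from data: ",
                 paste(absent, collapse = ", "))
        colMeans(m[gs, , drop = FALSE])
    }, numeric(ncol(m))))
    rownames(act) <- vapply(nodes, `[[`, character(1), "name")
    act
}

#' Label functional nodes by gene-set overrepresentation
#'
#' Assigns each node the name of the gene set with the smallest
#' BH-adjusted hypergeometric tail probability (overlap >= 3 required);
#' nodes with no qualifying set stay unlabeled (`NA`).
#'
#' @param nodes list of [functionalNode()] objects.
#' @param geneSets named list of character vectors (e.g. [readGmt()]).
#' @param universe background gene list (typically `geneIds(x)`).
#' @return the nodes, with a `label` element added to each.
#' @export
labelFunctionalNodes <- function(nodes, geneSets, universe) {
    lapply(nodes, function(nd) {
        enr <- hypergeometricEnrichment(intersect(nd$genes, universe),
                                        geneSets, universe)
        nd$label <- enr$winner
        nd
    })
}
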