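#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CohortExperiment: a multi-batch log-expression matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples log2-expression matrix in the `"exprs"` assay, with a
#' mandatory per-sample `batch` column in `colData`. All pipeline stages
#' consume and produce this class.
#'
#' Validity requires: unique, non-empty row and column names; a complete
#' (no `NA`) numeric assay; and a `batch` label for every sample.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
    msg <- character()
    if (!("exprs" %in% assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- assay(object, "exprs")
        if (!is.numeric(v)) msg <- c(msg, "assay 'exprs' must be numeric")
        if (anyNA(v)) msg <- c(msg, "assay 'exprs' must not contain NA")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (!("batch" %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain a 'batch' column")
    else if (anyNA(colData(object)$batch))
        msg <- c(msg, "every sample needs exactly one batch label")
    if (length(msg)) msg else TRUE
})

#' Construct a CohortExperiment
#'
#' @param values numeric matrix, genes in rows (rownames = gene or probe ids),
#'   samples in columns (colnames = sample ids); log2 scale by convention.
#' @param batch character/factor of per-sample cohort labels, recycled if
#'   length 1. Defaults to a single batch `"cohort1"`.
#' @param colData optional extra per-sample columns (a data.frame), e.g. a
#'   clinical table aligned to the samples.
#' @return a [CohortExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ce <- CohortExperiment(m, batch = rep(c("a", "b"), each = 2))
#' @export
CohortExperiment <- function(values, batch = "cohort1", colData = NULL) {
    values <- as.matrix(values)
    if (length(batch) == 1L) batch <- rep(batch, ncol(values))
    cd <- DataFrame(batch = as.character(batch), row.names = colnames(values))
    if (!is.null(colData)) {
        extra <- as(colData, "DataFrame")
        stopifnot(nrow(extra) == ncol(values))
        rownames(extra) <- colnames(values)
        cd <- cbind(cd, extra[, setdiff(colnames(extra), "batch"), drop = FALSE])
    }
    new("CohortExperiment",
        SummarizedExperiment(assays = list(exprs = values), colData = cd))
}

setMethod("show", "CohortExperiment", function(object) {
    cat(sprintf("CohortExperiment: %d genes x %d samples, %d batch(es)\n",
                nrow(object), ncol(object),
                length(unique(colData(object)$batch))))
    tab <- table(colData(object)$batch)
    cat("  batches:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
})

#' DecomposableGraph: a chordal Gaussian graphical model
#'
#' Undirected chordal (decomposable) graph over genes with its junction-tree
#' bookkeeping (cliques and separators, the latter with multiplicities kept as
#' list entries) and the model BIC at the sample size used to fit it.
#'
#' @slot genes character vector of vertex names.
#' @slot edges character matrix with two columns, one row per undirected edge.
#' @slot cliques list of character vectors, the maximal cliques.
#' @slot separators list of character vectors, junction-tree separators
#'   (possibly repeated; empty separators are dropped).
#' @slot bic numeric, model BIC (-2 logLik + params * log n); `NA` until scored.
#' @slot n integer, number of samples behind `bic`.
#' @export
setClass("DecomposableGraph",
         representation(genes = "character", edges = "matrix",
                        cliques = "list", separators = "list",
                        bic = "numeric", n = "integer"))

setValidity("DecomposableGraph", function(object) {
    msg <- character()
    e <- object@edges
    if (nrow(e) && (!is.character(e) || ncol(e) != 2L))
        msg <- c(msg, "edges must be a 2-column character matrix")
    if (nrow(e)) {
        if (!all(e %in% object@genes))
            msg <- c(msg, "edge endpoints must be declared vertices")
        if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self loops are not allowed")
        key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        if (anyDuplicated(key)) msg <- c(msg, "duplicated edges")
    }
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicated vertex names")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DecomposableGraph", function(object) {
    cat(sprintf("DecomposableGraph: %d vertices, %d edges, %d cliques\n",
                length(object@genes), nrow(object@edges),
                length(object@cliques)))
    if (!is.na(object@bic))
        cat(sprintf("  BIC = %.3f (n = %d)\n", object@bic, object@n))
})

#' Layer: one peeled layer of sample structure
#'
#' A gene subset selected by sparse k-means (with its weights) together with
#' the consensus-cluster sample partition it induces, the chosen number of
#' groups and the PAC table over the candidate k range.
#'
#' @slot index integer, position in the peeling order (1-based).
#' @slot genes character, the selected genes (strictly positive weights).
#' @slot weights numeric named by gene, the sparse k-means weights.
#' @slot k integer, number of groups chosen by minimal PAC.
#' @slot partition factor named by sample id, group per sample.
#' @slot pac numeric named by candidate k.
#' @slot label character, functional annotation (possibly `NA`).
#' @export
setClass("Layer",
         representation(index = "integer", genes = "character",
                        weights = "numeric", k = "integer",
                        partition = "factor", pac = "numeric",
                        label = "character"))

setValidity("Layer", function(object) {
    msg <- character()
    if (!length(object@genes)) msg <- c(msg, "a layer needs >=1 selected gene")
    if (!identical(sort(names(object@weights)), sort(object@genes)))
        msg <- c(msg, "weights must be named by the selected genes")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
    if (!length(object@partition) || anyNA(object@partition))
        msg <- c(msg, "partition must cover all samples")
    if (nlevels(droplevels(object@partition)) != object@k)
        msg <- c(msg, "partition must have exactly k nonempty groups")
    if (length(msg)) msg else TRUE
})

setMethod("show", "Layer", function(object) {
    cat(sprintf("Layer %d: %d genes, k = %d (%s)\n", object@index,
                length(object@genes), object@k,
                if (is.na(object@label)) "unlabeled" else object@label))
    grp <- table(object@partition)
    cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = " "),
        "\n")
})

#' LayerSet: the ordered peeled layers and their merged form
#'
#' @slot layers list of raw [Layer-class] objects in peeling order.
#' @slot merged list of merged [Layer-class] objects (redundant raw layers
#'   combined; partitions re-derived by consensus clustering on the union
#'   gene set).
#' @slot mergeMap character named by raw layer index, value = merged layer
#'   name; each raw layer maps to exactly one merged layer.
#' @export
setClass("LayerSet",
         representation(layers = "list", merged = "list",
                        mergeMap = "character"))

setValidity("LayerSet", function(object) {
    msg <- character()
    if (!all(vapply(object@layers, is, logical(1), "Layer")))
        msg <- c(msg, "layers must be Layer objects")
    if (!all(vapply(object@merged, is, logical(1), "Layer")))
        msg <- c(msg, "merged must be Layer objects")
    if (length(object@mergeMap) &&
        anyDuplicated(names(object@mergeMap)))
        msg <- c(msg, "a raw layer maps to at most one merged layer")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LayerSet", function(object) {
    cat(sprintf("LayerSet: %d raw layer(s), %d merged layer(s)\n",
                length(object@layers), length(object@merged)))
    for (nm in names(object@merged)) {
        ly <- object@merged[[nm]]
        cons <- names(object@mergeMap)[object@mergeMap == nm]
        lab <- if (!is.na(ly@label)) sprintf(" [%s]", ly@label) else ""
        cat(sprintf("  %s <- raw {%s}: %d genes, k = %d%s\n", nm,
                    paste(cons, collapse = ","), length(ly@genes), ly@k, lab))
    }
})
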