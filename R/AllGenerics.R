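#' Accessors for layerscope objects
#'
#' Small accessor layer so user code never touches slots directly:
#' `exprValues()` returns the genes x samples matrix, `batchLabels()` the
#' per-sample cohort labels, `geneIds()`/`sampleIds()` the dimnames;
#' `graphEdges()`, `graphCliques()`, `graphSeparators()` and `bicValue()`
#' expose a [DecomposableGraph-class]; `layerGenes()`, `layerWeights()` and
#' `layerPartition()` a [Layer-class]; `rawLayers()` and `mergedLayers()` a
#' [LayerSet-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("graphCliques", function(x) standardGeneric("graphCliques"))
#' @rdname accessors
#' @export
setGeneric("graphSeparators", function(x) standardGeneric("graphSeparators"))
#' @rdname accessors
#' @export
setGeneric("bicValue", function(x) standardGeneric("bicValue"))
#' @rdname accessors
#' @export
setGeneric("layerGenes", function(x) standardGeneric("layerGenes"))
#' @rdname accessors
#' @export
setGeneric("layerWeights", function(x) standardGeneric("layerWeights"))
#' @rdname accessors
#' @export
setGeneric("layerPartition", function(x) standardGeneric("layerPartition"))
#' @rdname accessors
#' @export
setGeneric("rawLayers", function(x) standardGeneric("rawLayers"))
#' @rdname accessors
#' @export
setGeneric("mergedLayers", function(x) standardGeneric("mergedLayers"))

#' @rdname accessors
#' @export
setMethod("exprValues", "CohortExperiment",
          function(x) assay(x, "exprs"))
#' @rdname accessors
#' @export
setMethod("batchLabels", "CohortExperiment",
          function(x) as.character(colData(x)$batch))
#' @rdname accessors
#' @export
setMethod("geneIds", "CohortExperiment", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "CohortExperiment", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("geneIds", "DecomposableGraph", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("graphEdges", "DecomposableGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("graphCliques", "DecomposableGraph", function(x) x@cliques)
#' @rdname accessors
#' @export
setMethod("graphSeparators", "DecomposableGraph", function(x) x@separators)
#' @rdname accessors
#' @export
setMethod("bicValue", "DecomposableGraph", function(x) x@bic)

#' @rdname accessors
#' @export
setMethod("layerGenes", "Layer", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("layerWeights", "Layer", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("layerPartition", "Layer", function(x) x@partition)
#' @rdname accessors
#' @export
setMethod("rawLayers", "LayerSet", function(x) x@layers)
#' @rdname accessors
#' @export
setMethod("mergedLayers", "LayerSet", function(x) x@merged)
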