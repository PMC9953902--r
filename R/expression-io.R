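#' Read a genes x samples expression matrix from a TSV file
#'
#' Expects a tab-separated series-matrix-like layout: first column holds the
#' probe/gene identifiers, the header row holds sample identifiers, and the
#' body is numeric log2 expression. Ragged rows, duplicated sample columns,
#' duplicated row ids and non-numeric cells are rejected.
#'
#' @param path path to the TSV file.
#' @param batch batch (cohort) label to attach to every sample; defaults to
#'   the file name without extension.
#' @return a [CohortExperiment-class].
#' @seealso [writeExpressionMatrix()], [mergeCohorts()]
#' @export
readExpressionMatrix <- function(path, batch = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1L),
                            data.table = FALSE, fill = FALSE)
    if (ncol(dt) < 2L) stop("expected an id column plus >=1 sample column")
    ids <- dt[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated row ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    hdr <- colnames(dt)[-1L]
    if (anyDuplicated(hdr))
        stop("duplicated sample ids: ",
             paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
    body <- dt[, -1L, drop = FALSE]
    bad <- !vapply(body, is.numeric, logical(1))
    if (any(bad))
        stop("non-numeric expression column(s): ",
             paste(hdr[bad], collapse = ", "))
    m <- as.matrix(body)
    rownames(m) <- ids
    if (is.null(batch)) batch <- sub("\\.[^.]*$", "", basename(path))
    CohortExperiment(m, batch = batch)
}

#' Write an expression matrix as TSV (round-trips with readExpressionMatrix)
#'
#' @param x a [CohortExperiment-class] or genes x samples matrix.
#' @param path output path.
#' @param idColumn name for the identifier column.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "gene_id") {
    m <- asExprMatrix(x)
    # 17 significant digits: doubles survive the text round trip exactly
    chr <- apply(m, 2L, function(col) sprintf("%.17g", col))
    if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(m))
    df <- data.frame(id = rownames(m), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c(idColumn, colnames(m))
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_symbol`), many probes to one gene.
#' Control/unmapped probes must simply be absent from the file.
#'
#' @param path path to the TSV.
#' @return named character vector: `map[probe_id] == gene_symbol`.
#' @export
readProbeMap <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", data.table = FALSE)
    if (ncol(dt) < 2L) stop("probe map needs two columns (probe, gene)")
    if (anyDuplicated(dt[[1L]]))
        stop("a probe must map to exactly one gene symbol")
    stats::setNames(dt[[2L]], dt[[1L]])
}

#' Merge expression cohorts on their common probe/gene set
#'
#' Rows are intersected across cohorts (a probe absent from any cohort is
#' dropped, so the merged matrix has no missing entries); columns are
#' concatenated and keep their source cohort as batch label.
#'
#' @param cohorts list of >=2 [CohortExperiment-class] objects.
#' @return a [CohortExperiment-class] with `length(cohorts)`-level batch.
#' @export
mergeCohorts <- function(cohorts) {
    stopifnot(length(cohorts) >= 2L)
    rows <- Reduce(intersect, lapply(cohorts, geneIds))
    if (!length(rows))
        stop("no probes/genes shared by all cohorts; nothing to merge")
    samples <- unlist(lapply(cohorts, sampleIds), use.names = FALSE)
    if (anyDuplicated(samples))
        stop("sample id collision across cohorts: ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    values <- do.call(cbind, lapply(cohorts, function(ce)
        exprValues(ce)[rows, , drop = FALSE]))
    batch <- unlist(lapply(cohorts, batchLabels), use.names = FALSE)
    CohortExperiment(values, batch = batch)
}

#' Collapse probes to genes by maximal variance
#'
#' For each gene the probe with the largest variance across all samples
#' survives; ties break to the lexicographically smallest probe id. Probes
#' missing from the map are an error (control probes must be pre-dropped
#' from the map, not silently passed through).
#'
#' @param x [CohortExperiment-class] keyed by probe id.
#' @param map named character vector (see [readProbeMap()]).
#' @return a [CohortExperiment-class] keyed by gene symbol.
#' @export
collapseProbes <- function(x, map) {
    probes <- geneIds(x)
    missing <- setdiff(probes, names(map))
    if (length(missing))
        stop("probe(s) absent from the map: ",
             paste(utils::head(missing, 10L), collapse = ", "),
             if (length(missing) > 10L) sprintf(" (+%d more)",
                                                length(missing) - 10L))
    v <- exprValues(x)
    vars <- rowSds(v)^2
    ord <- order(map[probes], -vars, probes, method = "radix")
    keep <- ord[!duplicated(map[probes][ord])]
    keep <- sort(keep)          # preserve input row order among survivors
    out <- v[keep, , drop = FALSE]
    rownames(out) <- unname(map[probes[keep]])
    CohortExperiment(out, batch = batchLabels(x),
                     colData = colData(x)[, -1L, drop = FALSE])
}

#' Remove additive batch effects by per-gene batch-mean centering
#'
#' Per gene, each batch's mean is subtracted and the gene's grand mean
#' (across all samples) added back -- the least-squares removal of batch
#' indicator covariates with no other model terms. After correction every
#' gene's per-batch means coincide (within numerical noise). Single-batch
#' input is returned unchanged; a batch with one sample is allowed but its
#' offset is then estimated from that single sample (with a warning).
#'
#' @param x [CohortExperiment-class].
#' @return corrected [CohortExperiment-class].
#' @export
correctBatchEffect <- function(x) {
    batch <- batchLabels(x)
    if (length(unique(batch)) < 2L) return(x)
    sizes <- table(batch)
    if (any(sizes < 2L))
        warning("batch(es) with a single sample: ",
                paste(names(sizes)[sizes < 2L], collapse = ", "),
                "; their offsets are estimated from one sample")
    v <- exprValues(x)
    grand <- rowMeans(v)
    groups <- split(seq_len(ncol(v)), batch)
    bm <- vapply(groups, function(j) rowMeans(v[, j, drop = FALSE]),
                 numeric(nrow(v)))
    if (!is.matrix(bm))                       # single-gene input
        bm <- matrix(bm, nrow = 1L,
                     dimnames = list(rownames(v), names(groups)))
    corrected <- v - bm[, batch] + grand
    out <- x
    assay(out, "exprs") <- corrected
    out
}

#' Keep highly variable genes (standard deviation strictly above a cutoff)
#'
#' @param x [CohortExperiment-class].
#' @param sdThreshold keep genes with sample SD `>` this value (default 2.0,
#'   the conventional cutoff for log2 microarray cohorts of this size).
#' @return filtered [CohortExperiment-class], gene order preserved.
#' @export
filterByVariability <- function(x, sdThreshold = 2.0) {
    stopifnot(sdThreshold >= 0)
    keep <- rowSds(exprValues(x)) > sdThreshold
    if (!any(keep))
        stop("no gene exceeds SD > ", sdThreshold,
             "; lower the threshold")
    x[keep, ]
}

#' Read and validate a clinical table
#'
#' Comma- or tab-separated, one row per sample. Required columns (after
#' `columnMap` renaming): `sample_id`, `dfs_months`, `relapse_event`.
#' Optional: `batch`, `stage`, `location`, `cms`. Unparseable stage/location
#' values are coded `NA` and counted in a message. `eventMap` converts a
#' non-numeric event column (e.g. `c(yes = 1, no = 0)`).
#'
#' @param path CSV/TSV path.
#' @param columnMap named character vector mapping file headers to canonical
#'   names, e.g. `c(dfs = "dfs_months")`.
#' @param eventMap named numeric vector mapping event codes to 0/1.
#' @return validated `data.frame` with canonical columns.
#' @export
readClinicalTable <- function(path, columnMap = NULL, eventMap = NULL) {
    dt <- data.table::fread(path, data.table = FALSE)
    if (!is.null(columnMap)) {
        hit <- match(names(columnMap), colnames(dt))
        colnames(dt)[hit[!is.na(hit)]] <- columnMap[!is.na(hit)]
    }
    req <- c("sample_id", "dfs_months", "relapse_event")
    miss <- setdiff(req, colnames(dt))
    if (length(miss))
        stop("clinical table lacks required column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(dt$sample_id)) stop("duplicated sample_id")
    dt$dfs_months <- as.numeric(dt$dfs_months)
    if (anyNA(dt$dfs_months) || any(dt$dfs_months < 0))
        stop("dfs_months must be non-negative and numeric")
    ev <- dt$relapse_event
    if (!is.null(eventMap)) ev <- unname(eventMap[as.character(ev)])
    ev <- as.numeric(ev)
    if (anyNA(ev) || !all(ev %in% c(0, 1)))
        stop("relapse_event must code to 0/1 (supply eventMap if needed)")
    dt$relapse_event <- ev
    for (col in c("stage", "location", "cms")) {
        if (!col %in% colnames(dt)) { dt[[col]] <- NA; next }
        ok <- switch(col,
                     stage    = as.character(dt[[col]]) %in% as.character(1:4),
                     location = dt[[col]] %in% c("proximal", "distal"),
                     cms      = dt[[col]] %in% paste0("CMS", 1:4))
        nbad <- sum(!ok & !is.na(dt[[col]]))
        if (nbad) message(nbad, " unparseable '", col, "' value(s) coded NA")
        dt[[col]][!ok] <- NA
    }
    dt$stage <- as.integer(dt$stage)
    if (!"batch" %in% colnames(dt)) dt$batch <- NA_character_
    dt[, c("sample_id", "batch", "dfs_months", "relapse_event",
           "stage", "location", "cms")]
}
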