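# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

rowSds <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (n - 1))
}

# Coerce CohortExperiment or plain matrix to genes x samples matrix.
asExprMatrix <- function(x) {
    if (is(x, "CohortExperiment")) exprValues(x)
    else if (is(x, "SummarizedExperiment")) assay(x, 1L)
    else as.matrix(x)
}

# Canonical undirected edge key, used for dedup and deterministic ordering.
edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
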