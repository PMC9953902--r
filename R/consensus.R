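#' Consensus clustering over sample subsamples
#'
#' For each candidate number of groups k, samples are repeatedly subsampled
#' without replacement (`subsampleFrac` of the cohort), clustered by
#' k-means, and pairwise co-clustering frequencies accumulated into a
#' consensus matrix \eqn{M_k(i,j)} = (times i,j clustered together) /
#' (times i,j subsampled together). Per k the empirical consensus CDF, its
#' area, the delta-area relative to k-1, and the PAC score (proportion of
#' ambiguous off-diagonal entries strictly inside `(pacLower, pacUpper)`)
#' are computed; final labels at each k come from average-linkage
#' hierarchical clustering of `1 - M_k`.
#'
#' If some sample pair is never co-subsampled, additional resample rounds
#' are drawn (up to 10x `nResamples`) before erroring.
#'
#' @param x [CohortExperiment-class] or genes x samples matrix (already
#'   restricted to the selected genes).
#' @param kRange candidate k values, within `[2, n/3]`.
#' @param nResamples subsampling iterations per k (default 1000).
#' @param subsampleFrac fraction of samples per draw (default 0.8).
#' @param pacLower,pacUpper ambiguity window for PAC (defaults 0.1, 0.9).
#' @param nstart k-means restarts per draw.
#' @param seed RNG seed.
#' @return S3 `ConsensusResult`: `consensus` (list of matrices by k),
#'   `pac`, `area`, `deltaArea` (named numeric), `labels` (list of factors
#'   by k), `kRange`.
#' @references Monti et al. (2003) Machine Learning 52:91-118; Senbabaoglu
#'   et al. (2014) Sci Rep 4:6207 (PAC).
#' @export
consensusCluster <- function(x, kRange = 2:5, nResamples = 1000L,
                             subsampleFrac = 0.8, pacLower = 0.1,
                             pacUpper = 0.9, nstart = 3L, seed = 1L) {
    m <- asExprMatrix(x)
    n <- ncol(m)
    kRange <- sort(unique(as.integer(kRange)))
    if (any(kRange < 2L) || any(kRange > max(2L, floor(n / 3))))
        stop("kRange must lie within [2, n/3]")
    sm <- t(m - rowMeans(m))                   # samples x genes
    nSub <- max(2L, floor(subsampleFrac * n))
    withSeed(seed, {
        res <- lapply(kRange, function(k) {
            hits <- matrix(0, n, n)
            co <- matrix(0, n, n)
            drawn <- 0L
            repeat {
                for (b in seq_len(nResamples)) {
                    idx <- sort(sample.int(n, nSub))
                    cl <- stats::kmeans(sm[idx, , drop = FALSE], centers = k,
                                        nstart = nstart, iter.max = 30L)$cluster
                    same <- outer(cl, cl, "==")
                    hits[idx, idx] <- hits[idx, idx] + same
                    co[idx, idx] <- co[idx, idx] + 1
                }
                drawn <- drawn + nResamples
                off <- co[upper.tri(co)]
                if (all(off > 0)) break
                if (drawn >= 10L * nResamples)
                    stop("sample pair(s) never co-subsampled after ",
                         drawn, " resamples")
            }
            M <- hits / co
            diag(M) <- 1
            dimnames(M) <- list(colnames(m), colnames(m))
            M
        })
        names(res) <- as.character(kRange)
        up <- function(M) M[upper.tri(M)]
        pac <- vapply(res, function(M)
            mean(up(M) > pacLower & up(M) < pacUpper), numeric(1))
        grid <- seq(0, 1, by = 0.005)
        area <- vapply(res, function(M)
            sum(stats::ecdf(up(M))(grid)) * 0.005, numeric(1))
        deltaArea <- c(area[1L],
                       if (length(area) > 1L) diff(area) / utils::head(area, -1L))
        names(deltaArea) <- names(area)
        labels <- lapply(seq_along(res), function(i) {
            hc <- stats::hclust(stats::as.dist(1 - res[[i]]),
                                method = "average")
            cl <- stats::cutree(hc, k = kRange[i])
            f <- factor(cl)
            names(f) <- names(cl)
            f
        })
        names(labels) <- as.character(kRange)
        structure(list(consensus = res, pac = pac, area = area,
                       deltaArea = deltaArea, labels = labels,
                       kRange = kRange),
                  class = "ConsensusResult")
    })
}

#' @export
print.ConsensusResult <- function(x, ...) {
    cat("ConsensusResult over k =", paste(x$kRange, collapse = ", "), "\n")
    print(data.frame(k = x$kRange, PAC = round(x$pac, 4),
                     deltaArea = round(x$deltaArea, 4)), row.names = FALSE)
    invisible(x)
}

#' Choose the number of groups from a consensus-clustering run
#'
#' Picks k by minimal PAC, resolved for nested structure: among the k
#' values whose PAC lies within `pacEpsilon` of the minimum, the largest k
#' wins. A genuine k-group structure often admits a perfectly stable
#' 2-way supercut (PAC(2) = 0 as well), so the plain minimum
#' systematically under-splits nested groups; a spuriously large k never
#' shows near-minimal PAC because splitting homogeneous groups creates
#' ambiguous co-clustering. With `pacEpsilon = 0`, the rule reduces to the
#' plain minimum with ties to the larger k. The delta-area curve is
#' carried along for diagnostics. When `pacThreshold` is given and even
#' the best PAC exceeds it, the result is flagged as "no structure".
#'
#' @param cc a `ConsensusResult`.
#' @param pacThreshold optional no-structure cutoff on the minimal PAC.
#' @param pacEpsilon tolerance above the minimal PAC within which a larger
#'   k is preferred (default 0.03).
#' @return list: `k`, `pac` (at the chosen k), `noStructure` (logical),
#'   `labels` (factor named by sample), `deltaArea`.
#' @export
chooseK <- function(cc, pacThreshold = NULL, pacEpsilon = 0.03) {
    stopifnot(inherits(cc, "ConsensusResult"), length(cc$kRange) >= 1L)
    best <- min(cc$pac)
    k <- max(cc$kRange[cc$pac <= best + pacEpsilon])
    list(k = k,
         pac = unname(cc$pac[as.character(k)]),
         noStructure = if (is.null(pacThreshold)) FALSE
                       else best > pacThreshold,
         labels = cc$labels[[as.character(k)]],
         deltaArea = cc$deltaArea)
}
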