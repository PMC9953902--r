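#' Peel layers of sample structure by iterative sparse k-means selection
#'
#' The core discovery loop. At each round the sparsity bound is tuned by
#' the gap statistic, sparse k-means is fitted with k = 2 (the cheapest
#' structure detector; the final group count per layer is decided by
#' consensus clustering, not here), and the genes with strictly positive
#' weight become the candidate layer. Consensus clustering restricted to
#' those genes chooses the number of groups by minimal PAC; if even the
#' best PAC exceeds `pacThreshold` the cohort is declared structureless and
#' the loop stops without accepting the layer. Accepted genes are removed
#' from the matrix and the analysis repeats on the remainder, so every gene
#' belongs to at most one layer.
#'
#' Stopping rules: fewer than `minGenes` genes selected (or remaining),
#' `maxLayers` layers accepted, or the PAC no-structure rule.
#'
#' @param x [CohortExperiment-class] or genes x samples matrix.
#' @param kRange candidate group counts for consensus clustering.
#' @param sGrid sparsity grid for [tuneSparsity()] (`NULL` = automatic,
#'   rescaled to the genes remaining each round).
#' @param nPerms gap-statistic permutations per round.
#' @param nResamples,subsampleFrac consensus-clustering controls.
#' @param pacThreshold no-structure cutoff on minimal PAC (default 0.3).
#' @param minGenes minimum selected genes to accept a layer (default 20).
#' @param maxLayers maximum layers to peel (default 9).
#' @param nstart k-means restarts.
#' @param seed RNG seed; round r uses derived seed `seed + 131 * r`.
#' @return a [LayerSet-class] with raw layers (merge slots empty until
#'   [mergeLayers()] is run).
#' @export
peelLayers <- function(x, kRange = 2:5, sGrid = NULL, nPerms = 5L,
                       nResamples = 1000L, subsampleFrac = 0.8,
                       pacThreshold = 0.3, minGenes = 20L, maxLayers = 9L,
                       nstart = 3L, seed = 1L) {
    m <- asExprMatrix(x)
    layers <- list()
    round <- 0L
    while (nrow(m) >= minGenes && length(layers) < maxLayers) {
        round <- round + 1L
        rSeed <- seed + 131L * round
        grid <- sGrid
        if (!is.null(grid)) grid <- grid[grid <= sqrt(nrow(m))]
        if (is.null(grid) || length(grid) < 2L)
            grid <- exp(seq(log(1.2), log(sqrt(nrow(m))), length.out = 4L))
        tune <- tuneSparsity(m, k = 2L, sGrid = grid, nPerms = nPerms,
                             seed = rSeed, nstart = nstart)
        fit <- sparseKmeans(m, k = 2L, s = tune$best, seed = rSeed,
                            nstart = nstart)
        # a layer must be a strict gene subset: if the tuned bound leaves
        # every weight positive (the L1 constraint never bound), step down
        # the grid until the soft threshold actually zeroes genes
        sNext <- sort(grid[grid < tune$best], decreasing = TRUE)
        while (all(fit$weights > 0) && length(sNext)) {
            fit <- sparseKmeans(m, k = 2L, s = sNext[1L], seed = rSeed,
                                nstart = nstart)
            sNext <- sNext[-1L]
        }
        sel <- names(fit$weights)[fit$weights > 0]
        if (length(sel) < minGenes || length(sel) == nrow(m)) break
        cc <- consensusCluster(m[sel, , drop = FALSE],
                               kRange = kRange, nResamples = nResamples,
                               subsampleFrac = subsampleFrac,
                               nstart = nstart, seed = rSeed + 1L)
        pick <- chooseK(cc, pacThreshold = pacThreshold)
        if (pick$noStructure) break
        layers[[length(layers) + 1L]] <-
            new("Layer", index = length(layers) + 1L, genes = sel,
                weights = fit$weights[sel], k = as.integer(pick$k),
                partition = pick$labels, pac = cc$pac,
                label = NA_character_)
        m <- m[setdiff(rownames(m), sel), , drop = FALSE]
    }
    new("LayerSet", layers = layers, merged = list(),
        mergeMap = stats::setNames(character(0), character(0)))
}

#' Merge redundant layers by partition agreement
#'
#' Raw layers whose sample partitions agree (pairwise adjusted Rand index
#' >= `ariThreshold`) carry the same information and are merged: the merge
#' relation is closed transitively, gene sets are unioned, and each merged
#' layer's group count and final partition are re-derived by consensus
#' clustering on the union gene set.
#'
#' @param ls a [LayerSet-class] from [peelLayers()].
#' @param x the expression data the layers were peeled from.
#' @param ariThreshold merge cutoff on the pairwise ARI (default 0.6).
#' @param kRange,nResamples,subsampleFrac,nstart consensus controls for the
#'   re-derivation.
#' @param seed RNG seed.
#' @return the [LayerSet-class] with `merged` layers (named `M1`, `M2`, ...
#'   in order of their earliest constituent) and the raw-to-merged
#'   `mergeMap` filled in.
#' @export
mergeLayers <- function(ls, x, ariThreshold = 0.6, kRange = 2:5,
                        nResamples = 1000L, subsampleFrac = 0.8,
                        nstart = 3L, seed = 1L) {
    stopifnot(is(ls, "LayerSet"))
    raw <- ls@layers
    if (!length(raw)) return(ls)
    m <- asExprMatrix(x)
    L <- length(raw)
    agree <- diag(1, L)
    if (L > 1L)
        for (i in seq_len(L - 1L))
            for (j in (i + 1L):L)
                agree[i, j] <- agree[j, i] <- mclust::adjustedRandIndex(
                    as.character(raw[[i]]@partition[sampleIds_(m)]),
                    as.character(raw[[j]]@partition[sampleIds_(m)]))
    # transitive closure: connected components of the >= threshold graph
    groups <- rep(NA_integer_, L)
    gid <- 0L
    for (i in seq_len(L)) {
        if (!is.na(groups[i])) next
        gid <- gid + 1L
        queue <- i
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            if (!is.na(groups[v])) next
            groups[v] <- gid
            queue <- c(queue, which(agree[v, ] >= ariThreshold &
                                    is.na(groups)))
        }
    }
    merged <- list(); mergeMap <- character(0)
    for (gcur in seq_len(max(groups))) {
        members <- which(groups == gcur)
        name <- sprintf("M%d", length(merged) + 1L)
        genes <- sort(unique(unlist(lapply(raw[members], layerGenes))))
        weights <- unlist(lapply(raw[members], layerWeights))
        weights <- weights[!duplicated(names(weights))][genes]
        if (length(members) == 1L) {
            base <- raw[[members]]
            lay <- new("Layer", index = base@index, genes = genes,
                       weights = weights, k = base@k,
                       partition = base@partition, pac = base@pac,
                       label = NA_character_)
        } else {
            cc <- consensusCluster(m[genes, , drop = FALSE], kRange = kRange,
                                   nResamples = nResamples,
                                   subsampleFrac = subsampleFrac,
                                   nstart = nstart, seed = seed + gcur)
            pick <- chooseK(cc)
            lay <- new("Layer", index = min(members), genes = genes,
                       weights = weights, k = as.integer(pick$k),
                       partition = pick$labels, pac = cc$pac,
                       label = NA_character_)
        }
        merged[[name]] <- lay
        mergeMap[as.character(members)] <- name
    }
    # order merged layers by earliest constituent, relabel M1..Mk
    ord <- order(vapply(merged, function(l) l@index, integer(1)))
    merged <- merged[ord]
    newNames <- sprintf("M%d", seq_along(merged))
    rename <- stats::setNames(newNames, names(merged))
    names(merged) <- newNames
    mergeMap[] <- rename[mergeMap]
    new("LayerSet", layers = raw, merged = merged, mergeMap = mergeMap)
}

sampleIds_ <- function(m) colnames(m)
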