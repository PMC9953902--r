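# Lighter layer-discovery tests; the full spec-scale peeling runs live in
# test-acceptance.R.

test_that("peeled layers have disjoint gene sets covering a data subset", {
    sim <- generateCohort(cohortConfig(
        nSamples = 120L,
        genesPerBlock = c(adhesion = 60L, immune = 60L, molecular_1 = 0L,
                          molecular_2 = 0L, molecular_3 = 0L,
                          molecular_4 = 0L, noise = 80L),
        delta = c(adhesion = 2, immune = 1.6, molecular = 0), seed = 21L))
    x <- correctBatchEffect(sim$expr)
    ls0 <- peelLayers(x, kRange = 2:3, nPerms = 3, nResamples = 80,
                      nstart = 2, seed = 1)
    expect_s4_class(ls0, "LayerSet")
    expect_gte(length(rawLayers(ls0)), 2L)
    gsets <- lapply(rawLayers(ls0), layerGenes)
    expect_identical(anyDuplicated(unlist(gsets)), 0L)
    expect_true(all(unlist(gsets) %in% geneIds(x)))
    for (ly in rawLayers(ls0)) {
        expect_true(all(layerWeights(ly) > 0))
        expect_identical(length(layerPartition(ly)), ncol(x))
        expect_identical(nlevels(layerPartition(ly)), ly@k)
    }
    # the two planted factors are recovered by the first two layers
    a1 <- scorePartition(layerPartition(rawLayers(ls0)[[1]]), sim$truth,
                         "adhesion")
    i2 <- scorePartition(layerPartition(rawLayers(ls0)[[2]]), sim$truth,
                         "immune")
    expect_gte(a1, 0.8)
    expect_gte(i2, 0.8)
})

test_that("merging joins redundant layers and leaves independent ones", {
    sim <- generateCohort(cohortConfig(nSamples = 100L, seed = 31L))
    x <- correctBatchEffect(sim$expr)
    ids <- sampleIds(x)
    mkLayer <- function(idx, genes, part) {
        new("Layer", index = idx, genes = genes,
            weights = stats::setNames(rep(0.1, length(genes)), genes),
            k = nlevels(factor(part)),
            partition = factor(stats::setNames(part, ids)),
            pac = c(`2` = 0.01), label = NA_character_)
    }
    adh <- sim$truth$membership$adhesion
    imm <- sim$truth$membership$immune
    gs <- geneIds(x)
    # layers 1 and 2 carry the same partition (identical -> ARI 1);
    # layer 3 is an independent factor
    ls0 <- new("LayerSet",
               layers = list(mkLayer(1L, gs[1:40], adh),
                             mkLayer(2L, gs[41:80], adh),
                             mkLayer(3L, gs[81:120], imm)),
               merged = list(), mergeMap = character(0))
    ls1 <- mergeLayers(ls0, x, nResamples = 80, seed = 4)
    expect_identical(length(mergedLayers(ls1)), 2L)
    expect_identical(unname(ls1@mergeMap[c("1", "2")]), c("M1", "M1"))
    expect_identical(unname(ls1@mergeMap["3"]), "M2")
    expect_identical(length(layerGenes(mergedLayers(ls1)$M1)), 80L)

    # independent random partitions never merge
    set.seed(9)
    ls2 <- new("LayerSet",
               layers = list(mkLayer(1L, gs[1:40], sample(adh)),
                             mkLayer(2L, gs[41:80], sample(adh))),
               merged = list(), mergeMap = character(0))
    ls3 <- mergeLayers(ls2, x, nResamples = 80, seed = 4)
    expect_identical(length(mergedLayers(ls3)), 2L)
})

test_that("duplicate-signal design merges into one layer end-to-end", {
    # two gene blocks driven by the same latent factor: peel twice, merge once
    set.seed(77)
    n <- 90
    grp <- sample(rep(1:2, length.out = n))
    blockA <- matrix(rnorm(40 * n), 40, n) +
        outer(rep(2.2, 40), ifelse(grp == 2, 1, -1) / 2)
    blockB <- matrix(rnorm(40 * n), 40, n) +
        outer(rep(1.4, 40), ifelse(grp == 2, 1, -1) / 2)
    noise <- matrix(rnorm(60 * n), 60, n)
    m <- rbind(blockA, blockB, noise)
    dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                        sprintf("s%03d", seq_len(n)))
    ls0 <- peelLayers(m, kRange = 2:3, nPerms = 3, nResamples = 80,
                      nstart = 2, seed = 2)
    ls1 <- mergeLayers(ls0, m, nResamples = 80, seed = 3)
    expect_gte(length(rawLayers(ls1)), 2L)
    expect_identical(length(mergedLayers(ls1)), 1L)
    truthPart <- factor(stats::setNames(grp, colnames(m)))
    expect_gte(mclust::adjustedRandIndex(
        layerPartition(mergedLayers(ls1)$M1), truthPart), 0.9)
})
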