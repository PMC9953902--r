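test_that("cohort generation is a pure function of its configuration", {
    cfg <- cohortConfig(nSamples = 60L, seed = 9L)
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(exprValues(a$expr), exprValues(b$expr))
    expect_identical(a$clinical, b$clinical)
    expect_identical(a$truth, b$truth)
    # a different seed changes the data
    c <- generateCohort(cohortConfig(nSamples = 60L, seed = 10L))
    expect_false(identical(exprValues(a$expr), exprValues(c$expr)))
})

test_that("planted structure matches the configured geometry", {
    cfg <- cohortConfig(nSamples = 150L, seed = 2L)
    sim <- generateCohort(cfg)
    expect_identical(nrow(sim$expr), sum(cfg$genesPerBlock))
    expect_identical(ncol(sim$expr), 150L)
    expect_identical(sort(unique(unname(sim$truth$blocks))),
                     sort(names(cfg$genesPerBlock)))
    mem <- sim$truth$membership
    expect_identical(nrow(mem), 150L)
    expect_setequal(unique(mem$adhesion), c("low", "high"))
    expect_true(all(mem$molecular %in% 1:4))
    # noise genes carry zero loading
    expect_true(all(sim$truth$loadings[sim$truth$blocks == "noise"] == 0))

    # same-block genes correlate more than cross-block pairs on average
    v <- exprValues(correctBatchEffect(sim$expr))
    adh <- names(sim$truth$blocks)[sim$truth$blocks == "adhesion"][1:20]
    imm <- names(sim$truth$blocks)[sim$truth$blocks == "immune"][1:20]
    cc <- cor(t(v[c(adh, imm), ]))
    within <- mean(cc[1:20, 1:20][upper.tri(cc[1:20, 1:20])])
    across <- mean(cc[1:20, 21:40])
    expect_gt(within, across)

    # per-group block-gene means reflect the planted difference
    g <- adh[1]
    hi <- mean(v[g, mem$adhesion == "high"])
    lo <- mean(v[g, mem$adhesion == "low"])
    beta <- sim$truth$loadings[g]
    expect_lt(abs((hi - lo) - beta), 3 * 1 / sqrt(50))
})

test_that("null configuration produces pure batch + noise", {
    cfg <- cohortConfig(nSamples = 80L,
                        delta = c(adhesion = 0, immune = 0, molecular = 0),
                        seed = 3L)
    sim <- generateCohort(cfg)
    expect_true(all(sim$truth$loadings == 0))
    # clustering the (corrected) data cannot recover the latent groups
    v <- exprValues(correctBatchEffect(sim$expr))
    cl <- kmeans(t(v), 2, nstart = 5)$cluster
    expect_lt(abs(scorePartition(stats::setNames(cl, colnames(v)),
                                 sim$truth, "adhesion")), 0.15)
})

test_that("single-batch data makes batch correction a near-identity", {
    cfg <- cohortConfig(nSamples = 50L, nBatches = 1L, batchProps = 1,
                        seed = 5L)
    sim <- generateCohort(cfg)
    expect_lt(max(abs(exprValues(correctBatchEffect(sim$expr)) -
                      exprValues(sim$expr))), 1e-10)
})

test_that("scorePartition matches adjusted-Rand conventions", {
    cfg <- cohortConfig(nSamples = 100L, seed = 7L)
    sim <- generateCohort(cfg)
    mem <- sim$truth$membership
    ids <- mem$sample_id

    # identity up to relabeling -> ARI 1
    relab <- stats::setNames(ifelse(mem$adhesion == "high", "g1", "g2"), ids)
    expect_equal(scorePartition(relab, sim$truth, "adhesion"), 1)

    # everything merged into one group -> ARI 0
    expect_equal(scorePartition(stats::setNames(rep("one", 100), ids),
                                sim$truth, "molecular"), 0)

    # random relabelings hover near zero
    set.seed(42)
    aris <- replicate(100, {
        scorePartition(stats::setNames(sample(mem$adhesion), ids),
                       sim$truth, "adhesion")
    })
    expect_lt(max(abs(aris)), 0.1)

    expect_error(scorePartition(relab, sim$truth, "flavor"), "unknown layer")
    expect_error(scorePartition(relab[1:50], sim$truth, "adhesion"),
                 "cover all samples")
})

test_that("survival arm of the generator reflects the adhesion hazard", {
    # higher-hazard config so event counts are informative at modest n
    cfg <- cohortConfig(nSamples = 500L, lambda0 = 0.01, horizon = 60,
                        seed = 11L)
    sim <- generateCohort(cfg)
    cl <- sim$clinical
    grp <- sim$truth$membership$adhesion
    rateHigh <- mean(cl$relapse_event[grp == "high"])
    rateLow <- mean(cl$relapse_event[grp == "low"])
    expect_gt(rateHigh, rateLow)
    expect_true(all(cl$dfs_months >= 0 & cl$dfs_months <= 60))
    expect_true(all(cl$relapse_event[cl$dfs_months == 60] == 0))
})

test_that("truthGeneSets exposes the planted blocks as gene sets", {
    sim <- generateCohort(cohortConfig(nSamples = 30L, seed = 1L))
    sets <- truthGeneSets(sim$truth)
    expect_setequal(names(sets), c("adhesion", "immune", "molecular"))
    expect_identical(length(sets$molecular), 200L)
    full <- truthGeneSets(sim$truth, collapseMolecular = FALSE)
    expect_true(all(sprintf("molecular_%d", 1:4) %in% names(full)))
})
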