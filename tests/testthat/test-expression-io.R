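test_that("expression TSV round-trips at full float precision", {
    m <- toyMatrix(3, 2, seed = 1)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionMatrix(m, tmp)
    ce <- readExpressionMatrix(tmp, batch = "b1")
    expect_s4_class(ce, "CohortExperiment")
    expect_identical(dim(ce), c(3L, 2L))
    expect_identical(geneIds(ce), rownames(m))
    expect_identical(sampleIds(ce), colnames(m))
    expect_equal(exprValues(ce), m, tolerance = 0)

    big <- toyMatrix(40, 17, seed = 42)
    writeExpressionMatrix(big, tmp)
    expect_equal(exprValues(readExpressionMatrix(tmp)), big, tolerance = 0)
})

test_that("malformed expression files are rejected", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id\ts1\ts1", "g1\t1\t2", "g2\t3\t4"), tmp)
    expect_error(readExpressionMatrix(tmp), "duplicated sample")
    writeLines(c("id\ts1\ts2", "g1\t1\tx", "g2\t3\t4"), tmp)
    expect_error(readExpressionMatrix(tmp), "non-numeric")
    writeLines(c("id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), tmp)
    expect_error(readExpressionMatrix(tmp), "duplicated row")
    expect_error(readExpressionMatrix(file.path(tempdir(), "nope.tsv")),
                 "not found")
})

test_that("mergeCohorts intersects rows, concatenates samples, tracks batch", {
    a <- CohortExperiment(toyMatrix(4, 3, seed = 1), batch = "A")
    m2 <- toyMatrix(4, 2, seed = 2)
    rownames(m2) <- c("g02", "g03", "g04", "g09")
    colnames(m2) <- c("t01", "t02")
    b <- CohortExperiment(m2, batch = "B")
    merged <- mergeCohorts(list(a, b))
    expect_setequal(geneIds(merged), c("g02", "g03", "g04"))
    expect_identical(ncol(merged), 5L)
    expect_identical(batchLabels(merged), c("A", "A", "A", "B", "B"))

    # identical row sets: pure column concatenation
    c2 <- CohortExperiment(toyMatrix(4, 2, seed = 3), batch = "C")
    colnames(c2) <- c("u01", "u02")
    both <- mergeCohorts(list(a, c2))
    expect_identical(nrow(both), 4L)
    expect_identical(ncol(both), 5L)

    # merge is associative up to row order on fixed intersections
    abc1 <- mergeCohorts(list(mergeCohorts(list(a, b)), c2))
    abc2 <- mergeCohorts(list(a, mergeCohorts(list(b, c2))))
    expect_setequal(geneIds(abc1), geneIds(abc2))
    expect_equal(exprValues(abc1)[sort(geneIds(abc1)), ],
                 exprValues(abc2)[sort(geneIds(abc1)), ])

    # failure modes
    disjoint <- CohortExperiment(
        matrix(1:4, 2, 2, dimnames = list(c("zz1", "zz2"), c("w1", "w2"))),
        batch = "D")
    expect_error(mergeCohorts(list(a, disjoint)), "shared")
    clash <- CohortExperiment(toyMatrix(4, 3, seed = 4), batch = "E")
    expect_error(mergeCohorts(list(a, clash)), "collision")
})

test_that("collapseProbes keeps the most variable probe per gene", {
    set.seed(7)
    m <- rbind(p1 = rnorm(6, sd = 0.5), p2 = rnorm(6, sd = 3),
               p3 = rnorm(6, sd = 1))
    colnames(m) <- sprintf("s%d", 1:6)
    ce <- CohortExperiment(m)
    map <- c(p1 = "G1", p2 = "G1", p3 = "G2")
    out <- collapseProbes(ce, map)
    expect_setequal(geneIds(out), c("G1", "G2"))
    expect_equal(exprValues(out)["G1", ], m["p2", ])  # larger variance wins

    # one probe per gene: identity up to renaming
    one <- collapseProbes(ce, c(p1 = "A", p2 = "B", p3 = "C"))
    expect_identical(nrow(one), 3L)
    expect_equal(unname(exprValues(one)), unname(m))

    # exact variance tie: lexicographically smaller probe id survives
    tieM <- rbind(pa = c(1, 2, 3), pz = c(3, 2, 1))
    colnames(tieM) <- c("s1", "s2", "s3")
    tie <- CohortExperiment(tieM)
    out2 <- collapseProbes(tie, c(pa = "G", pz = "G"))
    expect_equal(exprValues(out2)["G", ], tieM["pa", ])

    expect_error(collapseProbes(ce, c(p1 = "G1")), "absent from the map")
})

test_that("batch-mean correction equalizes per-batch means and is idempotent", {
    # closed-form check: batch means (5, 9), grand mean 7
    v <- matrix(c(4, 6, 8, 10), 1, 4,
                dimnames = list("g1", sprintf("s%d", 1:4)))
    ce <- CohortExperiment(v, batch = c("a", "a", "b", "b"))
    out <- correctBatchEffect(ce)
    expect_equal(mean(exprValues(out)[, 1:2]), 7)
    expect_equal(mean(exprValues(out)[, 3:4]), 7)

    # random multi-batch matrix: all batch means equal after correction
    set.seed(11)
    m <- toyMatrix(20, 30, seed = 11)
    batch <- sample(c("x", "y", "z"), 30, TRUE)
    ce2 <- correctBatchEffect(CohortExperiment(m, batch = batch))
    v2 <- exprValues(ce2)
    bm <- sapply(split(seq_len(30), batch),
                 function(j) rowMeans(v2[, j, drop = FALSE]))
    expect_lt(max(apply(bm, 1, function(r) diff(range(r)))), 1e-10)
    # grand means preserved
    expect_equal(rowMeans(v2), rowMeans(m))
    # idempotent
    expect_equal(exprValues(correctBatchEffect(ce2)), v2, tolerance = 1e-12)
    # single batch: identity
    ce3 <- CohortExperiment(m, batch = "only")
    expect_equal(exprValues(correctBatchEffect(ce3)), m)
})

test_that("batch correction agrees with limma's linear-model removal", {
    skip_if_not_installed("limma")
    m <- toyMatrix(15, 24, seed = 5)
    batch <- rep(c("a", "b", "c"), times = c(10, 6, 8))
    mine <- exprValues(correctBatchEffect(CohortExperiment(m, batch = batch)))
    theirs <- limma::removeBatchEffect(m, batch = batch)
    # identical up to a per-gene constant (different intercept conventions)
    shift <- rowMeans(mine) - rowMeans(theirs)
    expect_equal(mine, theirs + shift, tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("variability filter keeps genes strictly above the SD cutoff", {
    n <- 200
    sds <- c(1.9, 2.0, 2.1)
    set.seed(3)
    m <- t(sapply(sds, function(s) {
        z <- rnorm(n)
        (z - mean(z)) / sd(z) * s         # exact sample SD
    }))
    dimnames(m) <- list(c("lo", "mid", "hi"), sprintf("s%03d", 1:n))
    ce <- CohortExperiment(m)
    kept <- filterByVariability(ce, 2)
    expect_identical(geneIds(kept), "hi")   # strict inequality drops SD == 2
    expect_identical(geneIds(filterByVariability(ce, 0)), rownames(m))
    expect_error(filterByVariability(ce, 99), "threshold")
})

test_that("clinical tables are typed, validated and mapped", {
    tmp <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,dfs_months,relapse_event,stage,location,cms",
                 "s1,12.5,1,2,proximal,CMS3",
                 "s2,40,0,9,somewhere,CMS9"), tmp)
    expect_message(cl <- readClinicalTable(tmp), "unparseable")
    expect_identical(nrow(cl), 2L)
    expect_identical(cl$stage, c(2L, NA))
    expect_identical(cl$location, c("proximal", NA))
    expect_identical(cl$cms, c("CMS3", NA))

    writeLines(c("id,dfs,event", "s1,10,yes", "s2,5,no"), tmp)
    cl2 <- readClinicalTable(tmp,
                             columnMap = c(id = "sample_id",
                                           dfs = "dfs_months",
                                           event = "relapse_event"),
                             eventMap = c(yes = 1, no = 0))
    expect_identical(cl2$relapse_event, c(1, 0))

    writeLines(c("sample_id,dfs_months,relapse_event", "s1,-3,1"), tmp)
    expect_error(readClinicalTable(tmp), "non-negative")
    writeLines(c("sample_id,dfs_months", "s1,3"), tmp)
    expect_error(readClinicalTable(tmp), "required column")
})
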