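#' Cross-tabulate two sample groupings
#'
#' Counts plus row and column percentages, used to compare discovered
#' groups with provided labels (e.g. CMS assignments or planted truth).
#' Samples with `NA` in either labeling are dropped from the table.
#'
#' @param a,b per-sample label vectors of equal length.
#' @param aName,bName dimension names for the table.
#' @return list: `counts` (table), `rowPct`, `colPct` (matrices, percent).
#' @export
crossTabulate <- function(a, b, aName = "a", bName = "b") {
    keep <- !is.na(a) & !is.na(b)
    tab <- table(a[keep], b[keep], dnn = c(aName, bName))
    list(counts = tab,
         rowPct = round(100 * prop.table(tab, 1L), 1),
         colPct = round(100 * prop.table(tab, 2L), 1))
}

defaultRunConfig <- function() {
    list(seed = 1L,
         simulate = list(),               # cohortConfig() overrides
         sdThreshold = 0,                 # synthetic data is pre-filtered
         pgm = list(maxEdges = 50L, candidates = "local",
                    targetCount = NULL, minSize = 5L, maxSize = NULL,
                    maxGenes = 200L),
         layers = list(kRange = 2:5, nPerms = 5L, nResamples = 200L,
                       subsampleFrac = 0.8, pacThreshold = 0.3,
                       minGenes = 20L, maxLayers = 9L, nstart = 3L,
                       ariThreshold = 0.6),
         sam = list(nPerms = 200L, fdrTarget = 0.05))
}

mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
            mergeConfig(base[[nm]], user[[nm]]) else user[[nm]]
    }
    base
}

#' Run the full layered-subtyping pipeline
#'
#' Orchestrates the stages in their fixed order: data acquisition
#' (synthetic simulation or files on disk), preprocessing (merge, probe
#' collapse, batch correction, variability filter), graphical model
#' (association, likelihood spanning tree, BIC forward search, branch
#' split, node activities), layer discovery (peeling + merging), per-layer
#' SAM and node-activity Kruskal-Wallis/Dunn comparisons, survival
#' stratification, and cross-tabulation of discovered groups against any
#' provided labels (CMS, planted truth). Every artifact is written under
#' `outDir` as TSV/CSV/JSON together with a JSON run manifest (config,
#' config hash, seeds, stage gene/sample counts, file inventory), and the
#' whole run is a pure function of (inputs, config, seed).
#'
#' Config entries (all optional, see the package vignette): `seed`;
#' `simulate` ([cohortConfig()] overrides) *or* `input` (list with `expr`
#' = vector of expression TSVs, optional `probeMap`, `clinical`);
#' `sdThreshold`; `pgm` (`maxGenes`, `maxEdges`, `candidates`,
#' `targetCount`, `minSize`, `maxSize`); `layers` (peeling and merge
#' controls); `sam` (`nPerms`, `fdrTarget`).
#'
#' @param config nested list, or path to a YAML file holding one.
#' @param outDir output directory (created if needed).
#' @return invisibly, a `ReportBundle` list: `expr`, `clinical`, `truth`
#'   (or `NULL`), `graph`, `nodes`, `activities`, `layerSet`, `sam`,
#'   `nodeTests`, `survival`, `crossTabs`, `manifest`.
#' @export
runPipeline <- function(config = list(), outDir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- mergeConfig(defaultRunConfig(), config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package = "layerscope",
                     version = as.character(utils::packageVersion("layerscope")),
                     seed = cfg$seed, stages = list(), files = character(0))
    writeJson <- function(x, file) {
        path <- file.path(outDir, file)
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null")
        manifest$files <<- c(manifest$files, file)
        path
    }
    writeTsv <- function(df, file) {
        path <- file.path(outDir, file)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest$files <<- c(manifest$files, file)
        path
    }
    stage <- function(name, expr) {
        out <- tryCatch(expr, error = function(e) {
            manifest$stages[[name]] <<- list(status = "error",
                                             message = conditionMessage(e))
            writeJson(manifest, "manifest.json")
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        # no wall-clock times in the manifest: identical config + seed must
        # reproduce every output file byte-identically
        manifest$stages[[name]] <<-
            c(manifest$stages[[name]], list(status = "ok"))
        out
    }
    note <- function(name, ...) {
        manifest$stages[[name]] <<- c(manifest$stages[[name]], list(...))
    }

    # --- data ---------------------------------------------------------
    truth <- NULL
    dat <- stage("data", {
        if (!is.null(cfg$input)) {
            cohorts <- lapply(cfg$input$expr, readExpressionMatrix)
            expr <- if (length(cohorts) > 1L) mergeCohorts(cohorts)
                    else cohorts[[1L]]
            if (!is.null(cfg$input$probeMap))
                expr <- collapseProbes(expr, readProbeMap(cfg$input$probeMap))
            clinical <- if (!is.null(cfg$input$clinical))
                readClinicalTable(cfg$input$clinical) else NULL
            list(expr = expr, clinical = clinical)
        } else {
            sim <- generateCohort(do.call(cohortConfig,
                                          c(cfg$simulate,
                                            if (is.null(cfg$simulate$seed))
                                                list(seed = cfg$seed))))
            truth <- sim$truth
            writeTsv(sim$truth$membership, "truth_membership.tsv")
            sim[c("expr", "clinical")]
        }
    })
    note("data", genes = nrow(dat$expr), samples = ncol(dat$expr))

    # --- preprocess ---------------------------------------------------
    expr <- stage("preprocess", {
        out <- correctBatchEffect(dat$expr)
        out <- filterByVariability(out, cfg$sdThreshold)
        writeExpressionMatrix(out, file.path(outDir, "expression.tsv"))
        manifest$files <- c(manifest$files, "expression.tsv")
        out
    })
    note("preprocess", genes = nrow(expr), samples = ncol(expr),
         sdThreshold = cfg$sdThreshold)

    # --- graphical model ----------------------------------------------
    pgm <- stage("pgm", {
        keep <- order(-rowSds(exprValues(expr)))[
            seq_len(min(cfg$pgm$maxGenes, nrow(expr)))]
        sub <- expr[sort(keep), ]
        assoc <- pairwiseAssociation(sub)
        tree <- likelihoodSpanningTree(assoc)
        graph <- forwardEdgeSearch(tree, sub, maxEdges = cfg$pgm$maxEdges,
                                   candidates = cfg$pgm$candidates)
        tc <- cfg$pgm$targetCount
        if (is.null(tc)) tc <- max(2L, round(nrow(sub) / 130))
        ms <- cfg$pgm$maxSize
        if (is.null(ms)) ms <- ceiling(1.5 * nrow(sub) / tc)
        nodes <- splitIntoBranches(graph, targetCount = tc,
                                   minSize = cfg$pgm$minSize, maxSize = ms)
        if (!is.null(truth))
            nodes <- labelFunctionalNodes(nodes, truthGeneSets(truth),
                                          geneIds(sub))
        act <- nodeActivity(sub, nodes)
        writeTsv(as.data.frame(graphEdges(graph),
                               stringsAsFactors = FALSE) |>
                     stats::setNames(c("gene1", "gene2")), "pgm_edges.tsv")
        writeTsv(data.frame(
            gene = unlist(lapply(nodes, `[[`, "genes"), use.names = FALSE),
            node = rep(names(nodes),
                       vapply(nodes, function(n) length(n$genes), integer(1))),
            label = rep(vapply(nodes, function(n)
                if (is.null(n$label)) NA_character_ else n$label,
                character(1)),
                vapply(nodes, function(n) length(n$genes), integer(1)))),
            "pgm_branches.tsv")
        writeTsv(data.frame(node = rownames(act), act, check.names = FALSE),
                 "node_activity.tsv")
        list(graph = graph, nodes = nodes, activities = act)
    })
    note("pgm", vertices = length(geneIds(pgm$graph)),
         edges = nrow(graphEdges(pgm$graph)), bic = bicValue(pgm$graph),
         branches = length(pgm$nodes))

    # --- layer discovery ----------------------------------------------
    lcfg <- cfg$layers
    layerSet <- stage("layers", {
        ls0 <- peelLayers(expr, kRange = lcfg$kRange, nPerms = lcfg$nPerms,
                          nResamples = lcfg$nResamples,
                          subsampleFrac = lcfg$subsampleFrac,
                          pacThreshold = lcfg$pacThreshold,
                          minGenes = lcfg$minGenes,
                          maxLayers = lcfg$maxLayers, nstart = lcfg$nstart,
                          seed = cfg$seed)
        ls1 <- mergeLayers(ls0, expr, ariThreshold = lcfg$ariThreshold,
                           kRange = lcfg$kRange,
                           nResamples = lcfg$nResamples,
                           subsampleFrac = lcfg$subsampleFrac,
                           nstart = lcfg$nstart, seed = cfg$seed + 7L)
        for (i in seq_along(rawLayers(ls1))) {
            ly <- rawLayers(ls1)[[i]]
            writeTsv(data.frame(gene = layerGenes(ly),
                                weight = unname(layerWeights(ly))),
                     sprintf("layer%02d_genes.tsv", i))
        }
        assign <- data.frame(sample_id = sampleIds(expr))
        for (nm in names(mergedLayers(ls1)))
            assign[[nm]] <-
                as.character(layerPartition(
                    mergedLayers(ls1)[[nm]])[assign$sample_id])
        writeTsv(assign, "merged_layer_assignments.tsv")
        writeJson(list(
            mergeMap = as.list(ls1@mergeMap),
            pac = lapply(rawLayers(ls1), function(l) as.list(l@pac))),
            "layer_diagnostics.json")
        ls1
    })
    note("layers", rawLayers = length(rawLayers(layerSet)),
         mergedLayers = length(mergedLayers(layerSet)))

    # --- per-layer statistics ------------------------------------------
    stats_ <- stage("statistics", {
        samOut <- list(); nodeTests <- list()
        for (nm in names(mergedLayers(layerSet))) {
            grp <- layerPartition(mergedLayers(layerSet)[[nm]])[
                sampleIds(expr)]
            if (any(table(grp) < 2L)) next     # SAM needs >= 2 per class
            sam <- samTest(expr, grp, nPerms = cfg$sam$nPerms,
                           fdrTarget = cfg$sam$fdrTarget,
                           seed = cfg$seed + 17L)
            samOut[[nm]] <- sam
            writeTsv(data.frame(gene = names(sam$d), d = unname(sam$d),
                                significant = names(sam$d) %in%
                                    sam$significant,
                                direction = ifelse(
                                    names(sam$d) %in% sam$significant,
                                    unname(sam$direction[names(sam$d)]),
                                    NA_character_)),
                     sprintf("sam_%s.tsv", nm))
            writeJson(list(layer = nm, s0 = sam$s0, delta = sam$delta,
                           fdr = sam$fdr, nSignificant =
                               length(sam$significant)),
                      sprintf("sam_%s_summary.json", nm))
            nodeTests[[nm]] <- lapply(rownames(pgm$activities), function(nd)
                kruskalWallisDunn(pgm$activities[nd, ], grp))
            names(nodeTests[[nm]]) <- rownames(pgm$activities)
            writeTsv(data.frame(
                node = rownames(pgm$activities),
                H = vapply(nodeTests[[nm]], `[[`, numeric(1), "H"),
                p = vapply(nodeTests[[nm]], `[[`, numeric(1), "p")),
                sprintf("node_tests_%s.tsv", nm))
        }
        list(sam = samOut, nodeTests = nodeTests)
    })

    # --- survival ------------------------------------------------------
    surv <- stage("survival", {
        if (is.null(dat$clinical)) return(NULL)
        cl <- dat$clinical
        out <- list()
        for (nm in names(mergedLayers(layerSet))) {
            grp <- layerPartition(mergedLayers(layerSet)[[nm]])[cl$sample_id]
            res <- list(km = kmEstimate(cl$dfs_months, cl$relapse_event, grp),
                        logrank = logRankTest(cl$dfs_months,
                                              cl$relapse_event, grp))
            if (nlevels(droplevels(as.factor(grp))) == 2L &&
                sum(cl$relapse_event) > 0)
                res$hr <- hazardRatio(cl$dfs_months, cl$relapse_event, grp)
            out[[nm]] <- res
            writeTsv(res$km, sprintf("km_%s.tsv", nm))
            writeJson(list(layer = nm, chisq = res$logrank$chisq,
                           p = res$logrank$p,
                           hr = if (!is.null(res$hr)) res$hr$hr,
                           ci = if (!is.null(res$hr)) res$hr$ci),
                      sprintf("survival_%s.json", nm))
        }
        out
    })

    # --- cross-tabulations --------------------------------------------
    crossTabs <- stage("crosstab", {
        out <- list()
        labelSources <- list()
        if (!is.null(dat$clinical) && any(!is.na(dat$clinical$cms)))
            labelSources$cms <- stats::setNames(dat$clinical$cms,
                                                dat$clinical$sample_id)
        if (!is.null(truth))
            for (ly in c("adhesion", "immune", "molecular"))
                labelSources[[paste0("truth_", ly)]] <-
                    stats::setNames(truth$membership[[ly]],
                                    truth$membership$sample_id)
        for (nm in names(mergedLayers(layerSet))) {
            grp <- layerPartition(mergedLayers(layerSet)[[nm]])
            for (src in names(labelSources)) {
                ct <- crossTabulate(as.character(grp[sampleIds(expr)]),
                                    labelSources[[src]][sampleIds(expr)],
                                    nm, src)
                out[[paste(nm, src, sep = "_vs_")]] <- ct
                cdf <- as.data.frame.matrix(ct$counts)
                writeTsv(cbind(group = rownames(cdf), cdf),
                         sprintf("crosstab_%s_vs_%s.tsv", nm, src))
            }
        }
        out
    })

    cfgPath <- file.path(outDir, "config.json")
    jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    manifest$files <- c(manifest$files, "config.json")
    manifest$configHash <- unname(tools::md5sum(cfgPath))
    writeJson(manifest, "manifest.json")

    invisible(list(expr = expr, clinical = dat$clinical, truth = truth,
                   graph = pgm$graph, nodes = pgm$nodes,
                   activities = pgm$activities, layerSet = layerSet,
                   sam = stats_$sam, nodeTests = stats_$nodeTests,
                   survival = surv, crossTabs = crossTabs,
                   manifest = manifest))
}
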