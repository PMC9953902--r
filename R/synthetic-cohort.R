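#' Configuration for the synthetic layered cohort generator
#'
#' The generator plants the data-generating structure that the layer-peeling
#' analysis assumes: gene blocks driven by latent per-sample group factors
#' (a binary adhesion factor, a binary immune factor, a 4-level molecular
#' factor), additive per-batch offsets, background noise genes, and
#' exponential disease-free survival whose hazard depends on the adhesion
#' group. Factors are sampled independently of each other and of batch, so
#' the layers are statistically orthogonal.
#'
#' Defaults emulate a merged resected colorectal-carcinoma cohort at desk
#' scale: 805 samples over three batches with the observed prevalences
#' (adhesion-high 351/805, immune-high 364/805, molecular groups
#' 221:137:300:147), 600 genes (100 adhesion, 100 immune, 4 x 50 molecular,
#' 200 noise), and a rare-relapse survival regime (~4.5% events with median
#' follow-up 37 months; high-adhesion hazard ratio 2.4).
#'
#' @param nSamples number of samples.
#' @param nBatches number of batches; samples are assigned with
#'   `batchProps` probabilities.
#' @param batchProps per-batch sampling proportions (length `nBatches`).
#' @param genesPerBlock named integer vector with entries `adhesion`,
#'   `immune`, `molecular_1..molecular_4`, `noise`.
#' @param delta named effect sizes (`adhesion`, `immune`, `molecular`):
#'   between-group mean difference of a block gene, in units of the residual
#'   SD `sigma`.
#' @param loadingSpread SD of the per-gene loading around its block mean,
#'   as a fraction of the block mean loading.
#' @param sigma residual (within-group) SD on the log2 scale.
#' @param batchSd SD of per-(gene, batch) additive offsets.
#' @param prevalence list of group prevalences per layer.
#' @param lambda0 baseline hazard (events/month) of the adhesion-low group.
#' @param betaSurv log hazard ratio of adhesion-high vs adhesion-low.
#' @param horizon administrative censoring horizon in months.
#' @param seed integer seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return a `CohortConfig` list.
#' @export
cohortConfig <- function(nSamples = 805L,
                         nBatches = 3L,
                         batchProps = c(177, 62, 566) / 805,
                         genesPerBlock = c(adhesion = 100L, immune = 100L,
                                           molecular_1 = 50L, molecular_2 = 50L,
                                           molecular_3 = 50L, molecular_4 = 50L,
                                           noise = 200L),
                         delta = c(adhesion = 1.5, immune = 1.2,
                                   molecular = 1.0),
                         loadingSpread = 0.2,
                         sigma = 1,
                         batchSd = 0.5,
                         prevalence = list(
                             adhesion = c(low = 454, high = 351) / 805,
                             immune = c(low = 441, high = 364) / 805,
                             molecular = c(221, 137, 300, 147) / 805),
                         lambda0 = 7.5e-4,
                         betaSurv = log(2.4),
                         horizon = 37,
                         seed = 1L) {
    blocks <- c("adhesion", "immune", paste0("molecular_", 1:4), "noise")
    gp <- genesPerBlock[blocks]
    names(gp) <- blocks
    gp[is.na(gp)] <- 0L
    stopifnot(all(gp >= 0), sigma > 0, lambda0 > 0,
              length(batchProps) == nBatches,
              abs(sum(batchProps) - 1) < 1e-8)
    for (ly in c("adhesion", "immune", "molecular")) {
        if (delta[[ly]] > 0 &&
            sum(gp[grep(paste0("^", ly), names(gp))]) == 0)
            stop("layer '", ly, "' requests signal but has zero genes")
    }
    structure(list(nSamples = as.integer(nSamples),
                   nBatches = as.integer(nBatches),
                   batchProps = batchProps, genesPerBlock = gp,
                   delta = delta, loadingSpread = loadingSpread,
                   sigma = sigma, batchSd = batchSd,
                   prevalence = prevalence, lambda0 = lambda0,
                   betaSurv = betaSurv, horizon = horizon,
                   seed = as.integer(seed)),
              class = "CohortConfig")
}

#' Generate a synthetic cohort with planted layer structure
#'
#' The expression model per gene g and sample i is
#' \deqn{x_{gi} = \mu_g + \beta_g s_{L(g)}(i) + b_{batch(i),g} + \epsilon_{gi}}
#' with \eqn{\epsilon \sim N(0, \sigma^2)}, loadings \eqn{\beta_g} drawn
#' around the block effect size, and zero loadings for noise genes. Group
#' codes are +/-1/2 for the binary layers (so the between-group difference
#' of a block gene is \eqn{\beta_g}, i.e. `delta * sigma` on average) and
#' centered one-vs-rest indicator contrasts for the four molecular blocks
#' (block m genes are elevated in molecular group m). Survival times are
#' exponential with hazard `lambda0 * exp(betaSurv * [adhesion high])`,
#' administratively censored at `horizon` months.
#'
#' @param cfg a [cohortConfig()] object.
#' @return list with elements `expr` ([CohortExperiment-class]),
#'   `clinical` (data.frame as from [readClinicalTable()]) and `truth`
#'   (list: `membership` data.frame, `blocks` per-gene assignment,
#'   `batchOffsets` matrix, `betaSurv`, `loadings`).
#' @export
generateCohort <- function(cfg) {
    stopifnot(inherits(cfg, "CohortConfig"))
    withSeed(cfg$seed, {
        n <- cfg$nSamples
        gp <- cfg$genesPerBlock
        p <- sum(gp)
        sampleIds <- sprintf("S%04d", seq_len(n))
        batch <- sprintf("batch%d", sample.int(cfg$nBatches, n, replace = TRUE,
                                               prob = cfg$batchProps))
        adhesion <- sample(c("low", "high"), n, TRUE,
                           prob = cfg$prevalence$adhesion[c("low", "high")])
        immune <- sample(c("low", "high"), n, TRUE,
                         prob = cfg$prevalence$immune[c("low", "high")])
        molecular <- sample.int(4L, n, TRUE, prob = cfg$prevalence$molecular)

        blocks <- rep(names(gp), gp)
        geneIds <- unlist(lapply(names(gp), function(b)
            sprintf("%s_g%03d", toupper(b), seq_len(gp[[b]]))),
            use.names = FALSE)

        # block mean loading = delta * sigma (between-group difference for
        # the +/- 1/2 codes); per-gene spread around it
        blockDelta <- c(adhesion = unname(cfg$delta["adhesion"]),
                        immune = unname(cfg$delta["immune"]),
                        molecular_1 = unname(cfg$delta["molecular"]),
                        molecular_2 = unname(cfg$delta["molecular"]),
                        molecular_3 = unname(cfg$delta["molecular"]),
                        molecular_4 = unname(cfg$delta["molecular"]),
                        noise = 0)
        loadMean <- blockDelta[blocks] * cfg$sigma
        loadings <- stats::rnorm(p, loadMean, abs(loadMean) * cfg$loadingSpread)
        loadings[blocks == "noise"] <- 0

        # sample-level codes per block
        pm <- cfg$prevalence$molecular
        codes <- matrix(0, nrow = p, ncol = n)
        codeFor <- function(block) {
            switch(block,
                   adhesion = ifelse(adhesion == "high", 0.5, -0.5),
                   immune = ifelse(immune == "high", 0.5, -0.5),
                   noise = rep(0, n),
                   { m <- as.integer(sub("molecular_", "", block))
                     as.numeric(molecular == m) - pm[m] })
        }
        for (b in unique(blocks))
            codes[blocks == b, ] <- matrix(codeFor(b), nrow = sum(blocks == b),
                                           ncol = n, byrow = TRUE)

        mu <- stats::rnorm(p, 7, 1)
        offsets <- matrix(stats::rnorm(p * cfg$nBatches, 0, cfg$batchSd),
                          nrow = p,
                          dimnames = list(geneIds,
                                          sprintf("batch%d",
                                                  seq_len(cfg$nBatches))))
        values <- mu + loadings * codes + offsets[, batch] +
            matrix(stats::rnorm(p * n, 0, cfg$sigma), p, n)
        dimnames(values) <- list(geneIds, sampleIds)

        rate <- cfg$lambda0 * exp(cfg$betaSurv * (adhesion == "high"))
        tEvent <- stats::rexp(n, rate)
        dfs <- pmin(tEvent, cfg$horizon)
        event <- as.numeric(tEvent <= cfg$horizon)
        clinical <- data.frame(
            sample_id = sampleIds, batch = batch,
            dfs_months = dfs, relapse_event = event,
            stage = sample.int(4L, n, TRUE, prob = c(0.2, 0.35, 0.33, 0.12)),
            location = sample(c("proximal", "distal"), n, TRUE),
            cms = sample(c(paste0("CMS", 1:4), NA), n, TRUE,
                         prob = c(0.163, 0.39, 0.12, 0.233, 0.094)),
            stringsAsFactors = FALSE)

        truth <- list(
            membership = data.frame(sample_id = sampleIds,
                                    adhesion = adhesion, immune = immune,
                                    molecular = molecular,
                                    stringsAsFactors = FALSE),
            blocks = stats::setNames(blocks, geneIds),
            batchOffsets = offsets,
            loadings = stats::setNames(loadings, geneIds),
            betaSurv = cfg$betaSurv)

        list(expr = CohortExperiment(values, batch = batch,
                                     colData = clinical[, -1L, drop = FALSE]),
             clinical = clinical, truth = truth)
    })
}

#' Score a sample partition against the planted truth
#'
#' @param partition factor/vector of group labels named by sample id (or in
#'   truth order); must cover all samples.
#' @param truth the `truth` element of [generateCohort()] output.
#' @param layer `"adhesion"`, `"immune"` or `"molecular"`.
#' @return the adjusted Rand index in `[-1, 1]`; 1 iff the partitions agree
#'   up to relabeling.
#' @export
scorePartition <- function(partition, truth, layer) {
    mem <- truth$membership
    if (!layer %in% c("adhesion", "immune", "molecular"))
        stop("unknown layer name: ", layer)
    lab <- if (!is.null(names(partition))) {
        if (!all(mem$sample_id %in% names(partition)))
            stop("partition must cover all samples")
        partition[mem$sample_id]
    } else {
        if (length(partition) != nrow(mem))
            stop("partition must cover all samples")
        partition
    }
    mclust::adjustedRandIndex(as.character(lab), as.character(mem[[layer]]))
}

#' Ground-truth gene sets of a synthetic cohort
#'
#' Returns the planted gene blocks as named gene sets (GMT-style list),
#' usable as the user-supplied sets for [hypergeometricEnrichment()].
#'
#' @param truth the `truth` element of [generateCohort()] output.
#' @param collapseMolecular merge the four molecular blocks into one set.
#' @return named list of character vectors.
#' @export
truthGeneSets <- function(truth, collapseMolecular = TRUE) {
    sets <- split(names(truth$blocks), truth$blocks)
    sets$noise <- NULL
    if (collapseMolecular) {
        mol <- grep("^molecular_", names(sets), value = TRUE)
        if (length(mol)) {
            combined <- unlist(sets[mol], use.names = FALSE)
            sets[mol] <- NULL
            sets$molecular <- combined
        }
    }
    sets
}
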