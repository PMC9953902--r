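#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Global tie-corrected Kruskal-Wallis H (chi-square, df = K-1) via
#' [stats::kruskal.test()], followed by Dunn's rank-based pairwise z tests
#' \deqn{z_{ab} = (\bar R_a - \bar R_b) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_a} +
#'   \frac{1}{n_b}\right)}}
#' with two-sided normal p-values adjusted across pairs (Bonferroni by
#' default, matching the usual "Dunn's multiple comparison test"; BH
#' available).
#'
#' @param values numeric vector (e.g. one node's activities).
#' @param groups per-sample group labels (>= 2 nonempty groups).
#' @param adjust `"bonferroni"` or `"BH"`.
#' @return S3 `MultiComparisonResult`: `H`, `df`, `p`, and `pairwise`
#'   data.frame (group pair, z, raw and adjusted p).
#' @export
kruskalWallisDunn <- function(values, groups, adjust = c("bonferroni", "BH")) {
    adjust <- match.arg(adjust)
    groups <- as.factor(droplevels(as.factor(groups)))
    if (nlevels(groups) < 2L) stop("need >= 2 groups")
    if (any(table(groups) == 0L)) stop("empty group")
    stopifnot(length(values) == length(groups))
    if (length(unique(values)) == 1L) {
        kw <- list(statistic = 0, parameter = nlevels(groups) - 1L,
                   p.value = 1)
    } else {
        kt <- stats::kruskal.test(values, groups)
        kw <- list(statistic = unname(kt$statistic),
                   parameter = unname(kt$parameter), p.value = kt$p.value)
    }
    N <- length(values)
    r <- rank(values)
    rbar <- tapply(r, groups, mean)
    sizes <- table(groups)
    ties <- table(values)
    tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2L)
    z <- apply(pairs, 2L, function(ab) {
        a <- ab[1L]; b <- ab[2L]
        sdPool <- sqrt((N * (N + 1) / 12 - tieTerm) *
                       (1 / sizes[[a]] + 1 / sizes[[b]]))
        if (sdPool == 0) return(0)
        (rbar[[a]] - rbar[[b]]) / sdPool
    })
    pRaw <- 2 * stats::pnorm(-abs(z))
    pAdj <- stats::p.adjust(pRaw, method = if (adjust == "BH") "BH"
                                           else "bonferroni")
    structure(list(H = kw$statistic, df = kw$parameter, p = kw$p.value,
                   pairwise = data.frame(group1 = pairs[1L, ],
                                         group2 = pairs[2L, ],
                                         z = z, p = pRaw, pAdjusted = pAdj,
                                         stringsAsFactors = FALSE)),
              class = "MultiComparisonResult")
}

#' @export
print.MultiComparisonResult <- function(x, ...) {
    cat(sprintf("Kruskal-Wallis H = %.4f (df = %d), p = %.4g\n",
                x$H, x$df, x$p))
    print(x$pairwise, row.names = FALSE, digits = 4)
    invisible(x)
}

#' Hypergeometric gene-set overrepresentation
#'
#' Upper-tail hypergeometric test of each gene set against a query list
#' within a universe, with Benjamini-Hochberg adjustment across sets. The
#' winning label is the set with the smallest adjusted p among those
#' overlapping the query in at least `minOverlap` genes.
#'
#' @param query character vector, a subset of `universe`.
#' @param geneSets named list of character vectors; each is intersected
#'   with the universe before testing.
#' @param universe background gene list.
#' @param minOverlap minimum overlap for a set to win (default 3).
#' @return S3 `EnrichmentResult`: `table` (set, setSize, overlap, p,
#'   pAdjusted) sorted by adjusted p, and `winner` (`NA` if none
#'   qualifies).
#' @export
hypergeometricEnrichment <- function(query, geneSets, universe,
                                     minOverlap = 3L) {
    if (!length(universe)) stop("empty universe")
    if (!length(query)) stop("empty query")
    universe <- unique(universe)
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    rows <- lapply(names(geneSets), function(nm) {
        set <- intersect(unique(geneSets[[nm]]), universe)
        ov <- length(intersect(set, query))
        p <- stats::phyper(ov - 1L, length(set),
                           length(universe) - length(set), length(query),
                           lower.tail = FALSE)
        data.frame(set = nm, setSize = length(set), overlap = ov, p = p,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$pAdjusted <- stats::p.adjust(tab$p, method = "BH")
    tab <- tab[order(tab$pAdjusted, tab$p, tab$set), , drop = FALSE]
    ok <- tab$overlap >= minOverlap
    winner <- if (any(ok)) tab$set[ok][1L] else NA_character_
    structure(list(table = tab, winner = winner), class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
    cat("EnrichmentResult: winner =",
        if (is.na(x$winner)) "<none>" else x$winner, "\n")
    print(utils::head(x$table, 10L), row.names = FALSE, digits = 4)
    invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) < 3L
    if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
    stats::setNames(lapply(parts, function(f) unique(f[-(1:2)])),
                    vapply(parts, `[[`, character(1), 1L))
}
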