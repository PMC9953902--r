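#' @importFrom survival Surv survfit survdiff coxph
NULL

checkSurvivalInput <- function(time, event, group = NULL) {
    if (any(time < 0)) stop("survival times must be non-negative")
    if (!all(event %in% c(0, 1))) stop("event must be 0/1")
    if (!is.null(group)) {
        group <- droplevels(as.factor(group))
        if (any(table(group) == 0L)) stop("empty group")
        group
    }
}

#' Kaplan-Meier disease-free-survival curves
#'
#' Product-limit estimator with right censoring (simultaneous decrement for
#' tied event times) and Greenwood standard errors, per group.
#'
#' @param time follow-up in months (>= 0).
#' @param event 1 = relapse/event, 0 = censored.
#' @param group optional per-sample group labels; `NULL` = one curve.
#' @return data.frame: `group`, `time`, `nRisk`, `nEvent`, `nCensor`,
#'   `surv`, `stdErr` (Greenwood, on the survival scale), `lower`, `upper`
#'   (log-transformed 95% CI as in [survival::survfit()]).
#' @export
kmEstimate <- function(time, event, group = NULL) {
    if (is.null(group)) group <- rep("all", length(time))
    group <- checkSurvivalInput(time, event, group)
    fit <- survfit(Surv(time, event) ~ group)
    s <- summary(fit, censored = TRUE)
    grp <- if (is.null(s$strata)) rep(levels(group)[1L], length(s$time))
           else sub("^group=", "", as.character(s$strata))
    data.frame(group = grp, time = s$time, nRisk = s$n.risk,
               nEvent = s$n.event, nCensor = s$n.censor, surv = s$surv,
               stdErr = s$std.err, lower = s$lower, upper = s$upper,
               stringsAsFactors = FALSE)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected chi-square with hypergeometric variance
#' at each event time, df = K - 1, two-sided p. Degenerate input with no
#' events returns statistic 0, p = 1.
#'
#' @inheritParams kmEstimate
#' @param group per-sample group labels (>= 2 groups).
#' @return list: `chisq`, `df`, `p`, `observed`, `expected` (named by
#'   group).
#' @export
logRankTest <- function(time, event, group) {
    group <- checkSurvivalInput(time, event, group)
    if (nlevels(group) < 2L) stop("need >= 2 groups")
    if (sum(event) == 0) {
        obs <- stats::setNames(rep(0, nlevels(group)), levels(group))
        return(list(chisq = 0, df = nlevels(group) - 1L, p = 1,
                    observed = obs, expected = obs))
    }
    sd <- survdiff(Surv(time, event) ~ group)
    nm <- sub("^group=", "", names(sd$n))
    list(chisq = unname(sd$chisq), df = length(sd$n) - 1L,
         p = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE),
         observed = stats::setNames(as.vector(sd$obs), nm),
         expected = stats::setNames(as.vector(sd$exp), nm))
}

#' Hazard ratio between two groups
#'
#' Default estimate is the Mantel-Haenszel ratio from the log-rank table,
#' HR = (O2/E2)/(O1/E1) with group 1 the reference, and 95% CI
#' \eqn{\exp(\ln HR \pm 1.96 \sqrt{1/E_1 + 1/E_2})}. A Cox
#' partial-likelihood estimate (Efron ties) is reported alongside.
#' Swapping the reference group inverts the HR and its CI.
#'
#' @inheritParams kmEstimate
#' @param group per-sample labels with exactly 2 groups.
#' @param reference the reference group (denominator hazard); default the
#'   first factor level.
#' @return S3 `LogRankHR`: `hr`, `ci` (length 2), `chisq`, `p` (log-rank),
#'   `coxHr`, `coxCi`, `reference`, `comparison`.
#' @export
hazardRatio <- function(time, event, group, reference = NULL) {
    group <- checkSurvivalInput(time, event, group)
    if (nlevels(group) != 2L) stop("hazardRatio needs exactly 2 groups")
    if (is.null(reference)) reference <- levels(group)[1L]
    if (!reference %in% levels(group)) stop("unknown reference group")
    group <- stats::relevel(group, ref = reference)
    lr <- logRankTest(time, event, group)
    O <- lr$observed[levels(group)]
    E <- lr$expected[levels(group)]
    if (any(E == 0)) stop("a group has zero expected events")
    hr <- (O[2L] / E[2L]) / (O[1L] / E[1L])
    seLog <- sqrt(1 / E[1L] + 1 / E[2L])
    ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * seLog)
    cox <- coxph(Surv(time, event) ~ group, ties = "efron")
    coxHr <- unname(exp(stats::coef(cox)))
    coxCi <- unname(exp(stats::confint(cox)))
    structure(list(hr = unname(hr), ci = unname(ci), chisq = lr$chisq,
                   p = lr$p, coxHr = coxHr, coxCi = as.vector(coxCi),
                   reference = reference,
                   comparison = levels(group)[2L]),
              class = "LogRankHR")
}

#' @export
print.LogRankHR <- function(x, ...) {
    cat(sprintf("HR (%s vs %s) = %.3f, 95%% CI (%.3f-%.3f); log-rank p = %.4g\n",
                x$comparison, x$reference, x$hr, x$ci[1L], x$ci[2L], x$p))
    cat(sprintf("  Cox HR = %.3f, 95%% CI (%.3f-%.3f)\n",
                x$coxHr, x$coxCi[1L], x$coxCi[2L]))
    invisible(x)
}
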