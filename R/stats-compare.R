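## Representativeness statistics: per-subject two-sample KS statistics for
## nodal metric distributions, z-scores for global metrics, Welch t and
## one-way ANOVA (with eta-squared effect size) across group networks, and
## Bonferroni correction.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Exact supremum of the absolute difference between the two empirical
#' distribution functions (no continuity correction); only the statistic,
#' not a p-value, feeds the representativeness comparisons.
#'
#' @param a,b numeric samples.
#' @return statistic in [0, 1].
#' @export
ksStatistic <- function(a, b) {
    if (!length(a) || !length(b)) stop("empty sample")
    w <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(w) - stats::ecdf(b)(w)))
}

#' Mean per-subject KS statistic for a nodal metric
#'
#' The KS statistic between the group network's nodal-metric distribution
#' and each subject's, averaged over subjects; lower means closer
#' correspondence to the cohort.
#'
#' @param groupValues per-node metric values of the group network.
#' @param cohortValues list of per-node value vectors, one per subject.
#' @return list with \code{mean}, \code{sd} (sample SD over subjects, 0 for
#'   a single subject) and \code{perSubject}.
#' @export
meanKS <- function(groupValues, cohortValues) {
    if (!length(cohortValues)) stop("no subject value sets")
    ks <- vapply(cohortValues, ksStatistic, numeric(1), a = groupValues)
    list(mean = mean(ks),
         sd = if (length(ks) > 1L) stats::sd(ks) else 0,
         perSubject = ks)
}

#' z-score of a group-level global metric against the cohort
#'
#' (group value - subject mean) / subject sample SD; small absolute values
#' indicate similarity to the cohort.
#'
#' @param groupValue scalar metric of the group network.
#' @param subjectValues per-subject metric values (>= 2).
#' @return scalar z (signed infinity with a warning when the subject SD is
#'   zero and the group deviates).
#' @export
globalZscore <- function(groupValue, subjectValues) {
    if (length(subjectValues) < 2L) stop("need at least 2 subject values")
    s <- stats::sd(subjectValues)
    delta <- groupValue - mean(subjectValues)
    if (s == 0) {
        if (delta == 0) return(0)
        warning("zero subject SD: z-score is infinite")
        return(sign(delta) * Inf)
    }
    delta / s
}

#' Welch's t-test
#'
#' Two-sided Welch statistic with Satterthwaite degrees of freedom
#' (unequal-variance two-sample comparison).
#'
#' @param a,b numeric samples of size >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchT <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
    fit <- stats::t.test(a, b, var.equal = FALSE)
    list(t = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value)
}

#' One-way ANOVA with eta-squared effect size
#'
#' Standard one-way F across groups with eta^2 = SS_between / SS_total
#' (e.g. 4 groups of 40 observations give df (3, 156)).
#'
#' @param groups list of numeric samples (>= 2 groups, each >= 2 values).
#' @return list with \code{F}, \code{dfBetween}, \code{dfWithin}, \code{p},
#'   \code{etaSq}.
#' @export
onewayAnovaEta <- function(groups) {
    if (length(groups) < 2L) stop("need at least 2 groups")
    if (any(lengths(groups) < 2L)) stop("each group needs >= 2 observations")
    dat <- data.frame(
        y = unlist(groups, use.names = FALSE),
        g = factor(rep(seq_along(groups), lengths(groups))))
    tab <- stats::anova(stats::aov(y ~ g, data = dat))
    ssb <- tab[["Sum Sq"]][1L]
    ssw <- tab[["Sum Sq"]][2L]
    list(F = tab[["F value"]][1L],
         dfBetween = tab[["Df"]][1L],
         dfWithin = tab[["Df"]][2L],
         p = tab[["Pr(>F)"]][1L],
         etaSq = ssb / (ssb + ssw))
}

#' Bonferroni significance flags
#'
#' Flags p_i < alpha / m where m is the number of comparisons in the family
#' (defaults to the number of p-values supplied).
#'
#' @param pValues numeric p-values in [0, 1].
#' @param alpha nominal family-wise level.
#' @param m number of comparisons.
#' @return logical vector.
#' @export
bonferroni <- function(pValues, alpha = 0.01, m = length(pValues)) {
    stopifnot(all(pValues >= 0 & pValues <= 1))
    pValues < alpha / m
}

#' Across-group ANOVA of dynamical distances to the subjects
#'
#' For each group network, the per-subject squared Euclidean distances
#' between its metastability profile and the subjects' profiles
#' ([profileSqEuclid()]); a one-way ANOVA (with eta^2) across group
#' networks; and Bonferroni-corrected pairwise Welch post-hocs. Group
#' profiles are paired with the subject profiles via the shared simulation
#' seed.
#'
#' @param groupNetworks named list of \linkS4class{BinaryConnectome}s (>= 2).
#' @param subjectProfiles list of subject profiles.
#' @param grid coupling grid the profiles share.
#' @param config \linkS4class{SimulationConfig} used for the subject
#'   profiles.
#' @param alpha nominal level for the post-hoc flags.
#' @return list with \code{distances} (subjects x groups matrix),
#'   \code{anova} (see [onewayAnovaEta()]) and \code{pairwise} (data.frame
#'   of Welch contrasts with Bonferroni flags; m = number of pairs).
#' @export
dynamicalAnova <- function(groupNetworks, subjectProfiles,
                           grid = couplingGrid(),
                           config = simulationConfig(), alpha = 0.01) {
    if (length(groupNetworks) < 2L) stop("need at least 2 group networks")
    if (is.null(names(groupNetworks))) {
        names(groupNetworks) <- paste0("group", seq_along(groupNetworks))
    }
    dist_mat <- vapply(groupNetworks, function(net) {
        gp <- metastabilityProfile(net, grid, config)
        vapply(subjectProfiles, profileSqEuclid, numeric(1),
               groupProfile = gp)
    }, numeric(length(subjectProfiles)))
    groups <- lapply(seq_len(ncol(dist_mat)), function(j) dist_mat[, j])
    fit <- onewayAnovaEta(groups)
    pairs <- utils::combn(length(groups), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        w <- welchT(groups[[i]], groups[[j]])
        data.frame(group_a = names(groupNetworks)[i],
                   group_b = names(groupNetworks)[j],
                   t = w$t, df = w$df, p = w$p)
    }))
    pw$significant <- bonferroni(pw$p, alpha = alpha, m = nrow(pw))
    list(distances = dist_mat, anova = fit, pairwise = pw)
}
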