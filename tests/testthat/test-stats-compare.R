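test_that("the KS statistic is the ECDF sup-difference", {
    expect_equal(ksStatistic(1:4, 1:4), 0)
    expect_equal(ksStatistic(1:4, 5:8), 1)  # disjoint supports
    expect_equal(ksStatistic(c(1, 2), c(1, 3)), 0.5)
    # symmetry and invariance under a common monotone transform
    withr::with_seed(20, {
        a <- rnorm(30); b <- rnorm(25, 0.5)
    })
    expect_equal(ksStatistic(a, b), ksStatistic(b, a))
    expect_equal(ksStatistic(exp(a), exp(b)), ksStatistic(a, b))
    expect_error(ksStatistic(numeric(0), 1), "empty")
})

test_that("mean KS aggregates per-subject statistics", {
    g <- c(1, 2, 3, 4)
    same <- list(g, g, g)
    res <- meanKS(g, same)
    expect_equal(res$mean, 0)
    expect_equal(res$sd, 0)
    mixed <- list(g, g + 10)
    res2 <- meanKS(g, mixed)
    expect_equal(res2$perSubject, c(0, 1))
    expect_equal(res2$mean, 0.5)
    expect_equal(res2$sd, sd(c(0, 1)))
    expect_error(meanKS(g, list()), "subject")
})

test_that("global z-scores standardise by the subject sample SD", {
    expect_equal(globalZscore(2, c(1, 2, 3)), 0)
    expect_equal(globalZscore(3, c(1, 2, 3)), 1)
    expect_equal(globalZscore(1, c(1, 2, 3)), -1)
    expect_warning(z <- globalZscore(1, c(2, 2, 2)), "zero")
    expect_identical(z, -Inf)
    expect_equal(globalZscore(2, c(2, 2)), 0)
})

test_that("Welch and ANOVA statistics agree with direct computation", {
    expect_equal(welchT(c(1, 2, 3), c(1, 2, 3)),
                 list(t = 0, df = 4, p = 1))
    withr::with_seed(22, {
        for (i in 1:20) {
            a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
            b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
            w <- welchT(a, b)
            # Welch-Satterthwaite reference from first principles
            va <- var(a) / length(a); vb <- var(b) / length(b)
            tRef <- (mean(a) - mean(b)) / sqrt(va + vb)
            dfRef <- (va + vb)^2 /
                (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
            expect_equal(w$t, tRef, tolerance = 1e-10)
            expect_equal(w$df, dfRef, tolerance = 1e-10)
            expect_equal(w$p, 2 * pt(-abs(tRef), dfRef), tolerance = 1e-10)

            groups <- lapply(1:4, function(g) rnorm(sample(5:30, 1),
                                                    mean = runif(1, 0, 1)))
            fit <- onewayAnovaEta(groups)
            # brute-force sums of squares
            all <- unlist(groups)
            ssb <- sum(lengths(groups) *
                       (vapply(groups, mean, numeric(1)) - mean(all))^2)
            sst <- sum((all - mean(all))^2)
            dfb <- 3; dfw <- length(all) - 4
            fRef <- (ssb / dfb) / ((sst - ssb) / dfw)
            expect_equal(fit$F, fRef, tolerance = 1e-10)
            expect_equal(fit$etaSq, ssb / sst, tolerance = 1e-10)
            expect_equal(fit$p, pf(fRef, dfb, dfw, lower.tail = FALSE),
                         tolerance = 1e-10)
            # eta^2 from F and dfs must agree with the SS ratio
            etaFromF <- fit$F * dfb / (fit$F * dfb + dfw)
            expect_equal(fit$etaSq, etaFromF, tolerance = 1e-12)

            # KS cross-check against the reference implementation
            expect_equal(ksStatistic(a, b),
                         unname(suppressWarnings(
                             ks.test(a, b)$statistic)),
                         tolerance = 1e-10)
        }
    })
})

test_that("ANOVA on four groups of forty has df (3, 156)", {
    withr::with_seed(23, {
        groups <- lapply(1:4, function(g) rnorm(40, mean = g / 10))
    })
    fit <- onewayAnovaEta(groups)
    expect_equal(fit$dfBetween, 3)
    expect_equal(fit$dfWithin, 156)
    same <- lapply(1:3, function(g) c(1, 2, 3))
    expect_equal(onewayAnovaEta(same)$F, 0)
    expect_equal(onewayAnovaEta(same)$etaSq, 0)
    expect_error(onewayAnovaEta(list(1:3)), "2 groups")
})

test_that("Bonferroni flags compare p-values to alpha over m", {
    expect_true(bonferroni(0.009, alpha = 0.01))  # m = 1 keeps alpha
    expect_equal(bonferroni(c(0.001, 0.005, 0.5, 0.0001, 0.002, 0.9),
                            alpha = 0.01),
                 c(0.001, 0.005, 0.5, 0.0001, 0.002, 0.9) < 0.01 / 6)
    expect_true(bonferroni(0.001, alpha = 0.01, m = 6))
    expect_false(bonferroni(0.005, alpha = 0.01, m = 6))
    expect_error(bonferroni(1.2), "pValues")
})

test_that("the dynamical ANOVA separates an unrepresentative group network", {
    withr::with_seed(25, {
        res <- generateCohort(cohortSpec(nSubjects = 8, nNodes = 15,
                                         targetDensity = 0.5,
                                         flipCountMean = 6, flipCountSD = 2,
                                         rngSeed = 25))
    })
    cfg <- tinySimConfig(rngSeed = 8)
    grid <- couplingGrid(0, 3, 0.5)
    profs <- lapply(members(res$cohort), metastabilityProfile,
                    grid = grid, config = cfg)
    sparse <- edgeNet(15, c(1, 2), nodeTable(res$cohort))
    groups <- list(seed = res$groundTruth,
                   union = uniformConsensus(res$cohort, 100 / 8),
                   near_empty = sparse)
    out <- dynamicalAnova(groups, profs, grid, cfg, alpha = 0.01)
    expect_equal(dim(out$distances), c(8, 3))
    expect_equal(nrow(out$pairwise), 3)
    # the near-empty graph dominates the distances and is flagged
    expect_gt(mean(out$distances[, "near_empty"]),
              mean(out$distances[, "seed"]))
    flagged <- out$pairwise$significant[
        out$pairwise$group_b == "near_empty" |
        out$pairwise$group_a == "near_empty"]
    expect_true(any(flagged))
})
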