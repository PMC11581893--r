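test_that("edge prevalence sums member adjacencies", {
    m1 <- edgeNet(4, c(1, 2, 1, 3))
    m2 <- edgeNet(4, c(1, 2, 2, 3))
    m3 <- edgeNet(4, c(1, 2))
    cohort <- connectomeCohort(list(m1, m2, m3))
    prev <- edgePrevalence(cohort)
    expect_equal(prev[1, 2], 3)
    expect_equal(prev[1, 3], 1)
    expect_equal(prev[2, 3], 1)
    expect_equal(prev[1, 4], 0)

    same <- connectomeCohort(list(m1, m1, m1, m1))
    expect_true(all(edgePrevalence(same) %in% c(0, 4)))

    wc <- connectomeCohort(list(weightedConnectome(adjacency(m1) * 2)))
    expect_error(edgePrevalence(wc), "binarize")
})

test_that("prevalence histogram is a normalised pair distribution", {
    m1 <- edgeNet(4, c(1, 2, 1, 3))
    m2 <- edgeNet(4, c(1, 2, 2, 3))
    m3 <- edgeNet(4, c(1, 2))
    cohort <- connectomeCohort(list(m1, m2, m3))
    h <- prevalenceHistogram(edgePrevalence(cohort), 3)
    # 6 pairs: counts {3:(1,2)}, {1:(1,3),(2,3)}, {0: three pairs}
    expect_equal(h$fraction_pairs, c(3, 2, 0, 1) / 6)
    expect_equal(sum(h$fraction_pairs), 1)

    # identical members at density rho: mass rho at level n, 1 - rho at 0
    same <- connectomeCohort(list(m1, m1))
    h2 <- prevalenceHistogram(edgePrevalence(same), 2)
    rho <- edgeDensity(m1)
    expect_equal(h2$fraction_pairs[c(1, 3)], c(1 - rho, rho))

    empty <- connectomeCohort(list(edgeNet(4, integer(0))))
    h3 <- prevalenceHistogram(edgePrevalence(empty), 1)
    expect_equal(h3$fraction_pairs, c(1, 0))
})

test_that("uniform consensus applies the ceiling subject-count rule", {
    # n = 40 members; one edge present in 17 members, another in 16
    members <- lapply(1:40, function(i) {
        edges <- c(if (i <= 17) c(1, 2), if (i <= 16) c(3, 4), c(1, 4))
        edgeNet(4, edges)
    })
    cohort <- connectomeCohort(members)
    g <- uniformConsensus(cohort, 42.5)
    expect_equal(adjacency(g)[1, 2], 1)  # 17/40 retained at 42.5%
    expect_equal(adjacency(g)[3, 4], 0)  # 16/40 dropped
    expect_equal(adjacency(g)[1, 4], 1)

    # T = 100/n keeps the union; T = 100 the intersection
    prev <- edgePrevalence(cohort)
    expect_identical(adjacency(uniformConsensus(cohort, 2.5)),
                     (prev >= 1) + 0)
    expect_identical(adjacency(uniformConsensus(cohort, 100)),
                     (prev >= 40) + 0)
    expect_error(uniformConsensus(cohort, 0), "threshold")
    expect_error(uniformConsensus(cohort, 101), "threshold")
})

test_that("a quoted two-of-three threshold keeps majority edges", {
    m1 <- edgeNet(4, c(1, 2, 1, 3))
    m2 <- edgeNet(4, c(1, 2, 2, 3))
    m3 <- edgeNet(4, c(1, 2, 2, 3))
    cohort <- connectomeCohort(list(m1, m2, m3))
    g <- uniformConsensus(cohort, 66.7)
    prev <- edgePrevalence(cohort)
    expect_identical(adjacency(g), (prev >= 2) + 0)  # brute-force reference
})

test_that("the ladder has one nested network per subject", {
    withr::with_seed(21, {
        cohort <- randomCohort(12, 15)
    })
    ladder <- buildLadder(cohort)
    expect_equal(thresholds(ladder), (1:12) * 100 / 12)
    nets <- members(ladder)
    for (k in 2:length(nets)) {
        expect_true(all(adjacency(nets[[k]]) <= adjacency(nets[[k - 1]])))
    }
    # union and intersection bound every rung
    expect_identical(adjacency(nets[[1]]),
                     (edgePrevalence(cohort) >= 1) + 0)

    one <- buildLadder(connectomeCohort(list(cohort[[1]])))
    expect_equal(thresholds(one), 100)
    expect_identical(adjacency(members(one)[[1]]), adjacency(cohort[[1]]))

    same <- connectomeCohort(list(cohort[[1]], cohort[[1]], cohort[[1]]))
    lsame <- buildLadder(same)
    for (net in members(lsame)) {
        expect_identical(adjacency(net), adjacency(cohort[[1]]))
    }
})

test_that("euclidean distances are metric and match hand geometry", {
    nodes <- defaultNodeTable(3)
    nodes$x <- c(0, 3, 0); nodes$y <- c(0, 4, 0); nodes$z <- 0
    D <- euclideanDistanceMatrix(nodes)
    expect_equal(D[1, 2], 5)  # 3-4-5 triangle
    expect_equal(D[1, 3], 0)  # coincident centroids
    expect_equal(diag(D), rep(0, 3))

    withr::with_seed(4, {
        rn <- defaultNodeTable(10)
        rn$x <- runif(10, -70, 70); rn$y <- runif(10, -100, 70)
        rn$z <- runif(10, -50, 80)
        DR <- euclideanDistanceMatrix(rn)
        for (i in 1:10) for (j in 1:10) for (k in 1:10) {
            expect_lte(DR[i, k], DR[i, j] + DR[j, k] + 1e-12)
        }
    })
})

test_that("distance-dependent consensus reproduces an identical cohort", {
    withr::with_seed(8, {
        net <- randomCohort(1, 16, density = 0.5)[[1]]
    })
    cohort <- connectomeCohort(list(net, net, net))
    out <- distanceDependentConsensus(cohort, nBins = 5)
    expect_identical(adjacency(out), adjacency(net))
})

test_that("distance-dependent consensus keeps the m most prevalent, shortest-first", {
    # one hemisphere, one bin: prevalences {2, 1, 1}, m = round(4/2) = 2
    nodes <- defaultNodeTable(4)
    nodes$hemisphere <- "left"
    nodes$x <- c(0, 1, 10, 30); nodes$y <- 0; nodes$z <- 0
    s1 <- edgeNet(4, c(1, 2, 1, 3, 1, 4), nodes)  # lengths 1, 10, 30
    s2 <- edgeNet(4, c(1, 2), nodes)
    out <- distanceDependentConsensus(connectomeCohort(list(s1, s2)),
                                      nBins = 1)
    A <- adjacency(out)
    expect_equal(A[1, 2], 1)  # prevalence 2
    expect_equal(A[1, 3], 1)  # shorter of the two prevalence-1 edges
    expect_equal(A[1, 4], 0)
})

test_that("distance-dependent output density tracks the cohort mean", {
    withr::with_seed(31, {
        res <- generateCohort(cohortSpec(nSubjects = 12, nNodes = 40,
                                         targetDensity = 0.45,
                                         flipCountMean = 60,
                                         flipCountSD = 15, rngSeed = 31))
    })
    cohort <- res$cohort
    nBins <- 41
    out <- distanceDependentConsensus(cohort, nBins = nBins)
    meanDensity <- mean(vapply(members(cohort), edgeDensity, numeric(1)))
    N <- nNodes(cohort)
    slack <- nBins * 2 / (N * (N - 1)) + 1 / (N * (N - 1) / 2)
    expect_lte(abs(edgeDensity(out) - meanDensity), slack)

    # no pair absent from every member is ever retained
    expect_true(all(adjacency(out) <= edgePrevalence(cohort)))
})

test_that("consistency thresholding ranks by coefficient of variation", {
    # pair (1,2): weights (10, 10, 10) -> CV 0; pair (1,3): (10, 20, 30) -> CV 0.5
    mk <- function(w12, w13) {
        A <- matrix(0, 3, 3)
        A[1, 2] <- A[2, 1] <- w12
        A[1, 3] <- A[3, 1] <- w13
        weightedConnectome(A)
    }
    cohort <- connectomeCohort(list(mk(10, 10), mk(10, 20), mk(10, 30)))
    one <- consistencyConsensus(cohort, targetDensity = 1 / 3)
    expect_equal(adjacency(one)[1, 2], 1)
    expect_equal(adjacency(one)[1, 3], 0)

    # requested density is honoured exactly
    withr::with_seed(13, {
        wm <- lapply(1:5, function(i) {
            A <- matrix(0, 12, 12)
            ut <- upper.tri(A)
            A[ut] <- rexp(sum(ut)) * rbinom(sum(ut), 1, 0.7)
            weightedConnectome(A + t(A))
        })
    })
    wcoh <- connectomeCohort(wm)
    out <- consistencyConsensus(wcoh, targetDensity = 0.4)
    expect_equal(sum(adjacency(out)) / 2, floor(0.4 * 12 * 11 / 2))

    # infeasible request keeps every present pair, with a warning
    sparse <- connectomeCohort(list(mk(1, 0), mk(1, 0)))
    expect_warning(all3 <- consistencyConsensus(sparse, 1), "nonzero mean")
    expect_equal(sum(adjacency(all3)) / 2, 1)
})

test_that("consistency thresholding of identical members recovers the member", {
    withr::with_seed(17, {
        A <- matrix(0, 10, 10)
        ut <- which(upper.tri(A))
        on <- sample(ut, 20)
        A[on] <- runif(20, 1, 50)
        A <- A + t(A)
    })
    w <- weightedConnectome(A)
    cohort <- connectomeCohort(list(w, w, w))
    out <- consistencyConsensus(cohort, targetDensity = edgeDensity(w))
    expect_identical(adjacency(out), adjacency(binarize(w)))
})
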