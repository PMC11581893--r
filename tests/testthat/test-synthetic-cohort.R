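test_that("zero flip noise reproduces the seed in every member", {
    res <- generateCohort(cohortSpec(nSubjects = 4, nNodes = 15,
                                     flipCountMean = 0, flipCountSD = 0,
                                     rngSeed = 3))
    for (m in members(res$cohort)) {
        expect_identical(adjacency(m), adjacency(res$groundTruth))
    }
})

test_that("member distance to the seed equals the drawn flip count", {
    res <- generateCohort(cohortSpec(nSubjects = 10, nNodes = 25,
                                     flipCountMean = 12, flipCountSD = 4,
                                     rngSeed = 11))
    d <- vapply(members(res$cohort), manhattanDistance, numeric(1),
                b = res$groundTruth)
    expect_equal(d, res$flipCounts)
    # full-matrix count is twice the upper-triangle count, by symmetry
    full <- sum(abs(adjacency(res$cohort[[1]]) -
                    adjacency(res$groundTruth)))
    expect_equal(full, 2 * res$flipCounts[1])
})

test_that("generated members are symmetric, hollow, and keep the core", {
    res <- generateCohort(cohortSpec(nSubjects = 8, nNodes = 20,
                                     flipCountMean = 30, flipCountSD = 10,
                                     coreFraction = 0.3, rngSeed = 5))
    core <- res$coreEdges
    expect_equal(nrow(core),
                 floor(0.3 * sum(adjacency(res$groundTruth)) / 2))
    for (m in members(res$cohort)) {
        A <- adjacency(m)
        expect_true(all(A == t(A)))
        expect_true(all(diag(A) == 0))
        expect_true(all(A[core] == 1))
    }
})

test_that("a fully immutable complete seed admits no rewiring", {
    seed <- completeNet(6)
    res <- suppressWarnings(generateCohort(
        cohortSpec(nSubjects = 3, seedNetwork = seed, flipCountMean = 5,
                   flipCountSD = 0, coreFraction = 1, rngSeed = 2)))
    for (m in members(res$cohort)) {
        expect_identical(adjacency(m), adjacency(seed))
    }
})

test_that("cohort generation is reproducible from its seed", {
    spec <- cohortSpec(nSubjects = 4, nNodes = 18, rngSeed = 9,
                       flipCountMean = 10, flipCountSD = 2)
    a <- generateCohort(spec)
    b <- generateCohort(spec)
    expect_identical(lapply(members(a$cohort), adjacency),
                     lapply(members(b$cohort), adjacency))
    expect_identical(a$coreEdges, b$coreEdges)
})

test_that("Manhattan distance counts differing upper-triangle entries", {
    a <- edgeNet(3, c(1, 2))
    b <- edgeNet(3, c(1, 2, 2, 3))
    expect_equal(manhattanDistance(a, a), 0)
    expect_equal(manhattanDistance(a, b), 1)
    n <- 7
    expect_equal(manhattanDistance(edgeNet(n, integer(0)), completeNet(n)),
                 n * (n - 1) / 2)
    expect_error(manhattanDistance(a, completeNet(4)), "mismatch")
})

test_that("pairwise flip statistics give the mean and sample SD over pairs", {
    # three members at pairwise distances {2, 4, 6}: disjoint flip sets
    base <- edgeNet(10, c(1, 2, 3, 4, 5, 6))
    m2 <- adjacency(base); m2[1, 3] <- m2[3, 1] <- 1; m2[2, 4] <- m2[4, 2] <- 1
    m3 <- adjacency(base)
    for (e in list(c(5, 7), c(6, 8), c(7, 9), c(8, 10))) {
        m3[e[1], e[2]] <- m3[e[2], e[1]] <- 1
    }
    cohort <- connectomeCohort(list(base, binaryConnectome(m2),
                                    binaryConnectome(m3)))
    st <- pairwiseFlipStatistics(cohort)
    expect_equal(st$mean, 4)
    expect_equal(st$sd, 2)

    same <- connectomeCohort(list(base, base, base))
    expect_equal(pairwiseFlipStatistics(same), list(mean = 0, sd = 0))

    two <- connectomeCohort(list(base, binaryConnectome(m2)))
    expect_warning(st2 <- pairwiseFlipStatistics(two), "single")
    expect_equal(st2, list(mean = 2, sd = 0))
    expect_error(pairwiseFlipStatistics(connectomeCohort(list(base))),
                 "at least 2")
})

test_that("nearest member search sorts distances and breaks ties low", {
    seed <- edgeNet(8, c(1, 2, 2, 3, 3, 4))
    far <- adjacency(seed)
    for (e in list(c(1, 5), c(2, 6), c(3, 7))) {
        far[e[1], e[2]] <- far[e[2], e[1]] <- 1
    }
    pool <- list(seed, binaryConnectome(far), seed)
    res <- nearestMember(seed, pool)
    expect_equal(res$index, 1)  # tie with member 3 resolved to lowest index
    expect_equal(res$distance, 0)
    expect_equal(res$table$distance, c(0, 0, 3))
    expect_error(nearestMember(seed, list()), "empty")

    near <- adjacency(seed); near[1, 8] <- near[8, 1] <- 1
    res2 <- nearestMember(binaryConnectome(near), list(binaryConnectome(far), seed))
    expect_equal(res2$index, 2)
})

test_that("flip counts clip at the mutable-entry budget with a warning", {
    w <- capture_warnings(
        res <- generateCohort(cohortSpec(nSubjects = 2, nNodes = 6,
                                         flipCountMean = 500,
                                         flipCountSD = 0, rngSeed = 4)))
    expect_match(w, "clipped", all = TRUE)
    expect_length(w, 2)  # one clip warning per member
    M <- 6 * 5 / 2 - nrow(res$coreEdges)
    expect_true(all(res$flipCounts == M))
})
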