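## Ground-truth-anchored synthetic cohorts: each member is the seed network
## with k randomly toggled node pairs (k ~ round Normal, drawn per subject),
## excluding an immutable core of seed edges. Because flips are sampled
## without replacement, a member's Manhattan distance to the seed equals its
## drawn flip count exactly.

#' Synthetic cohort generation parameters
#'
#' Defaults emulate the validation setting: 40 subjects over 82 nodes, a seed
#' (ground-truth) network at density 0.59, per-subject flip counts drawn from
#' round(Normal(75, 15)) and clipped to the mutable range, and a randomly
#' chosen immutable core of 30\% of the seed's edges that no member may lose.
#'
#' @param nSubjects cohort size (>= 1).
#' @param nNodes number of nodes (used when \code{seedNetwork} is NULL).
#' @param seedNetwork optional \linkS4class{BinaryConnectome} ground truth;
#'   when NULL an Erd\enc{ő}{o}s--R\enc{é}{e}nyi G(n, m) network at
#'   \code{targetDensity} is drawn.
#' @param targetDensity density of the generated seed network.
#' @param flipCountMean,flipCountSD mean and SD of the per-subject Normal
#'   flip-count draw (upper-triangle entries toggled).
#' @param coreFraction fraction of the seed's edges frozen for all members.
#' @param rngSeed integer seed; all randomness in the generator flows from it.
#' @return a list with class \code{CohortSpec}.
#' @seealso [generateCohort()]
#' @export
cohortSpec <- function(nSubjects = 40L, nNodes = 82L, seedNetwork = NULL,
                       targetDensity = 0.59, flipCountMean = 75,
                       flipCountSD = 15, coreFraction = 0.3, rngSeed = 1L) {
    if (nSubjects < 1L) stop("nSubjects must be >= 1")
    if (is.null(seedNetwork)) {
        if (nNodes < 2L) stop("nNodes must be >= 2")
        if (targetDensity <= 0 || targetDensity > 1) {
            stop("targetDensity must be in (0, 1]")
        }
    } else {
        stopifnot(is(seedNetwork, "BinaryConnectome"))
        if (sum(adjacency(seedNetwork)) == 0) {
            stop("seed network must have at least one edge")
        }
    }
    if (flipCountMean < 0 || flipCountSD < 0) {
        stop("flip count mean and SD must be >= 0")
    }
    if (coreFraction < 0 || coreFraction > 1) {
        stop("coreFraction must be in [0, 1]")
    }
    structure(list(nSubjects = as.integer(nSubjects),
                   nNodes = as.integer(nNodes),
                   seedNetwork = seedNetwork,
                   targetDensity = targetDensity,
                   flipCountMean = flipCountMean,
                   flipCountSD = flipCountSD,
                   coreFraction = coreFraction,
                   rngSeed = as.integer(rngSeed)),
              class = "CohortSpec")
}

## Erdős–Rényi G(n, m) binary connectome with m = round(density * n(n-1)/2),
## drawn from the current RNG stream.
randomSeedNetwork <- function(nNodes, targetDensity, nodes = NULL) {
    npairs <- nNodes * (nNodes - 1L) / 2L
    m <- max(1L, round(targetDensity * npairs))
    picked <- sample.int(npairs, m)
    A <- matrix(0, nNodes, nNodes)
    ut <- which(upper.tri(A))
    A[ut[picked]] <- 1
    A <- A + t(A)
    binaryConnectome(A, nodes)
}

## Random but anatomically plausible centroids: left hemisphere x in
## [-70, -5] mm, right in [5, 70], y in [-100, 70], z in [-50, 80].
synthNodeTable <- function(n) {
    nL <- ceiling(n / 2)
    hemi <- rep(c("left", "right"), c(nL, n - nL))
    data.frame(
        node_id = seq_len(n) - 1L,
        label = sprintf("region_%03d", seq_len(n) - 1L),
        hemisphere = hemi,
        x = ifelse(hemi == "left", -1, 1) * stats::runif(n, 5, 70),
        y = stats::runif(n, -100, 70),
        z = stats::runif(n, -50, 80),
        stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws (or accepts) a seed network, freezes a random core of
#' \code{floor(coreFraction * nEdges)} of its edges, then builds each member
#' by toggling \code{k} distinct non-core upper-triangle node pairs, with
#' \code{k ~ round(Normal(flipCountMean, flipCountSD))} clipped to
#' \code{[0, #mutable pairs]} (a clip at the upper bound emits a warning).
#' Symmetry is maintained by mirroring; the diagonal is untouched. All
#' randomness derives from \code{spec$rngSeed}.
#'
#' @param spec a [cohortSpec()].
#' @return list with elements \code{groundTruth}
#'   (\linkS4class{BinaryConnectome}), \code{cohort}
#'   (\linkS4class{ConnectomeCohort}), \code{coreEdges} (two-column matrix of
#'   1-based upper-triangle indices; subtract 1 for the on-disk 0-based
#'   convention) and \code{flipCounts} (per-member drawn counts).
#' @examples
#' res <- generateCohort(cohortSpec(nSubjects = 5, nNodes = 20, rngSeed = 7))
#' manhattanDistance(res$cohort[[1]], res$groundTruth) == res$flipCounts[1]
#' @export
generateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    withr::with_seed(spec$rngSeed, {
        if (is.null(spec$seedNetwork)) {
            nodes <- synthNodeTable(spec$nNodes)
            seed <- randomSeedNetwork(spec$nNodes, spec$targetDensity, nodes)
        } else {
            seed <- spec$seedNetwork
            nodes <- nodeTable(seed)
        }
        n <- nNodes(seed)
        A0 <- adjacency(seed)
        ut <- which(upper.tri(A0))
        edge_idx <- ut[A0[ut] == 1]
        n_core <- floor(spec$coreFraction * length(edge_idx))
        core <- if (n_core > 0) sample(edge_idx, n_core) else integer(0)
        mutable <- setdiff(ut, core)
        M <- length(mutable)
        flips <- integer(spec$nSubjects)
        members <- vector("list", spec$nSubjects)
        for (s in seq_len(spec$nSubjects)) {
            k <- round(stats::rnorm(1L, spec$flipCountMean, spec$flipCountSD))
            if (k > M) {
                warning(sprintf(
                    "flip count %d exceeds %d mutable pairs; clipped", k, M))
                k <- M
            }
            k <- max(0L, as.integer(k))
            flips[s] <- k
            A <- A0
            if (k > 0) {
                tog <- sample(mutable, k)
                A[tog] <- 1 - A[tog]
                A[lower.tri(A)] <- t(A)[lower.tri(A)]
            }
            members[[s]] <- binaryConnectome(A, nodes)
        }
        core_rc <- arrayInd(core, c(n, n))
        colnames(core_rc) <- c("i", "j")
        list(groundTruth = seed,
             cohort = connectomeCohort(members, nodes),
             coreEdges = core_rc,
             flipCounts = flips)
    })
}

#' Manhattan distance between two binary networks
#'
#' Number of differing adjacency entries counted over the strict upper
#' triangle (half the full-matrix count, by symmetry).
#'
#' @param a,b \linkS4class{BinaryConnectome} objects with identical node sets.
#' @return non-negative integer.
#' @export
manhattanDistance <- function(a, b) {
    stopifnot(is(a, "BinaryConnectome"), is(b, "BinaryConnectome"))
    if (nNodes(a) != nNodes(b)) {
        stop(sprintf("shape mismatch: %d vs %d nodes", nNodes(a), nNodes(b)))
    }
    d <- abs(adjacency(a) - adjacency(b))
    as.integer(sum(d[upper.tri(d)]))
}

#' Pairwise Manhattan-distance statistics of a cohort
#'
#' Mean and sample SD of the Manhattan distance over all unordered member
#' pairs. These statistics parameterise [cohortSpec()] when emulating an
#' observed cohort's variability.
#'
#' @param cohort a binary \linkS4class{ConnectomeCohort} of size >= 2.
#' @return list with \code{mean} and \code{sd} (a single pair yields
#'   \code{sd = 0} with a warning).
#' @export
pairwiseFlipStatistics <- function(cohort) {
    stopifnot(is(cohort, "ConnectomeCohort"))
    n <- length(cohort)
    if (n < 2L) stop("need a cohort of at least 2 members")
    ds <- unlist(lapply(seq_len(n - 1L), function(i) {
        vapply((i + 1L):n, function(j) {
            manhattanDistance(cohort[[i]], cohort[[j]])
        }, numeric(1))
    }))
    if (length(ds) == 1L) {
        warning("single member pair: SD reported as 0")
        return(list(mean = ds, sd = 0))
    }
    list(mean = mean(ds), sd = stats::sd(ds))
}

#' Nearest cohort member to a query network
#'
#' @param query a \linkS4class{BinaryConnectome}.
#' @param pool list of \linkS4class{BinaryConnectome} (or a cohort).
#' @return list with \code{index} and \code{distance} of the nearest member
#'   (ties broken toward the lowest index) and \code{table}, the full
#'   distance table sorted ascending.
#' @export
nearestMember <- function(query, pool) {
    if (is(pool, "ConnectomeCohort")) pool <- members(pool)
    if (!length(pool)) stop("empty pool")
    d <- vapply(pool, manhattanDistance, numeric(1), b = query)
    ord <- order(d, seq_along(d))
    list(index = ord[1L], distance = d[ord[1L]],
         table = data.frame(index = ord, distance = d[ord]))
}
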