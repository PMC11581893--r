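## Group-network construction: the uniform consensus ladder (the candidate
## pool for dynamics-based selection), distance-dependent consensus, and
## consistency-based thresholding. All tie-breaks are deterministic so group
## networks are bit-reproducible.

#' Edge prevalence across a binary cohort
#'
#' Elementwise sum of the members' adjacency matrices: entry (i, j) counts
#' the members containing edge (i, j).
#'
#' @param cohort a binary \linkS4class{ConnectomeCohort}.
#' @return symmetric integer matrix with values in 0..n.
#' @export
edgePrevalence <- function(cohort) {
    stopifnot(is(cohort, "ConnectomeCohort"))
    if (!is(cohort[[1L]], "BinaryConnectome")) {
        stop("edge prevalence needs a binary cohort; run binarize() first")
    }
    Reduce(`+`, lapply(members(cohort), adjacency))
}

#' Edge prevalence histogram
#'
#' Fraction of the strict-upper-triangle node pairs at each prevalence level
#' 0..n: how much of the topology is shared by how much of the cohort.
#'
#' @param prevalence matrix from [edgePrevalence()].
#' @param n cohort size.
#' @return data.frame with columns \code{count} (0..n),
#'   \code{fraction_subjects} (count/n) and \code{fraction_pairs} (sums to 1).
#' @export
prevalenceHistogram <- function(prevalence, n) {
    v <- prevalence[upper.tri(prevalence)]
    counts <- tabulate(factor(v, levels = 0:n), nbins = n + 1L)
    data.frame(count = 0:n,
               fraction_subjects = (0:n) / n,
               fraction_pairs = counts / length(v))
}

#' Uniform consensus group network
#'
#' Retains an edge iff it is present in at least \code{ceiling(T * n / 100)}
#' of the n members: an exact integer count when T is a multiple of 100/n
#' (T = 42.5 with n = 40 retains edges present in >= 17 subjects), and
#' well defined between ladder thresholds. Because thresholds are quoted
#' percentages (e.g. 66.7 for 2-of-3), T*n/100 is snapped to the nearest
#' integer count when within 0.05 percentage points of it.
#'
#' @param cohort a binary \linkS4class{ConnectomeCohort}.
#' @param threshold consensus percentage in (0, 100].
#' @return a \linkS4class{BinaryConnectome}.
#' @export
uniformConsensus <- function(cohort, threshold) {
    if (threshold <= 0 || threshold > 100) {
        stop("threshold must be in (0, 100]")
    }
    prev <- edgePrevalence(cohort)
    minCount <- consensusMinCount(threshold, length(cohort))
    binaryConnectome((prev >= minCount) + 0, nodeTable(cohort))
}

## ceiling, except that near-exact counts (threshold quoted to ~0.05
## percentage points) snap to the exact integer
consensusMinCount <- function(threshold, n) {
    x <- threshold * n / 100
    r <- round(x)
    count <- if (abs(x - r) <= max(1e-9, 5e-4 * n)) r else ceiling(x)
    max(1L, as.integer(count))
}

#' Build the full consensus-threshold ladder
#'
#' One group network per threshold k*100/n, k = 1..n: from "present in at
#' least one subject" (the union) up to "present in all subjects" (the
#' intersection). Edge sets are nested along the ladder.
#'
#' @param cohort a binary \linkS4class{ConnectomeCohort}.
#' @return a \linkS4class{ThresholdLadder}.
#' @export
buildLadder <- function(cohort) {
    n <- length(cohort)
    prev <- edgePrevalence(cohort)
    nodes <- nodeTable(cohort)
    networks <- lapply(seq_len(n), function(k) {
        binaryConnectome((prev >= k) + 0, nodes)
    })
    new("ThresholdLadder", thresholds = seq_len(n) * 100 / n,
        networks = networks)
}

#' Euclidean distance matrix between node centroids
#'
#' @param nodes a node metadata table with finite \code{x}, \code{y},
#'   \code{z} centroid coordinates in mm.
#' @return symmetric N x N matrix of straight-line distances (mm).
#' @export
euclideanDistanceMatrix <- function(nodes) {
    ok <- validNodeTable(nodes)
    if (!isTRUE(ok)) stop("invalid node table: ", ok)
    D <- as.matrix(stats::dist(as.matrix(nodes[, c("x", "y", "z")])))
    dimnames(D) <- NULL
    D
}

#' Distance-dependent consensus group network
#'
#' Builds a group network whose connection-length distribution tracks the
#' cohort's. Intra- and inter-hemispheric node pairs are handled
#' independently (so the longer inter-hemispheric connections are not
#' under-represented): within each class, pairs are partitioned into
#' \code{nBins} linearly spaced Euclidean-distance bins spanning the class's
#' observed [min, max] pair distance; in each bin the mean per-subject edge
#' count m (rounded half away from zero) is computed and the m most prevalent
#' pairs are retained (ties broken toward shorter distance, then lower
#' lexicographic index). Pairs absent from every member are never retained.
#' The output density approximates the mean member density.
#'
#' @param cohort a binary \linkS4class{ConnectomeCohort}.
#' @param distanceMatrix optional distance matrix; defaults to
#'   [euclideanDistanceMatrix()] of the cohort's node table.
#' @param nBins number of distance bins per connection class (default 41).
#' @return a \linkS4class{BinaryConnectome}.
#' @export
distanceDependentConsensus <- function(cohort, distanceMatrix = NULL,
                                       nBins = 41L) {
    if (nBins < 1L) stop("nBins must be >= 1")
    nodes <- nodeTable(cohort)
    if (is.null(distanceMatrix)) {
        distanceMatrix <- euclideanDistanceMatrix(nodes)
    }
    N <- nNodes(cohort)
    if (!identical(dim(distanceMatrix), c(N, N))) {
        stop("distance matrix does not match the cohort's node count")
    }
    prev <- edgePrevalence(cohort)
    n <- length(cohort)
    ut <- which(upper.tri(prev), arr.ind = TRUE)
    hemi <- nodes$hemisphere
    intra <- hemi[ut[, 1L]] == hemi[ut[, 2L]]
    d <- distanceMatrix[upper.tri(distanceMatrix)]
    p <- prev[upper.tri(prev)]
    A <- matrix(0, N, N)
    for (cls in c(TRUE, FALSE)) {
        sel <- which(intra == cls)
        if (!length(sel)) next
        dc <- d[sel]
        edges <- seq(min(dc), max(dc), length.out = nBins + 1L)
        bin <- findInterval(dc, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
        for (b in unique(bin)) {
            inb <- sel[bin == b]
            m <- roundHalfUp(sum(p[inb]) / n)
            if (m < 1L) next
            cand <- inb[p[inb] > 0]
            if (!length(cand)) next
            ord <- cand[order(-p[cand], d[cand], ut[cand, 1L], ut[cand, 2L])]
            keep <- ord[seq_len(min(m, length(ord)))]
            A[cbind(ut[keep, 1L], ut[keep, 2L])] <- 1
        }
    }
    A <- A + t(A)
    binaryConnectome(A, nodes)
}

## round half away from zero (base round() rounds half to even)
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

#' Consistency-based group network
#'
#' Retains the node pairs whose weights are most consistent across subjects:
#' for every pair with nonzero mean weight, the coefficient of variation
#' CV = sample SD / mean of the weight across all subjects (absent edges
#' contribute weight 0 when \code{cvIncludeZeros}, the default) is ranked
#' ascending and the first \code{floor(targetDensity * N(N-1)/2)} pairs are
#' kept (ties broken toward higher mean weight, then lower lexicographic
#' index), then binarized. With \code{cvIncludeZeros = FALSE} the CV is
#' computed over the subjects possessing the edge only (pairs present in
#' fewer than two subjects rank last).
#'
#' @param cohort a weighted (or binary) \linkS4class{ConnectomeCohort}.
#' @param targetDensity desired group density in (0, 1]; typically set to the
#'   density of the network it is compared against.
#' @param cvIncludeZeros whether absent edges enter the CV as zero weights.
#' @return a \linkS4class{BinaryConnectome} with exactly
#'   \code{floor(targetDensity * N(N-1)/2)} edges (fewer, with a warning,
#'   when the cohort has fewer pairs with nonzero mean weight).
#' @export
consistencyConsensus <- function(cohort, targetDensity,
                                 cvIncludeZeros = TRUE) {
    stopifnot(is(cohort, "ConnectomeCohort"))
    if (targetDensity <= 0 || targetDensity > 1) {
        stop("targetDensity must be in (0, 1]")
    }
    N <- nNodes(cohort)
    W <- vapply(members(cohort), function(m) {
        adjacency(m)[upper.tri(adjacency(m))]
    }, numeric(N * (N - 1L) / 2L))
    W <- matrix(W, ncol = length(cohort))
    mu <- rowMeans(W)
    if (cvIncludeZeros) {
        sdw <- apply(W, 1L, stats::sd)
        cv <- ifelse(mu > 0, sdw / mu, Inf)
    } else {
        cv <- apply(W, 1L, function(w) {
            w <- w[w > 0]
            if (length(w) < 2L) return(Inf)
            stats::sd(w) / mean(w)
        })
        cv[mu == 0] <- Inf
    }
    ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    eligible <- which(mu > 0)
    ## guard against floating-point shortfall when targetDensity is an
    ## exact edge-count fraction
    target <- floor(targetDensity * N * (N - 1L) / 2L + 1e-9)
    if (target > length(eligible)) {
        warning(sprintf(
            "target of %d pairs exceeds the %d pairs with nonzero mean weight; keeping all",
            target, length(eligible)))
        target <- length(eligible)
    }
    ord <- eligible[order(cv[eligible], -mu[eligible],
                          ut[eligible, 1L], ut[eligible, 2L])]
    keep <- ord[seq_len(target)]
    A <- matrix(0, N, N)
    A[cbind(ut[keep, 1L], ut[keep, 2L])] <- 1
    A <- A + t(A)
    binaryConnectome(A, nodeTable(cohort))
}
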