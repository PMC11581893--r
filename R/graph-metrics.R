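## Nodal and global graph metrics used to compare group networks against the
## cohort, following binary undirected conventions: raw (unnormalised)
## betweenness, triangles-over-triples clustering, shortest paths in hops.

asIgraph <- function(network) {
    igraph::graph_from_adjacency_matrix(adjacency(network),
                                        mode = "undirected", diag = FALSE)
}

#' Nodal graph metrics
#'
#' Degree (row sum), clustering coefficient (triangles over triples, 0 by
#' convention for degree < 2), betweenness centrality (raw Brandes
#' shortest-path counts, endpoints excluded) and eigenvector centrality (the
#' principal eigenvector of A, sign-fixed non-negative and scaled to unit
#' Euclidean norm). On a disconnected network betweenness is per component
#' and eigenvector centrality is computed on the largest component with
#' zeros elsewhere, with a warning.
#'
#' @param network a \linkS4class{BinaryConnectome}.
#' @return data.frame with columns \code{node_id}, \code{degree},
#'   \code{clustering}, \code{betweenness}, \code{eigenvector}.
#' @export
nodalMetrics <- function(network) {
    stopifnot(is(network, "BinaryConnectome"))
    N <- nNodes(network)
    if (N < 2L) stop("metrics need at least 2 nodes")
    A <- adjacency(network)
    g <- asIgraph(network)
    clustering <- igraph::transitivity(g, type = "local")
    clustering[!is.finite(clustering)] <- 0
    comp <- igraph::components(g)
    ev <- numeric(N)
    if (comp$no > 1L) {
        warning("disconnected network: eigenvector centrality restricted to the largest component")
    }
    main <- which(comp$membership == which.max(comp$csize))
    if (length(main) >= 2L && sum(A[main, main]) > 0) {
        v <- eigen(A[main, main, drop = FALSE], symmetric = TRUE)$vectors[, 1L]
        if (sum(v) < 0) v <- -v
        v[v < 0] <- 0  # Perron vector is non-negative; clip numeric dust
        ev[main] <- v / sqrt(sum(v^2))
    }
    data.frame(node_id = nodeTable(network)$node_id,
               degree = as.integer(rowSums(A)),
               clustering = clustering,
               betweenness = igraph::betweenness(g, directed = FALSE,
                                                 normalized = FALSE),
               eigenvector = ev)
}

#' Global graph metrics
#'
#' Density, modularity Q (best of \code{modularityRepeats} seeded multilevel
#' Louvain runs at resolution 1), average nodal clustering and characteristic
#' path length (mean shortest-path length over connected node pairs;
#' disconnected pairs are excluded with a warning).
#'
#' @param network a \linkS4class{BinaryConnectome}.
#' @param modularityRepeats number of community-detection restarts.
#' @param rngSeed seed for the restarts (Q is reproducible given the seed and
#'   never decreases as repeats increase under a fixed seed).
#' @return named list with \code{density}, \code{modularity},
#'   \code{avgClustering}, \code{charPathLength}.
#' @export
globalMetrics <- function(network, modularityRepeats = 100L, rngSeed = 1L) {
    stopifnot(is(network, "BinaryConnectome"))
    if (nNodes(network) < 2L) stop("metrics need at least 2 nodes")
    g <- asIgraph(network)
    nodal <- suppressWarnings(nodalMetrics(network))
    d <- igraph::distances(g)
    finite <- is.finite(d) & upper.tri(d)
    if (any(!is.finite(d[upper.tri(d)]))) {
        warning("disconnected network: characteristic path length excludes unreachable pairs")
    }
    cpl <- if (any(finite)) mean(d[finite]) else NA_real_
    Q <- if (igraph::ecount(g) == 0) {
        NA_real_
    } else {
        withr::with_seed(rngSeed, {
            max(vapply(seq_len(modularityRepeats), function(i) {
                igraph::modularity(igraph::cluster_louvain(g))
            }, numeric(1)))
        })
    }
    list(density = edgeDensity(network),
         modularity = Q,
         avgClustering = mean(nodal$clustering),
         charPathLength = cpl)
}

#' Edge length distribution
#'
#' Uses the network as a logical mask on a distance matrix: the Euclidean
#' distances of the existing (upper-triangle) edges.
#'
#' @param network a \linkS4class{BinaryConnectome}.
#' @param distanceMatrix N x N distance matrix; defaults to
#'   [euclideanDistanceMatrix()] of the network's node table.
#' @return numeric vector, one distance per edge.
#' @export
edgeLengths <- function(network, distanceMatrix = NULL) {
    stopifnot(is(network, "BinaryConnectome"))
    if (is.null(distanceMatrix)) {
        distanceMatrix <- euclideanDistanceMatrix(nodeTable(network))
    }
    A <- adjacency(network)
    if (!identical(dim(distanceMatrix), dim(A))) {
        stop("distance matrix does not match the network's node count")
    }
    distanceMatrix[upper.tri(A) & A == 1]
}
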