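#' Constructors for connectome objects
#'
#' Build a validated connectome from an adjacency matrix and (optionally) a
#' node metadata table. When \code{nodes} is omitted a deterministic default
#' table is generated: generic labels, left/right hemispheres split down the
#' node ordering, and centroids laid out on two lateral grids so that
#' distance-based operations remain well defined.
#'
#' @param adjacency square symmetric numeric matrix, zero diagonal. For
#'   \code{binaryConnectome} entries must be 0/1; for
#'   \code{weightedConnectome} entries must be non-negative.
#' @param nodes node metadata \code{data.frame} with columns
#'   \code{node_id} (0-based), \code{label}, \code{hemisphere}, \code{x},
#'   \code{y}, \code{z}; or \code{NULL} for the default layout.
#' @return a \linkS4class{BinaryConnectome} or
#'   \linkS4class{WeightedConnectome}.
#' @examples
#' A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1
#' binaryConnectome(A)
#' @export
binaryConnectome <- function(adjacency, nodes = NULL) {
    adjacency <- unname(as.matrix(adjacency))
    if (is.null(nodes)) nodes <- defaultNodeTable(nrow(adjacency))
    new("BinaryConnectome", adjacency = adjacency, nodes = nodes)
}

#' @rdname binaryConnectome
#' @export
weightedConnectome <- function(adjacency, nodes = NULL) {
    adjacency <- unname(as.matrix(adjacency))
    if (is.null(nodes)) nodes <- defaultNodeTable(nrow(adjacency))
    new("WeightedConnectome", adjacency = adjacency, nodes = nodes)
}

#' Default node metadata table
#'
#' Deterministic stand-in node table used when no parcellation metadata is
#' supplied: nodes \code{0..n-1}, labels \code{region_k}, the first half of
#' the ordering assigned to the left hemisphere, and centroids on two
#' hemisphere-offset 10 mm grids.
#'
#' @param n number of nodes.
#' @return a node \code{data.frame}.
#' @export
defaultNodeTable <- function(n) {
    stopifnot(n >= 1)
    nL <- ceiling(n / 2)
    hemi <- rep(c("left", "right"), c(nL, n - nL))
    idx <- c(seq_len(nL), seq_len(n - nL))  # position within each hemisphere
    grid_side <- ceiling(sqrt(nL))
    data.frame(
        node_id = seq_len(n) - 1L,
        label = sprintf("region_%03d", seq_len(n) - 1L),
        hemisphere = hemi,
        x = ifelse(hemi == "left", -40, 40),
        y = 10 * ((idx - 1L) %% grid_side) - 50,
        z = 10 * ((idx - 1L) %/% grid_side) - 30,
        stringsAsFactors = FALSE)
}

#' Construct a cohort
#'
#' @param members list of connectomes (all binary or all weighted) sharing one
#'   node set.
#' @param nodes shared node table; defaults to the first member's.
#' @return a \linkS4class{ConnectomeCohort}.
#' @export
connectomeCohort <- function(members, nodes = NULL) {
    if (is.null(nodes) && length(members)) nodes <- members[[1L]]@nodes
    new("ConnectomeCohort", members = members, nodes = nodes)
}

#' Adjacency matrix of a connectome
#' @param x a connectome object.
#' @return the numeric adjacency matrix.
#' @name adjacency
#' @export
setMethod("adjacency", "Connectome", function(x) x@adjacency)

#' Node metadata table
#' @param x a connectome or cohort.
#' @return the node \code{data.frame}.
#' @name nodeTable
#' @export
setMethod("nodeTable", "Connectome", function(x) x@nodes)

#' @rdname nodeTable
setMethod("nodeTable", "ConnectomeCohort", function(x) x@nodes)

#' Number of nodes
#' @param x a connectome or cohort.
#' @return integer node count.
#' @name nNodes
#' @export
setMethod("nNodes", "Connectome", function(x) nrow(x@adjacency))

#' @rdname nNodes
setMethod("nNodes", "ConnectomeCohort", function(x) nrow(x@nodes))

#' Cohort members
#' @param x a \linkS4class{ConnectomeCohort} or \linkS4class{ThresholdLadder}.
#' @return list of connectomes.
#' @name members
#' @export
setMethod("members", "ConnectomeCohort", function(x) x@members)

#' @rdname members
setMethod("members", "ThresholdLadder", function(x) x@networks)

#' Ladder thresholds
#' @param x a \linkS4class{ThresholdLadder} or \linkS4class{DBCSelection}.
#' @return numeric vector of consensus percentages.
#' @name thresholds
#' @export
setMethod("thresholds", "ThresholdLadder", function(x) x@thresholds)

#' @rdname thresholds
setMethod("thresholds", "DBCSelection", function(x) x@thresholds)

#' Number of cohort members
#' @param x a \linkS4class{ConnectomeCohort}.
#' @export
setMethod("length", "ConnectomeCohort", function(x) length(x@members))

#' Extract a cohort member
#' @param x a \linkS4class{ConnectomeCohort}.
#' @param i member index.
#' @export
setMethod("[[", "ConnectomeCohort", function(x, i) x@members[[i]])

#' Profile values as a data.frame
#' @param x a \linkS4class{MetastabilityProfile}.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "MetastabilityProfile", function(x, ...) {
    data.frame(K = x@K, metastability = x@values,
               realisation_sd = x@realisationSD)
})

#' MSE table of a selection result
#'
#' @param x a \linkS4class{DBCSelection}.
#' @return \code{data.frame} with columns \code{threshold} and \code{mse}.
#' @export
mseTable <- function(x) {
    stopifnot(is(x, "DBCSelection"))
    data.frame(threshold = x@thresholds, mse = x@mse)
}

#' Selected DBC network
#' @param x a \linkS4class{DBCSelection}.
#' @return the selected \linkS4class{BinaryConnectome}.
#' @export
dbcNetwork <- function(x) {
    stopifnot(is(x, "DBCSelection"))
    x@dbcNetwork
}

#' Selected DBC threshold (percent)
#' @param x a \linkS4class{DBCSelection}.
#' @export
dbcThreshold <- function(x) {
    stopifnot(is(x, "DBCSelection"))
    x@dbcThreshold
}

setMethod("show", "BinaryConnectome", function(object) {
    n <- nNodes(object)
    cat(sprintf("BinaryConnectome: %d nodes, %d edges (density %.3f)\n",
                n, sum(object@adjacency) / 2,
                if (n > 1) sum(object@adjacency) / (n * (n - 1)) else NA_real_))
})

setMethod("show", "WeightedConnectome", function(object) {
    n <- nNodes(object)
    cat(sprintf("WeightedConnectome: %d nodes, %d weighted edges\n",
                n, sum(object@adjacency[upper.tri(object@adjacency)] > 0)))
})

setMethod("show", "ConnectomeCohort", function(object) {
    cat(sprintf("ConnectomeCohort: %d %s members, %d nodes\n",
                length(object@members), tolower(sub("Connectome", "",
                class(object@members[[1L]]))), nrow(object@nodes)))
})

setMethod("show", "ThresholdLadder", function(object) {
    cat(sprintf("ThresholdLadder: %d consensus networks, thresholds %.3g%%..%g%%\n",
                length(object@networks), min(object@thresholds),
                max(object@thresholds)))
})

setMethod("show", "MetastabilityProfile", function(object) {
    cat(sprintf("MetastabilityProfile: %d couplings, K in [%g, %g], peak %.4g at K = %g\n",
                length(object@K), min(object@K), max(object@K),
                max(object@values), object@K[which.max(object@values)]))
})

setMethod("show", "DBCSelection", function(object) {
    cat(sprintf("DBCSelection: DBC at %g%% consensus (MSE %.4g over %d thresholds)\n",
                object@dbcThreshold,
                object@mse[match(object@dbcThreshold, object@thresholds)],
                length(object@thresholds)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %g s total (%g s transient), dt = %g s, ",
                       "omega ~ N(%.4g, %g) rad/s, %d realisation(s), seed %d\n"),
                object@totalTime, object@transientTime, object@dt,
                object@meanFrequency, object@frequencySD,
                object@nRealisations, object@rngSeed))
})
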