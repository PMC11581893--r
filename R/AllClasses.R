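#' @import methods
NULL

## Node tables are plain data.frames with a fixed column contract
## (node_id, label, hemisphere, x, y, z); validated on construction of
## every connectome object rather than wrapped in a class of their own.

validNodeTable <- function(nodes, n = NULL) {
    required <- c("node_id", "label", "hemisphere", "x", "y", "z")
    if (!is.data.frame(nodes)) {
        return("node table must be a data.frame")
    }
    missing <- setdiff(required, names(nodes))
    if (length(missing)) {
        return(paste0("node table lacks column(s): ",
                      paste(missing, collapse = ", ")))
    }
    if (!is.null(n) && nrow(nodes) != n) {
        return(sprintf("node table has %d rows but the matrix has %d nodes",
                       nrow(nodes), n))
    }
    if (!identical(as.integer(nodes$node_id), seq_len(nrow(nodes)) - 1L)) {
        return("node_id must be consecutive 0..N-1")
    }
    if (anyDuplicated(nodes$label)) {
        return("node labels must be unique")
    }
    if (!all(nodes$hemisphere %in% c("left", "right"))) {
        return("hemisphere must be 'left' or 'right' for every node")
    }
    if (!all(is.finite(nodes$x) & is.finite(nodes$y) & is.finite(nodes$z))) {
        return("node centroid coordinates must all be finite")
    }
    TRUE
}

validAdjacency <- function(A, binary = FALSE) {
    if (!is.matrix(A) || !is.numeric(A)) {
        return("adjacency must be a numeric matrix")
    }
    if (nrow(A) != ncol(A)) {
        return("adjacency must be square")
    }
    if (anyNA(A) || any(!is.finite(A))) {
        return("adjacency must be finite with no missing values")
    }
    if (any(A != t(A))) {
        return("adjacency must be symmetric")
    }
    if (any(diag(A) != 0)) {
        return("adjacency diagonal must be all zero")
    }
    if (binary) {
        if (!all(A %in% c(0, 1))) {
            return("binary adjacency entries must be 0 or 1")
        }
    } else if (any(A < 0)) {
        return("weights must be non-negative")
    }
    TRUE
}

#' Connectome classes
#'
#' A connectome is a square symmetric adjacency matrix over a fixed set of
#' parcellation nodes, together with a node metadata table (0-based
#' \code{node_id}, \code{label}, \code{hemisphere} in \code{left}/\code{right},
#' and 3-D centroid coordinates \code{x}, \code{y}, \code{z} in mm).
#' \code{WeightedConnectome} holds non-negative edge weights (e.g. streamline
#' counts); \code{BinaryConnectome} holds 0/1 presence. Both enforce symmetry
#' and a zero diagonal.
#'
#' @slot adjacency square symmetric numeric matrix with zero diagonal.
#' @slot nodes node metadata \code{data.frame}.
#'
#' @aliases WeightedConnectome-class BinaryConnectome-class
#' @name Connectome-class
#' @exportClass Connectome
setClass("Connectome",
         representation("VIRTUAL",
                        adjacency = "matrix",
                        nodes = "data.frame"))

#' @exportClass WeightedConnectome
setClass("WeightedConnectome", contains = "Connectome",
         validity = function(object) {
             ok <- validAdjacency(object@adjacency, binary = FALSE)
             if (!isTRUE(ok)) return(ok)
             validNodeTable(object@nodes, nrow(object@adjacency))
         })

#' @exportClass BinaryConnectome
setClass("BinaryConnectome", contains = "Connectome",
         validity = function(object) {
             ok <- validAdjacency(object@adjacency, binary = TRUE)
             if (!isTRUE(ok)) return(ok)
             validNodeTable(object@nodes, nrow(object@adjacency))
         })

#' Cohort of connectomes
#'
#' An ordered collection of connectomes sharing one node set (identical N and
#' node ordering). Members are all binary or all weighted.
#'
#' @slot members list of \linkS4class{Connectome} objects.
#' @slot nodes the shared node metadata table.
#'
#' @name ConnectomeCohort-class
#' @exportClass ConnectomeCohort
setClass("ConnectomeCohort",
         representation(members = "list", nodes = "data.frame"),
         validity = function(object) {
             if (length(object@members) < 1L) {
                 return("cohort must contain at least one member")
             }
             cls <- vapply(object@members, function(m) class(m)[1L], character(1))
             if (!all(cls %in% c("BinaryConnectome", "WeightedConnectome"))) {
                 return("cohort members must be connectome objects")
             }
             if (length(unique(cls)) != 1L) {
                 return("cohort members must be all binary or all weighted")
             }
             ns <- vapply(object@members, function(m) nrow(m@adjacency), integer(1))
             if (length(unique(ns)) != 1L || ns[1L] != nrow(object@nodes)) {
                 return("all members must share the cohort's node set")
             }
             for (m in object@members) {
                 if (!identical(m@nodes$label, object@nodes$label)) {
                     return("member node ordering differs from the cohort node table")
                 }
             }
             validNodeTable(object@nodes)
         })

#' Uniform consensus threshold ladder
#'
#' One binary group network per consensus threshold k*100/n, k = 1..n, for a
#' cohort of n subjects. Edge sets are nested: raising the threshold can only
#' remove edges.
#'
#' @slot thresholds numeric vector of consensus percentages.
#' @slot networks list of \linkS4class{BinaryConnectome}, parallel to
#'   \code{thresholds}.
#'
#' @name ThresholdLadder-class
#' @exportClass ThresholdLadder
setClass("ThresholdLadder",
         representation(thresholds = "numeric", networks = "list"),
         validity = function(object) {
             if (length(object@thresholds) != length(object@networks)) {
                 return("thresholds and networks differ in length")
             }
             if (is.unsorted(object@thresholds, strictly = TRUE)) {
                 return("thresholds must be strictly ascending")
             }
             TRUE
         })

#' Metastability profile
#'
#' The metastability (standard deviation of the Kuramoto order parameter over
#' the post-transient window) of one network, evaluated at every coupling
#' strength K of a sweep. Used as the network's dynamical signature.
#'
#' @slot K the coupling grid.
#' @slot values per-K metastability, averaged over realisations.
#' @slot realisationSD per-K sample SD across realisations (0 for a single
#'   realisation).
#'
#' @name MetastabilityProfile-class
#' @exportClass MetastabilityProfile
setClass("MetastabilityProfile",
         representation(K = "numeric", values = "numeric",
                        realisationSD = "numeric"),
         validity = function(object) {
             if (length(object@K) != length(object@values) ||
                 length(object@K) != length(object@realisationSD)) {
                 return("K, values and realisationSD must have equal length")
             }
             if (is.unsorted(object@K, strictly = TRUE) || object@K[1L] < 0) {
                 return("K must be strictly ascending and non-negative")
             }
             if (any(object@values < 0)) {
                 return("metastability values must be non-negative")
             }
             TRUE
         })

#' Kuramoto simulation configuration
#'
#' Parameters of the oscillator simulation protocol: total simulated time,
#' discarded transient, Euler step, natural-frequency distribution
#' (Normal(meanFrequency, frequencySD) in rad/s), number of realisations and
#' the RNG seed from which initial phases and frequencies are drawn.
#'
#' @slot totalTime total simulated time per realisation, seconds.
#' @slot transientTime initial window discarded from analysis, seconds.
#' @slot dt Euler integration step, seconds.
#' @slot meanFrequency mean natural frequency, rad/s.
#' @slot frequencySD natural-frequency SD, rad/s.
#' @slot nRealisations number of independent (phase, frequency) draws.
#' @slot rngSeed integer seed for the draws.
#'
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(totalTime = "numeric", transientTime = "numeric",
                        dt = "numeric", meanFrequency = "numeric",
                        frequencySD = "numeric", nRealisations = "integer",
                        rngSeed = "integer"),
         validity = function(object) {
             if (object@dt <= 0) return("dt must be positive")
             if (object@transientTime < 0 ||
                 object@transientTime >= object@totalTime) {
                 return("need 0 <= transientTime < totalTime")
             }
             if (object@frequencySD < 0) return("frequencySD must be >= 0")
             if (object@nRealisations < 1L) return("nRealisations must be >= 1")
             TRUE
         })

#' Dynamics-based consensus selection result
#'
#' The MSE between each ladder network's metastability profile and the
#' subjects' profiles, and the selected dynamics-based consensus (DBC): the
#' ladder network minimising that MSE.
#'
#' @slot thresholds ladder thresholds (percent).
#' @slot mse per-threshold mean squared profile error.
#' @slot dbcThreshold the selected consensus threshold.
#' @slot dbcNetwork the selected \linkS4class{BinaryConnectome}.
#' @slot subjectMean per-K mean of the subject profiles.
#' @slot subjectSD per-K sample SD of the subject profiles.
#' @slot grid the coupling grid shared by all profiles.
#'
#' @name DBCSelection-class
#' @exportClass DBCSelection
setClass("DBCSelection",
         representation(thresholds = "numeric", mse = "numeric",
                        dbcThreshold = "numeric",
                        dbcNetwork = "BinaryConnectome",
                        subjectMean = "numeric", subjectSD = "numeric",
                        grid = "numeric"),
         validity = function(object) {
             if (length(object@thresholds) != length(object@mse)) {
                 return("thresholds and mse differ in length")
             }
             if (any(object@mse < 0)) return("MSE values must be >= 0")
             if (!object@dbcThreshold %in% object@thresholds) {
                 return("dbcThreshold must be one of the ladder thresholds")
             }
             TRUE
         })
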