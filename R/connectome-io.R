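## Reading, validating, binarizing and subsetting connectivity matrices.
## Matrix files are plain delimited text (whitespace or comma), no header,
## one row per node. Node metadata is a TSV with header
## node_id<TAB>label<TAB>hemisphere<TAB>x<TAB>y<TAB>z; node_id is 0-based,
## as are all indices in files and error messages.

#' Read a connectivity matrix (and node table) from disk
#'
#' Reads a square delimited numeric matrix and optional node metadata,
#' validates it, enforces symmetry within an absolute tolerance by
#' symmetrisation \code{W <- (W + t(W)) / 2}, and forces the diagonal to zero.
#' Asymmetries beyond \code{symmetryTol} are rejected with the offending
#' (0-based) indices.
#'
#' @param matrixPath path to a whitespace- or comma-delimited square numeric
#'   matrix, no header.
#' @param nodeTablePath optional path to a node metadata TSV (columns
#'   \code{node_id}, \code{label}, \code{hemisphere}, \code{x}, \code{y},
#'   \code{z}); when omitted a default table is generated.
#' @param symmetryTol absolute tolerance within which asymmetries are
#'   symmetrised rather than rejected.
#' @return a \linkS4class{WeightedConnectome}.
#' @seealso [binarize()], [writeConnectome()]
#' @export
readConnectome <- function(matrixPath, nodeTablePath = NULL,
                           symmetryTol = 1e-8) {
    first <- readLines(matrixPath, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    W <- as.matrix(utils::read.table(matrixPath, header = FALSE, sep = sep))
    dimnames(W) <- NULL
    if (!is.numeric(W)) {
        stop("matrix file '", matrixPath, "' contains non-numeric entries")
    }
    if (nrow(W) != ncol(W)) {
        stop(sprintf("non-square matrix in '%s': %d rows x %d columns",
                     matrixPath, nrow(W), ncol(W)))
    }
    if (any(W < 0)) {
        bad <- which(W < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative entry at (%d, %d) in '%s'",
                     bad[1L] - 1L, bad[2L] - 1L, matrixPath))
    }
    asym <- abs(W - t(W))
    if (any(asym > symmetryTol)) {
        bad <- which(asym > symmetryTol, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "asymmetry beyond tolerance %g at (%d, %d) in '%s'",
            symmetryTol, bad[1L] - 1L, bad[2L] - 1L, matrixPath))
    }
    W <- (W + t(W)) / 2
    diag(W) <- 0
    nodes <- if (is.null(nodeTablePath)) {
        defaultNodeTable(nrow(W))
    } else {
        readNodeTable(nodeTablePath)
    }
    if (nrow(nodes) != nrow(W)) {
        stop(sprintf("node table has %d rows but matrix is %d x %d",
                     nrow(nodes), nrow(W), ncol(W)))
    }
    weightedConnectome(W, nodes)
}

#' @rdname readConnectome
#' @param x a connectome object.
#' @param path output file path.
#' @export
writeConnectome <- function(x, path) {
    stopifnot(is(x, "Connectome"))
    A <- adjacency(x)
    lines <- apply(A, 1L, function(row) {
        paste(format(row, trim = TRUE, scientific = FALSE, digits = 15),
              collapse = " ")
    })
    writeLines(lines, path)
    invisible(path)
}

#' Read or write a node metadata TSV
#'
#' @param path file path; TSV with header columns \code{node_id},
#'   \code{label}, \code{hemisphere}, \code{x}, \code{y}, \code{z}.
#' @return \code{readNodeTable} returns the validated \code{data.frame}.
#' @export
readNodeTable <- function(path) {
    nodes <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    ok <- validNodeTable(nodes)
    if (!isTRUE(ok)) stop("invalid node table '", path, "': ", ok)
    nodes
}

#' @rdname readNodeTable
#' @param nodes a node metadata \code{data.frame}.
#' @export
writeNodeTable <- function(nodes, path) {
    ok <- validNodeTable(nodes)
    if (!isTRUE(ok)) stop("invalid node table: ", ok)
    utils::write.table(nodes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Binarize a connectome
#'
#' An edge is present iff its weight is strictly positive; the node table is
#' preserved. Idempotent on binary input.
#'
#' @param x a connectome.
#' @return a \linkS4class{BinaryConnectome}.
#' @name binarize
#' @export
setMethod("binarize", "WeightedConnectome", function(x) {
    A <- (adjacency(x) > 0) + 0
    binaryConnectome(A, nodeTable(x))
})

#' @rdname binarize
setMethod("binarize", "BinaryConnectome", function(x) x)

#' @rdname binarize
setMethod("binarize", "ConnectomeCohort", function(x) {
    connectomeCohort(lapply(x@members, binarize), x@nodes)
})

#' Drop parcellation regions by label
#'
#' Removes the named regions' rows/columns and node entries (e.g. cerebellar
#' regions before analysis); remaining node_ids are re-indexed 0..N'-1
#' preserving order.
#'
#' @param x a connectome or cohort.
#' @param labels character vector of region labels to drop; every label must
#'   exist in the node table.
#' @return object of the same class with the regions removed.
#' @name dropRegions
#' @export
setMethod("dropRegions", "Connectome", function(x, labels) {
    nodes <- nodeTable(x)
    unknown <- setdiff(labels, nodes$label)
    if (length(unknown)) {
        stop("unknown region label(s): ", paste(unknown, collapse = ", "))
    }
    keep <- !(nodes$label %in% labels)
    A <- adjacency(x)[keep, keep, drop = FALSE]
    nodes <- nodes[keep, , drop = FALSE]
    nodes$node_id <- seq_len(nrow(nodes)) - 1L
    rownames(nodes) <- NULL
    if (is(x, "BinaryConnectome")) binaryConnectome(A, nodes)
    else weightedConnectome(A, nodes)
})

#' @rdname dropRegions
setMethod("dropRegions", "ConnectomeCohort", function(x, labels) {
    members <- lapply(x@members, dropRegions, labels = labels)
    connectomeCohort(members, nodeTable(members[[1L]]))
})

#' Binary edge density
#'
#' Fraction of the N(N-1)/2 node pairs that carry an edge (for weighted
#' input, a strictly positive weight). Distinct from the coupling normaliser
#' used by the oscillator model, which sums the full adjacency.
#'
#' @param x a connectome.
#' @return fraction in [0, 1].
#' @name edgeDensity
#' @export
setMethod("edgeDensity", "Connectome", function(x) {
    n <- nNodes(x)
    if (n < 2) stop("density undefined for fewer than 2 nodes")
    A <- adjacency(x)
    sum(A[upper.tri(A)] > 0) / (n * (n - 1) / 2)
})
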