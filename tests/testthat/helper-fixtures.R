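# Small graph and cohort fixtures built in code.

# binary connectome from a 2-column (1-based) edge list
edgeNet <- function(n, edges, nodes = NULL) {
    A <- matrix(0, n, n)
    if (length(edges)) {
        e <- matrix(edges, ncol = 2, byrow = TRUE)
        A[e] <- 1
        A[e[, 2:1, drop = FALSE]] <- 1
    }
    binaryConnectome(A, nodes)
}

completeNet <- function(n) {
    A <- matrix(1, n, n) - diag(n)
    binaryConnectome(A)
}

ringNet <- function(n) {
    edgeNet(n, as.vector(t(cbind(seq_len(n), c(seq_len(n)[-1], 1)))))
}

starNet <- function(nLeaves) {
    edgeNet(nLeaves + 1, as.vector(t(cbind(1, 1 + seq_len(nLeaves)))))
}

# cohort of random binary members drawn from the current RNG stream
randomCohort <- function(nMembers, nNodes, density = 0.4) {
    members <- lapply(seq_len(nMembers), function(i) {
        A <- matrix(0, nNodes, nNodes)
        ut <- which(upper.tri(A))
        on <- ut[stats::runif(length(ut)) < density]
        A[on] <- 1
        binaryConnectome(A + t(A), defaultNodeTable(nNodes))
    })
    connectomeCohort(members)
}

# 84-label parcellation-style node table including cerebellar regions
parcellationNodeTable <- function() {
    nodes <- defaultNodeTable(84)
    nodes$label[42] <- "left-cerebellum-cortex"
    nodes$label[84] <- "right-cerebellum-cortex"
    nodes
}

# quick low-resolution simulation settings for dynamics tests
tinySimConfig <- function(rngSeed = 1L, ...) {
    simulationConfig(totalTime = 2, transientTime = 1, dt = 0.005,
                     rngSeed = rngSeed, ...)
}
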