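## End-to-end orchestration: cohort (synthetic or on-disk) -> consensus
## ladder -> subject and candidate profiles -> DBC selection -> reference
## group networks -> dynamical and structural comparison report, with every
## stage seeded from one master seed and a JSON manifest of the whole run.

#' Pipeline configuration
#'
#' @param spec a [cohortSpec()] to generate a synthetic cohort, or NULL to
#'   read one from \code{cohortDir}.
#' @param cohortDir directory of member matrix files (\code{member_*.txt})
#'   plus \code{nodes.tsv}, used when \code{spec} is NULL.
#' @param simConfig a \linkS4class{SimulationConfig}; its seed is re-derived
#'   from \code{rngSeed}.
#' @param grid coupling grid.
#' @param nBins distance-dependent consensus bin count.
#' @param targetDensity consistency-consensus density; NULL (default) uses
#'   the selected DBC's density.
#' @param cvIncludeZeros see [consistencyConsensus()].
#' @param referenceThresholds extra uniform-consensus thresholds to carry
#'   into the comparison (must lie on the ladder; default 62.5).
#' @param dropLabels region labels removed before analysis (e.g. cerebellar
#'   regions).
#' @param alpha nominal level for Bonferroni-corrected post-hocs.
#' @param modularityRepeats community-detection restarts per network.
#' @param outputDir run directory to create/write.
#' @param rngSeed master seed; per-stage seeds are derived from it.
#' @return a list with class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(spec = NULL, cohortDir = NULL,
                           simConfig = simulationConfig(),
                           grid = couplingGrid(), nBins = 41L,
                           targetDensity = NULL, cvIncludeZeros = TRUE,
                           referenceThresholds = 62.5,
                           dropLabels = character(), alpha = 0.01,
                           modularityRepeats = 100L,
                           outputDir = tempfile("dynconn_run_"),
                           rngSeed = 1L) {
    if (is.null(spec) && is.null(cohortDir)) {
        stop("provide either a cohort spec or a cohort directory")
    }
    structure(list(spec = spec, cohortDir = cohortDir,
                   simConfig = simConfig, grid = grid,
                   nBins = as.integer(nBins), targetDensity = targetDensity,
                   cvIncludeZeros = cvIncludeZeros,
                   referenceThresholds = referenceThresholds,
                   dropLabels = dropLabels, alpha = alpha,
                   modularityRepeats = as.integer(modularityRepeats),
                   outputDir = outputDir, rngSeed = as.integer(rngSeed)),
              class = "PipelineConfig")
}

## Per-stage seeds derived from the master seed by a fixed counter scheme,
## kept below 2^31 - 1.
stageSeed <- function(master, index) {
    as.integer((as.numeric(master) + index * 1000003) %% 2147483647)
}

#' Read a cohort from a directory
#'
#' Expects member matrix files named \code{member_*.txt} (read in sorted
#' order) and a shared \code{nodes.tsv} node table.
#'
#' @param dir directory path.
#' @return a \linkS4class{ConnectomeCohort} (weighted; binarize as needed).
#' @export
readCohort <- function(dir) {
    files <- sort(list.files(dir, pattern = "^member_.*\\.txt$",
                             full.names = TRUE))
    if (!length(files)) stop("no member_*.txt files in ", dir)
    nodesPath <- file.path(dir, "nodes.tsv")
    if (!file.exists(nodesPath)) stop("missing ", nodesPath)
    members <- lapply(files, readConnectome, nodeTablePath = nodesPath)
    connectomeCohort(members)
}

#' Write a cohort (and optional ground truth) to a directory
#'
#' @param cohort a \linkS4class{ConnectomeCohort}.
#' @param dir output directory (created if needed).
#' @param groundTruth optional seed network to write alongside.
#' @param coreEdges optional 1-based core edge index matrix; written 0-based.
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir, groundTruth = NULL, coreEdges = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeNodeTable(nodeTable(cohort), file.path(dir, "nodes.tsv"))
    for (i in seq_along(members(cohort))) {
        writeConnectome(cohort[[i]],
                        file.path(dir, sprintf("member_%03d.txt", i)))
    }
    if (!is.null(groundTruth)) {
        writeConnectome(groundTruth, file.path(dir, "ground_truth.txt"))
    }
    if (!is.null(coreEdges)) {
        utils::write.table(
            data.frame(i = coreEdges[, 1L] - 1L, j = coreEdges[, 2L] - 1L),
            file.path(dir, "core_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}

runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
    })
}

#' Run the full group-network construction and comparison pipeline
#'
#' Stages: (1) obtain the cohort (generate synthetic or read from disk,
#' dropping any configured regions and binarizing); (2) build the consensus
#' ladder and edge-prevalence histogram; (3) simulate subject metastability
#' profiles; (4) select the DBC; (5) build the distance-dependent and
#' consistency-based reference networks (the latter at the DBC's density
#' unless overridden); (6) compare all group networks to the cohort
#' dynamically (profile-distance ANOVA with post-hocs) and structurally
#' (mean KS per nodal metric, z-scores per global metric, edge-length KS);
#' (7) write networks, tables, the report and a manifest to
#' \code{config$outputDir}. Re-running with an identical configuration
#' reproduces all numeric outputs bit-identically.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list with the cohort, ladder, selection, group
#'   networks, comparison report and output directory.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    out <- config$outputDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)

    ## stage 1: cohort
    synth <- NULL
    cohortW <- runStage("cohort", {
        if (!is.null(config$spec)) {
            spec <- config$spec
            spec$rngSeed <- stageSeed(config$rngSeed, 1L)
            synth <- generateCohort(spec)
            synth$cohort
        } else {
            readCohort(config$cohortDir)
        }
    })
    if (length(config$dropLabels)) {
        cohortW <- dropRegions(cohortW, config$dropLabels)
        if (!is.null(synth)) {
            synth$groundTruth <- dropRegions(synth$groundTruth,
                                             config$dropLabels)
        }
    }
    cohort <- binarize(cohortW)
    n <- length(cohort)

    ## reference thresholds must lie on the ladder before any simulation
    ladderT <- seq_len(n) * 100 / n
    badT <- config$referenceThresholds[
        !vapply(config$referenceThresholds,
                function(t) any(abs(ladderT - t) < 1e-9), logical(1))]
    if (length(badT)) {
        stop("reference threshold(s) not on the n = ", n, " ladder: ",
             paste(badT, collapse = ", "))
    }

    ## stage 2: candidate ladder and prevalence
    ladder <- runStage("ladder", buildLadder(cohort))
    prev <- edgePrevalence(cohort)
    hist <- prevalenceHistogram(prev, n)

    ## stage 3: subject profiles
    simConfig <- config$simConfig
    simConfig@rngSeed <- stageSeed(config$rngSeed, 2L)
    subjectProfiles <- runStage("subject-profiles", {
        lapply(members(cohort), metastabilityProfile,
               grid = config$grid, config = simConfig)
    })

    ## stage 4: DBC selection
    selection <- runStage("dbc-selection", {
        selectDbc(ladder, subjectProfiles, config$grid, simConfig)
    })

    ## stage 5: reference group networks
    groups <- runStage("reference-builders", {
        targetDensity <- if (is.null(config$targetDensity)) {
            edgeDensity(dbcNetwork(selection))
        } else {
            config$targetDensity
        }
        g <- list(dbc = dbcNetwork(selection))
        for (t in config$referenceThresholds) {
            g[[sprintf("consensus_%g", t)]] <- uniformConsensus(cohort, t)
        }
        g$distance_dependent <-
            distanceDependentConsensus(cohort, nBins = config$nBins)
        g$consistency <- consistencyConsensus(
            cohortW, targetDensity, cvIncludeZeros = config$cvIncludeZeros)
        g
    })

    ## stage 6: comparison report
    report <- runStage("comparison", {
        compareGroupNetworks(groups, cohort, subjectProfiles,
                             grid = config$grid, config = simConfig,
                             alpha = config$alpha,
                             modularityRepeats = config$modularityRepeats,
                             metricsSeed = stageSeed(config$rngSeed, 3L))
    })

    ## stage 7: outputs
    runStage("write-outputs", {
        if (!is.null(synth)) {
            writeCohort(cohort, file.path(out, "cohort"),
                        groundTruth = synth$groundTruth,
                        coreEdges = synth$coreEdges)
        }
        for (nm in names(groups)) {
            writeConnectome(groups[[nm]],
                            file.path(out, paste0(nm, ".txt")))
        }
        utils::write.table(mseTable(selection), file.path(out, "mse.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(hist, file.path(out, "prevalence_histogram.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        prof <- data.frame(K = selection@grid,
                           subject_mean = selection@subjectMean,
                           subject_sd = selection@subjectSD)
        utils::write.table(prof, file.path(out, "subject_profile.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(reportAsJson(report, selection),
                             file.path(out, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        manifest <- list(
            rng_seed = config$rngSeed,
            stage_seeds = list(cohort = stageSeed(config$rngSeed, 1L),
                               profiles = stageSeed(config$rngSeed, 2L),
                               metrics = stageSeed(config$rngSeed, 3L)),
            n_subjects = n, n_nodes = nNodes(cohort),
            coupling_grid = config$grid,
            simulation = list(total_time = simConfig@totalTime,
                              transient_time = simConfig@transientTime,
                              dt = simConfig@dt,
                              mean_frequency = simConfig@meanFrequency,
                              frequency_sd = simConfig@frequencySD,
                              n_realisations = simConfig@nRealisations,
                              paired_seeds = TRUE),
            builders = list(n_bins = config$nBins,
                            target_density =
                                edgeDensity(groups$consistency),
                            cv_include_zeros = config$cvIncludeZeros),
            reference_thresholds = config$referenceThresholds,
            dbc_threshold = dbcThreshold(selection),
            synthetic = !is.null(synth))
        jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })

    invisible(list(cohort = cohort, weightedCohort = cohortW,
                   groundTruth = if (!is.null(synth)) synth$groundTruth,
                   ladder = ladder, selection = selection,
                   subjectProfiles = subjectProfiles, groups = groups,
                   prevalenceHistogram = hist, report = report,
                   outputDir = out))
}

#' Compare group networks to the cohort
#'
#' Dynamical comparison (profile-distance ANOVA with Bonferroni-corrected
#' Welch post-hocs) plus structural comparison: mean per-subject KS
#' statistics for each nodal metric, z-scores for each global metric, and
#' edge-length distribution KS (both mean per-subject and against the pooled
#' subject distribution).
#'
#' @param groups named list of group \linkS4class{BinaryConnectome}s.
#' @param cohort the binary cohort.
#' @param subjectProfiles subject metastability profiles.
#' @param grid,config simulation grid and configuration (shared seed pairs
#'   group profiles with the subjects').
#' @param alpha post-hoc significance level.
#' @param modularityRepeats community-detection restarts.
#' @param metricsSeed seed for the metric computations.
#' @return list with \code{dynamical}, \code{nodalKS}, \code{globalZ},
#'   \code{edgeLengthKS}.
#' @export
compareGroupNetworks <- function(groups, cohort, subjectProfiles,
                                 grid = couplingGrid(),
                                 config = simulationConfig(), alpha = 0.01,
                                 modularityRepeats = 100L,
                                 metricsSeed = 1L) {
    dynamical <- dynamicalAnova(groups, subjectProfiles, grid, config,
                                alpha = alpha)
    subjNodal <- lapply(members(cohort),
                        function(m) suppressWarnings(nodalMetrics(m)))
    subjGlobal <- lapply(members(cohort), function(m) {
        suppressWarnings(globalMetrics(m, modularityRepeats, metricsSeed))
    })
    D <- euclideanDistanceMatrix(nodeTable(cohort))
    subjLengths <- lapply(members(cohort), edgeLengths, distanceMatrix = D)
    pooled <- unlist(subjLengths)

    nodalNames <- c("degree", "clustering", "betweenness", "eigenvector")
    globalNames <- c("density", "modularity", "avgClustering",
                     "charPathLength")
    nodalKS <- lapply(groups, function(net) {
        gm <- suppressWarnings(nodalMetrics(net))
        sapply(nodalNames, function(metric) {
            res <- meanKS(gm[[metric]],
                          lapply(subjNodal, `[[`, metric))
            c(mean = res$mean, sd = res$sd)
        })
    })
    globalZ <- lapply(groups, function(net) {
        gm <- suppressWarnings(globalMetrics(net, modularityRepeats,
                                             metricsSeed))
        vapply(globalNames, function(metric) {
            globalZscore(gm[[metric]],
                         vapply(subjGlobal, `[[`, numeric(1), metric))
        }, numeric(1))
    })
    edgeLengthKS <- lapply(groups, function(net) {
        len <- edgeLengths(net, D)
        per <- meanKS(len, subjLengths)
        list(mean = per$mean, sd = per$sd,
             pooled = ksStatistic(len, pooled))
    })
    list(dynamical = dynamical, nodalKS = nodalKS, globalZ = globalZ,
         edgeLengthKS = edgeLengthKS)
}

reportAsJson <- function(report, selection) {
    list(
        dbc_threshold = dbcThreshold(selection),
        dbc_mse = min(selection@mse),
        dynamical_anova = report$dynamical$anova,
        dynamical_pairwise = report$dynamical$pairwise,
        nodal_ks = lapply(report$nodalKS, function(m) {
            as.data.frame(t(m))
        }),
        global_z = report$globalZ,
        edge_length_ks = report$edgeLengthKS)
}
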