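## Dynamics-based consensus selection: mean squared error between candidate
## group profiles and the subjects' profiles, minimised over the consensus
## ladder.

profileValues <- function(p) {
    if (is(p, "MetastabilityProfile")) p@values else as.numeric(p)
}

checkSharedGrid <- function(a, b) {
    if (is(a, "MetastabilityProfile") && is(b, "MetastabilityProfile") &&
        !isTRUE(all.equal(a@K, b@K))) {
        stop("profiles were computed on different coupling grids")
    }
    if (length(profileValues(a)) != length(profileValues(b))) {
        stop("profiles differ in length")
    }
}

#' Mean squared error between a group profile and the subject profiles
#'
#' For each subject, the mean over grid points of the squared difference
#' between the group and subject metastability profiles; then the mean over
#' subjects. The grid-point mean makes the value comparable across grids of
#' different resolution (set \code{gridReduction = "sum"} for the
#' per-subject sum instead).
#'
#' @param groupProfile a \linkS4class{MetastabilityProfile} (or numeric
#'   vector of profile values).
#' @param subjectProfiles list of profiles on the same grid.
#' @param gridReduction \code{"mean"} (default) or \code{"sum"}.
#' @return non-negative scalar.
#' @export
profileMse <- function(groupProfile, subjectProfiles,
                       gridReduction = c("mean", "sum")) {
    gridReduction <- match.arg(gridReduction)
    reduce <- if (gridReduction == "mean") mean else sum
    g <- profileValues(groupProfile)
    errs <- vapply(subjectProfiles, function(s) {
        checkSharedGrid(groupProfile, s)
        reduce((g - profileValues(s))^2)
    }, numeric(1))
    mean(errs)
}

#' Squared Euclidean distance between two profiles
#'
#' Sum over grid points of squared differences; the per-subject dynamical
#' distance fed to the across-group ANOVA.
#'
#' @param groupProfile,subjectProfile profiles on the same grid.
#' @return non-negative scalar.
#' @export
profileSqEuclid <- function(groupProfile, subjectProfile) {
    checkSharedGrid(groupProfile, subjectProfile)
    sum((profileValues(groupProfile) - profileValues(subjectProfile))^2)
}

#' Select the dynamics-based consensus (DBC) network
#'
#' Computes a metastability profile for every ladder network (profiles are
#' paired with the subjects' via the shared simulation seed), the MSE of
#' each against the subject profiles, and selects the threshold attaining
#' the minimum. Exact MSE ties are broken toward the threshold nearest 50\%
#' consensus (thresholds far from 50\% risk unrepresentative density), then
#' toward the lower threshold. Nested ladder networks with identical edge
#' sets are simulated once.
#'
#' @param ladder a \linkS4class{ThresholdLadder}.
#' @param subjectProfiles list of subject \linkS4class{MetastabilityProfile}s
#'   computed with the same \code{grid} and \code{config}.
#' @param grid coupling grid.
#' @param config \linkS4class{SimulationConfig} (seed shared with the
#'   subject profiles).
#' @param gridReduction passed to [profileMse()].
#' @return a \linkS4class{DBCSelection}.
#' @export
selectDbc <- function(ladder, subjectProfiles, grid = couplingGrid(),
                      config = simulationConfig(),
                      gridReduction = c("mean", "sum")) {
    stopifnot(is(ladder, "ThresholdLadder"), length(subjectProfiles) >= 1L)
    gridReduction <- match.arg(gridReduction)
    ## nesting means two ladder networks are identical iff their edge counts
    ## match, so simulate each distinct network once
    counts <- vapply(ladder@networks, function(x) sum(adjacency(x)),
                     numeric(1))
    uniq <- !duplicated(counts)
    profiles_uniq <- lapply(ladder@networks[uniq], metastabilityProfile,
                            grid = grid, config = config)
    profiles <- profiles_uniq[match(counts, counts[uniq])]
    mse <- vapply(profiles, profileMse, numeric(1),
                  subjectProfiles = subjectProfiles,
                  gridReduction = gridReduction)
    best <- which(mse == min(mse))
    if (length(best) > 1L) {
        best <- best[order(abs(ladder@thresholds[best] - 50),
                           ladder@thresholds[best])][1L]
    }
    subj <- vapply(subjectProfiles, profileValues, numeric(length(grid)))
    subj <- matrix(subj, nrow = length(grid))
    new("DBCSelection",
        thresholds = ladder@thresholds,
        mse = unname(mse),
        dbcThreshold = ladder@thresholds[best],
        dbcNetwork = ladder@networks[[best]],
        subjectMean = rowMeans(subj),
        subjectSD = if (ncol(subj) > 1L) apply(subj, 1L, stats::sd)
                    else rep(0, nrow(subj)),
        grid = as.numeric(grid))
}
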