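# End-to-end per-fly analysis and cohort comparison.

#' Analyze one fly end to end
#'
#' Smoothing, kinematics, Schmidt-trigger segmentation, turn
#' classification, epoch delineation, transit detection and the 17 motor
#' parameters, under one configuration.
#'
#' @param traj a \linkS4class{FlyTrajectory}.
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}). A \code{smoothingWindow} of 1
#'   skips smoothing, appropriate for noise-free synthetic tracks.
#' @return List with elements trajectory (smoothed), kinematics,
#'   segmentation, epochs, transits and features.
#' @export
analyzeFly <- function(traj, config = defaultPipelineConfig()) {
  kcfg <- config$kinematics
  sm <- if (kcfg$smoothingWindow > 1L)
    smoothTrack(traj, kcfg$smoothingWindow) else traj
  kin <- computeKinematics(sm, kcfg$minSpeedForAngular)
  seg <- segmentRunsStops(kin$speed, kcfg$stopThreshold,
                          kcfg$runThreshold, frameRate(sm))
  seg <- classifyTurns(sm, kin, seg, kcfg$turnWindow,
                       kcfg$smoothTurnThreshold, kcfg$sharpTurnThreshold)
  epochs <- delineateEpochs(sm, config$epochs$odorOn,
                            config$epochs$latency,
                            config$epochs$duringLength)
  transits <- detectTransits(sm, debounce = kcfg$transitDebounce)
  fv <- computeFeatureVector(sm, kin, seg, epochs, transits,
                             ringHalfWidth = kcfg$ringHalfWidth)
  list(trajectory = sm, kinematics = kin, segmentation = seg,
       epochs = epochs, transits = transits, features = fv)
}

#' Run the full comparison pipeline
#'
#' Tracks (already-extracted trajectories) are analyzed per fly, the 17
#' motor parameters assembled into a feature matrix, and two groups
#' compared with the rank-sum panel, the pairwise-correlation screen,
#' PCA and canonical variate analysis with a label-shuffle permutation
#' test. Excluded flies (never entering the odor zone) are listed with
#' their reasons. Results are optionally written as TSV tables plus a
#' YAML run manifest recording the configuration, its hash and all seeds,
#' which suffices to reproduce every output.
#'
#' @param trajectories list of \linkS4class{FlyTrajectory} objects, or a
#'   path to a trajectory TSV table.
#' @param groups group label per fly (length matching the input).
#' @param config configuration list.
#' @param outDir optional output directory for TSV results.
#' @return List with featureMatrix, groups, panel, correlations, pca,
#'   cva (permutation-tested), excluded and manifest.
#' @export
runPipeline <- function(trajectories, groups,
                        config = defaultPipelineConfig(),
                        outDir = NULL) {
  if (is.character(trajectories) && length(trajectories) == 1L) {
    geom <- do.call(arenaGeometry, config$arena)
    trajectories <- readTrajectoryTable(trajectories, geom = geom)
  }
  if (!length(trajectories))
    stop("no input trajectories", call. = FALSE)
  if (length(groups) != length(trajectories))
    stop("one group label per fly required", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups for comparison", call. = FALSE)

  analyses <- lapply(trajectories, analyzeFly, config = config)
  features <- lapply(analyses, `[[`, "features")
  M <- featureMatrix(features)

  excluded <- data.frame(fly_id = rownames(M),
                         group = as.character(groups),
                         reason = vapply(features, function(f) {
                           if (isTRUE(attr(f, "excluded")))
                             unname(attr(f, "reasons")["excluded"])
                           else ""
                         }, character(1)))
  excluded <- excluded[nzchar(excluded$reason), , drop = FALSE]

  lev <- levels(groups)
  panel <- ranksumPanel(M[groups == lev[1L], , drop = FALSE],
                        M[groups == lev[2L], , drop = FALSE],
                        alpha = config$stats$alpha)
  correlations <- pairwiseCorrelations(M, alpha = config$stats$alpha)
  pca <- pcaVariance(M, standardize = config$stats$standardize)
  cvaRes <- permutationTest(M, groups, nPerm = config$stats$nPerm,
                            seed = config$seed,
                            ridge = config$stats$ridge)

  manifest <- list(package = "flywalkr",
                   version = as.character(utils::packageVersion("flywalkr")),
                   configHash = rlang::hash(config),
                   config = config,
                   nFlies = length(trajectories),
                   groups = as.character(groups),
                   excluded = excluded$fly_id)

  out <- list(featureMatrix = M, groups = groups, panel = panel,
              correlations = correlations, pca = pca, cva = cvaRes,
              excluded = excluded, manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(x, file.path(outDir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE, na = "NA")
    wt(data.frame(fly_id = rownames(M), group = as.character(groups),
                  M, check.names = FALSE), "features.tsv")
    wt(panel, "ranksum_panel.tsv")
    wt(correlations, "correlations.tsv")
    wt(data.frame(component = seq_along(pca$fractions),
                  variance_fraction = pca$fractions), "pca_variance.tsv")
    wt(data.frame(fly_id = rownames(M)[stats::complete.cases(M)],
                  group = as.character(cvaRes@groups),
                  cv1 = cvaRes@projections), "cva_projections.tsv")
    wt(data.frame(statistic = c("cv1_median_distance", "permutation_p",
                                "permutation_p_plus1", "n_perm"),
                  value = c(cvaRes@distance, cvaRes@permutationP,
                            cvaRes@permutationPPlusOne, cvaRes@nPerm)),
       "cva_summary.tsv")
    wt(excluded, "excluded_flies.tsv")
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  out
}
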