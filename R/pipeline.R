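#' Default full-pipeline configuration
#'
#' One nested list drives the whole run: the cohort simulation parameters,
#' the preprocessing and metric settings, the inference thresholds, and the
#' behavioral-score association. Serialises losslessly to/from YAML.
#'
#' @param seed root seed for the run.
#' @param outDir optional output directory (NIfTI maps, cluster TSVs,
#'   manifest JSON are written when set).
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L, outDir = NULL) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    cohort = list(nPerGroup = 12, gridShape = c(24, 24, 24), trS = 3.0,
                  nVolumes = 120, noiseSd = 10, motionSeverity = 0.5),
    preproc = preprocConfig(),
    metrics = metricConfig(),
    alffInput = "unfiltered",
    inference = list(voxelP = 0.05, clusterP = 0.05, twoTailed = TRUE,
                     connectivity = 26),
    scores = list(slope = 2, intercept = 10, noiseSd = 0)
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror [defaultRunConfig()].
#' @return configuration list (missing keys filled with defaults).
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(user[[k]]) && is.list(cfg[[k]]))
      utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
  }
  cfg
}

.stageLog <- function(manifest, stage, msg) {
  manifest$log <- c(manifest$log, sprintf("[%s] %s", stage, msg))
  manifest
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, preprocess (with motion QC), site-coverage matching,
#' metric computation (all five maps, standardized + smoothed, plus the
#' unstandardized PerAF branch), voxelwise group inference with GRF cluster
#' correction per metric, and cluster-score partial correlations, in that
#' fixed order. Flag contracts are enforced at every stage and a violation
#' aborts with the stage name. Outputs are deterministic for a fixed seed.
#'
#' @param config configuration list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return list with `manifest` (config snapshot, stage log, subject
#'   inclusion accounting, file hashes), `clusters` (per-metric cluster
#'   tables), `correlations` (partial-correlation table), `covariates`
#'   (included subjects).
#' @export
runFullPipeline <- function(config = defaultRunConfig()) {
  manifest <- list(version = as.character(utils::packageVersion("restiba")),
                   config = config, log = character(), files = list(),
                   timestamp = format(Sys.time(), tz = "UTC"))
  stage <- "simulate"
  result <- tryCatch({
    ## --- simulate -----------------------------------------------------
    cc <- config$cohort
    spec <- cohortSpec(nPerGroup = cc$nPerGroup, gridShape = cc$gridShape,
                       trS = cc$trS, nVolumes = cc$nVolumes,
                       noiseSd = cc$noiseSd, seed = config$seed)
    cohort <- generateCohort(spec, motionSeverity = cc$motionSeverity)
    manifest <- .stageLog(manifest, stage,
                          sprintf("%d subjects generated", length(cohort$subjects)))

    ## --- preprocess + motion QC --------------------------------------
    stage <- "preprocess"
    qc <- vapply(cohort$subjects, function(s)
      motionQC(s$motion, config$preproc$motionLimitMm,
               config$preproc$motionLimitDeg)$include, logical(1))
    records <- cohort$covariates
    records$qc_exclude <- !qc
    kept <- matchFilterCohort(records)
    excl <- attr(kept, "exclusions")
    for (i in seq_len(nrow(excl)))
      manifest <- .stageLog(manifest, stage, sprintf(
        "excluded %s (%s)", excl$subject_id[i], excl$reason[i]))
    manifest$inclusion <- list(
      enrolled = nrow(records),
      excluded_motion = sum(excl$reason == "motion"),
      excluded_site_coverage = sum(excl$reason == "site-coverage"),
      included = nrow(kept))
    stopifnot(manifest$inclusion$included ==
                manifest$inclusion$enrolled - nrow(excl))
    idx <- match(kept$subject_id, records$subject_id)
    subjects <- cohort$subjects[idx]
    preps <- lapply(subjects, function(s)
      suppressMessages(preprocessSubject(s, config$preproc)))
    kept$mean_fd <- vapply(preps, function(p) p$fd$meanFd, numeric(1))
    manifest <- .stageLog(manifest, stage,
                          sprintf("%d subjects preprocessed", length(preps)))

    ## --- metrics ------------------------------------------------------
    stage <- "metrics"
    if (!identical(config$alffInput, "unfiltered")) {
      for (p in preps) computeALFF(p$filtered)  # contract violation -> error
    }
    metricSets <- lapply(preps, function(p)
      suppressMessages(computeAllMetrics(p, config$metrics)))
    metricNames <- names(metricSets[[1]])
    manifest <- .stageLog(manifest, stage, paste(
      length(metricSets), "subjects x", length(metricNames), "maps"))

    ## --- group inference ---------------------------------------------
    stage <- "group"
    design <- buildDesignMatrix(kept)
    inf <- config$inference
    clusters <- list()
    statMaps <- list()
    for (mn in metricNames) {
      maps <- lapply(metricSets, `[[`, mn)
      stat <- glmTwoSampleT(maps, design)
      smooth <- estimateSmoothness(stat)
      tab <- grfClusterInference(stat, smooth, inf$voxelP, inf$clusterP,
                                 inf$twoTailed, inf$connectivity)
      clusters[[mn]] <- tab
      statMaps[[mn]] <- stat
      manifest <- .stageLog(manifest, stage,
                            sprintf("%s: %d surviving cluster(s)", mn, nrow(tab)))
    }

    ## --- behavioral correlations -------------------------------------
    stage <- "correlate"
    correlations <- data.frame()
    revRows <- which(kept$group == "reverter")
    for (mn in metricNames) {
      tab <- clusters[[mn]]
      if (!nrow(tab)) next
      maps <- lapply(metricSets[revRows], `[[`, mn)
      masks <- attr(tab, "masks")
      clMeans <- vapply(maps, function(m) mean(m@values[masks[[1]]]),
                        numeric(1))
      scores <- data.frame(synthetic_scale = generateBehavioralScores(
        clMeans, slope = config$scores$slope,
        intercept = config$scores$intercept,
        noiseSd = config$scores$noiseSd,
        seed = substreamSeed(config$seed, "scores")))
      cors <- clusterScoreCorrelations(
        maps, tab, scores,
        data.frame(site = factor(kept$site[revRows])))
      cors$metric <- mn
      correlations <- rbind(correlations, cors)
    }
    manifest <- .stageLog(manifest, stage,
                          sprintf("%d cluster-scale pair(s)", nrow(correlations)))

    ## --- outputs ------------------------------------------------------
    if (!is.null(config$outDir)) {
      dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
      for (mn in metricNames) {
        tpath <- file.path(config$outDir, paste0("stat_", mn, ".nii.gz"))
        RNifti::writeNifti(.asNiftiArray(statMaps[[mn]]@tValues,
                                         statMaps[[mn]]@voxelSizeMm), tpath)
        cpath <- file.path(config$outDir, paste0("clusters_", mn, ".tsv"))
        writeClusterTable(clusters[[mn]], cpath)
        manifest$files[[basename(tpath)]] <- unname(tools::md5sum(tpath))
        manifest$files[[basename(cpath)]] <- unname(tools::md5sum(cpath))
      }
      if (nrow(correlations)) {
        rpath <- file.path(config$outDir, "correlations.tsv")
        utils::write.table(correlations, rpath, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        manifest$files[[basename(rpath)]] <- unname(tools::md5sum(rpath))
      }
    }
    list(clusters = clusters, correlations = correlations,
         covariates = kept, statMaps = statMaps)
  }, error = function(e) {
    manifest <<- .stageLog(manifest, stage, paste("FAILED:", conditionMessage(e)))
    manifest$status <<- "failed"
    if (!is.null(config$outDir)) {
      dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest,
                           file.path(config$outDir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    }
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest$status <- "ok"
  if (!is.null(config$outDir)) {
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  c(list(manifest = manifest), result)
}
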