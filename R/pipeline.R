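#' Default pipeline configuration
#'
#' Returns the full stage-parameter list consumed by [runPipeline()]; any
#' element can be overridden through \code{...}. Unspecified values fall
#' back to these defaults and are recorded in the run manifest.
#'
#' @param ... named overrides, e.g. \code{lambda = 0.2}, \code{k = 4}.
#' @return named list of pipeline parameters.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulate
    nGroupA = 20L, nGroupB = 20L, nTimepoints = 230L,
    # postproc
    detrendOrder = 1L, despikeZ = 3.5, lowpassHz = 0.15,
    # dfnc
    widthTr = 30L, stepTr = 1L, lambda = 0.1,
    # cluster
    k = 4L, nInit = 5L,
    # stats
    fdrQ = 0.05, tVariant = "pooled",
    # mediation
    nBoot = 5000L, mediator = "dwell_s1", outcome = "MoCA",
    # classification
    nFolds = 10L, nRepeats = 100L, svmCost = 1, mode = "fold_safe")
  utils::modifyList(cfg, list(...))
}

#' Run the full dFNC pipeline on a synthetic cohort
#'
#' Executes simulate -> post-process -> windowed FNC -> state clustering ->
#' temporal metrics -> group statistics -> mediation -> classification,
#' writing every intermediate artifact and a JSON manifest (parameters,
#' seeds, per-file hashes) under \code{outDir}. Re-running with the same
#' config is bit-identical for the deterministic stages.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir output directory.
#' @param cohort optional pre-built [CohortBundle-class]; by default one is
#'   simulated from the config.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, cohort = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(cohort)) {
      spec <- syntheticSpec(nGroupA = config$nGroupA, nGroupB = config$nGroupB,
                            nTimepoints = config$nTimepoints,
                            seed = config$seed)
      cohort <- simulateCohort(spec)
    }
    writeCohort(cohort, file.path(outDir, "cohort"))

    stage <- "postproc"
    clean <- lapply(timecourses(cohort), postprocess,
                    detrendOrder = config$detrendOrder,
                    despikeZ = config$despikeZ, lowpassHz = config$lowpassHz)

    stage <- "dfnc"
    wspec <- windowSpec(config$widthTr, config$stepTr)
    series <- cohortDFNC(clean, spec = wspec, lambda = config$lambda)
    dir.create(file.path(outDir, "fnc"), showWarnings = FALSE)
    for (s in series)
      writeFNCSeries(s, file.path(outDir, "fnc", paste0(subjectId(s), ".tsv")))

    stage <- "cluster"
    model <- fitStateModel(series, k = config$k, nInit = config$nInit,
                           seed = config$seed)
    write.table(centroids(model), file.path(outDir, "centroids.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    labDf <- do.call(rbind, lapply(names(stateLabels(model)), function(id)
      data.frame(subject_id = id,
                 window = seq_along(stateLabels(model)[[id]]) - 1L,
                 state = stateLabels(model)[[id]])))
    write.table(labDf, file.path(outDir, "state_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "metrics"
    profiles <- temporalProfiles(model)
    clin <- clinicalTable(cohort)
    profiles <- merge(profiles, clin[, c("subject_id", "group")],
                      by = "subject_id")
    write.table(profiles, file.path(outDir, "temporal_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "stats"
    stats <- runGroupAnalysis(profiles[setdiff(names(profiles), "group")],
                              clin, q = config$fdrQ,
                              variant = config$tVariant)
    write.table(stats$groupTests, file.path(outDir, "group_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(stats$correlations))
      write.table(stats$correlations, file.path(outDir, "correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "mediate"
    merged <- merge(profiles, clin, by = c("subject_id", "group"))
    med <- bootstrapMediation(
      x = as.integer(merged$group == "CD"),
      m = merged[[config$mediator]], y = merged[[config$outcome]],
      nBoot = config$nBoot, seed = config$seed)
    .writeSidecar(file.path(outDir, "mediation"), list(
      a = med@a, b = med@b, c = med@c, c_prime = med@cPrime,
      indirect = med@indirect, bca = med@bcaInterval,
      percentile = med@percentileInterval, boot_p = med@bootP,
      n_boot = med@nBoot, seed = med@seed))

    stage <- "classify"
    groups <- setNames(clin$group, clin$subject_id)
    cls <- evaluateClassifier(series, stateLabels(model), groups,
                              k = config$k, mode = config$mode,
                              nFolds = config$nFolds,
                              nRepeats = config$nRepeats,
                              cost = config$svmCost, seed = config$seed)
    .writeSidecar(file.path(outDir, "classification"), list(
      mode = cls@mode, mean_accuracy = mean(cls@accuracy),
      class_accuracy = as.list(cls@classAccuracy), auc = cls@auc,
      scheme = cls@scheme, seed = cls@seed))
    write.table(cls@roc, file.path(outDir, "roc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    list(cohort = cohort, series = series, model = model,
         profiles = profiles, stats = stats, mediation = med,
         classification = cls)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outDir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dfncstates")),
    config = config,
    files = lapply(setNames(files, sub(paste0("^", outDir, "/?"), "", files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
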