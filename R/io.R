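#' @name io
#' @title Delimited-text readers and writers
#' @description All pipeline artifacts are plain TSV plus a JSON sidecar
#'   (\code{<file>.json}) recording parameters and seeds. Timepoint and
#'   window indices are 0-based in files; state labels are 1-based.
NULL

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.readTsvStrict <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric or missing cell at row ", bad[1], ", column '",
           names(df)[j], "' of ", path)
    df[[j]] <- v
  }
  df
}

#' Write component time courses as TSV (+ JSON sidecar)
#'
#' @param tc a [ComponentTimecourses-class].
#' @param path output TSV path (rows = timepoints, columns = components).
#' @return \code{path}, invisibly.
#' @export
writeTimecourses <- function(tc, path) {
  stopifnot(is(tc, "ComponentTimecourses"))
  df <- as.data.frame(tc@data)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeSidecar(path, list(
    subject_id = tc@subjectId, tr_seconds = tc@trSeconds,
    partition = as.list(table(networkLabels(tc))),
    component_networks = as.character(networkLabels(tc))))
  invisible(path)
}

#' Read component time courses written by [writeTimecourses()]
#'
#' @param path TSV path; the JSON sidecar (if present) restores TR,
#'   subject id and partition.
#' @param trSeconds,subjectId,partitionSizes fallbacks when no sidecar
#'   exists.
#' @return A [ComponentTimecourses-class].
#' @export
readTimecourses <- function(path, trSeconds = 2, subjectId = NULL,
                            partitionSizes = NULL) {
  df <- .readTsvStrict(path)
  X <- as.matrix(df)
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    nets <- meta$component_networks
    if (length(nets) != ncol(X))
      stop("sidecar partition (", length(nets),
           " components) does not match the file header (", ncol(X), ")")
    part <- new("NetworkPartition",
                networks = setNames(factor(nets, levels = c("DMN", "CEN", "SN")),
                                    colnames(X)))
    return(componentTimecourses(X, trSeconds = meta$tr_seconds,
                                subjectId = meta$subject_id, partition = part))
  }
  part <- if (is.null(partitionSizes)) NULL
    else networkPartition(partitionSizes, componentNames = colnames(X))
  componentTimecourses(X, trSeconds = trSeconds,
                       subjectId = if (is.null(subjectId)) basename(path) else subjectId,
                       partition = part)
}

#' Write a windowed FNC series as TSV (+ JSON sidecar)
#'
#' @param series a [WindowedFNCSeries-class].
#' @param path output TSV path (rows = windows, columns = pairs).
#' @return \code{path}, invisibly.
#' @export
writeFNCSeries <- function(series, path) {
  df <- as.data.frame(fncMatrix(series))
  names(df) <- pairNames(series)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeSidecar(path, list(subject_id = subjectId(series),
                           lambda = series@lambda,
                           window_starts = windowStarts(series)))
  invisible(path)
}

#' Write / read the clinical table
#'
#' @param clinical data.frame with subject_id, group and covariate columns.
#' @param path TSV path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
writeClinicalTable <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClinicalTable
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "group") %in% names(df)))
  df
}

#' Write a full synthetic cohort to a directory
#'
#' One TSV per subject, a clinical TSV, a per-timepoint ground-truth label
#' TSV, and a JSON sidecar recording the full spec and seed.
#'
#' @param cohort a [CohortBundle-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tc in cohort@timecourses)
    writeTimecourses(tc, file.path(dir, paste0(subjectId(tc), ".tsv")))
  writeClinicalTable(cohort@clinical, file.path(dir, "clinical.tsv"))
  ids <- names(cohort@timecourses)
  gt <- do.call(rbind, lapply(ids, function(id)
    data.frame(subject_id = id,
               timepoint = seq_along(cohort@groundTruth[[id]]$labels) - 1L,
               state = cohort@groundTruth[[id]]$labels)))
  write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  spec <- cohort@spec
  .writeSidecar(file.path(dir, "cohort"), list(
    n_group_a = spec@nGroupA, n_group_b = spec@nGroupB,
    n_components = spec@nComponents, partition_sizes = spec@partitionSizes,
    n_timepoints = spec@nTimepoints, tr_seconds = spec@trSeconds,
    n_states = spec@nStates, observation_noise_sd = spec@observationNoiseSd,
    transition_matrix_a = spec@transitionMatrixA,
    transition_matrix_b = spec@transitionMatrixB,
    clinical_model = spec@clinicalModel, seed = spec@seed))
  invisible(dir)
}
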