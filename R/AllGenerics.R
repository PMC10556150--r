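#' @name accessors
#' @title Accessors for the core dFNC classes
#' @description Slot access for [ComponentTimecourses-class],
#'   [WindowedFNCSeries-class], [StateModel-class] and [CohortBundle-class].
#' @param object an object of one of the classes above.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("tcData", function(object) standardGeneric("tcData"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("partition", function(object) standardGeneric("partition"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("networkLabels", function(object) standardGeneric("networkLabels"))
#' @rdname accessors
#' @export
setGeneric("fncMatrix", function(object) standardGeneric("fncMatrix"))
#' @rdname accessors
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setGeneric("pairNames", function(object) standardGeneric("pairNames"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("stateCost", function(object) standardGeneric("stateCost"))
#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(object) standardGeneric("clinicalTable"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("cohortSpec", function(object) standardGeneric("cohortSpec"))
#' @rdname accessors
#' @export
setGeneric("timecourses", function(object) standardGeneric("timecourses"))

setMethod("tcData", "ComponentTimecourses", function(object) object@data)
setMethod("trSeconds", "ComponentTimecourses", function(object) object@trSeconds)
setMethod("subjectId", "ComponentTimecourses", function(object) object@subjectId)
setMethod("partition", "ComponentTimecourses", function(object) object@partition)
setMethod("nComponents", "ComponentTimecourses", function(object) ncol(object@data))
setMethod("nComponents", "NetworkPartition", function(object) length(object@networks))
setMethod("networkLabels", "NetworkPartition", function(object) object@networks)
setMethod("networkLabels", "ComponentTimecourses",
          function(object) object@partition@networks)

setMethod("subjectId", "WindowedFNCSeries", function(object) object@subjectId)
setMethod("fncMatrix", "WindowedFNCSeries", function(object) object@z)
setMethod("windowStarts", "WindowedFNCSeries", function(object) object@windowStarts)
setMethod("pairNames", "WindowedFNCSeries", function(object) object@pairNames)

setMethod("centroids", "StateModel", function(object) object@centroids)
setMethod("stateLabels", "StateModel", function(object) object@labels)
setMethod("nStates", "StateModel", function(object) object@k)
setMethod("stateCost", "StateModel", function(object) object@cost)

setMethod("timecourses", "CohortBundle", function(object) object@timecourses)
setMethod("clinicalTable", "CohortBundle", function(object) object@clinical)
setMethod("groundTruth", "CohortBundle", function(object) object@groundTruth)
setMethod("cohortSpec", "CohortBundle", function(object) object@spec)

setMethod("show", "ComponentTimecourses", function(object) {
  cat("ComponentTimecourses '", object@subjectId, "': ",
      nrow(object@data), " timepoints x ", ncol(object@data),
      " components (TR = ", object@trSeconds, " s)\n", sep = "")
  cat("  partition:", paste(table(object@partition@networks), collapse = "/"),
      "(DMN/CEN/SN)\n")
})

setMethod("show", "WindowedFNCSeries", function(object) {
  cat("WindowedFNCSeries '", object@subjectId, "': ", nrow(object@z),
      " windows x ", ncol(object@z), " pairs (lambda = ", object@lambda,
      ")\n", sep = "")
})

setMethod("show", "StateModel", function(object) {
  cat("StateModel: k =", object@k, "states,",
      length(object@labels), "subjects, total L1 cost",
      format(object@cost, digits = 6), "\n")
  occ <- table(factor(unlist(object@labels), levels = seq_len(object@k)))
  pct <- 100 * occ / sum(occ)
  cat("  occupancy:", paste(sprintf("S%d %.1f%%", seq_len(object@k), pct),
                            collapse = ", "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nGroupA, "+", object@nGroupB, "subjects,",
      object@nComponents, "components,", object@nTimepoints, "timepoints,",
      object@nStates, "states, noise sd", object@observationNoiseSd,
      ", seed", object@seed, "\n")
})

setMethod("show", "CohortBundle", function(object) {
  cat("CohortBundle:", length(object@timecourses), "subjects (",
      sum(object@clinical$group == "CD"), "CD /",
      sum(object@clinical$group == "HC"), "HC ),",
      ncol(object@clinical) - 2L, "clinical covariates\n")
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult: a =", signif(object@a, 4), ", b =", signif(object@b, 4),
      ", c =", signif(object@c, 4), ", c' =", signif(object@cPrime, 4), "\n")
  cat(sprintf("  indirect a*b = %.4g, %d%% BCa CI [%.4g, %.4g], boot p = %.4g (n_boot = %d)\n",
              object@indirect, round(100 * object@level),
              object@bcaInterval[1], object@bcaInterval[2],
              object@bootP, object@nBoot))
})

setMethod("show", "ClassificationResult", function(object) {
  cat("ClassificationResult (", object@mode, "): mean accuracy ",
      sprintf("%.1f%%", 100 * mean(object@accuracy)), ", AUC ",
      sprintf("%.3f", object@auc), "\n", sep = "")
  cat("  per-class:", paste(sprintf("%s %.1f%%", names(object@classAccuracy),
                                    100 * object@classAccuracy), collapse = ", "), "\n")
})
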