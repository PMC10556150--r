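#' Component-to-network partition
#'
#' Assigns each independent component to one of the three intrinsic
#' connectivity networks analysed by the pipeline: default mode (DMN),
#' central executive (CEN) and salience (SN).
#'
#' @slot networks factor of length n_components with levels
#'   \code{c("DMN", "CEN", "SN")}; names are the component names.
#' @export
setClass("NetworkPartition", representation(networks = "factor"))

setValidity("NetworkPartition", function(object) {
  nw <- object@networks
  if (anyNA(nw)) return("every component must be labeled exactly once")
  if (!all(levels(nw) == c("DMN", "CEN", "SN")))
    return("levels must be DMN, CEN, SN")
  if (is.null(names(nw)) || anyDuplicated(names(nw)))
    return("components must have unique names")
  TRUE
})

#' Construct a NetworkPartition
#'
#' @param sizes named integer vector of component counts per network,
#'   in DMN, CEN, SN order. Defaults to the 7/9/7 split used throughout.
#' @param componentNames optional component names; default \code{c01..cNN}.
#' @return A [NetworkPartition-class] object.
#' @examples
#' networkPartition()            # 23 components, 7 DMN + 9 CEN + 7 SN
#' @export
networkPartition <- function(sizes = c(DMN = 7L, CEN = 9L, SN = 7L),
                             componentNames = NULL) {
  stopifnot(length(sizes) == 3L, all(sizes >= 1L))
  nets <- factor(rep(c("DMN", "CEN", "SN"), times = sizes),
                 levels = c("DMN", "CEN", "SN"))
  if (is.null(componentNames))
    componentNames <- sprintf("c%02d", seq_len(sum(sizes)))
  names(nets) <- componentNames
  new("NetworkPartition", networks = nets)
}

#' Per-subject component time courses
#'
#' The object all connectivity estimation consumes: one subject's
#' time x component matrix with its repetition time and network partition.
#'
#' @slot data numeric matrix, rows = timepoints, columns = components.
#' @slot trSeconds repetition time in seconds.
#' @slot subjectId subject identifier.
#' @slot partition a [NetworkPartition-class].
#' @export
setClass("ComponentTimecourses",
         representation(data = "matrix", trSeconds = "numeric",
                        subjectId = "character", partition = "NetworkPartition"))

setValidity("ComponentTimecourses", function(object) {
  if (!is.numeric(object@data)) return("data must be numeric")
  if (anyNA(object@data) || !all(is.finite(object@data)))
    return("data must contain no missing or non-finite values")
  if (nrow(object@data) < 2L) return("need at least 2 timepoints")
  if (ncol(object@data) != length(object@partition@networks))
    return("column count must match the partition")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    return("trSeconds must be a single positive number")
  TRUE
})

#' Construct ComponentTimecourses
#'
#' @param data time x component numeric matrix.
#' @param trSeconds repetition time (s); default 2.
#' @param subjectId subject identifier.
#' @param partition a [NetworkPartition-class]; default 7/9/7 over
#'   \code{ncol(data)} components (which must then be 23).
#' @return A [ComponentTimecourses-class] object.
#' @export
componentTimecourses <- function(data, trSeconds = 2, subjectId = "s01",
                                 partition = NULL) {
  data <- as.matrix(data)
  if (is.null(partition)) {
    if (ncol(data) != 23L)
      stop("default partition is 7/9/7 over 23 components; supply `partition` for ",
           ncol(data), " components")
    partition <- networkPartition()
  }
  colnames(data) <- names(partition@networks)
  new("ComponentTimecourses", data = data, trSeconds = as.numeric(trSeconds),
      subjectId = as.character(subjectId), partition = partition)
}

#' Windowed functional network connectivity for one subject
#'
#' Rows are sliding windows, columns are component pairs; entries are
#' Fisher-z transformed partial correlations derived from the regularised
#' inverse covariance of each window.
#'
#' @slot subjectId subject identifier.
#' @slot z numeric matrix, n_windows x n_pairs.
#' @slot windowStarts 0-based window start indices (in TR units).
#' @slot lambda the L1 penalty used for the precision estimates.
#' @slot pairNames component-pair column labels, upper-triangle row-major.
#' @export
setClass("WindowedFNCSeries",
         representation(subjectId = "character", z = "matrix",
                        windowStarts = "integer", lambda = "numeric",
                        pairNames = "character"))

setValidity("WindowedFNCSeries", function(object) {
  if (!all(is.finite(object@z))) return("every FNC entry must be finite")
  if (nrow(object@z) != length(object@windowStarts))
    return("row count must match windowStarts")
  if (ncol(object@z) != length(object@pairNames))
    return("column count must match pairNames")
  TRUE
})

#' Fitted brain-state model
#'
#' Result of Manhattan-distance k-means on windowed FNC vectors pooled over
#' subjects, with states relabelled in order of first emergence in the
#' concatenated assignment stream.
#'
#' @slot k number of states.
#' @slot centroids k x n_pairs matrix (emergence order).
#' @slot labels named list of per-subject integer label sequences (1..k).
#' @slot cost total within-cluster Manhattan cost of the best run.
#' @slot nInit number of random initialisations used.
#' @slot seed RNG seed used for initialisation.
#' @slot diagnostics list: per-run costs, cost traces, exemplar info.
#' @export
setClass("StateModel",
         representation(k = "integer", centroids = "matrix", labels = "list",
                        cost = "numeric", nInit = "integer", seed = "integer",
                        diagnostics = "list"))

setValidity("StateModel", function(object) {
  if (nrow(object@centroids) != object@k) return("centroid count must equal k")
  lab <- unlist(object@labels, use.names = FALSE)
  if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
    return("labels must lie in 1..k")
  TRUE
})

#' Generative specification for a synthetic dFNC cohort
#'
#' Defines a two-group cohort whose component time courses switch among
#' state-specific covariance regimes under a first-order Markov chain, with
#' clinical covariates linearly coupled to state occupancy.
#'
#' @slot nGroupA,nGroupB subjects per group (A = patients, B = controls).
#' @slot nComponents number of components (default 23).
#' @slot partitionSizes DMN/CEN/SN component counts (default 7, 9, 7).
#' @slot nTimepoints scan length in TR (default 230).
#' @slot trSeconds repetition time in seconds (default 2).
#' @slot nStates number of covariance states (default 4).
#' @slot stateCovariances list of SPD matrices, one per state.
#' @slot transitionMatrixA,transitionMatrixB row-stochastic k x k matrices.
#' @slot observationNoiseSd isotropic observation noise sd.
#' @slot clinicalModel named list of per-covariate couplings; each element is
#'   \code{list(intercept=, coefficient=, statistic=, residualSd=)} where
#'   \code{statistic} names an occupancy statistic such as \code{"frac_s1"}.
#' @slot seed master seed; all cohort randomness is fanned out from it.
#' @export
setClass("SyntheticSpec",
         representation(nGroupA = "integer", nGroupB = "integer",
                        nComponents = "integer", partitionSizes = "integer",
                        nTimepoints = "integer", trSeconds = "numeric",
                        nStates = "integer", stateCovariances = "list",
                        transitionMatrixA = "matrix", transitionMatrixB = "matrix",
                        observationNoiseSd = "numeric", clinicalModel = "list",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  k <- object@nStates
  if (sum(object@partitionSizes) != object@nComponents)
    return("partition sizes must sum to nComponents")
  if (length(object@stateCovariances) != k)
    return("need one covariance per state")
  for (s in seq_len(k)) {
    Sig <- object@stateCovariances[[s]]
    if (!isSymmetric(Sig, tol = 1e-8))
      return(sprintf("state %d covariance is not symmetric", s))
    ev <- min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      return(sprintf("state %d covariance is not positive definite (min eigenvalue %.3g)",
                     s, ev))
  }
  for (nm in c("transitionMatrixA", "transitionMatrixB")) {
    P <- slot(object, nm)
    if (!all(dim(P) == c(k, k))) return(sprintf("%s must be %d x %d", nm, k, k))
    if (any(P < 0)) return(sprintf("%s has negative entries", nm))
    if (any(abs(rowSums(P) - 1) > 1e-12))
      return(sprintf("%s rows must sum to 1 within 1e-12", nm))
  }
  if (object@observationNoiseSd < 0) return("observationNoiseSd must be >= 0")
  TRUE
})

#' Synthetic cohort bundle
#'
#' Holds the simulated subjects' time courses, the clinical table, the
#' generative ground truth, and the spec that produced them.
#'
#' @slot timecourses named list of [ComponentTimecourses-class].
#' @slot clinical data.frame with subject_id, group and covariate columns.
#' @slot groundTruth named list; per subject: state label sequence (one label
#'   per timepoint) and the generative transition matrix; plus the planted
#'   clinical coefficients.
#' @slot spec the [SyntheticSpec-class] used.
#' @export
setClass("CohortBundle",
         representation(timecourses = "list", clinical = "data.frame",
                        groundTruth = "list", spec = "SyntheticSpec"))

setValidity("CohortBundle", function(object) {
  n <- length(object@timecourses)
  if (nrow(object@clinical) != n)
    return("clinical table must have one row per subject")
  TRUE
})

#' Bootstrap mediation result
#'
#' Product-of-coefficients mediation of a binary exposure on an outcome
#' through a single mediator, with percentile and BCa bootstrap intervals.
#'
#' @slot a,b,c,cPrime path coefficients (total effect \code{c}, direct
#'   \code{cPrime}); \code{indirect} = a*b.
#' @slot indirect point estimate of the indirect effect.
#' @slot bootIndirect bootstrap distribution of the indirect effect.
#' @slot bcaInterval,percentileInterval two-sided intervals at \code{level}.
#' @slot bootP two-sided bootstrap p-value for the indirect effect.
#' @slot level confidence level; \code{nBoot} resamples; \code{seed} RNG seed.
#' @slot nDegenerate count of redrawn single-level-exposure resamples.
#' @export
setClass("MediationResult",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        cPrime = "numeric", indirect = "numeric",
                        bootIndirect = "numeric", bcaInterval = "numeric",
                        percentileInterval = "numeric", bootP = "numeric",
                        level = "numeric", nBoot = "integer", seed = "integer",
                        nDegenerate = "integer"))

#' Classifier evaluation result
#'
#' Repeated stratified k-fold cross-validation of a linear SVM on
#' centroid-regression features.
#'
#' @slot accuracy per-(repeat, fold) overall accuracies.
#' @slot classAccuracy named per-class mean accuracies (sensitivities).
#' @slot roc data.frame of pooled ROC points (fpr, tpr); \code{auc} its area.
#' @slot features the subjects x features matrix used.
#' @slot mode \code{"fold_safe"} or \code{"paper_faithful"}.
#' @slot scheme list: folds, repeats, svm cost; \code{seed} RNG seed.
#' @export
setClass("ClassificationResult",
         representation(accuracy = "numeric", classAccuracy = "numeric",
                        roc = "data.frame", auc = "numeric",
                        features = "matrix", mode = "character",
                        scheme = "list", seed = "integer"))
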