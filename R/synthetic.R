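#' Block-structured correlation matrix over the DMN/CEN/SN partition
#'
#' Builds an n x n correlation-scale covariance with constant within-network
#' and between-network correlations, the elementary building block of the
#' synthetic state covariances.
#'
#' @param nComponents total number of components.
#' @param partitionSizes DMN/CEN/SN component counts.
#' @param within within-network correlation; scalar or length 3
#'   (DMN, CEN, SN).
#' @param between between-network correlation; scalar or length 3
#'   (DMN-CEN, DMN-SN, CEN-SN).
#' @return SPD matrix with unit diagonal.
#' @export
blockCovariance <- function(nComponents = 23L, partitionSizes = c(7L, 9L, 7L),
                            within = 0.1, between = 0.02) {
  stopifnot(sum(partitionSizes) == nComponents)
  within <- rep_len(within, 3L)
  between <- rep_len(between, 3L)
  net <- rep(1:3, times = partitionSizes)
  Sig <- matrix(0, nComponents, nComponents)
  betweenIdx <- matrix(0L, 3, 3)
  betweenIdx[1, 2] <- betweenIdx[2, 1] <- 1L # DMN-CEN
  betweenIdx[1, 3] <- betweenIdx[3, 1] <- 2L # DMN-SN
  betweenIdx[2, 3] <- betweenIdx[3, 2] <- 3L # CEN-SN
  for (i in seq_len(nComponents)) for (j in seq_len(nComponents)) {
    Sig[i, j] <- if (i == j) 1
      else if (net[i] == net[j]) within[net[i]]
      else between[betweenIdx[net[i], net[j]]]
  }
  ev <- min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop(sprintf("constructed covariance is not positive definite (min eigenvalue %.3g)", ev))
  Sig
}

# Edge-list helpers on 1-based component indices.
.chainEdges <- function(idx) cbind(idx[-length(idx)], idx[-1])
.skipEdges <- function(idx, lag) {
  n <- length(idx)
  if (n <= lag) stop("network block too small for lag-", lag, " edges")
  cbind(idx[seq_len(n - lag)], idx[seq_len(n - lag) + lag])
}
.pairUp <- function(a, b) {
  m <- min(length(a), length(b))
  cbind(a[seq_len(m)], b[seq_len(m)])
}
.shiftPair <- function(a, b) {
  m <- min(length(a), length(b))
  cbind(a[seq_len(m)], b[c(seq_len(m)[-1], 1L)])
}

# Connectivity profiles for the four recurring states, specified in the
# precision (conditional-dependence) domain. Each state owns a sparse edge
# set largely disjoint from the other states' sets, so the states occupy
# distinct directions of connectivity space rather than being scaled
# versions of one another: state 1 is globally weak (small lag-3
# within-network couplings only), the two intermediates emphasise the DMN
# (with DMN-CEN anticorrelation) and the CEN/SN (with CEN-SN coupling)
# respectively, and state 4 carries strong within-DMN and DMN-SN coupling.
# Disjoint supports keep every state's precision comfortably positive
# definite at coupling strengths that survive the graphical-lasso shrinkage
# applied downstream.
.stateGraph <- function(profile, dmn, cen, sn) {
  pieces <- switch(profile,
    weak_sparse = list(
      list(.skipEdges(dmn, 3L), 0.16), list(.skipEdges(cen, 3L), 0.16),
      list(.skipEdges(sn, 3L), 0.16)),
    intermediate_1 = list(
      list(.chainEdges(dmn), 0.32), list(.pairUp(dmn, cen), -0.26),
      list(.shiftPair(dmn, cen), -0.22), list(.shiftPair(rev(cen), sn), -0.30)),
    intermediate_2 = list(
      list(.chainEdges(cen), 0.35), list(.chainEdges(sn), 0.35),
      list(.pairUp(rev(cen), sn), 0.35), list(.skipEdges(sn, 2L), -0.30)),
    strong_dense = list(
      list(.skipEdges(dmn, 2L), 0.32), list(.pairUp(dmn, rev(sn)), 0.36),
      list(.shiftPair(dmn, rev(sn)), 0.30), list(.skipEdges(cen, 2L), 0.25)),
    stop("unknown profile '", profile, "'"))
  list(edges = do.call(rbind, lapply(pieces, `[[`, 1L)),
       weights = unlist(lapply(pieces, function(p) rep(p[[2]], nrow(p[[1]])))))
}

#' State covariance from a sparse conditional-dependence graph
#'
#' Builds a precision matrix \code{Theta = I - W} (W holding the requested
#' partial correlations on the graph edges), inverts it, and rescales to
#' unit variances. Errors if the construction is not positive definite.
#'
#' @param edges two-column matrix of component index pairs.
#' @param weights partial-correlation weight per edge (recycled).
#' @param nComponents matrix dimension.
#' @return SPD covariance matrix with unit diagonal.
#' @export
precisionGraphCovariance <- function(edges, weights, nComponents = 23L) {
  Theta <- diag(nComponents)
  weights <- rep_len(weights, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    Theta[i, j] <- Theta[j, i] <- -weights[e]
  }
  ev <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop(sprintf("constructed precision is not positive definite (min eigenvalue %.3g)", ev))
  stats::cov2cor(solve(Theta))
}

#' State covariance presets
#'
#' Constructs one SPD covariance per named connectivity profile. The
#' \code{weak_sparse} preset has near-zero off-block correlations; the
#' \code{strong_dense} preset has elevated within-DMN and DMN-SN block
#' correlations.
#'
#' @param profiles character vector of presets, each one of
#'   \code{"weak_sparse"}, \code{"intermediate_1"}, \code{"intermediate_2"},
#'   \code{"strong_dense"}. The default yields the four default states in
#'   that order.
#' @param nComponents,partitionSizes component count and DMN/CEN/SN split.
#' @param weightScale multiplier on every preset edge weight; 0 requests
#'   zero off-diagonals and returns identity matrices.
#' @return list of SPD matrices, one per requested profile.
#' @examples
#' covs <- makeStateCovariances()
#' sapply(covs, function(S) min(eigen(S, symmetric = TRUE)$values)) # all > 0
#' @export
makeStateCovariances <- function(profiles = c("weak_sparse", "intermediate_1",
                                              "intermediate_2", "strong_dense"),
                                 nComponents = 23L,
                                 partitionSizes = c(7L, 9L, 7L),
                                 weightScale = 1) {
  stopifnot(sum(partitionSizes) == nComponents)
  valid <- c("weak_sparse", "intermediate_1", "intermediate_2", "strong_dense")
  stopifnot(all(profiles %in% valid))
  dmn <- seq_len(partitionSizes[1])
  cen <- partitionSizes[1] + seq_len(partitionSizes[2])
  sn <- partitionSizes[1] + partitionSizes[2] + seq_len(partitionSizes[3])
  out <- lapply(profiles, function(p) {
    g <- .stateGraph(p, dmn, cen, sn)
    precisionGraphCovariance(g$edges, g$weights * weightScale, nComponents)
  })
  names(out) <- make.unique(profiles)
  out
}

.checkStochastic <- function(P) {
  if (any(P < 0)) stop("transition matrix has negative entries")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("each transition-matrix row must sum to 1 within 1e-12")
  invisible(P)
}

#' Simulate a first-order Markov state sequence
#'
#' @param transitionMatrix row-stochastic k x k matrix.
#' @param nSteps sequence length (>= 1).
#' @param seed optional integer seed (RNG state restored afterwards).
#' @param startState initial state; default drawn uniformly.
#' @return integer vector of state labels in 1..k.
#' @examples
#' P <- matrix(0.25, 4, 4)
#' table(simulateStateSequence(P, 1000, seed = 1))
#' @export
simulateStateSequence <- function(transitionMatrix, nSteps, seed = NULL,
                                  startState = NULL) {
  .checkStochastic(transitionMatrix)
  stopifnot(nSteps >= 1)
  k <- nrow(transitionMatrix)
  sim <- function() {
    s <- integer(nSteps)
    s[1] <- if (is.null(startState)) sample.int(k, 1L) else as.integer(startState)
    for (t in seq_len(nSteps - 1L))
      s[t + 1L] <- sample.int(k, 1L, prob = transitionMatrix[s[t], ])
    s
  }
  if (is.null(seed)) sim() else withr::with_seed(as.integer(seed), sim())
}

#' Construct a SyntheticSpec
#'
#' Defaults define the study conditions emulated throughout: two groups
#' (50 patients, 57 controls), 23 components split 7/9/7 over DMN/CEN/SN,
#' 230 timepoints at TR 2 s, four covariance states with Markov switching.
#' Patients (group A) dwell longer in the weakly connected state 1 and less
#' in the strongly connected state 4 than controls (group B); cognitive and
#' affective covariates are linearly coupled to state occupancy.
#'
#' @param nGroupA,nGroupB subjects per group (A = CD patients, B = HC).
#' @param nComponents,partitionSizes,nTimepoints,trSeconds,nStates see
#'   [SyntheticSpec-class].
#' @param stateCovariances list of SPD matrices; default
#'   [makeStateCovariances()] presets in weak-to-strong order.
#' @param stayA,stayB per-state stay probabilities used to build the default
#'   transition matrices (off-diagonal mass spread uniformly).
#' @param transitionMatrixA,transitionMatrixB explicit matrices (override
#'   \code{stayA}/\code{stayB}).
#' @param observationNoiseSd isotropic observation noise sd; default 0.25.
#' @param clinicalModel per-covariate linear couplings; see
#'   [SyntheticSpec-class]. The default couples MoCA negatively and SAS
#'   positively to the fraction of time in state 1, and SDS negatively to
#'   the fraction of time in state 4.
#' @param seed master seed.
#' @return A validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGroupA = 50L, nGroupB = 57L, nComponents = 23L,
                          partitionSizes = c(7L, 9L, 7L), nTimepoints = 230L,
                          trSeconds = 2, nStates = 4L,
                          stateCovariances = NULL,
                          stayA = c(0.995, 0.99, 0.99, 0.98),
                          stayB = c(0.98, 0.99, 0.99, 0.995),
                          transitionMatrixA = NULL, transitionMatrixB = NULL,
                          observationNoiseSd = 0.25,
                          clinicalModel = NULL, seed = 20260101L) {
  if (is.null(stateCovariances))
    stateCovariances <- makeStateCovariances(nComponents = nComponents,
                                             partitionSizes = partitionSizes)
  mkP <- function(stay) {
    stay <- rep_len(stay, nStates)
    P <- matrix(0, nStates, nStates)
    for (s in seq_len(nStates)) {
      P[s, ] <- (1 - stay[s]) / (nStates - 1)
      P[s, s] <- stay[s]
    }
    P
  }
  if (is.null(transitionMatrixA)) transitionMatrixA <- mkP(stayA)
  if (is.null(transitionMatrixB)) transitionMatrixB <- mkP(stayB)
  if (is.null(clinicalModel))
    clinicalModel <- list(
      MoCA = list(intercept = 27, coefficient = -12, statistic = "frac_s1",
                  residualSd = 2.5),
      SAS  = list(intercept = 25, coefficient = 25, statistic = "frac_s1",
                  residualSd = 5),
      SDS  = list(intercept = 45, coefficient = -20, statistic = "frac_s4",
                  residualSd = 6))
  new("SyntheticSpec", nGroupA = as.integer(nGroupA),
      nGroupB = as.integer(nGroupB), nComponents = as.integer(nComponents),
      partitionSizes = as.integer(partitionSizes),
      nTimepoints = as.integer(nTimepoints), trSeconds = as.numeric(trSeconds),
      nStates = as.integer(nStates), stateCovariances = stateCovariances,
      transitionMatrixA = transitionMatrixA,
      transitionMatrixB = transitionMatrixB,
      observationNoiseSd = as.numeric(observationNoiseSd),
      clinicalModel = clinicalModel, seed = as.integer(seed))
}

# Per-subject seed fan-out from the master seed: a fixed affine counter
# scheme keeps every subject reproducible in isolation.
.fanSeed <- function(master, counter) {
  as.integer((as.numeric(master) + 1009 * as.numeric(counter)) %% 2147483647)
}

#' Simulate one subject's component time courses
#'
#' Draws a Markov state sequence and, at each timepoint, a zero-mean
#' multivariate normal with the covariance of the active state, plus
#' isotropic observation noise.
#'
#' @param spec a [SyntheticSpec-class].
#' @param group \code{"A"} (patients) or \code{"B"} (controls).
#' @param seed integer seed for this subject.
#' @param subjectId identifier stored on the result.
#' @param startState optional fixed initial state (default: drawn uniformly).
#' @return list with \code{tc} ([ComponentTimecourses-class]) and
#'   \code{groundTruth} (list: \code{labels} per timepoint,
#'   \code{transitionMatrix}).
#' @export
simulateSubject <- function(spec, group = c("A", "B"), seed,
                            subjectId = "s01", startState = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  group <- match.arg(group)
  P <- if (group == "A") spec@transitionMatrixA else spec@transitionMatrixB
  Tn <- spec@nTimepoints
  d <- spec@nComponents
  chols <- lapply(spec@stateCovariances, function(S) chol(S))
  out <- withr::with_seed(as.integer(seed), {
    labels <- simulateStateSequence(P, Tn, startState = startState)
    Z <- matrix(rnorm(Tn * d), nrow = Tn, ncol = d)
    X <- matrix(0, Tn, d)
    for (t in seq_len(Tn)) X[t, ] <- Z[t, ] %*% chols[[labels[t]]]
    if (spec@observationNoiseSd > 0)
      X <- X + matrix(rnorm(Tn * d, sd = spec@observationNoiseSd), Tn, d)
    list(labels = labels, X = X)
  })
  part <- networkPartition(setNames(spec@partitionSizes, c("DMN", "CEN", "SN")))
  tc <- componentTimecourses(out$X, trSeconds = spec@trSeconds,
                             subjectId = subjectId, partition = part)
  list(tc = tc, groundTruth = list(labels = out$labels, transitionMatrix = P))
}

#' Occupancy statistics of a ground-truth label sequence
#'
#' @param labels integer state sequence.
#' @param nStates number of states.
#' @return named numeric vector: \code{frac_s<j>}, \code{dwell_s<j>} for each
#'   state, and \code{n_transitions}.
#' @export
occupancyStats <- function(labels, nStates) {
  out <- c(
    setNames(vapply(seq_len(nStates), function(s) fractionTime(labels, s),
                    numeric(1)), paste0("frac_s", seq_len(nStates))),
    setNames(vapply(seq_len(nStates), function(s) meanDwellTime(labels, s),
                    numeric(1)), paste0("dwell_s", seq_len(nStates))),
    n_transitions = nTransitions(labels))
  out
}

#' Simulate the clinical covariate table
#'
#' Each covariate is generated as intercept + coefficient x occupancy
#' statistic + Gaussian noise, per the spec's \code{clinicalModel}.
#'
#' @param groundTruths list of per-subject ground-truth lists (each with a
#'   \code{labels} element).
#' @param spec a [SyntheticSpec-class].
#' @param seed integer seed.
#' @return data.frame, one row per subject, one column per covariate.
#' @export
simulateClinical <- function(groundTruths, spec, seed) {
  stats <- t(vapply(groundTruths,
                    function(g) occupancyStats(g$labels, spec@nStates),
                    numeric(2L * spec@nStates + 1L)))
  n <- length(groundTruths)
  withr::with_seed(as.integer(seed), {
    cols <- lapply(spec@clinicalModel, function(m) {
      if (!m$statistic %in% colnames(stats))
        stop("unknown occupancy statistic '", m$statistic, "'")
      m$intercept + m$coefficient * stats[, m$statistic] +
        rnorm(n, sd = m$residualSd)
    })
    as.data.frame(cols)
  })
}

#' Simulate a full two-group cohort
#'
#' Fans the master seed out per subject (documented affine counter scheme),
#' simulates every subject and the clinical table, and bundles them with the
#' generative ground truth. Regeneration with the same spec is bit-identical.
#' Within each group the initial state rotates deterministically over
#' 1..nStates so every state is represented at cohort scale even when mean
#' dwell times approach the scan length; group differences in occupancy
#' arise from the asymmetric transition matrices, not the start states.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A [CohortBundle-class].
#' @examples
#' spec <- syntheticSpec(nGroupA = 3, nGroupB = 3, nTimepoints = 60)
#' cohort <- simulateCohort(spec)
#' cohort
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- spec@nGroupA + spec@nGroupB
  ids <- sprintf("sub%03d", seq_len(n))
  groups <- rep(c("CD", "HC"), c(spec@nGroupA, spec@nGroupB))
  withinIdx <- c(seq_len(spec@nGroupA), seq_len(spec@nGroupB))
  subs <- lapply(seq_len(n), function(i)
    simulateSubject(spec, group = if (groups[i] == "CD") "A" else "B",
                    seed = .fanSeed(spec@seed, i), subjectId = ids[i],
                    startState = (withinIdx[i] - 1L) %% spec@nStates + 1L))
  tcs <- setNames(lapply(subs, `[[`, "tc"), ids)
  gts <- setNames(lapply(subs, `[[`, "groundTruth"), ids)
  clin <- cbind(data.frame(subject_id = ids, group = groups,
                           stringsAsFactors = FALSE),
                simulateClinical(gts, spec, seed = .fanSeed(spec@seed, n + 1L)))
  rownames(clin) <- NULL
  new("CohortBundle", timecourses = tcs, clinical = clin,
      groundTruth = c(gts, list(.clinicalModel = spec@clinicalModel)),
      spec = spec)
}

#' Window-level ground-truth labels by majority vote
#'
#' Maps a per-timepoint state sequence to per-window labels: each window's
#' label is the most frequent timepoint state inside it; ties go to the
#' lowest state label.
#'
#' @param labels per-timepoint integer state sequence.
#' @param widthTr,stepTr window width and step in TR; defaults 30 and 1.
#' @return integer vector, one label per window (window count per
#'   [makeWindows()]).
#' @export
majorityWindowLabels <- function(labels, widthTr = 30L, stepTr = 1L) {
  win <- makeWindows(length(labels), windowSpec(widthTr, stepTr))
  vapply(seq_len(nrow(win)), function(i) {
    seg <- labels[(win[i, "start"] + 1L):win[i, "end"]]
    tab <- tabulate(seg)
    which.max(tab) # ties resolve to the lowest state label
  }, integer(1))
}
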