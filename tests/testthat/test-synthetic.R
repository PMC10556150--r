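test_that("blockCovariance builds SPD matrices and reports non-SPD failures", {
  S <- blockCovariance(23L, c(7L, 9L, 7L), within = 0.5, between = 0.1)
  expect_equal(dim(S), c(23L, 23L))
  expect_equal(unname(diag(S)), rep(1, 23))
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  # zero off-diagonal request -> identity, trivially SPD
  expect_equal(blockCovariance(23L, c(7L, 9L, 7L), 0, 0), diag(23))
  # an impossible correlation structure errors with the offending eigenvalue
  expect_error(blockCovariance(6L, c(2L, 2L, 2L), within = 0.1, between = -0.9),
               "not positive definite")
})

test_that("makeStateCovariances presets satisfy the documented contracts", {
  covs <- makeStateCovariances()
  expect_length(covs, 4L)
  for (S in covs) {
    expect_equal(unname(diag(S)), rep(1, 23))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  offmean <- function(S) mean(abs(S[upper.tri(S)]))
  # strong_dense strictly denser than weak_sparse
  expect_gt(offmean(covs$strong_dense), offmean(covs$weak_sparse))
  # weak_sparse has near-zero off-block correlations
  blocks <- rep(c("DMN", "CEN", "SN"), c(7, 9, 7))
  off <- outer(blocks, blocks, `!=`)
  expect_lt(max(abs(covs$weak_sparse[off])), 0.05)
  # strong_dense elevates within-DMN and DMN-SN blocks over weak_sparse
  dmnBlock <- outer(blocks == "DMN", blocks == "DMN", `&`) & upper.tri(off)
  dmnSn <- outer(blocks == "DMN", blocks == "SN", `&`)
  expect_gt(mean(abs(covs$strong_dense[dmnBlock])),
            mean(abs(covs$weak_sparse[dmnBlock])))
  expect_gt(mean(abs(covs$strong_dense[dmnSn])),
            mean(abs(covs$weak_sparse[dmnSn])))
  # weightScale = 0 requests zero off-diagonals -> identity matrices
  expect_equal(makeStateCovariances(weightScale = 0)$weak_sparse, diag(23))
  expect_error(makeStateCovariances("no_such_profile"))
})

test_that("precisionGraphCovariance honours the requested graph", {
  edges <- cbind(1:2, 2:3)
  S <- precisionGraphCovariance(edges, c(0.4, 0.4), nComponents = 4L)
  Th <- solve(S)
  pcor <- -Th[1, 2] / sqrt(Th[1, 1] * Th[2, 2])
  expect_equal(pcor, 0.4, tolerance = 1e-10)
  # absent edge has zero partial correlation
  expect_equal(Th[1, 4], 0, tolerance = 1e-12)
  expect_error(precisionGraphCovariance(cbind(1L, 2L), 1.5, 3L),
               "not positive definite")
})

test_that("simulateStateSequence is a seeded, valid Markov sampler", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  s1 <- simulateStateSequence(P, 500L, seed = 11L)
  s2 <- simulateStateSequence(P, 500L, seed = 11L)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% 1:2))
  expect_identical(simulateStateSequence(P, 5L, seed = 1L, startState = 2L)[1],
                   2L)
  # absorbing state never leaves
  Pabs <- matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)
  expect_true(all(simulateStateSequence(Pabs, 100L, seed = 3L,
                                        startState = 1L) == 1L))
  bad <- matrix(c(0.5, 0.4, 0.2, 0.8), 2, byrow = TRUE)
  expect_error(simulateStateSequence(bad, 10L, seed = 1L), "sum to 1")
  expect_error(simulateStateSequence(matrix(c(0.5, 0.5, -0.1, 1.1), 2,
                                            byrow = TRUE), 10L, seed = 1L),
               "negative")
})

test_that("simulateSubject has the contracted shape and determinism", {
  spec <- smallSpec()
  a <- simulateSubject(spec, group = "A", seed = 5L, subjectId = "x")
  b <- simulateSubject(spec, group = "A", seed = 5L, subjectId = "x")
  expect_identical(a$tc@data, b$tc@data)
  expect_equal(dim(a$tc@data), c(120L, 23L))
  expect_length(a$groundTruth$labels, 120L)
  expect_true(all(a$groundTruth$labels %in% 1:4))
  # startState pins the first label
  c3 <- simulateSubject(spec, group = "B", seed = 5L, startState = 3L)
  expect_identical(c3$groundTruth$labels[1], 3L)
})

test_that("single-state identity covariance yields near-identity sample moments", {
  spec <- syntheticSpec(nGroupA = 1L, nGroupB = 1L, nTimepoints = 8000L,
                        nStates = 1L, stateCovariances = list(diag(23)),
                        transitionMatrixA = matrix(1, 1, 1),
                        transitionMatrixB = matrix(1, 1, 1),
                        stayA = 1, stayB = 1,
                        observationNoiseSd = 0, seed = 77L)
  sub <- simulateSubject(spec, "A", seed = 77L)
  S <- crossprod(sub$tc@data) / nrow(sub$tc@data)
  expect_lt(max(abs(S - diag(23))), 0.08)
})

test_that("simulateClinical couples covariates to occupancy as planted", {
  # coefficient 0 -> covariate independent of occupancy
  P <- matrix(0.25, 4, 4)
  spec0 <- syntheticSpec(nGroupA = 250L, nGroupB = 250L, nTimepoints = 40L,
                         transitionMatrixA = P, transitionMatrixB = P,
                         clinicalModel = list(
                           null_cov = list(intercept = 0, coefficient = 0,
                                           statistic = "frac_s1",
                                           residualSd = 1)),
                         seed = 909L)
  gts <- lapply(1:500, function(i) list(
    labels = simulateStateSequence(P, 40L, seed = 1000L + i)))
  clin <- simulateClinical(gts, spec0, seed = 2L)
  occ <- vapply(gts, function(g) fractionTime(g$labels, 1L), numeric(1))
  expect_lt(abs(cor(clin$null_cov, occ)), 0.1)
  # coefficient -1, residual sd 0 -> exact linear map, r = -1
  spec1 <- syntheticSpec(nGroupA = 1L, nGroupB = 1L, nTimepoints = 40L,
                         transitionMatrixA = P, transitionMatrixB = P,
                         clinicalModel = list(
                           det_cov = list(intercept = 3, coefficient = -1,
                                          statistic = "frac_s1",
                                          residualSd = 0)),
                         seed = 909L)
  clin1 <- simulateClinical(gts, spec1, seed = 2L)
  expect_equal(cor(clin1$det_cov, occ), -1)
  # unknown occupancy statistic -> configuration error
  spec2 <- syntheticSpec(nGroupA = 1L, nGroupB = 1L,
                         clinicalModel = list(
                           bad = list(intercept = 0, coefficient = 1,
                                      statistic = "frac_s99",
                                      residualSd = 1)), seed = 1L)
  expect_error(simulateClinical(gts[1:2], spec2, seed = 1L),
               "unknown occupancy statistic")
})

test_that("planted clinical coupling recovers the closed-form correlation", {
  # r = c * sigma_occ / sqrt(c^2 sigma_occ^2 + sigma_res^2); pick sd so the
  # planted population r is about -0.5 and check recovery at n = 2000
  P <- matrix(0.25, 4, 4)
  gts <- lapply(1:2000, function(i) list(
    labels = simulateStateSequence(P, 60L, seed = 5000L + i)))
  occ <- vapply(gts, function(g) fractionTime(g$labels, 1L), numeric(1))
  coefficient <- -1
  sigmaRes <- sqrt(3) * sd(occ) # population |r| = 0.5 at this residual sd
  spec <- syntheticSpec(nGroupA = 1L, nGroupB = 1L,
                        transitionMatrixA = P, transitionMatrixB = P,
                        clinicalModel = list(
                          cov = list(intercept = 0, coefficient = coefficient,
                                     statistic = "frac_s1",
                                     residualSd = sigmaRes)), seed = 31L)
  clin <- simulateClinical(gts, spec, seed = 8L)
  expect_lt(abs(cor(clin$cov, occ) - (-0.5)), 0.05)
})

test_that("simulateCohort assembles ids, groups, clinical and ground truth", {
  cohort <- smallCohort()
  expect_s4_class(cohort, "CohortBundle")
  expect_length(timecourses(cohort), 8L)
  clin <- clinicalTable(cohort)
  expect_identical(clin$subject_id, sprintf("sub%03d", 1:8))
  expect_identical(clin$group, rep(c("CD", "HC"), each = 4L))
  expect_true(all(c("MoCA", "SAS", "SDS") %in% names(clin)))
  gt <- cohort@groundTruth[["sub001"]]
  expect_length(gt$labels, 120L)
  # start states rotate within each group
  starts <- vapply(sprintf("sub%03d", 1:8),
                   function(id) cohort@groundTruth[[id]]$labels[1], integer(1))
  expect_identical(unname(starts), rep(1:4, 2L))
  # regeneration is bit-identical
  again <- simulateCohort(smallSpec())
  expect_identical(timecourses(again)[["sub003"]]@data,
                   timecourses(cohort)[["sub003"]]@data)
})

test_that("spec validity rejects broken inputs", {
  expect_error(syntheticSpec(partitionSizes = c(7L, 9L, 8L)),
               "partition")
  covs <- makeStateCovariances()
  covs[[2]][1, 2] <- 5 # break symmetry/SPD
  expect_error(syntheticSpec(stateCovariances = covs))
})

test_that("occupancyStats and majorityWindowLabels follow their contracts", {
  labs <- c(1L, 1L, 2L, 2L, 2L, 1L)
  st <- occupancyStats(labs, 2L)
  expect_equal(unname(st["frac_s1"]), 0.5)
  expect_equal(unname(st["dwell_s2"]), 3)
  expect_equal(unname(st["n_transitions"]), 2)
  # majority vote with ties going to the lowest state label
  seq40 <- c(rep(1L, 15L), rep(2L, 25L))
  w <- majorityWindowLabels(seq40, widthTr = 30L, stepTr = 1L)
  expect_length(w, 10L) # floor((40 - 30) / 1)
  # window 1 covers t=1..30: 15 ones, 15 twos -> tie -> lowest label 1
  expect_identical(w[1], 1L)
  # last window covers t=10..39: 6 ones, 24 twos -> label 2
  expect_identical(w[10], 2L)
})
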