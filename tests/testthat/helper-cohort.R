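# Small shared fixtures, built lazily once per test run and cached in the
# testthat process. Sizes are kept small so module tests stay fast; the
# acceptance tests build their own full-size cohorts.

.cache <- new.env(parent = emptyenv())

smallSpec <- function() {
  if (is.null(.cache$spec))
    .cache$spec <- syntheticSpec(nGroupA = 4L, nGroupB = 4L,
                                 nTimepoints = 120L, seed = 424242L)
  .cache$spec
}

smallCohort <- function() {
  if (is.null(.cache$cohort)) .cache$cohort <- simulateCohort(smallSpec())
  .cache$cohort
}

smallSeries <- function() {
  if (is.null(.cache$series))
    .cache$series <- cohortDFNC(timecourses(smallCohort()),
                                spec = windowSpec(30L, 1L), lambda = 0.1)
  .cache$series
}

smallModel <- function() {
  if (is.null(.cache$model))
    .cache$model <- fitStateModel(smallSeries(), k = 4L, nInit = 3L, seed = 1L)
  .cache$model
}
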