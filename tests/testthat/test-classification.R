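mkZSeries <- function(Z, id) {
  new("WindowedFNCSeries", subjectId = id, z = Z,
      windowStarts = seq_len(nrow(Z)) - 1L, lambda = 0.1,
      pairNames = paste0("p", seq_len(ncol(Z))))
}

test_that("buildCentroidDesign averages windows per (group, state) cell", {
  # two subjects, 3 pairs, hand-computable cell means
  Za <- rbind(c(1, 0, 0), c(3, 0, 0), c(0, 2, 0)) # states 1, 1, 2
  Zb <- rbind(c(5, 0, 0), c(0, 0, 4))             # states 1, 2
  series <- list(mkZSeries(Za, "a"), mkZSeries(Zb, "b"))
  labels <- list(a = c(1L, 1L, 2L), b = c(1L, 2L))
  groups <- c(a = "CD", b = "HC")
  D <- buildCentroidDesign(series, labels, groups, k = 2L)
  expect_identical(colnames(D), c("CD.s1", "CD.s2", "HC.s1", "HC.s2"))
  expect_equal(unname(D[, "CD.s1"]), c(2, 0, 0)) # mean of windows 1 and 2
  expect_equal(unname(D[, "CD.s2"]), c(0, 2, 0))
  expect_equal(unname(D[, "HC.s1"]), c(5, 0, 0))
  expect_equal(unname(D[, "HC.s2"]), c(0, 0, 4))
  # empty cell is dropped with a warning
  labels2 <- list(a = c(1L, 1L, 1L), b = c(1L, 2L))
  expect_warning(D2 <- buildCentroidDesign(series, labels2, groups, k = 2L),
                 "CD.s2")
  expect_equal(ncol(D2), 3L)
})

test_that("windowBetas is centered OLS on the design", {
  set.seed(40)
  D <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  beta <- c(2, -1, 0.5, 0)
  w <- D %*% beta + 3 # intercept offset is absorbed by centering
  b <- windowBetas(as.numeric(w), D)
  expect_equal(unname(b), beta, tolerance = 1e-8)
  expect_named(b, colnames(D))
  expect_error(windowBetas(w[1:10], D))
  # rank-deficient design: warning plus a finite minimum-norm solution
  Dr <- cbind(D[, 1], D[, 1], D[, 2])
  expect_warning(br <- windowBetas(as.numeric(w), Dr), "rank-deficient")
  expect_true(all(is.finite(br)))
})

test_that("subjectFeatures averages window betas and cohortFeatures stacks them", {
  set.seed(41)
  D <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("c", 1:3)))
  Z <- matrix(rnorm(5 * 30), 5, 30)
  s <- mkZSeries(Z, "x")
  f <- subjectFeatures(s, D)
  byWindow <- rowMeans(vapply(seq_len(nrow(Z)),
                              function(i) windowBetas(Z[i, ], D),
                              numeric(3)))
  expect_equal(unname(f), unname(byWindow), tolerance = 1e-10)
  F2 <- cohortFeatures(list(s, mkZSeries(Z + 1, "y")), D)
  expect_equal(dim(F2), c(2L, 3L))
  expect_identical(rownames(F2), c("x", "y"))
  expect_equal(unname(F2["x", ]), unname(f))
})

test_that("stratified folds keep class balance", {
  groups <- rep(c("CD", "HC"), c(20, 30))
  withr::with_seed(1L, {
    fold <- dfncstates:::.stratifiedFolds(groups, 10L)
    expect_equal(sort(unique(fold)), 1:10)
    perFold <- table(fold, groups)
    expect_true(all(perFold[, "CD"] == 2))
    expect_true(all(perFold[, "HC"] == 3))
  })
})

test_that("evaluateClassifier is near-perfect on separable features", {
  set.seed(42)
  n <- 30
  groups <- setNames(rep(c("CD", "HC"), each = n / 2),
                     sprintf("s%02d", seq_len(n)))
  feats <- rbind(matrix(rnorm(n / 2 * 4, mean = 3, sd = 0.3), n / 2, 4),
                 matrix(rnorm(n / 2 * 4, mean = -3, sd = 0.3), n / 2, 4))
  rownames(feats) <- names(groups)
  res <- evaluateClassifier(groups = groups, mode = "paper_faithful",
                            features = feats, nFolds = 5L, nRepeats = 3L,
                            seed = 9L)
  expect_s4_class(res, "ClassificationResult")
  expect_equal(mean(res@accuracy), 1)
  expect_equal(unname(res@classAccuracy), c(1, 1))
  expect_equal(res@auc, 1)
  expect_length(res@accuracy, 5L * 3L)
  # ROC curve spans (0,0) to (1,1) monotonically
  expect_equal(res@roc$fpr[1], 0)
  expect_equal(res@roc$tpr[nrow(res@roc)], 1)
  expect_true(all(diff(res@roc$tpr) >= 0))
  # determinism under a fixed seed
  res2 <- evaluateClassifier(groups = groups, mode = "paper_faithful",
                             features = feats, nFolds = 5L, nRepeats = 3L,
                             seed = 9L)
  expect_identical(res2@accuracy, res@accuracy)
})

test_that("fold_safe mode rebuilds the design inside each fold", {
  set.seed(43)
  nPairs <- 12
  # group- and state-specific connectivity patterns: windows of a (group,
  # state) cell are noisy multiples of that cell's pattern, so the centroid
  # design recovers the patterns and subject betas separate the groups
  pat <- replicate(4, rnorm(nPairs), simplify = FALSE)
  names(pat) <- c("CD.1", "CD.2", "HC.1", "HC.2")
  mkSubj <- function(id, grp) {
    states <- rep(1:2, 4)
    Z <- t(vapply(states, function(s)
      rnorm(1, mean = 1, sd = 0.1) * pat[[paste0(grp, ".", s)]] +
        rnorm(nPairs, sd = 0.1), numeric(nPairs)))
    mkZSeries(Z, id)
  }
  ids <- sprintf("s%02d", 1:12)
  groups <- setNames(rep(c("CD", "HC"), each = 6), ids)
  series <- lapply(seq_along(ids),
                   function(i) mkSubj(ids[i], unname(groups[i])))
  labels <- setNames(replicate(12, rep(1:2, 4), simplify = FALSE), ids)
  res <- evaluateClassifier(series, labels, groups, k = 2L,
                            mode = "fold_safe", nFolds = 3L, nRepeats = 2L,
                            seed = 4L)
  expect_identical(res@mode, "fold_safe")
  expect_length(res@accuracy, 6L)
  expect_gt(mean(res@accuracy), 0.9) # strongly separated group means
  expect_gt(res@auc, 0.9)
  # fold_safe requires the raw series and labels
  expect_error(evaluateClassifier(groups = groups, mode = "fold_safe"))
})
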