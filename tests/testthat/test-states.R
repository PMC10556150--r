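test_that("manhattanKMeans recovers well-separated blobs and the L1 optimum", {
  set.seed(10)
  X <- rbind(matrix(rnorm(12, mean = 0, sd = 0.1), 6, 2),
             matrix(rnorm(12, mean = 10, sd = 0.1), 6, 2))
  fit <- manhattanKMeans(X, 2, nInit = 3, seed = 1)
  expect_identical(fit$labels, rep(1:2, each = 6L)) # emergence order
  # matches the exhaustive best 2-partition by total L1 cost on 12 points
  bestCost <- Inf
  for (m in 1:(2^11)) {
    g <- as.integer(intToBits(m))[1:12]
    if (all(g == g[1])) next
    cost <- 0
    for (grp in 0:1) {
      rows <- X[g == grp, , drop = FALSE]
      med <- apply(rows, 2, median)
      cost <- cost + sum(abs(sweep(rows, 2, med)))
    }
    bestCost <- min(bestCost, cost)
  }
  expect_equal(fit$cost, bestCost, tolerance = 1e-10)
  # duplicating every row leaves the centroids unchanged (median invariance)
  fit2 <- manhattanKMeans(rbind(X, X), 2, nInit = 3, seed = 1)
  expect_equal(sort(fit2$centroids[, 1]), sort(fit$centroids[, 1]),
               tolerance = 1e-10)
  # cost trace is non-increasing within the winning run
  expect_true(all(diff(fit$costTrace) <= 1e-10))
  # same seed, same answer
  fit3 <- manhattanKMeans(X, 2, nInit = 3, seed = 1)
  expect_identical(fit3$labels, fit$labels)
  expect_error(manhattanKMeans(X, 13), "exceeds")
})

test_that("centroids are coordinate-wise medians of their members", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  fit <- manhattanKMeans(X, 2, nInit = 5, seed = 2)
  for (g in 1:2) {
    med <- apply(X[fit$labels == g, , drop = FALSE], 2, median)
    expect_equal(unname(fit$centroids[g, ]), unname(med), tolerance = 1e-10)
  }
})

test_that("selectExemplars picks local variance maxima per subject", {
  mkSeries <- function(Z, id) new("WindowedFNCSeries", subjectId = id, z = Z,
                                  windowStarts = seq_len(nrow(Z)) - 1L,
                                  lambda = 0.1,
                                  pairNames = paste0("p", seq_len(ncol(Z))))
  # hand-built variance profile with peaks at windows 10 and 50
  n <- 60; p <- 5
  sds <- rep(1, n); sds[10] <- 6; sds[50] <- 6
  set.seed(12)
  Z <- do.call(rbind, lapply(seq_len(n), function(i) rnorm(p, sd = sds[i])))
  ex <- selectExemplars(list(mkSeries(Z, "a")))
  expect_true(all(c(10L, 50L) %in% ex$window))
  v <- apply(Z, 1, var)
  expect_true(all(v[ex$window] >= v[pmax(ex$window - 1, 1)]))
  # strictly increasing variance -> single exemplar at the last window
  Zinc <- do.call(rbind, lapply(1:20, function(i) seq_len(4) * i))
  exInc <- selectExemplars(list(mkSeries(Zinc, "b")))
  expect_identical(exInc$window, 20L)
  # constant variance -> fallback to the first index
  Zconst <- matrix(rep(c(1, 2, 3, 4), 10), 10, 4, byrow = TRUE)
  exC <- selectExemplars(list(mkSeries(Zconst, "c")))
  expect_identical(exC$window, 1L)
  expect_error(selectExemplars(list(mkSeries(Zconst[1:2, ], "d"))),
               "at least 3 windows")
})

test_that("chooseK recovers planted k and exposes both criteria", {
  set.seed(13)
  mkBlob <- function(center, n) sweep(matrix(rnorm(n * 4, sd = 0.2), n, 4),
                                      2, center, `+`)
  X2 <- rbind(mkBlob(c(0, 0, 0, 0), 40), mkBlob(c(5, 5, 5, 5), 40))
  ck2 <- chooseK(X2, 2:6, nInit = 3, seed = 1)
  # the second-difference elbow is only defined at interior candidates, so
  # planted k = 2 is checked through the silhouette criterion
  expect_equal(ck2$silhouetteK, 2L)
  expect_true(ck2$elbowK %in% 3:5)
  X4 <- rbind(mkBlob(c(0, 0, 0, 0), 30), mkBlob(c(6, 0, 0, 0), 30),
              mkBlob(c(0, 6, 0, 0), 30), mkBlob(c(0, 0, 6, 0), 30))
  ck4 <- chooseK(X4, 2:8, nInit = 5, seed = 1)
  expect_equal(ck4$elbowK, 4L)
  expect_equal(ck4$silhouetteK, 4L)
  expect_length(ck4$cost, 7L)
  expect_length(ck4$silhouette, 7L)
  # a single Gaussian blob: silhouette low everywhere, and no crash
  X1 <- mkBlob(rep(0, 4), 80)
  ck1 <- chooseK(X1, 2:5, nInit = 3, seed = 1)
  expect_lt(max(ck1$silhouette), 0.3)
  expect_error(chooseK(X4, 2:3, method = "elbow"), "at least 3 candidate")
})

test_that("assignStates maps windows to nearest centroids with tie-break", {
  C <- rbind(c(0, 0), c(4, 0), c(0, 4))
  mkSeries <- function(Z) new("WindowedFNCSeries", subjectId = "s", z = Z,
                              windowStarts = seq_len(nrow(Z)) - 1L,
                              lambda = 0.1, pairNames = c("p1", "p2"))
  Z <- rbind(c(0, 4),      # exact match with centroid 3
             c(2, 0),      # equidistant between 1 and 2 -> lowest index 1
             c(3.9, 0.1))  # nearest centroid 2
  lab <- assignStates(list(mkSeries(Z)), C)[["s"]]
  expect_identical(lab, c(3L, 1L, 2L))
  # brute-force nearest-centroid scan on random windows
  set.seed(14)
  Zr <- matrix(rnorm(40), 20, 2)
  labr <- assignStates(list(mkSeries(Zr)), C)[["s"]]
  brute <- apply(Zr, 1, function(w)
    which.min(colSums(abs(t(C) - w))))
  expect_identical(labr, as.integer(brute))
  expect_error(assignStates(list(mkSeries(Zr)), cbind(C, 0)),
               "does not match")
})

test_that("fitStateModel returns emergence-ordered labels and diagnostics", {
  model <- smallModel()
  expect_s4_class(model, "StateModel")
  expect_equal(model@k, 4L)
  expect_equal(dim(centroids(model)), c(4L, 253L))
  labs <- stateLabels(model)
  expect_named(labs, sprintf("sub%03d", 1:8))
  stream <- unlist(labs, use.names = FALSE)
  expect_true(all(stream %in% 1:4))
  # emergence ordering: first occurrences appear in increasing label order
  firsts <- vapply(1:4, function(s) match(s, stream), integer(1))
  expect_true(all(diff(firsts) > 0))
  # labels are reproducible for a fixed seed
  model2 <- fitStateModel(smallSeries(), k = 4L, nInit = 3L, seed = 1L)
  expect_identical(stateLabels(model2), labs)
  # single-stage fit runs and labels every window too
  m1 <- fitStateModel(smallSeries(), k = 3L, nInit = 2L, seed = 2L,
                      twoStage = FALSE)
  expect_true(all(unlist(stateLabels(m1)) %in% 1:3))
})

test_that("stateSummary counts and percentages are consistent", {
  model <- smallModel()
  sm <- stateSummary(model)
  expect_equal(sum(sm$count), 8L * 90L)
  expect_equal(sum(sm$percent), 100, tolerance = 1e-9)
  expect_identical(sm$state, 1:4)
})

test_that("adjustedRandIndex matches known values", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
  # independent labelings on a known contingency table
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 3, 3)
  # hand-computed: nij = 2, ai = 6, bj = 3, n2 = 15, expected = 1.2, max = 4.5
  expect_equal(adjustedRandIndex(a, b), (2 - 1.2) / (4.5 - 1.2))
  expect_error(adjustedRandIndex(1:3, 1:4))
})
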