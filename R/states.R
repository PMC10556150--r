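#' Manhattan-distance k-means
#'
#' City-block k-means: assignment minimises L1 distance and each centroid
#' coordinate is the component-wise median of its members (the L1-optimal
#' center). Runs \code{nInit} distance-weighted (k-means++-style, on L1
#' distances) initialisations and keeps the lowest-cost solution. The cost
#' is non-increasing across iterations within every run.
#'
#' @param X n_obs x n_dim numeric matrix.
#' @param k number of clusters (1 <= k <= n_obs).
#' @param nInit number of random initialisations; default 5.
#' @param seed integer seed for initialisation.
#' @param maxIter Lloyd iteration cap per run.
#' @return list: \code{centroids} (k x n_dim), \code{labels} (1..k, in order
#'   of first emergence), \code{cost}, \code{runCosts} (per-init final
#'   costs), \code{costTrace} (per-iteration costs of the winning run).
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 5), 20))
#' fit <- manhattanKMeans(X, 2, seed = 1)
#' fit$cost
#' @export
manhattanKMeans <- function(X, k, nInit = 5L, seed = 1L, maxIter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k (", k, ") exceeds the number of observations (", n, ")")
  stopifnot(k >= 1L, nInit >= 1L)
  runs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nInit), function(r) {
      init <- .seedL1(X, k)
      .kmeans_l1_cpp(X, X[init, , drop = FALSE], max_iter = maxIter)
    })
  })
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  best <- runs[[which.min(costs)]]
  relab <- .emergenceRelabel(as.integer(best$labels), k)
  list(centroids = best$centroids[relab$order, , drop = FALSE],
       labels = relab$labels, cost = best$cost, runCosts = costs,
       costTrace = as.numeric(best$cost_trace))
}

# Distance-weighted seeding on L1 distances (k-means++ flavour): first
# center uniform, subsequent centers with probability proportional to the
# L1 distance to the nearest chosen center.
.seedL1 <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k == 1L) return(centers)
  d <- rowSums(abs(X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE)))
  for (j in 2:k) {
    if (all(d == 0)) centers[j] <- sample.int(n, 1L)
    else centers[j] <- sample.int(n, 1L, prob = d)
    dj <- rowSums(abs(X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE)))
    d <- pmin(d, dj)
  }
  centers
}

# Relabel cluster ids by order of first occurrence in the label stream.
.emergenceRelabel <- function(labels, k) {
  first <- order(match(seq_len(k), labels), seq_len(k))
  map <- integer(k)
  map[first] <- seq_len(k)
  list(labels = map[labels], order = first)
}

#' Select exemplar windows
#'
#' Per subject, keeps the windows at local maxima of the across-pair
#' variance of the FNC vector over window index (endpoints eligible when
#' greater than their single neighbour). A subject with no local maximum
#' (e.g. a constant variance profile) contributes its global maximum, ties
#' resolving to the first index.
#'
#' @param series list of [WindowedFNCSeries-class].
#' @return list: \code{X} (exemplar windows x pairs matrix), \code{subject}
#'   and \code{window} index vectors identifying each exemplar.
#' @export
selectExemplars <- function(series) {
  rows <- list(); subj <- integer(0); winidx <- integer(0)
  for (i in seq_along(series)) {
    Z <- fncMatrix(series[[i]])
    if (nrow(Z) < 3L) stop("each subject needs at least 3 windows")
    v <- apply(Z, 1, var)
    n <- length(v)
    isMax <- logical(n)
    isMax[1] <- v[1] > v[2]
    isMax[n] <- v[n] > v[n - 1]
    if (n > 2L) {
      mid <- 2:(n - 1)
      isMax[mid] <- v[mid] > v[mid - 1] & v[mid] > v[mid + 1]
    }
    pick <- which(isMax)
    if (!length(pick)) pick <- which.max(v) # global-max fallback, first index
    rows[[i]] <- Z[pick, , drop = FALSE]
    subj <- c(subj, rep(i, length(pick)))
    winidx <- c(winidx, pick)
  }
  list(X = do.call(rbind, rows), subject = subj, window = winidx)
}

#' Choose the number of states
#'
#' Clusters the exemplars at each candidate k and selects k by the elbow
#' criterion (largest second difference of the total L1 cost over k) and/or
#' the mean silhouette with L1 distances. Both diagnostic curves are
#' returned.
#'
#' @param X exemplar matrix (rows = windows).
#' @param kRange candidate k values; default 2:8.
#' @param method \code{"elbow"} (default) or \code{"silhouette"}.
#' @param nInit,seed passed to [manhattanKMeans()].
#' @return list: \code{k} (chosen), \code{method}, \code{cost} and
#'   \code{silhouette} curves over \code{kRange}, and \code{elbowK},
#'   \code{silhouetteK} for both criteria.
#' @export
chooseK <- function(X, kRange = 2:8, method = c("elbow", "silhouette"),
                    nInit = 5L, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  stopifnot(all(kRange >= 2L), all(kRange <= nrow(X) - 1L))
  kRange <- sort(unique(as.integer(kRange)))
  if (method == "elbow" && length(kRange) < 3L)
    stop("the elbow criterion needs at least 3 candidate k values")
  D <- stats::dist(X, method = "manhattan")
  fits <- lapply(seq_along(kRange), function(i)
    manhattanKMeans(X, kRange[i], nInit = nInit,
                    seed = .fanSeed(seed, i), maxIter = 100L))
  cost <- vapply(fits, `[[`, numeric(1), "cost")
  sil <- vapply(seq_along(fits), function(i) {
    s <- cluster::silhouette(fits[[i]]$labels, D)
    mean(s[, "sil_width"])
  }, numeric(1))
  elbowK <- if (length(kRange) >= 3L) {
    d2 <- diff(cost, differences = 2) # at interior candidates
    kRange[which.max(d2) + 1L]
  } else NA_integer_
  silK <- kRange[which.max(sil)]
  list(k = if (method == "elbow") elbowK else silK, method = method,
       kRange = kRange, cost = cost, silhouette = sil,
       elbowK = elbowK, silhouetteK = silK)
}

#' Assign windows to fitted centroids
#'
#' Each window gets the L1-nearest centroid; ties break to the lowest
#' centroid index.
#'
#' @param series list of [WindowedFNCSeries-class].
#' @param centroids k x n_pairs matrix.
#' @return named list of per-subject integer label sequences.
#' @export
assignStates <- function(series, centroids) {
  centroids <- as.matrix(centroids)
  lapply(setNames(series, vapply(series, subjectId, character(1))),
         function(s) {
           Z <- fncMatrix(s)
           if (ncol(Z) != ncol(centroids))
             stop("centroid dimension (", ncol(centroids),
                  ") does not match pair dimension (", ncol(Z), ")")
           as.integer(.assign_l1_cpp(Z, centroids))
         })
}

#' Fit the brain-state model
#'
#' Two-stage fit mirroring common dFNC practice: Manhattan k-means on the
#' subjects' exemplar windows (with \code{nInit} restarts), whose centroids
#' then initialise a single full k-means over every window of every
#' subject. A single-stage fit on all windows is available with
#' \code{twoStage = FALSE}. States are relabelled in order of first
#' emergence in the concatenated assignment stream.
#'
#' @param series list of [WindowedFNCSeries-class].
#' @param k number of states; default 4.
#' @param nInit random initialisations; default 5.
#' @param seed integer seed.
#' @param twoStage fit on exemplars then assign all windows (default), or
#'   fit on all windows directly.
#' @return A [StateModel-class].
#' @export
fitStateModel <- function(series, k = 4L, nInit = 5L, seed = 1L,
                          twoStage = TRUE) {
  ids <- vapply(series, subjectId, character(1))
  X <- do.call(rbind, lapply(series, fncMatrix))
  if (twoStage) {
    ex <- selectExemplars(series)
    exFit <- manhattanKMeans(ex$X, k, nInit = nInit, seed = seed)
    full <- .kmeans_l1_cpp(X, exFit$centroids, max_iter = 100L)
    relab <- .emergenceRelabel(as.integer(full$labels), k)
    fit <- list(centroids = full$centroids[relab$order, , drop = FALSE],
                labels = relab$labels, cost = full$cost,
                runCosts = exFit$runCosts,
                costTrace = as.numeric(full$cost_trace))
  } else {
    fit <- manhattanKMeans(X, k, nInit = nInit, seed = seed)
  }
  labels <- assignStates(series, fit$centroids)
  # emergence order over the full concatenated stream
  stream <- unlist(labels, use.names = FALSE)
  perm <- .emergencePerm(stream, k)
  labels <- lapply(labels, function(l) perm[l])
  cent <- fit$centroids[order(perm), , drop = FALSE]
  new("StateModel", k = as.integer(k), centroids = cent,
      labels = setNames(labels, ids), cost = fit$cost,
      nInit = as.integer(nInit), seed = as.integer(seed),
      diagnostics = list(runCosts = fit$runCosts, costTrace = fit$costTrace,
                         twoStage = twoStage))
}

# Permutation old-label -> new-label by order of first occurrence.
.emergencePerm <- function(stream, k) {
  firstPos <- match(seq_len(k), stream)
  ord <- order(firstPos, seq_len(k), na.last = TRUE)
  perm <- integer(k)
  perm[ord] <- seq_len(k)
  perm
}

#' Per-state window counts and occurrence percentages
#'
#' @param model a [StateModel-class].
#' @return data.frame: state, count, percent. Counts sum to the total
#'   number of windows; percentages to 100.
#' @export
stateSummary <- function(model) {
  stopifnot(is(model, "StateModel"))
  lab <- unlist(model@labels, use.names = FALSE)
  counts <- tabulate(lab, nbins = model@k)
  data.frame(state = seq_len(model@k), count = counts,
             percent = 100 * counts / sum(counts))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings; used to score recovery
#' of planted state sequences.
#'
#' @param a,b integer label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}
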