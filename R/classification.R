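#' Group-by-state centroid design matrix
#'
#' Column (g, s) is the mean windowed-FNC pattern over all windows of
#' subjects in group g assigned to state s — 8 columns for 2 groups x 4
#' states. An empty (group, state) cell is dropped with a warning and the
#' feature length shrinks accordingly.
#'
#' @param series list of [WindowedFNCSeries-class].
#' @param labels named list of per-subject window label sequences.
#' @param groups named character vector (by subject id) of group labels.
#' @param k number of states.
#' @return n_pairs x n_cells matrix with \code{"<group>.s<state>"} column
#'   names.
#' @export
buildCentroidDesign <- function(series, labels, groups, k = 4L) {
  ids <- vapply(series, subjectId, character(1))
  glev <- sort(unique(unname(groups)))
  cols <- list()
  for (g in glev) for (s in seq_len(k)) {
    sums <- NULL; count <- 0
    for (i in seq_along(series)) {
      if (groups[[ids[i]]] != g) next
      Z <- fncMatrix(series[[i]])
      inState <- labels[[ids[i]]] == s
      if (!any(inState)) next
      cs <- colSums(Z[inState, , drop = FALSE])
      sums <- if (is.null(sums)) cs else sums + cs
      count <- count + sum(inState)
    }
    nm <- sprintf("%s.s%d", g, s)
    if (count == 0) {
      warning("empty (group, state) cell ", nm, " dropped from the design")
    } else cols[[nm]] <- sums / count
  }
  do.call(cbind, cols)
}

#' Window regression coefficients on the centroid design
#'
#' Ordinary least squares of one window's (pair-centered) FNC vector on the
#' (pair-centered) design columns, no intercept: one beta per
#' (group, state) pattern. Rank-deficient designs fall back to the
#' minimum-norm solution with a warning.
#'
#' @param windowVector FNC pair vector for one window.
#' @param design matrix from [buildCentroidDesign()].
#' @return named coefficient vector (length = design columns; 8 for the
#'   full 2 x 4 design).
#' @export
windowBetas <- function(windowVector, design) {
  stopifnot(length(windowVector) == nrow(design))
  D <- scale(design, center = TRUE, scale = FALSE)
  w <- windowVector - mean(windowVector)
  .betasCentered(matrix(w, ncol = 1), D)[, 1]
}

# OLS for many centered windows at once; columns of W are windows.
.betasCentered <- function(W, D) {
  XtX <- crossprod(D)
  b <- tryCatch(solve(XtX, crossprod(D, W)), error = function(e) NULL)
  if (is.null(b)) {
    warning("rank-deficient centroid design; using the minimum-norm solution")
    sv <- svd(D)
    keep <- sv$d > max(sv$d) * 1e-10
    b <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], W) / sv$d[keep])
  }
  rownames(b) <- colnames(D)
  b
}

#' Per-subject mean beta features
#'
#' The subject's feature vector is the mean of [windowBetas()] over all of
#' the subject's windows (8 mean beta coefficients for the full design).
#'
#' @param series a [WindowedFNCSeries-class].
#' @param design matrix from [buildCentroidDesign()].
#' @return named feature vector of length \code{ncol(design)}.
#' @export
subjectFeatures <- function(series, design) {
  Z <- fncMatrix(series)
  stopifnot(nrow(Z) >= 1L)
  D <- scale(design, center = TRUE, scale = FALSE)
  W <- scale(t(Z), center = TRUE, scale = FALSE) # pairs x windows, each window centered
  rowMeans(.betasCentered(W, D))
}

#' Cohort feature matrix
#'
#' @param seriesList list of [WindowedFNCSeries-class].
#' @param design matrix from [buildCentroidDesign()].
#' @return subjects x features matrix (row names = subject ids).
#' @export
cohortFeatures <- function(seriesList, design) {
  out <- t(vapply(seriesList, subjectFeatures, numeric(ncol(design)),
                  design = design))
  rownames(out) <- vapply(seriesList, subjectId, character(1))
  out
}

.stratifiedFolds <- function(groups, nFolds) {
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Evaluate a linear SVM by repeated stratified cross-validation
#'
#' Trains a linear support vector machine per fold and reports per-class
#' accuracy (sensitivity) averaged over folds and repeats, plus the ROC of
#' the pooled decision scores and its trapezoidal AUC.
#'
#' In \code{fold_safe} mode the group-by-state centroid design — the only
#' object that uses group labels — is rebuilt from the training subjects of
#' each fold and applied to held-out subjects; \code{paper_faithful} builds
#' it once from all subjects.
#'
#' @param seriesList list of [WindowedFNCSeries-class] (needed for
#'   \code{fold_safe}; optional for \code{paper_faithful} when
#'   \code{features} is supplied).
#' @param labels per-subject window label sequences.
#' @param groups named group vector (two classes, e.g. CD/HC).
#' @param k number of states.
#' @param mode \code{"fold_safe"} (default) or \code{"paper_faithful"}.
#' @param features optional precomputed subjects x features matrix (used in
#'   \code{paper_faithful} mode).
#' @param nFolds,nRepeats CV scheme; defaults 10 folds, 100 repeats.
#' @param cost SVM regularisation parameter C; default 1.
#' @param seed integer seed.
#' @return A [ClassificationResult-class].
#' @export
evaluateClassifier <- function(seriesList = NULL, labels = NULL, groups,
                               k = 4L, mode = c("fold_safe", "paper_faithful"),
                               features = NULL, nFolds = 10L, nRepeats = 100L,
                               cost = 1, seed = 1L) {
  mode <- match.arg(mode)
  ids <- names(groups)
  y <- factor(unname(groups))
  stopifnot(nlevels(y) == 2L)
  if (mode == "paper_faithful" && is.null(features)) {
    design <- buildCentroidDesign(seriesList, labels, groups, k = k)
    features <- cohortFeatures(seriesList, design)
  }
  if (mode == "fold_safe") stopifnot(!is.null(seriesList), !is.null(labels))
  n <- length(y)
  posLevel <- levels(y)[2]
  acc <- numeric(0)
  hits <- setNames(c(0, 0), levels(y))
  tot <- setNames(c(0, 0), levels(y))
  scores <- numeric(n * nRepeats)
  truth <- factor(rep(NA_character_, n * nRepeats), levels = levels(y))
  ptr <- 0L
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRepeats)) {
      fold <- .stratifiedFolds(as.character(y), nFolds)
      for (f in seq_len(nFolds)) {
        test <- which(fold == f)
        train <- which(fold != f)
        if (mode == "fold_safe") {
          design <- suppressWarnings(buildCentroidDesign(
            seriesList[train], labels[ids[train]], groups[ids[train]], k = k))
          feats <- cohortFeatures(seriesList, design)
        } else feats <- features
        fit <- e1071::svm(x = feats[train, , drop = FALSE], y = y[train],
                          kernel = "linear", cost = cost, scale = TRUE)
        pred <- predict(fit, feats[test, , drop = FALSE],
                        decision.values = TRUE)
        acc <- c(acc, mean(pred == y[test]))
        for (lv in levels(y)) {
          inClass <- y[test] == lv
          hits[lv] <- hits[lv] + sum(pred[inClass] == lv)
          tot[lv] <- tot[lv] + sum(inClass)
        }
        dvm <- attr(pred, "decision.values")
        dv <- dvm[, 1]
        # orient decision values so larger means the second factor level
        firstNamed <- sub("/.*$", "", colnames(dvm)[1])
        if (firstNamed != posLevel) dv <- -dv
        scores[ptr + seq_along(test)] <- dv
        truth[ptr + seq_along(test)] <- y[test]
        ptr <- ptr + length(test)
      }
    }
  })
  rocObj <- pROC::roc(response = truth, predictor = scores,
                      levels = levels(y), direction = "<", quiet = TRUE)
  rocDf <- data.frame(fpr = 1 - rocObj$specificities, tpr = rocObj$sensitivities)
  rocDf <- rocDf[order(rocDf$fpr, rocDf$tpr), ]
  new("ClassificationResult", accuracy = acc,
      classAccuracy = hits / tot, roc = rocDf,
      auc = as.numeric(pROC::auc(rocObj)),
      features = if (is.null(features)) matrix(numeric(0), 0, 0) else features,
      mode = mode, scheme = list(nFolds = nFolds, nRepeats = nRepeats,
                                 cost = cost), seed = as.integer(seed))
}
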