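#' Sliding-window specification
#'
#' @param widthTr window width in TR; default 30 (60 s at TR 2 s).
#' @param stepTr step between window starts in TR; default 1.
#' @return list of class \code{"WindowSpec"}.
#' @export
windowSpec <- function(widthTr = 30L, stepTr = 1L) {
  stopifnot(widthTr >= 2L, stepTr >= 1L)
  structure(list(widthTr = as.integer(widthTr), stepTr = as.integer(stepTr)),
            class = "WindowSpec")
}

#' Enumerate sliding windows
#'
#' Windows are half-open index ranges \code{[s, s + width)}, 0-based, with
#' starts 0, step, 2*step, ...; the count is
#' \code{floor((T - width) / step)}. This convention yields 200 windows for
#' a 230-timepoint scan with width 30 and step 1.
#'
#' @param nTimepoints number of timepoints T (must exceed the width).
#' @param spec a [windowSpec()].
#' @return integer matrix with columns \code{start} (0-based, inclusive) and
#'   \code{end} (0-based, exclusive), one row per window.
#' @examples
#' nrow(makeWindows(230, windowSpec(30, 1)))  # 200
#' @export
makeWindows <- function(nTimepoints, spec = windowSpec()) {
  w <- spec$widthTr; s <- spec$stepTr
  if (nTimepoints <= w)
    stop("need more timepoints (", nTimepoints, ") than the window width (", w, ")")
  nWin <- (nTimepoints - w) %/% s
  starts <- (seq_len(nWin) - 1L) * s
  cbind(start = starts, end = starts + w)
}

#' L1-regularised precision matrix (graphical lasso)
#'
#' Maximises \code{log det(Theta) - tr(S Theta) - lambda * ||Theta||_1,off}
#' by block coordinate descent (off-diagonal penalty only). At lambda = 0
#' with a well-conditioned S this reproduces the direct matrix inverse.
#'
#' @param sampleCov symmetric sample covariance (or correlation) matrix.
#' @param lambda nonnegative L1 penalty.
#' @param maxIter outer iteration cap.
#' @param tol relative convergence tolerance on the working covariance.
#' @return SPD precision matrix with attributes \code{iterations} and
#'   \code{dual_gap}.
#' @examples
#' S <- diag(4)
#' graphicalLassoPrecision(S, 0.1)  # identity
#' @export
graphicalLassoPrecision <- function(sampleCov, lambda, maxIter = 200L,
                                    tol = 1e-6) {
  stopifnot(lambda >= 0)
  sampleCov <- as.matrix(sampleCov)
  if (!isSymmetric(sampleCov, tol = 1e-8))
    stop("sample covariance must be symmetric")
  sampleCov <- (sampleCov + t(sampleCov)) / 2
  fit <- .glasso_cpp(sampleCov, lambda, max_outer = maxIter, tol = tol)
  if (!fit$converged)
    stop(sprintf("graphical lasso failed to converge within %d iterations (duality gap %.3g)",
                 maxIter, fit$dual_gap))
  theta <- fit$theta
  # SPD guard: the estimator should always be PD; fail loudly if not
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ch)) stop("estimated precision matrix is not positive definite")
  structure(theta, iterations = fit$iterations, dual_gap = fit$dual_gap)
}

#' Precision matrix to Fisher-z partial-correlation pair vector
#'
#' Partial correlation \code{r_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)},
#' Fisher transformed (\code{atanh}) after clipping |r| at 1 - 1e-7, and
#' vectorised over the upper triangle in row-major pair order.
#'
#' @param precision SPD precision matrix.
#' @return numeric vector of length p(p-1)/2.
#' @export
precisionToFisherZ <- function(precision) {
  d <- diag(precision)
  if (any(d <= 0)) stop("precision matrix has non-positive diagonal entries")
  r <- -precision / sqrt(outer(d, d))
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  atanh(t(r)[lower.tri(r)]) # upper triangle, row-major
}

.pairNames <- function(componentNames) {
  p <- length(componentNames)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sprintf("p_%s_%s", componentNames[idx[, 1]], componentNames[idx[, 2]])
}

#' Windowed FNC for one subject
#'
#' For each sliding window: standardise columns within the window, take the
#' sample correlation, estimate the L1-regularised precision, and convert to
#' a Fisher-z partial-correlation pair vector.
#'
#' @param tc a (post-processed) [ComponentTimecourses-class].
#' @param spec a [windowSpec()]; defaults give 200 windows for 230 TR.
#' @param lambda L1 penalty for the precision estimate; default 0.1 on
#'   within-window standardised data.
#' @return A [WindowedFNCSeries-class] (n_windows x n_pairs; 200 x 253 for
#'   the defaults on 23 components).
#' @export
subjectDFNC <- function(tc, spec = windowSpec(), lambda = 0.1) {
  stopifnot(is(tc, "ComponentTimecourses"))
  X <- tc@data
  win <- makeWindows(nrow(X), spec)
  p <- ncol(X)
  Z <- matrix(0, nrow(win), p * (p - 1) / 2)
  for (i in seq_len(nrow(win))) {
    seg <- X[(win[i, "start"] + 1L):win[i, "end"], , drop = FALSE]
    S <- cor(seg)
    theta <- graphicalLassoPrecision(S, lambda)
    Z[i, ] <- precisionToFisherZ(theta)
  }
  new("WindowedFNCSeries", subjectId = tc@subjectId, z = Z,
      windowStarts = as.integer(win[, "start"]), lambda = lambda,
      pairNames = .pairNames(colnames(X)))
}

#' Windowed FNC for a list of subjects
#'
#' @param tcs list of [ComponentTimecourses-class] (e.g.
#'   \code{timecourses(cohort)}).
#' @param spec,lambda passed to [subjectDFNC()].
#' @return named list of [WindowedFNCSeries-class].
#' @export
cohortDFNC <- function(tcs, spec = windowSpec(), lambda = 0.1) {
  out <- lapply(tcs, subjectDFNC, spec = spec, lambda = lambda)
  names(out) <- vapply(out, subjectId, character(1))
  out
}
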