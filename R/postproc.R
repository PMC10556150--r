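#' @name postproc
#' @title Component time-course post-processing
#' @description After back-reconstruction the component time courses still
#'   carry scanner drift, motion spikes and high-frequency noise. The
#'   cleaning chain applied before windowed connectivity is: polynomial
#'   detrend, robust-z despiking, zero-phase Butterworth low-pass at
#'   0.15 Hz, and regression of the six head-motion parameters.
NULL

.mapColumns <- function(tc, f) {
  X <- tc@data
  for (j in seq_len(ncol(X))) X[, j] <- f(X[, j])
  out <- tc
  out@data <- X
  out
}

#' Polynomial detrend
#'
#' Removes the per-column least-squares polynomial of the given order.
#'
#' @param tc a [ComponentTimecourses-class].
#' @param order polynomial order: 0 (mean), 1 (linear, default) or 2.
#' @return Detrended [ComponentTimecourses-class]; residual column means are
#'   zero to numerical precision.
#' @export
detrendTimecourses <- function(tc, order = 1L) {
  stopifnot(is(tc, "ComponentTimecourses"), order %in% 0:2)
  n <- nrow(tc@data)
  if (n < order + 1L) stop("fewer timepoints than polynomial coefficients")
  t0 <- seq_len(n)
  B <- outer(t0, 0:order, `^`)
  Q <- qr(B)
  .mapColumns(tc, function(x) as.numeric(qr.resid(Q, x)))
}

#' Robust-z despiking
#'
#' Samples whose robust z-score |x - median| / (1.4826 * MAD) exceeds the
#' threshold are replaced by linear interpolation between the nearest
#' non-spike neighbours (endpoints take the nearest non-spike value). The
#' pass repeats until no sample exceeds the threshold or \code{maxPasses}
#' is reached. An all-constant column (MAD = 0) is returned unchanged.
#'
#' @param tc a [ComponentTimecourses-class].
#' @param zThresh robust-z threshold (> 0); default 3.5.
#' @param maxPasses iteration cap; default 5.
#' @return Despiked [ComponentTimecourses-class].
#' @export
despikeTimecourses <- function(tc, zThresh = 3.5, maxPasses = 5L) {
  stopifnot(is(tc, "ComponentTimecourses"), zThresh > 0)
  .mapColumns(tc, function(x) {
    for (pass in seq_len(maxPasses)) {
      m <- median(x)
      s <- mad(x) # 1.4826 * MAD by default
      if (s == 0) return(x)
      spike <- abs(x - m) / s > zThresh
      if (!any(spike)) return(x)
      if (all(spike)) return(x) # nothing to anchor interpolation on
      keep <- which(!spike)
      x[spike] <- approx(keep, x[keep], xout = which(spike),
                         rule = 2)$y
    }
    x
  })
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) application of a 5th-order Butterworth
#' low-pass, the conventional frequency cut for windowed connectivity.
#'
#' @param tc a [ComponentTimecourses-class].
#' @param cutoffHz high-frequency cutoff in Hz; default 0.15. Must be below
#'   the Nyquist frequency 1/(2 TR).
#' @param order filter order; default 5.
#' @return Filtered [ComponentTimecourses-class].
#' @export
lowpassFilter <- function(tc, cutoffHz = 0.15, order = 5L) {
  stopifnot(is(tc, "ComponentTimecourses"))
  nyquist <- 1 / (2 * tc@trSeconds)
  if (cutoffHz >= nyquist)
    stop(sprintf("cutoff %.3f Hz is at or above Nyquist (%.3f Hz)",
                 cutoffHz, nyquist))
  bf <- signal::butter(order, cutoffHz / nyquist, type = "low")
  .mapColumns(tc, function(x) {
    mu <- mean(x) # filter around the mean so DC is preserved exactly
    as.numeric(signal::filtfilt(bf, x - mu)) + mu
  })
}

#' Regress out nuisance (motion) parameters
#'
#' Ordinary least squares of each component column on an intercept plus the
#' six motion regressors; returns the residuals (not re-centered).
#'
#' @param tc a [ComponentTimecourses-class].
#' @param nuisance time x 6 numeric matrix of motion parameters (any column
#'   count >= 1 is accepted).
#' @return Residual [ComponentTimecourses-class]; residuals are orthogonal
#'   to every regressor.
#' @export
regressNuisance <- function(tc, nuisance) {
  stopifnot(is(tc, "ComponentTimecourses"))
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(tc@data))
    stop("nuisance regressors must have the same number of rows as the time courses")
  X <- cbind(1, nuisance)
  Q <- qr(X)
  if (Q$rank < ncol(X))
    warning("rank-deficient regressor matrix; using the pseudo-inverse solution")
  .mapColumns(tc, function(y) as.numeric(qr.resid(Q, y)))
}

#' Full post-processing chain
#'
#' Applies, in order: detrend, despike, low-pass filter, nuisance
#' regression (the latter only when motion parameters are supplied). The
#' order is configurable through \code{steps}.
#'
#' @param tc a [ComponentTimecourses-class].
#' @param detrendOrder polynomial order for the detrend step.
#' @param despikeZ robust-z threshold.
#' @param lowpassHz low-pass cutoff (Hz).
#' @param nuisance optional time x 6 motion-parameter matrix.
#' @param steps character vector giving the step order.
#' @return Cleaned [ComponentTimecourses-class].
#' @export
postprocess <- function(tc, detrendOrder = 1L, despikeZ = 3.5,
                        lowpassHz = 0.15, nuisance = NULL,
                        steps = c("detrend", "despike", "filter", "nuisance")) {
  for (s in steps) {
    tc <- switch(s,
      detrend = detrendTimecourses(tc, detrendOrder),
      despike = despikeTimecourses(tc, despikeZ),
      filter = lowpassFilter(tc, lowpassHz),
      nuisance = if (is.null(nuisance)) tc else regressNuisance(tc, nuisance),
      stop("unknown post-processing step '", s, "'"))
  }
  tc
}
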