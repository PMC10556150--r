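#' Product-of-coefficients mediation paths
#'
#' Linear mediation of a binary exposure X on outcome Y through mediator M:
#' \code{a} from M ~ 1 + X; \code{b} and the direct effect \code{cPrime}
#' from Y ~ 1 + X + M; total effect \code{c} from Y ~ 1 + X. The indirect
#' effect is \code{a * b}; for the linear no-interaction model
#' \code{c = cPrime + a * b}.
#'
#' @param x binary exposure (0/1, logical, or two-level factor/character).
#' @param m mediator vector.
#' @param y outcome vector.
#' @return list: a, b, c, cPrime, indirect.
#' @export
fitMediationPaths <- function(x, m, y) {
  x <- .asBinary(x)
  stopifnot(length(x) == length(m), length(m) == length(y))
  if (length(unique(x)) < 2L) stop("exposure must have both levels")
  if (sd(m) == 0 || sd(y) == 0)
    stop("degenerate fit: constant mediator or outcome")
  n <- length(x)
  a <- mean(m[x == 1]) - mean(m[x == 0])
  cTot <- mean(y[x == 1]) - mean(y[x == 0])
  # Y ~ 1 + X + M by normal equations (with a collinearity guard)
  X2 <- cbind(1, x, m)
  fit <- tryCatch(solve(crossprod(X2), crossprod(X2, y)),
                  error = function(e) qr.coef(qr(X2), y))
  cPrime <- fit[2]; b <- fit[3]
  if (anyNA(c(cPrime, b))) { # collinear X and M: attribute to the mediator
    b <- cTot / a
    cPrime <- 0
  }
  list(a = a, b = unname(b), c = cTot, cPrime = unname(cPrime),
       indirect = a * unname(b))
}

.asBinary <- function(x) {
  if (is.numeric(x) || is.logical(x)) {
    u <- sort(unique(as.numeric(x)))
    if (!all(u %in% c(0, 1))) stop("numeric exposure must be coded 0/1")
    return(as.numeric(x))
  }
  f <- factor(x)
  if (nlevels(f) != 2L) stop("exposure must have exactly two levels")
  as.numeric(f) - 1
}

# fast indirect effect for bootstrap resamples (no input checks)
.indirectFast <- function(x, m, y) {
  n1 <- sum(x)
  if (n1 == 0L || n1 == length(x)) return(NA_real_)
  a <- sum(m * x) / n1 - sum(m * (1 - x)) / (length(x) - n1)
  X2 <- cbind(1, x, m)
  fit <- tryCatch(solve(crossprod(X2), crossprod(X2, y)),
                  error = function(e) rep(NA_real_, 3))
  a * fit[3]
}

#' Bootstrap mediation with BCa confidence intervals
#'
#' Resamples subjects with replacement, recomputes the indirect effect, and
#' reports percentile and bias-corrected-and-accelerated (BCa) intervals.
#' Bias correction \code{z0} comes from the fraction of bootstrap values
#' below the point estimate; acceleration from the jackknife skewness of
#' the indirect effect. Degenerate resamples (a single exposure level) are
#' redrawn and counted.
#'
#' @param x,m,y exposure, mediator, outcome (see [fitMediationPaths()]).
#' @param nBoot number of bootstrap resamples; default 5000.
#' @param level confidence level; default 0.95.
#' @param seed integer seed.
#' @return A [MediationResult-class].
#' @examples
#' set.seed(1)
#' x <- rep(0:1, each = 50)
#' m <- 0.5 * x + rnorm(100, sd = 0.5)
#' y <- 0.5 * m + rnorm(100, sd = 0.5)
#' bootstrapMediation(x, m, y, nBoot = 500, seed = 1)
#' @export
bootstrapMediation <- function(x, m, y, nBoot = 5000L, level = 0.95,
                               seed = 1L) {
  x <- .asBinary(x)
  paths <- fitMediationPaths(x, m, y)
  n <- length(x)
  nDegenerate <- 0L
  boot <- withr::with_seed(as.integer(seed), {
    out <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- .indirectFast(x[idx], m[idx], y[idx])
        if (!is.na(val)) break
        nDegenerate <- nDegenerate + 1L
      }
      out[b] <- val
    }
    out
  })
  alpha <- (1 - level) / 2
  pct <- unname(quantile(boot, c(alpha, 1 - alpha)))
  # BCa
  propBelow <- mean(boot < paths$indirect)
  z0 <- qnorm(pmin(pmax(propBelow, 1 / (nBoot + 1)), nBoot / (nBoot + 1)))
  jack <- vapply(seq_len(n), function(i)
    .indirectFast(x[-i], m[-i], y[-i]), numeric(1))
  jm <- mean(jack, na.rm = TRUE)
  dj <- jm - jack
  denom <- sum(dj^2, na.rm = TRUE)^1.5
  accel <- if (denom == 0) 0 else sum(dj^3, na.rm = TRUE) / (6 * denom)
  zlo <- qnorm(alpha); zhi <- qnorm(1 - alpha)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - accel * (z0 + z)))
  bca <- unname(quantile(boot, c(adj(zlo), adj(zhi))))
  # two-sided bootstrap p: smallest level at which the CI excludes 0
  pBoot <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  pBoot <- min(max(pBoot, 1 / nBoot), 1)
  new("MediationResult", a = paths$a, b = paths$b, c = paths$c,
      cPrime = paths$cPrime, indirect = paths$indirect,
      bootIndirect = boot, bcaInterval = bca, percentileInterval = pct,
      bootP = pBoot, level = level, nBoot = as.integer(nBoot),
      seed = as.integer(seed), nDegenerate = nDegenerate)
}
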