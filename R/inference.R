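#' Two-sample t-test from raw vectors or printed summary statistics
#'
#' Pooled-variance (default) or Welch t-test. Summary-statistic input lets
#' group contrasts be recomputed from published tables: with n, mean and sd
#' per group the pooled statistic is
#' \code{t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))} on \code{n1 + n2 - 2}
#' degrees of freedom.
#'
#' @param x,y raw vectors (ignored when \code{summary1}/\code{summary2}
#'   given).
#' @param summary1,summary2 per-group \code{c(n=, mean=, sd=)} summaries.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return data.frame: statistic, df, p (two-sided), mean difference.
#' @examples
#' twoSampleT(summary1 = c(n = 50, mean = 89.040, sd = 59.216),
#'            summary2 = c(n = 57, mean = 57.491, sd = 40.671))
#' @export
twoSampleT <- function(x = NULL, y = NULL, summary1 = NULL, summary2 = NULL,
                       variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (is.null(summary1)) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    summary1 <- c(n = length(x), mean = mean(x), sd = sd(x))
    summary2 <- c(n = length(y), mean = mean(y), sd = sd(y))
  }
  n1 <- summary1[["n"]]; m1 <- summary1[["mean"]]; s1 <- summary1[["sd"]]
  n2 <- summary2[["n"]]; m2 <- summary2[["mean"]]; s2 <- summary2[["sd"]]
  stopifnot(n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0 && m1 == m2)
    stop("undefined statistic: zero variance in both groups with equal means")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  data.frame(statistic = tstat, df = df,
             p = 2 * pt(-abs(tstat), df), meanDiff = m1 - m2)
}

#' Levene's test for equality of variances (two groups)
#'
#' One-way ANOVA F on absolute deviations from the group center (mean by
#' default; the median-centered Brown-Forsythe variant via
#' \code{center = "median"}).
#'
#' @param x,y the two samples.
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return data.frame: statistic (F), df1, df2, p.
#' @export
leveneEqualVariance <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  cf <- if (center == "mean") mean else median
  zx <- abs(x - cf(x)); zy <- abs(y - cf(y))
  n1 <- length(zx); n2 <- length(zy); n <- n1 + n2
  zbar <- mean(c(zx, zy))
  ssb <- n1 * (mean(zx) - zbar)^2 + n2 * (mean(zy) - zbar)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (ssw == 0) {
    fstat <- if (ssb == 0) 0 else Inf
  } else fstat <- (ssb / 1) / (ssw / (n - 2))
  p <- if (is.infinite(fstat)) 0 else pf(fstat, 1, n - 2, lower.tail = FALSE)
  if (fstat == 0) p <- 1
  data.frame(statistic = fstat, df1 = 1, df2 = n - 2, p = p)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' Pairs with missing values are dropped row-wise.
#'
#' @param x,y numeric vectors.
#' @return data.frame: r, n, df, p.
#' @export
pearsonCorrTest <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(r = unname(ct$estimate), n = length(x),
             df = unname(ct$parameter), p = ct$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (adjusted p = min over j >= i of m p_(j)/j,
#' capped at 1) and rejection flags at level \code{q}.
#'
#' @param p vector of p-values in [0, 1].
#' @param q FDR level; default 0.05.
#' @return data.frame: p, p_fdr, reject.
#' @export
fdrBH <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), q > 0, q < 1)
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_fdr = adj, reject = adj <= q)
}

#' Per-block mean connectivity of one subject in one state
#'
#' Averages the subject's windowed FNC vectors over the windows assigned to
#' \code{state}, then averages entries within each of the six network
#' blocks (DMN-DMN, CEN-CEN, SN-SN, DMN-CEN, DMN-SN, CEN-SN). A subject
#' with no window in the state returns all-NA (absent marker), so the group
#' contrast's degrees of freedom shrink by the number of absent subjects.
#'
#' @param series a [WindowedFNCSeries-class].
#' @param labels the subject's window label sequence.
#' @param partitionObj a [NetworkPartition-class].
#' @param state state label.
#' @return named numeric vector of 6 block means (NA if absent).
#' @export
stateBlockConnectivity <- function(series, labels, partitionObj, state) {
  blocks <- c("DMN-DMN", "CEN-CEN", "SN-SN", "DMN-CEN", "DMN-SN", "CEN-SN")
  Z <- fncMatrix(series)
  stopifnot(length(labels) == nrow(Z))
  inState <- labels == state
  if (!any(inState))
    return(setNames(rep(NA_real_, 6), blocks))
  v <- colMeans(Z[inState, , drop = FALSE])
  nets <- as.character(networkLabels(partitionObj))
  p <- length(nets)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pairBlock <- vapply(seq_len(nrow(idx)), function(i) {
    a <- nets[idx[i, 1]]; b <- nets[idx[i, 2]]
    if (a == b) paste(a, b, sep = "-")
    else paste(sort(factor(c(a, b), levels = c("DMN", "CEN", "SN")))[c(1, 2)],
               collapse = "-")
  }, character(1))
  setNames(vapply(blocks, function(bl) mean(v[pairBlock == bl]), numeric(1)),
           blocks)
}

#' Run the group-level statistical battery
#'
#' Orchestrates the published comparisons on a cohort's temporal profiles
#' and clinical table: per-state dwell-time and fraction t-tests plus the
#' transitions contrast (one FDR family), Levene variance checks, and
#' Pearson correlations of selected temporal properties with clinical
#' covariates (one FDR family per temporal property), with configurable
#' correlation scope (all participants or patients only).
#'
#' @param profiles data.frame from [temporalProfiles()].
#' @param clinical data.frame with \code{subject_id}, \code{group} and
#'   covariate columns; groups must be \code{"CD"} and \code{"HC"}.
#' @param corrVars temporal-property columns to correlate; default
#'   \code{c("dwell_s1", "dwell_s4")} when present.
#' @param corrScope named character vector mapping clinical columns to
#'   \code{"all"} or \code{"CD"}; unlisted columns default to \code{"all"}.
#' @param q FDR level; \code{variant} t-test variant.
#' @return list of data.frames: \code{groupTests} (t and Levene per
#'   temporal property, FDR-adjusted) and \code{correlations}.
#' @export
runGroupAnalysis <- function(profiles, clinical, corrVars = NULL,
                             corrScope = NULL, q = 0.05,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  orphans <- setdiff(profiles$subject_id, clinical$subject_id)
  if (length(orphans))
    stop("subjects missing from the clinical table: ",
         paste(orphans, collapse = ", "))
  df <- merge(profiles, clinical, by = "subject_id")
  stopifnot(all(df$group %in% c("CD", "HC")))
  tempVars <- grep("^(dwell_|frac_)", names(profiles), value = TRUE)
  tempVars <- c(tempVars, "n_transitions")
  cd <- df$group == "CD"
  tests <- lapply(tempVars, function(v) {
    tt <- twoSampleT(df[[v]][cd], df[[v]][!cd], variant = variant)
    lv <- leveneEqualVariance(df[[v]][cd], df[[v]][!cd])
    data.frame(analysis = "group_t", variable = v, statistic = tt$statistic,
               df = tt$df, p = tt$p, levene_F = lv$statistic,
               levene_p = lv$p, n1 = sum(cd), n2 = sum(!cd))
  })
  groupTests <- do.call(rbind, tests)
  fam <- fdrBH(groupTests$p, q)
  groupTests$p_fdr <- fam$p_fdr
  groupTests$reject_fdr <- fam$reject

  if (is.null(corrVars))
    corrVars <- intersect(c("dwell_s1", "dwell_s4"), names(profiles))
  clinCols <- setdiff(names(clinical), c("subject_id", "group"))
  correlations <- NULL
  if (length(corrVars) && length(clinCols)) {
    rows <- list()
    for (v in corrVars) {
      sub <- lapply(clinCols, function(cc) {
        scope <- if (!is.null(corrScope) && cc %in% names(corrScope))
          corrScope[[cc]] else "all"
        use <- if (scope == "CD") cd else rep(TRUE, nrow(df))
        ct <- pearsonCorrTest(df[[v]][use], df[[cc]][use])
        data.frame(analysis = "correlation", variable = v, covariate = cc,
                   scope = scope, r = ct$r, n = ct$n, df = ct$df, p = ct$p)
      })
      sub <- do.call(rbind, sub)
      famc <- fdrBH(sub$p, q) # one FDR family per temporal property
      sub$p_fdr <- famc$p_fdr
      sub$reject_fdr <- famc$reject
      rows[[v]] <- sub
    }
    correlations <- do.call(rbind, rows)
    rownames(correlations) <- NULL
  }
  list(groupTests = groupTests, correlations = correlations)
}
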