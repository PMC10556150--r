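---
title: "Methods: dynamic connectivity states, from windows to inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic connectivity states, from windows to inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the methodological choices behind `dfncstates`:
the conventions each stage follows, why the synthetic generator is built
the way it is, and where the implementation deliberately deviates from
common practice. Code chunks are illustrative and not evaluated at build
time; the README shows a fully executed session.

## Windowing and connectivity

Windows are enumerated with 0-based starts and exclusive ends:
`floor((T - width) / step)` windows, so a 230-timepoint scan with
width 30 and step 1 yields exactly 200 windows. Each window's
covariance is regularised with the graphical lasso
(`graphicalLassoPrecision()`, block-coordinate descent with a duality-gap
stopping rule); off-diagonal precision entries are converted to partial
correlations `r_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` and
Fisher-z transformed. Pairs are stored in row-major upper-triangle order
(`p_<c1>_<c2>`), 253 pairs for 23 components.

The default penalty is `lambda = 0.1`. With 30-timepoint windows over 23
components the per-window sample covariance is ill-conditioned; the lasso
trades a little shrinkage of true edges for exact zeros on most spurious
ones. Heavier penalties (0.15–0.2) shrink genuine between-state
differences faster than they remove noise, and `lambda -> 0` reduces to
the direct inverse (one of the acceptance checks).

## State clustering

`fitStateModel()` is k-means under the Manhattan (L1) metric: cluster
centroids are coordinate-wise **medians**, assignment uses L1 distance,
ties go to the lowest state index. L1 is less dominated by single
extreme pairs than L2 and the median centroid is robust to window
outliers.

Clustering is two-stage. Per-subject *exemplar* windows — local maxima of
the across-pair variance of each subject's windowed series — are
clustered first; the exemplar centroids then initialise a full k-means
over all windows. The second stage **updates** the centroids rather than
freezing them: empirically, freezing the exemplar centroids roughly
halves label-recovery ARI on synthetic cohorts because exemplars
over-represent transition-adjacent, high-variance windows.

Model order is chosen on the exemplar set by two criteria
(`chooseK()`):

* **elbow** — the k maximising the second difference of the k-means cost
  curve (only defined at interior candidates of the range);
* **silhouette** — the k maximising the mean L1 silhouette.

States are relabelled by *emergence order*: state 1 is the first state
any window of the concatenated cohort stream enters, and so on. This
makes labels reproducible across runs and readable in downstream tables.

## The synthetic generator

`simulateCohort()` draws each subject's state sequence from a first-order
Markov chain and emits observations from the active state's covariance.
Design choices that matter for recovery:

* **Disjoint precision supports.** Each of the four states is defined by
  a sparse precision graph (chain, skip and cross-network edges) whose
  edge sets barely overlap across states. States therefore differ in the
  *direction* of their connectivity patterns, not merely in amplitude —
  important because windowed estimates are noisy and amplitude-only
  differences wash out under the graphical lasso.
* **Long dwell times.** Stay probabilities are high (about 0.98–0.995)
  so that typical dwells are comparable to the window width. Sliding
  windows that straddle a transition produce blended connectivity
  vectors; essentially all label-recovery error comes from such windows,
  so dwell length is the signal-to-noise lever.
* **Start-state rotation.** Subjects' initial states rotate
  deterministically through 1..k within each group, which removes the
  large occupancy sampling variance that one-state-dominated scans
  otherwise produce in small cohorts. Group differences come only from
  the asymmetric transition matrices.
* **Clinical coupling.** Covariates (MoCA, SDS, SAS) are linear in a
  subject's occupancy statistics plus Gaussian residuals, so correlation
  and mediation layers have a planted, recoverable effect.

Ground truth (per-timepoint state labels) is carried in the cohort
bundle; window-level truth for recovery scoring uses the majority label
within each window (`majorityWindowLabels()`).

Note that the default post-processing chain is designed for real
component time courses; on synthetic data the 0.15 Hz low-pass at TR 2 s
removes within-window degrees of freedom and *hurts* recovery, so the
recovery benchmarks run `simulateCohort() -> cohortDFNC()` directly.

## Statistics

`twoSampleT()` accepts either raw vectors or printed summary statistics
`(n, mean, sd)`; the pooled variant reproduces published t and df values
exactly from a paper's tables. Levene/Brown–Forsythe checks
(`leveneEqualVariance()`) support the choice between pooled and Welch
variants. All family-wise corrections use Benjamini–Hochberg
(`fdrBH()`); the nine temporal-metric group tests form one family, and
each temporal variable's correlations with clinical covariates form one
family per variable.

`bootstrapMediation()` implements product-of-coefficients mediation with
a BCa bootstrap: bias correction from the fraction of resampled indirect
effects below the point estimate, acceleration from the jackknife
skewness. Resamples that lose one exposure group are redrawn and counted
(`nDegenerate`).

## Classification

Features are regression coefficients of each window's (centered) FNC
vector on the group-by-state centroid design — 2 groups x 4 states = 8
betas per window, averaged into 8 features per subject. A linear SVM is
evaluated by repeated stratified cross-validation with pooled decision
scores for the ROC/AUC.

Because the centroid design itself uses group labels, building it from
all subjects leaks information into held-out folds. The default
`fold_safe` mode rebuilds the design from each fold's training subjects
only; `paper_faithful` reproduces the one-design-for-everyone variant for
comparison. Expect `paper_faithful` to report optimistically higher
accuracy.

## Reproducibility and limitations

Every stochastic entry point takes an explicit seed; subject-level
streams are derived from the spec seed by a fixed affine fan-out, so
cohorts regenerate bit-identically. `runPipeline()` writes all
intermediate artifacts as TSV with JSON sidecars plus a manifest of MD5
hashes.

Limitations: the generator's states are stationary within dwell periods
(no within-state drift); clinical covariates are linear in occupancy
with Gaussian noise; the SVM feature set is deliberately the 8-beta
design rather than the full 253-pair vector; and silhouette values on
real-scale exemplar sets are small in absolute terms (within-cluster
spread dominates separation), so the *argmax* over k, not the magnitude,
is the meaningful quantity.
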