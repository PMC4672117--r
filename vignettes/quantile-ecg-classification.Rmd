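---
title: "Quantile-based ECG disease classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-based ECG disease classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgquantile)
```

## The problem and the modelling idea

Given delineated single-lead ECG records — per-beat fiducial points
(onset, peak, offset of the P wave, QRS complex and T wave) plus a
6-category T-wave morphology type — the package classifies subjects as
healthy or diseased and ranks candidate biomarkers. The central modelling
idea is distributional: a diseased heart produces *mostly normal beats
with a minority of abnormal ones*, so the per-beat distributions of
interval, amplitude and slope measurements in diseased subjects are
skewed, heavy-tailed or multimodal, while healthy subjects' distributions
are unimodal and light-tailed. Summarizing each subject by the *mean* of
each measurement discards exactly the information that separates the
groups; summarizing by *tail quantiles* retains it. Each of 18 beat-level
variables (6 time spans, 3 amplitudes, 9 segment slopes) is therefore
reduced to eight sample quantiles — p1, p5, p10, p25, p75, p90, p95,
p99 — giving 144 features per subject, plus the six T-type proportions.

## Pipeline stages

**Measurement.** `measure_beat()` computes, per beat: the six spans
(RR to the next R peak; PR = P onset to QRS onset; QT = QRS onset to T
offset; and the P/QRS/T widths); the isoelectric baseline as the pooled
mean of all samples in the PR, ST and TP segments (the literal "mean of
the values", not a mean of segment means — with fewer segments available
the mean is over those remaining); signed amplitudes as the
larger-magnitude of (max − baseline) and (min − baseline) over each wave
window, ties resolved to the positive deviation, with the R amplitude
window taken as the full QRS so deep negative complexes are captured; and
nine OLS slopes (mV/s, regressed on time in seconds so the unit is
independent of sampling rate) over the Up-P, Down-P, PR, Up-R, Down-R,
ST, Up-T, Down-T and TP segments. A missing wave makes only the
measurements that need it absent; a beat is never dropped wholesale at
this stage.

**RR correction.** Time spans lengthen with the beat period, so each is
modelled on healthy beats as `y = beta * RR^alpha + error`, `alpha`
selected on the grid 0, 0.1, ..., 1 by R-square, and corrected as
`y / RR^alpha` — Bazett's QTc being the `alpha = 0.5` case. `beta` is fit
through the origin (the model has no intercept), but R-square is computed
about the mean of `y` so that fits are comparable across exponents;
no-intercept R-square conventions vary, and the origin-convention would
make `alpha = 0` incomparable with the rest of the grid. Ties break to
the smaller exponent (parsimony). By default the pipeline applies the
reference exponents `default_corrections()` (QT 0.5, PR 0.2, P span 0.1,
T span 0.5, QRS span unadjusted — its RR correlation is negligible);
refitting on the data at hand is available via `fit_corrections()`.

**Quantile features.** `sample_quantile()` uses linear interpolation of
order statistics (position `h = (n-1)p/100 + 1` on the sorted sample, the
common "type 7" convention); the choice is fixed for reproducibility
since quantile definitions differ across software. Beats are pooled over
a subject's records; each variable uses its own non-missing beats.
Subjects with fewer than `min_beats = 30` usable beats are flagged and
excluded — below that, tail quantiles like p99 are order statistics of
the extreme one or two beats and essentially noise. The T-wave type is
summarized as six proportions (usable by every classifier) plus the modal
category (reported in the discriminant summaries).

**PCA.** Features are standardized to unit variance before the
decomposition — spans (s), amplitudes (mV) and slopes (mV/s) are not
commensurable, so covariance-scale PCA would be dominated by the
large-variance slope features. Eight components are kept by default, a
compact set for the strongly correlated quantile blocks; a
cumulative-variance rule is available. Loading columns are sign-fixed
(largest-magnitude entry positive) and top-loading ties break by feature
name, so reports are deterministic across linear-algebra backends.
T-type proportions bypass the PCA and rejoin the classifier input.

**Classification.** The discriminant classifier assigns a subject to the
class minimizing the generalized squared distance
`D^2 = (x - m_t)' S_t^{-1} (x - m_t) + g1(t)`: squared Mahalanobis
distance plus `g1(t) = ln|S_t|` when class covariances are held unequal,
and `g1 = 0` with the pooled covariance otherwise. Equal priors are
assumed throughout, so no prior-based offset enters. The pooled/per-class
decision is made by Box's M test (chi-square approximation) at threshold
0.10; the threshold, like the stepwise levels, is configurable. Variable
selection is forward-with-backward stepping on the partial F statistic
derived from Wilks' lambda, with `slentry = slstay = 0.15` (the common
stepwise-discriminant default; the levels are screening thresholds, not
inference). Near-singular class covariances receive a relative ridge of
`1e-8 * trace/dim`. The SVM (radial kernel, libsvm via **e1071**,
hyperparameters by seeded 5-fold cross-validation over a small
cost/gamma grid) and L1-penalized logistic regression (**glmnet**,
penalty at the cross-validated deviance minimum) serve as baselines;
both are established implementations wrapped behind a fixed-seed
interface, since neither method is this package's contribution.

Train/test splitting is stratified by class at 50/50 by default,
mirroring a near-equal-halves study design; missing feature entries are
imputed with *training-set* column medians, and PCA centers/scales are
likewise fit on training rows only and frozen for test rows.

## The synthetic-data generator

`simulate_beat_table()` generates cohorts with known ground truth. Per
beat: RR is truncated normal (lower bound 0.3 s — shorter beat periods
are not physiologically meaningful); each time span follows
`beta * RR^alpha * exp(eps)` with `eps ~ N(0, noise_cv)`. The
multiplicative lognormal noise is a deliberate divergence from an
additive error term: it keeps spans positive and matches the ratio form
of the RR corrections. Amplitudes are lognormal around group means;
slopes are Gaussian with an additive noise floor of 1 mV/s so that
zero-mean segments (PR, TP) still vary. Disease is an abnormal mixture
component: each abnormal beat (probability = the subject's abnormal
fraction) receives location shifts on the affected variables and a
four-fold noise-variance inflation — the simplest mechanism that
produces heavy tails and visible mixtures in beat distributions.

Two layers of between-subject heterogeneity make the cohorts behave like
a study population rather than replicates of one patient: a per-subject
lognormal scale factor (`subject_cv = 0.08`, i.e. roughly a 30 ms
between-subject spread on a 400 ms QT) on span scales and amplitude
means, and — for the disease group — a per-subject abnormal fraction
drawn from a Beta distribution with mean `abnormal_fraction = 0.15` and
concentration `abnormal_dispersion = 4`, so some diseased subjects
express almost no abnormal beats. The default disease component shifts
are diffuse and moderate (16 variables: prolonged QT/PR/T span, reduced
P/R/T amplitudes, T- and R-slopes pulled toward zero or reversed),
reflecting that real disease signal spreads over many correlated
measurements rather than concentrating in one dominant marker. The
default cohort is 52 healthy and 194 diseased subjects with 200 beats
each, the scale of a two-arm clinical ECG study split into near-equal
train/test halves.

What the generator does *not* emulate: realistic ECG morphology (the
waveform path `simulate_waveform()` is piecewise-linear by construction,
a measurement fixture, not a physiological model), delineation error
(fiducials are exact), non-stationarity within a record, and
disease-specific morphology classes. Passing tests on synthetic cohorts
therefore demonstrate the statistical machinery — not performance on any
clinical database, which additionally depends on delineator quality and
true disease composition.

## Numerical choices and degenerate inputs

- Fiducial monotonicity is enforced when annotations are parsed; a
  non-monotone beat goes to a rejects list with a reason and never
  reaches measurement.
- Constant spans make the power-law fit degenerate (zero total sum of
  squares); this raises an error directing the caller to `alpha = 0`
  rather than silently returning an arbitrary grid point.
- Amplitude ties (`|max - b| = |min - b|`) return the positive deviation.
- Exactly collinear candidates have partial F of 0 and never enter the
  stepwise selection; a cycle guard caps the entry/removal loop.
- If no variable meets the entry criterion, `train_sda()` falls back to
  the full feature set with a warning rather than fitting on nothing.
- Zero-variance features are dropped (with a warning) before PCA scaling.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make its statistical
claims measurable while keeping a full run around a minute: oracle
comparisons use tens of random instances; Monte-Carlo recovery checks use
100 replications (exponent-grid recovery at 500 beats, planted-feature
stepwise recovery at 100 subjects per class) and 200 replications for the
Box's M type-I-error band; the feature-set/PCA ordering experiment runs
the full four-arm design on 25 cohorts at the generator's default study
scale. At that scale the synthetic problem is somewhat easier than a real
clinical one (mean discriminant accuracies sit in the high 90s), so the
ordering margins — quantile over mean, PCA over no-PCA — are small though
consistently positive; at reduced cohort sizes the quantile margin widens
to several accuracy points while the PCA margin becomes size-dependent.

## Known limitations

- The annotation reader consumes rdann-style *text* dumps (ECGPUWAVE
  conventions); binary MIT-format annotation files must be converted
  with `rdann` first. The signal reader supports WFDB format 16 only.
- Lead naming is left to configuration: clinical databases disagree on
  lead labels, so the reader errors with the list of available leads
  rather than guessing.
- The stepwise partial-F levels are screening devices; selected-variable
  lists from small cohorts are unstable, which is precisely why the
  PCA-based biomarker report cross-references them.
- With per-class covariances and few subjects per class, `ln|S_t|` is
  estimated poorly; the homogeneity test's 0.10 threshold errs toward
  the pooled model for that reason.

## A worked example

```{r example, eval = FALSE}
co <- simulate_beat_table(healthy_spec(n_subjects = 20),
                          disease_spec(n_subjects = 40), seed = 1)
report <- classify_cohort(co, feature_stat = "quantile", use_pca = TRUE,
                          method = "sda", seed = 1)
report
top_loadings(report$pca, k_vars = 5)$PC1
```
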