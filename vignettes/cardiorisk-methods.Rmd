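---
title: "Methods: from single-lead ECG to stacked risk-zone prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-lead ECG to stacked risk-zone prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiorisk)
```

`cardiorisk` implements the computational core of a wearable-style
cardiovascular screening pipeline: it turns a raw single-lead ECG trace and
a 12-attribute clinical record (the processed UCI heart-disease schema,
minus the two attributes that require in-hospital tests) into a risk-zone
prediction — green/red under the two-level scheme, green/yellow/red under
the three-level scheme. This vignette explains each stage, its assumptions,
the tunable parameters, and the design decisions taken where the published
description of such systems leaves the choice open.

## 1. QRS detection: the Pan-Tompkins chain

R-peaks are the per-beat fiducial points everything downstream hangs on.
Detection follows the classic Pan-Tompkins recipe — a cascade of
integer-coefficient filters followed by a nonlinearity and an energy
integrator:

1. **Low-pass** (cutoff ≈ 11 Hz at the 200 Hz design rate):
   $y(n) = 2y(n-1) - y(n-2) + x(n) - 2x(n-6) + x(n-12)$,
   i.e. $H(z) = (1-z^{-6})^2/(1-z^{-1})^2$. DC gain 36, group delay 5
   samples.
2. **High-pass** (cutoff ≈ 5 Hz):
   $y(n) = y(n-1) - x(n)/32 + x(n-16) - x(n-17) + x(n-32)/32$.
   Zero DC gain, group delay 16 samples.
3. **Five-point derivative**:
   $y(n) = \tfrac18\,(2x(n) + x(n-1) - x(n-3) - 2x(n-4))$, group delay 2.
4. **Squaring**, emphasizing large slopes and rectifying the signal.
5. **Moving-window integration** over 150 ms — a causal average of
   $W = \lfloor 0.150\,f_s + 0.5\rfloor$ samples (53 at 350 Hz) that
   consolidates QRS energy into one lobe per beat.

All linear stages are causal with **zero initial state**: history terms
before the start of the record are taken as 0. This makes the transform a
pure function of the input vector; the price is a start-up transient of
roughly one filter memory, which all steady-state reasoning (and testing)
excludes.

Two coefficient conventions for stages 2–3 circulate in the applied
literature; they differ in the sign pattern of three taps. The package
defaults to the canonical set above and exposes `coeffs = "paper"` for the
sign-variant transcription, because recordings processed under either
convention should be reproducible. The variant derivative's taps sum to
1/4 rather than 0, so it passes DC — a measurable difference the test
suite pins down rather than hides.

The filters are applied at the **native sampling rate** (the device this
pipeline models samples at 350 Hz). No resampling to the 200 Hz design
rate is performed; a message notes the shifted passband whenever
`fs != 200`. Resampling first would be defensible, but it would change
every delay constant and sample-count convention downstream, and the
sample-count conventions (20/42 samples at 350 Hz) are part of the
contract.

**Thresholding.** The integrated envelope is scanned for local maxima
above an adaptive two-level threshold $T = N + 0.25\,(S - N)$, where the
signal level $S$ starts as the envelope maximum over the first 2 s, the
noise level $N$ as its mean over the same span, and both are updated with
the usual 1/8 running rule as candidates are accepted or rejected.
Candidates closer than the 200 ms refractory interval compete: the larger
survives. Each surviving candidate is then mapped back to the raw-signal
maximum inside `[c - D - 60 ms, c]`, where `D = 5 + 16 + 2 + (W-1)/2`
samples is the cumulative group delay of the linear stages. Signals
shorter than the 2 s initialization span are rejected; a flat record
yields an empty peak set, which is a result, not an error.

## 2. ST-segment slope

The ST segment — between the QRS end and the T wave — is cut as a fixed
window after each R-peak: 57.14 ms offset, 120 ms length by default, which
at 350 Hz is exactly **20 samples after the R-peak, 42 samples long**. The
defaults are expressed in milliseconds so other sampling rates remain
meaningful; the half-up rounding rule `round(ms * fs / 1000)` is the same
everywhere a duration becomes a sample count.

For a window of $N$ samples with first amplitude $Y$ and last amplitude
$X$, the slope is

$$\tan\theta = \frac{X - Y}{N}$$

in amplitude units per sample. The denominator is $N$, not $N-1$, matching
the printed convention this pipeline reproduces; on a perfect ramp of
per-sample increment $k$ the statistic therefore reads $k\,(N-1)/N$
(a 2.4 % negative bias at $N = 42$), which is inside every tolerance used
here. The slope is invariant to constant offsets, so no isoelectric-line
correction is attempted (clinical-grade ST deviation in mV is out of
scope). Per-session aggregation over beats is the mean by default (median
by flag); peaks whose window would run past the end of the record are
skipped and counted.

The continuous slope feeds the dataset's ordinal `slope` attribute
(1 = upsloping, 2 = flat, 3 = downsloping) through a symmetric dead band
of ±0.002 amplitude-units/sample on normalized signals. No published
mapping exists for this conversion; the dead band is a declared default,
configurable, chosen so that the generator's zero-slope beats fall in the
flat band and slopes an order of magnitude above the measurement error do
not.

Two attributes are derived rather than measured. `oldpeak` (exercise ST
depression, 0–6.2) is predicted by a support-vector regression on the
table columns whose absolute Pearson correlation with oldpeak reaches 0.2
(the screening threshold is a config knob; no published cutoff exists),
with predictions clipped to the attribute's observed domain. `restecg`
(0/1/2) comes from a support-vector classifier after the same screening.
`thalach` is operationalized exactly as the device protocol states: the
maximum of a burst of exactly 20 consecutive pulse readings, with a
30–250 bpm plausibility band (clamp-with-warning, or reject under
`strict = TRUE`).

## 3. Table preprocessing

The 14-column UCI dialect is read with `"?"` as the missing-value marker;
`ca` and `thal` are dropped (they require fluoroscopy and a thallium
stress test, which a home device cannot supply). Severity `num` 0–4 maps
to zones: 0 → green, 1 → yellow, 2–4 → red (three-level); 0 → green,
1–4 → red (two-level).

- **Imputation** is by chained equations: initialize missing entries from
  the column mean (mode for categoricals), then iterate per-column linear
  regressions on the observed rows, re-predicting the missing entries
  until the largest change drops below `tol = 1e-3` or 10 cycles pass.
  One completed dataset is produced (`m = 1`); categorical imputations
  are rounded and clamped to their domains, so an imputed `restecg` is
  always 0, 1 or 2. The regression-mean flavour is deterministic — a
  deliberate choice favouring reproducibility over between-imputation
  variance estimation, which nothing downstream consumes.
- **Robust scaling** maps each continuous column through
  $(x - \mathrm{median})/\mathrm{IQR}$; after scaling the column median is
  exactly 0 and the IQR exactly 1. A zero-IQR column is centered only,
  with a warning. The fitted centers/scales are kept so fresh records go
  through the identical affine map. Worth stating precisely: median/IQR
  scaling does *not* shrink outliers' standardized magnitude relative to
  mean/SD scaling — the opposite; what it protects is the scale of the
  bulk, which outliers would otherwise deflate.
- **Encoding** maps each categorical domain onto `0..K-1` in domain order
  (`cp` 1–4 → 0–3, `slope` 1–3 → 0–2); the dictionary is fixed by the
  schema, not learned, and invertible.
- **Oversampling** duplicates minority-class records uniformly with
  replacement up to the majority count. The default recipe order
  oversamples *before* the 70/30 split, reproducing the protocol this
  package mirrors — which leaks duplicated records across the partition
  boundary. The package emits a prominent warning and offers
  `split_first = TRUE` (split, then oversample the training part only);
  every internal evaluation in the tests uses the leakage-free order.
- **Split**: `round(0.7 n)` training records, stratified by zone when
  requested (per-class proportions preserved to within one record).

## 4. Stacking ensembles

Ten base-learner families are available: KNN, naive Bayes, random forest,
RBF-kernel SVM, gradient boosting, an SGD-trained linear (multinomial
logistic) model, XGBoost, a single-hidden-layer MLP, a CART decision tree,
and AdaBoost (SAMME over depth-2 trees). Each is tuned by exhaustive
search over a small declared grid, scored by macro-F1 under stratified
k-fold cross-validation; the searched points and scores are kept in the
tuning trace so a run is reproducible from its manifest.

The stack itself is built the standard leakage-free way, which the source
protocol leaves unspecified: each base learner contributes its
**out-of-fold class probabilities** (5-fold, stratified) as meta-features;
a logistic-regression meta-classifier (multinomial, small L2 stabilizer)
is fit on those; the base learners are then refit on the full training
table for prediction time. Probability argmax decides the zone, lowest
class index winning exact ties. Default base sets are the winning
combinations of the exhaustive search: KNN + XGB + MLP (two-zone) and
SVM + KNN + XGB (three-zone).

`enumerate_stack_combinations()` reproduces that search: all
$\binom53 + \binom54 + \binom55 = 16$ subsets of five candidates, each
evaluated on the held-out table and ranked by macro-F1. Per-learner
out-of-fold and test probabilities are computed once and shared across
subsets, so only the meta-classifier is refit 16 times.

**Metrics.** Evaluation reports the confusion matrix (rows = truth),
accuracy = trace/total, and per-class precision/recall/F1 with unweighted
(macro) means. Zero-denominator cases are defined as 0 with a warning.
ROC-AUC is one-vs-rest per class via the Mann-Whitney rank statistic with
half credit for ties; a class absent from the truth has no defined AUC and
is reported `NA`. The macro convention is validated by reproducing, to
printed precision, the derived statistics of the published field-evaluation
confusion matrices (two-level: accuracy 90 %, precision 90.7 %, recall
88.5 %, F1 89.3 %; three-level: accuracy 87.5 %, precision 87.2 %). The
three-level recall and F1 printed alongside those matrices do not follow
from them under macro, micro or support-weighted averaging; the package
does not assert them.

## 5. Synthetic generators

Both generators are pure functions of their parameter tuples, seed
included.

`simulate_ecg()` sums five Gaussian bumps per beat at fixed fractions of
the RR interval (P −0.20, Q −0.025, R 0, S +0.03, T +0.32; widths 0.02,
0.008, 0.01, 0.008, 0.04 RR; amplitudes 0.15, −0.12, 1, −0.2, 0.3 of the R
bump) and overlays a linear ramp of known slope across the 57–177 ms
post-R window. The T bump is deliberately placed late and narrow so the ST
window is uncontaminated at resting heart rates — at 120 bpm and above the
T wave would intrude, so slope-recovery fixtures run at 60–70 bpm. What
the generator does **not** emulate: baseline wander, electrode motion,
mains interference, arrhythmia, beat-to-beat morphology variation. Passing
detection tests here therefore demonstrates the algorithm's correctness,
not field robustness on ambulatory recordings.

`simulate_cohort()` draws zone labels from configurable proportions
(default 413/258/249 over 920, the three-zone composition of the combined
four-hospital dataset; the two-zone default is 413/507 — the printed
two-zone tally of 413/509 sums to 922, not 920, so the num-derived count
is used), then continuous attributes from class-conditional normals with
adjacent class means `effect_size` pooled SDs apart (thalach decreasing
with risk), clamped to the documented attribute ranges, and categorical
attributes from class-tilted multinomials. Missingness masks exactly
`round(rate * 12 n)` cells, MCAR by default, age-rank-weighted under
`mechanism = "mar"`. The default `effect_size = 1` is a realistic
epidemiological separation; property tests that require near-perfect
classification state their stronger separation (3 SD, or 6 SD where
effective linear separability is the premise) explicitly. Real
heart-disease data has correlated features, site effects and label noise
that this generator does not model — which is precisely why the published
test-set F1 scores (91 % two-zone, 80.4 % three-zone), dependent on
unpublished grids, seeds and oversampling draws, are not asserted
anywhere; the suite checks structural properties instead.

## 6. Problem sizes and numerical conventions

The test and acceptance runs use: 500-sample random vectors against the
brute-force convolution oracle (tolerance 1e−8); 10–50 s fixtures at
350 Hz (10–55 beats) for detection; cohorts of 200–400 records (70/30
split) for the ensemble properties; 300 records with 10 % masking for
imputation recovery. These sizes were chosen as the smallest at which the
asserted properties are stable across seeds.

Conventions worth knowing when extending the package:

- Sample indices in all outputs are **0-based** (time = index/fs);
  R-internal vectors are 1-based, and the boundary is crossed only in
  `extract_st_segments()` and the generators.
- Duration-to-samples conversion is half-up rounding everywhere.
- Argmax tie-breaks select the lowest class index, deterministically.
- `set.seed()` is called inside every stochastic fitting routine with the
  caller's seed, so end-to-end runs are bit-reproducible.
- Probabilities are clipped at 0 and renormalized to sum to 1 after every
  base learner, guarding against the small negative residues some
  back-ends emit.

## 7. Known limitations

Single-lead, resting-rate ECG only; no T/P delineation, no arrhythmia
handling. The oldpeak/restecg derivations assume the correlation structure
of the training table transfers to the device population. The paper-order
preprocessing (oversample before split) is reproduced for fidelity but is
statistically unsound; all conclusions drawn inside this package use the
leakage-free order. AUC for a class with no positive examples is
undefined by construction and reported as `NA` rather than imputed.
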