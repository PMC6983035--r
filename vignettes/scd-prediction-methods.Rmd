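---
title: "Predicting sudden cardiac death from raw ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sudden cardiac death from raw ECG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sudden cardiac death (SCD) — most often precipitated by ventricular
fibrillation — kills within minutes of symptom onset, so the clinically
useful question is not *detection* but *prediction*: can a monitoring
system flag an elevated risk tens of minutes before the fatal arrhythmia
begins? `scdemd` implements a prediction pipeline that works directly on
the raw single-lead ECG, without QRS detection or heart-rate-variability
preprocessing:

1. the ECG is resampled to a common 128 Hz rate and cut into one-minute
   windows — for SCD-class recordings, the 25 minutes immediately before
   the annotated onset; for normal-sinus-rhythm recordings, one randomly
   chosen minute;
2. each window is decomposed by **empirical mode decomposition (EMD)**
   into intrinsic mode functions (IMFs), an adaptive expansion into
   oscillatory modes ordered from fast to slow;
3. five nonlinear indices — Katz fractal dimension (KI), Higuchi fractal
   dimension (HI), box dimension (BDI), Shannon entropy (SEI) and
   permutation entropy (PEI) — are evaluated on the first six IMFs,
   giving 30 features per window;
4. one-way ANOVA screens the 30 features for between-group
   discriminability; the top pair (on real Holter data, HI of IMF 3 and
   PEI of IMF 5) feeds
5. a single-hidden-layer perceptron trained with a Levenberg–Marquardt
   optimizer on bounding-box-augmented training features, evaluated
   per pre-onset minute on held-out patients.

The package also ships a seeded synthetic ECG generator so the entire
pipeline is exercisable and testable without access to clinical data.

## Empirical mode decomposition

Sifting extracts one IMF at a time: locate all strict local extrema,
interpolate maxima and minima separately with cubic splines, subtract the
envelope mean, and repeat on the result until the candidate satisfies the
two IMF conditions (extrema and zero-crossing counts differ by at most
one; envelope mean locally zero). The extracted mode is removed and the
procedure recurses on the residue until it becomes monotonic or the
configured mode budget (`max_imfs`, default 6) is exhausted. The
decomposition is complete by construction: modes plus residue reconstruct
the input to floating-point accuracy, which the test suite asserts at
`1e-8` relative L2 on batches of random signals.

Several sifting details are genuinely open choices, fixed as follows:

* **Stop criterion.** Huang's standard normalized squared difference
  `SD = sum((h_prev - h)^2)/sum(h_prev^2) < 0.2` between successive sift
  candidates, combined with the countable IMF condition, capped at 100
  iterations per mode. The SD threshold and cap are exposed in
  `emd_config()`.
* **Boundary handling.** Two extrema are mirror-reflected about each end
  before spline fitting. Without extension, the envelopes collapse toward
  the end samples and the resulting end swings leak into the fractal
  indices of every mode.
* **Spline variant.** Natural cubic splines through the extended extrema.
* **Plateaus and ties.** A run of equal samples flanked by lower (higher)
  neighbours counts as a single maximum (minimum) at its midpoint,
  left-of-centre for even runs; zero crossings are strict sign changes
  with exact zeros counted once. These rules make the IMF-condition check
  deterministic.

## The five indices

All five indices are dimensionless complexity measures; smooth,
predictable waveforms score low, noise-like waveforms score high.

* **Shannon entropy (SEI).** The window is quantised onto `2^b` uniform
  levels spanning its own min–max range (`b = 12` by default, matching a
  12-bit ADC) and the entropy of the level frequencies is reported in
  bits, so the value lies in `[0, b]`. Anchoring the grid to the window
  range makes the index invariant under amplitude offset and gain.
* **Permutation entropy (PEI).** The normalized entropy of ordinal
  patterns of order `m` at lag `tau` (defaults 3 and 1; ties broken
  earlier-index-first), in `[0, 1]`. Order 3 keeps the pattern count
  (`6`) far below the ~7700 patterns available in a one-minute window,
  so estimates are well converged.
* **Katz dimension (KI).** `log10(L/a)/log10(d/a)` with `L` the summed
  absolute successive differences, `a` the mean step and `d` the maximum
  excursion from the first sample; exactly 1 for a monotone ramp.
* **Higuchi dimension (HI).** For scales `p = 1..Q_max` (default 64,
  about K/120 for 7680-sample windows) the window is decimated into `p`
  offset subsequences whose normalized curve lengths are pooled into a
  mean curve length `L(p) ~ p^-D`; `D` is the negated slope of the
  ordinary least-squares fit of `ln L(p)` on `ln p`. The pooling uses the
  standard mean over offsets (the pooled sum divided by `p^2` given the
  normalization of the per-offset lengths), which is the only reading
  under which the estimator reproduces its calibration values — white
  noise near 2, Brownian motion near `2 - H = 1.5`, smooth curves near 1
  — all asserted in the tests.
* **Box dimension (BDI).** The one-shot `-ln(L/dt)/ln(dt)` with `dt` the
  sampling interval in seconds (default 1/128; `dt = 1` is rejected since
  the denominator vanishes).

Each index is cross-checked against a deliberately naive
re-implementation (separate code path, loops and `lm()` fits) to `1e-10`
on batches of random signals.

## Feature screening

For every `(index, IMF)` pair the package runs a classical equal-variance
one-way ANOVA of normal versus pre-SCD values and ranks features by
ascending p-value. Two scopes are available: `per_minute` (each pre-onset
minute against the normal group, mirroring how per-minute summary tables
are reported) and `pooled` (all SCD minutes together), the default from
which the top-`k` pair is selected. No multiple-testing correction is
applied to the screening by default — the ranking, not the inference, is
what is consumed — but Benjamini–Hochberg adjustment is available via
`fdr = TRUE`. Undefined index values (degenerate windows) are excluded
pairwise and never imputed; with two groups `F` equals the squared
pooled-variance t statistic, which the tests assert to `1e-9`.

## Classifier

The perceptron has one hidden layer (default 10 units) and a single
logistic output; normal is coded 0 and pre-SCD 1, with the decision
threshold at 0.5, inclusive on the SCD side. Inputs are z-scored by
training-set statistics stored inside the model. Training minimizes the
sum-of-squares output error with a Levenberg–Marquardt optimizer written
for this purpose: analytic reverse-accumulation Jacobian, identity
damping `lambda` (initial `1e-3`) divided by 10 on accepted steps and
multiplied by 10 on rejections, so the huge-damping limit is small-step
gradient descent — a property the tests exercise directly, along with
one-iteration convergence on linear least-squares problems. Initial
weights are seeded uniform on `[-0.5, 0.5]`.

The training protocol follows the patient-level design: per class,
`round(0.45 * n)` subjects are drawn for training (8 of 18 at the default
cohort size) and the rest are held out. From the training windows' feature
values, a per-class, per-dimension `[min, max]` bounding box is formed and
400 synthetic points per class are drawn uniformly within it; when
augmentation is enabled the network trains on these points alone, which
matches a protocol of training on values generated "within the limits" of
the observed training features. Evaluation always uses the raw, never
augmented, held-out features — augmenting the test set would leak the
training boxes. Accuracy is reported per pre-onset minute, each minute's
test set being that minute's SCD windows plus all normal-group windows,
and summarized as the mean across the 25 minutes. Whether the original
protocol mixed normal windows into each per-minute test unit is not fully
specified; this definition is the package's own and is stated here rather
than asserted as anyone else's.

## Synthetic data: what it emulates, and what it does not

`synthesize_ecg()` builds 128 Hz single-lead ECG as a PQRST template (five
Gaussians on the beat-phase axis) evaluated over a seeded beat train whose
RR intervals are Gaussian (defaults: 70 bpm mean for normal, 90 for
pre-SCD, 3 bpm spread) truncated to [0.3 s, 2 s]. A non-cardiac component
of amplitude `noise_mv` (default 0.08 mV) mixes:

* band-limited broadband noise, weighted `complexity^2`, and
* slowly phase-drifting oscillations near 8.5 Hz and 2.2 Hz, weighted
  `1 - complexity`, placed to dominate IMF 3 and IMF 5 of a one-minute
  window.

`complexity` (normal default 0.65, pre-SCD 0.35) is therefore a
regularity knob: lowering it makes the mid- and low-frequency modes
tone-dominated, which lowers HI(IMF3) and PEI(IMF5) — the direction the
clinical group comparison reports for pre-SCD recordings. The quadratic
broadband weight is deliberate: the fractal indices saturate quickly with
even small amounts of broadband contamination, so a linear weight leaves
the knob nearly inert at moderate gaps. For SCD-class records the
signature mixing is applied from 26 minutes before onset; earlier samples
carry the normal-class mixing.

The generator is a test fixture targeting the *measured direction* of the
group differences, not a cardiac electrophysiology model: it contains no
ectopy, no ST-segment pathology, no real ventricular-fibrillation
morphology, no electrode artifacts, and its class signature is injected
rather than emergent. Passing the end-to-end tests therefore demonstrates
that the pipeline recovers a separation of the constructed kind and
magnitude — it says nothing further about clinical recordings, which is
why the group-direction benchmark against annotated Holter data remains a
separate, data-dependent check (`benchmark_cohort()`).

## Problem sizes and numerical choices

* The end-to-end study conditions are 18 normal + 18 pre-SCD subjects, 25
  pre-onset minutes each (468 one-minute windows), a 45/55 patient split,
  400 augmented points per class, and five independent split/training
  seeds; the acceptance script (`scripts/acceptance.R`) recomputes the
  whole chain at exactly these sizes.
* Unit tests use scaled-down cohorts (3–5 subjects, 3 minutes) for
  structural checks and 30 windows per group for the generator's
  separation contract; index calibration uses 4096-sample signals.
* Resampling uses an upfirdn-style polyphase chain (zero-stuffing by `L`,
  Kaiser-window linear-phase FIR at 0.9 of the narrower Nyquist with
  exact group-delay compensation, decimation by `M`), accurate to about
  `1e-4` on band-limited tones and energy-preserving to 0.1%.
* Degenerate inputs fail loudly with classed conditions
  (`scdemd_undefined_index`, `scdemd_config_error`, ...): constant
  signals have no Katz or box dimension, `dt = 1` has no box dimension,
  identical groups have no ANOVA, monotonic signals have no IMFs.
  Undefined feature values are carried as `NA` and excluded pairwise.
* All randomness (beat trains, noise, window placement, splits,
  augmentation, weight initialisation) flows from explicit integer seeds
  through an RNG-state-preserving scope, so every artifact is
  reproducible bit-for-bit from a master seed.

## Known limitations

* EMD has no uniqueness theory; different boundary rules or stop
  criteria shift index values slightly, so absolute index values are
  comparable only within a fixed configuration. Between-group contrasts
  are much more stable, which is what the pipeline consumes.
* The WFDB reader/writer covers the single-lead subset used here
  (formats 16 and 212, one signal per record) and is not a general WFDB
  implementation.
* Per-minute accuracies on a 20-window test set are quantized to 5%;
  small cohorts make the reported accuracy a coarse statistic.
* The MLP is intentionally small and the optimizer batch-mode; the
  pipeline targets one-minute windows, not streaming operation.
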