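---
title: "Monitoring solid-state fermentation by e-nose/NIRS fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring solid-state fermentation by e-nose/NIRS fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The monitoring problem

Solid-state fermentation (SSF) of protein feed progresses through lag,
exponential and stationary phases over roughly a week. Process control needs
to know *which day of fermentation* a sample corresponds to, quickly and
non-invasively. Two complementary instruments can fingerprint a sample: an
electronic nose — an array of eleven cross-sensitive gas sensors whose joint
response reflects the volatile organic compounds in the headspace — and a
near-infrared reflectance (NIR) spectrometer, whose log(1/R) absorbance over
10,000–4,000 cm⁻¹ reflects the substrate's C–H/O–H/N–H chemistry. Each
modality sees only part of the process, so **fermfuse** implements
feature-level (intermediate-level) fusion: features are extracted per
modality, concatenated, de-redundified by independent component analysis
(ICA), and classified by an AdaBoost ensemble of small backpropagation (BP)
networks into one of the seven day classes 0–6.

## Pipeline

1. **Characteristic values.** Each NIR spectrum is transformed by the
   standard normal variate (SNV): per spectrum, subtract the mean and divide
   by the standard deviation (n−1 denominator, the chemometrics convention;
   a config flag switches to n). SNV removes additive offsets and
   multiplicative scatter exactly: `snv(a·x + b) = snv(x)` for `a > 0`. Each
   e-nose recording is reduced to the **maximum response of each sensor**
   over the 120 s sampling window, an 11-vector.
2. **Column standardization**, fitted on training rows only and applied to
   held-out rows with the training statistics. Whether scaling statistics
   should come from all samples or from the training set alone is a free
   choice; training-only is the default because it cannot leak validation
   information (a full-data
   "exploratory" use is available simply by passing all rows).
3. **PCA per modality** (`fit_pca`, `project_pca`): mean-centered principal
   components, ordered by explained variance, signs fixed so the
   largest-magnitude loading element is positive (so refits are
   reproducible). The number of PCs per modality is selected by
   leave-one-out cross-validation (below).
4. **Fusion by ICA** (`concat_features`, `fit_ica`, `transform_ica`): the
   selected PC scores of both modalities are concatenated (e-nose first) and
   unmixed by a fixed-point ICA (logcosh contrast, symmetric decorrelation)
   under the model `x = A s`, `y = Wᵀ x`. Components are ordered by a
   negentropy proxy and sign-fixed like the PCA loadings; with a fixed seed
   the fit is deterministic. The IC count is selected by the same
   cross-validation.
5. **BP_AdaBoost** (`train_ensemble`, `predict`): the classifier is an
   ensemble of `T = 10` three-layer BP networks. Day labels are dummy-coded
   one-of-7. Each round resamples the training set by the current weight
   distribution `D_t`, trains a weak net, flags every sample whose output
   deviates from its target by more than 0.2 (maximum absolute deviation
   over the 7 outputs; mean-deviation and argmax rules are config
   alternatives), sums the flagged samples' weights into the round error
   `e_t`, votes with `a_t = ½·ln((1−e_t)/e_t)`, multiplies flagged weights
   by `k = 1.1` and renormalizes. (An exponential update
   `D·exp(−a·agreement)/B_t` is available as a config alternative.)
   Prediction averages the weak outputs with weights `a_t`; the winner must
   exceed the 0.5 cutoff, otherwise the sample is *unassigned*, which
   evaluation counts as misclassified but reports in its own confusion
   column. Argmax ties break toward the lower day — deterministic and
   documented.

### The weak learner

Each weak predictor is an input–10–7 sigmoid network. Fixed training
parameters: learning rate 0.1, momentum 0.1, initial weights uniform on
[−0.3, 0.3], permitted training error (MSE) 0.01, at most 50 epochs.
Training is **sequential** (per-sample updates in a seeded random order per
epoch) with the sigmoid delta rule at the output layer (output delta
`ŷ − y`, the cross-entropy gradient); the stopping criterion remains the
full-set MSE. This choice is deliberate: with full-batch mean-gradient
descent at this fixed learning rate, a 13–10–7 network cannot reach the
0.01 error target within 50 epochs even on a linearly separable four-point
toy problem (0/10 random initializations), whereas the sequential delta-rule
regime reaches it reliably and trains the study-scale networks to their
target in 15–35 epochs. The round error `e_t` is clamped to
`[10⁻¹⁰, 0.5 − 10⁻¹⁰]` before the vote weight, because the update is
undefined at 0 and a round at or beyond 0.5 carries no useful vote; such
rounds are kept with a warning and an approximately zero vote.

Classifier inputs are the selected component scores z-scored per column
with training statistics and scaled to standard deviation 3
(`input_scale`). Two failure modes motivated this: raw NIRS PC scores are
O(50) and saturate the sigmoids instantly, while unit-scale inputs pack the
seven day classes ~0.5 units apart along a component axis — too fine for
the fixed-rate, 50-epoch networks to carve thresholds. The score matrix fed
to ICA is likewise the normalized one: raw NIRS PC scores carry roughly an
order of magnitude more variance than e-nose scores (1557 vs 11 underlying
variables), and unnormalized concatenation makes the whitening step discard
the e-nose directions almost entirely — the "fused" model silently
degenerates to NIRS-only.

### Component-count selection

`loocv_rate` implements the selection criterion: for each training sample,
hold it out, train the ensemble on the rest, identify the held-out sample;
the identification rate is 100·correct/m. `select_components` picks the
**first local maximum** of the rate curve: the smallest count whose rate
strictly exceeds its predecessor's and is at least its successor's;
a monotone curve falls back to the global maximum. Candidate counts default
to 1–10 PCs per modality and 1 up to the concatenated total for ICs
(wide enough to bracket the optima this method selects at the study's
scale). Feature extraction is *not* refit per fold — the
cross-validation selects the classifier's input dimensionality on
already-extracted training scores, which matches the procedure of selecting
components first and keeps desk-scale runtime; all fold seeds are shared
across candidate counts so the curve is a paired comparison rather than
seed noise.

## The synthetic study generator

Real multi-run fermentation trials are rarely available, so the package
carries a first-class generator (`generate_study`) that emulates a
reference trial's statistical structure: 4 runs × 7 days × 5 replicates = 140
samples, split 105/35 by run (runs 1–3 train, run 4 validates).

Four latent analytes follow logistic trajectories in fermentation day —
one parametric family that encodes lag, exponential and stationary phases.
Defaults (floor, ceiling, midpoint, steepness): (0, 10, 1.2, 1.8),
(0, 6, 2.5, 1.15), (0, 8, 1.8, 1.5), (1, 9, 2.6, 1.35). Two properties are
engineered into these numbers and asserted by tests:

* **Stationary-phase plateau**: for every analyte the day-5→6 change is
  strictly the smallest adjacent-day change (< 5% of the analyte's range),
  so day 5 and day 6 are the near-identical class pair — the error
  structure characteristic of a fermentation that has entered its
  stationary phase.
* **Within-modality rank**: the two analytes a modality sees rise with
  different timing and steepness (early/steep vs late/gradual). With both
  midpoints near each other the two logistic curves are nearly collinear
  across days 0–6 and the modality's feature space collapses to rank one,
  which defeats both component selection and classification; the spread
  restores a genuinely two-dimensional geometry, akin to the multi-component
  PCA spectra of real e-nose data.

Run-to-run variation is an additive shift per run (sd 0.03 concentration
units, drawn once per run); replicate noise is per-sample (sd 0.1). These
were calibrated so the synthetic study behaves like a well-run trial —
validation rates in the high-80s to high-90s with errors
confined to the day-5/6 pair, and the fused model beating both single
techniques. Larger run effects make the held-out run systematically
mislabeled in whichever modality has the smaller day-5/6 margin, dragging
fusion below the single models; that regime is available through the config
but is not the default study condition. In **modality-split mode** (the
default) analytes 1–2 are visible only to the gas sensors and 3–4 only to
the spectra, so neither modality alone carries all the discriminating
information and fusion has something real to contribute.

The e-nose model renders 11 sensors with first-order rise kinetics over a
1 Hz, 0–120 s grid (121 points; the window length is the acquisition
condition, the 1 Hz rate a design choice):
`r_s(t) = baseline_s + (S·conc)_s·(1 − e^{−t/τ_s}) + drift·t + noise`, with
a fixed non-negative cross-sensitivity matrix, per-sensor time constants
16–35 s, drift 0.002 ppm/s and noise sd 0.02 ppm. The maximum response of a
noiseless trace is its value at 120 s, so the max-response feature is the
steady-state-ish response plus noise effects. The spectrum model renders
1557 absorbance points on the instrument-convention descending grid
(10,000 cm⁻¹ in steps of 3.856 cm⁻¹) as Beer–Lambert sums of per-analyte
Gaussian bands over a linear baseline; multiplicative scatter multiplies
the *whole* deterministic signal (`x = α·(chemistry + baseline) + β + …`,
α ~ N(1, 0.08²), β ~ N(0, 0.03²)) — placing the baseline inside the scatter
factor is what makes SNV remove the scatter exactly, and is how scatter
acts on a measured reflectance spectrum. All randomness flows from one
master seed through named substreams (run effects, per-sample noise,
per-modality measurement noise), so a fixed seed reproduces a study
bitwise and modalities can be regenerated independently.

What the generator does **not** emulate: real TGS sensor chemistry,
humidity/temperature sensitivity, drift aging, real VOC identities, or
band assignments of real substrates. Passing tests therefore demonstrate
that the pipeline recovers the structure this generator encodes — day
classes along smooth trajectories, a stationary-phase plateau, between-run
shifts — not that it would reach the same rates on any real fermentation
data.

## Numerical choices and degenerate inputs

* SNV and standardization error on constant input (zero variance), naming
  the offending column.
* PCA requires `k ≤ min(rows − 1, cols)`; ICA requires at least as many
  rows as columns and errors on rank-deficient whitening; near-Gaussian
  inputs trigger a warning (ICA is then unidentifiable).
* ICA iterates at most 500 fixed-point steps to tolerance 10⁻⁸ and returns
  the best iterate with a warning if unconverged.
* The LOOCV of a fold whose training remainder has fewer than two classes
  counts the fold as an error and warns.
* Reported rates are rounded half-up to two decimals (99.047…% prints as
  99.05) — `round_half_up`, not banker's rounding — with full precision
  kept internally.
* The e-nose/NIRS/fusion study runs at these problem sizes: 105 LOOCV folds
  per candidate count, 10 candidate PC counts per modality, IC candidates
  up to the concatenated total, 10 boosting rounds of 50-epoch networks;
  one full study comparison takes on the order of a minute and a half on a
  single CPU.

## Known limitations

* The boosting variant has no margin-theory guarantee; the non-decreasing
  training fit from 1 to 10 rounds is an empirical property of the study
  conditions, asserted as a median over seeds.
* The first-local-maximum rule is greedy by construction; on a curve whose
  early plateau reflects within-run separability it can pick fewer
  components than between-run robustness would want. The run-based split
  keeps this honest in evaluation.
* Over- and under-complete ICA (more sources than observations) is out of
  scope; the fusion use case only ever reduces dimension.
* The command-line interface exposes the two shell-level entry points
  (`simulate`, `run-study`); the finer-grained stages (preprocess, train,
  select, evaluate) are single function calls and are meant to be used from
  R.
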