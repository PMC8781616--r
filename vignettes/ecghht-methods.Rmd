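---
title: "Hilbert–Huang featuring and hybrid arrhythmia recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hilbert–Huang featuring and hybrid arrhythmia recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecghht)
```

## The problem and the model

Arrhythmia screening from a single MLII-style lead must separate five
rhythm classes — NSR, APC, AFib, VPC, VT (symptom IDs 1–5) — whose
time-domain morphology overlaps heavily in short windows. `ecghht`
summarises each 3 s frame by six numbers derived from Hilbert–Huang
analysis and feeds them to a small bank of classical classifiers. The
frame length is a deliberate compromise: long enough to contain one
complete symptomatic waveform (a premature complex plus its
compensatory pause, or several tachycardic cycles), short enough that a
frame rarely mixes two symptoms.

### Empirical mode decomposition

EMD assumes the signal is a superposition of oscillatory modes riding
on a trend. One sifting step subtracts the mean of the cubic-spline
envelopes through the local maxima and minima; a mode is accepted when
the counts of extrema and zero crossings differ by at most one *and*
the Cauchy criterion `sum((h_prev - h)^2) / sum(h_prev^2)` falls below
`stop_sd`. Decomposition stops when the residue has fewer than two
maxima or two minima. Because each accepted mode is subtracted exactly,
`sum(IMFs) + residue` reconstructs the input to machine precision — the
test suite asserts this on random frames, together with the
extrema/zero-crossing condition for every returned IMF.

Numerical choices that the method statement leaves open, fixed here
once:

* **Sifting stop** `stop_sd = 0.2` with at most 100 sifts per mode and
  10 modes per frame — the classic Hilbert–Huang default; deeper
  sifting over-smooths IMF1 amplitude.
* **Envelope boundaries**: the two end extrema of each kind are
  mirrored across the frame edges before spline fitting. Without
  mirroring, spline divergence at the edges corrupts IMF1 in the first
  and last ~0.2 s.
* **Degenerate frames**: a strictly monotonic (or constant) frame
  yields zero IMFs and `residue == input`; the feature extractor then
  reports an all-zero vector flagged `warn_low_imfs`. Frames producing
  only one or two IMFs have their missing centroids reported as (0, 0)
  with the same flag.

### Filtering

A 5th-order Butterworth low-pass at 16 Hz (for 360 Hz sampling)
precedes EMD. It is applied forward–backward so the PQRST morphology is
not phase-shifted; the effective magnitude response is the Butterworth
response squared, which the tests verify against the analytic
`1/(1 + (f/16)^10)` at 5, 16 and 60 Hz. The filter input is padded by
odd reflection before the two passes; the plain forward–backward
implementation pads with zeros internally, which sags toward zero at
the frame edges and would otherwise leak a spurious low-frequency edge
component into the decomposition.

### Hilbert spectrum, marginal spectrum, centroids

Per IMF, the FFT-based analytic signal gives the instantaneous
amplitude and the instantaneous frequency as the central difference of
the unwrapped phase. Three unglamorous choices matter in practice, all
fixed here: negative instantaneous frequencies (phase back-steps at low
amplitude) are clipped to 0; the first and last 2% of samples are
excluded from spectral accumulation (Gibbs edge suppression); and the
marginal spectrum accumulates `amplitude × dt` into 0.05 Hz bins over
0–20 Hz, with out-of-range frequencies folded into the top bin so that
the bin sum equals the time integral of the amplitude exactly (energy
conservation, asserted in the tests). The grid upper edge of 20 Hz is
uncritical: the signal is already band-limited at 16 Hz and all
published class centroids lie below 7 Hz.

The feature point of an IMF is the **area centroid** of its marginal
spectrum: mean frequency `x̄ = Σ ω·MHS(ω)/Σ MHS(ω)` and power
`ȳ = Σ MHS(ω)/T`, the energy per second of the featuring frame. The
phrase "area centroid" could also be read as the geometric centroid of
the region under the curve (whose ordinate would be half the mean MHS
value); the energy-per-second reading is adopted because it is the one
the method's own "(or power)" gloss names, and the published centroid
table cannot arbitrate between the two without the original data. For
the same reason the integrand is the amplitude envelope by default,
with `energy = "squared"` available in `hht_config()` for the
energy-density convention; the two differ only by a monotone per-IMF
rescaling of the power coordinate.

An empirical regularity worth knowing: EMD orders modes by descending
frequency, so `f1_freq > f2_freq > f3_freq` on ordinary frames — NSR
frames sit near the top of the frequency range with the lowest power,
VT at the bottom with the highest power. This ordering is what makes
the six centroids discriminative.

## The classifier bank

Four methods share one OVO wrapper: for `k` classes, `C(k,2)` binary
learners, each trained only on its pair's records; at prediction the
pair posterior for class `b` is added to `b`'s score and its complement
to `a`'s, scores are normalised to sum to one, and exact ties resolve
to the lower symptom ID. Features are z-scored with training-set
parameters stored in the model — without standardization a unit kernel
scale for the SVM is meaningless, and the MLP optimizer is poorly
conditioned (power features span two orders of magnitude across
classes).

* **MLP** — one hidden layer of 10 units, cross-entropy loss, BFGS to
  absolute tolerance 1e−6 or 500 epochs. No validation-split early
  stopping is used; the tolerance/epoch cap is the convergence
  contract.
* **"RF"** — the published parameter set describes an *adaptively
  boosted* tree ensemble (100 learning cycles, 10 nodes per tree)
  rather than a bagged forest, and that is the default here: discrete
  AdaBoost.M1 over CART trees grown with `cp = 0` and pruned back to at
  most 10 split nodes, posterior via the logistic link of the ensemble
  margin. A true bagging random forest is available with
  `rf_aggregation = "bag"`.
* **SVM** — linear kernel by default (the published parameter table;
  the accompanying text mentions an RBF, so `svm_kernel = "rbf"` with
  `K = exp(−‖x−y‖²/scale²)` is selectable), Platt-calibrated
  posteriors.
* **NB** — Gaussian class-conditional densities per feature, written
  directly as log-density sums so the posterior is the *exact*
  Gaussian computation; the tests hold it to 1e−9 against an
  independent hand computation. (Off-the-shelf naive Bayes predictors
  floor small densities for robustness, which breaks exactness.)

Determinism is part of the contract: the seed in `model_config()`
derives one seed per binary learner, and refitting with the same data,
config and seed reproduces predictions identically.

Evaluation reports the defining confusion arithmetic, ROC curves over
all thresholds with trapezoid AUC, and the operating point maximising
Youden's J (the single sensitivity/specificity pairs in the source
tables state no threshold rule; Youden is this package's choice).
In a pairwise pattern report ("NSR–VT"), the second-listed, higher-ID
symptom is the positive class. Stratified 5-fold cross-validation
assigns folds within each class after ordering records by their feature
values, so the assignment is invariant to input row order under a fixed
seed. The pairwise feature significance table uses Welch's t-test by
default (Mann–Whitney U optional); the original test family behind the
published p-values is unstated, so those p-values are not a
reproduction target.

## Synthetic data: what it emulates and what it does not

Two generators make the package self-contained:

* `simulate_features()` draws balanced per-class feature sets from the
  published per-class (μ, σ) table — the "simulative data set"
  construction, 1000 records per symptom by default. Draws are
  independent across the six features because no covariance was
  published; negative draws are truncated at zero (frequencies and
  powers are physical) and the truncated fraction is reported. The
  truncation slightly raises means of high-σ cells (VT powers);
  analyses of generator fidelity disable it.
* `simulate_ecg()` builds Gaussian-bump PQRST trains: NSR regular at
  75 bpm; APC with 25% early narrow beats; AFib at 100 bpm with RR
  drawn uniformly over ±40% of the base interval (coefficient of
  variation ≈ 0.23), no P waves, and 0.1 mV fibrillatory baseline
  waves; VPC with 25% early wide large-amplitude beats; VT a sustained
  wide-QRS run at 160 bpm. Rates and fractions follow the defining
  clinical descriptions (VT > 120 bpm, AFib without repetitive RR
  pattern or distinct P waves); they are fixture constants, not fitted
  quantities.

The waveform generator's test contract is **separability of NSR versus
VT** through the full pipeline (IMF1 power means more than one pooled
standard deviation apart, NSR higher in frequency and lower in power).
It does *not* guarantee a five-class frame labeler: an APC record is
mostly normal beats, so many of its 3 s windows contain no premature
beat and are — correctly — indistinguishable from NSR. The end-to-end
scanner check therefore trains an NSR-vs-VT *pattern model* (mirroring
pattern-specific scanning practice) on sliding-frame features of
labelled fixture records and requires ≥ 70% correct frame labels on
held-out NSR and VT records across ten seeds; in the shipped
configuration it attains 100%. Passing these tests shows the pipeline's
plumbing and the features' discriminative geometry are right; it says
nothing about performance on real ECG, where baseline wander,
electrode artefacts, inter-patient morphology variation and genuinely
mixed rhythms all appear.

## Problem sizes and reproducibility

The test suite builds everything programmatically: generator-fidelity
checks draw 100,000 values per examined cell; EMD structural invariants
run on 100 random 3 s frames; end-to-end recovery uses ten seeds with
one 30 s training record per class and one held-out record per scanned
class. These sizes keep the full suite around half a minute on one core
while leaving the stochastic checks four standard errors wide of their
targets. All randomness flows through explicit integer seeds
(`simulate_*`, `model_config`, `cross_validate`), and scans embed a
config snapshot so a trace can be audited later.

## Known limitations

* Feature draws ignore inter-feature covariance (none was published);
  simulated sets are slightly easier to separate than observed ones.
* The waveform generator is a fixture, not a physiological model; no
  baseline wander, muscle noise or morphology variation between beats
  of the same class.
* EMD mode mixing is untreated (no ensemble EMD); closely spaced tones
  below ~1 octave apart can share an IMF.
* Frames are labelled independently by the scanner; the optional
  majority-vote smoother is off by default.
* Published headline AUC/accuracy tables for the observed MIT-BIH-based
  data sets are not reproducible here: they require the external
  database plus the original manual sample screening.
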