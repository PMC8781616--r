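# ecghht

Hybrid arrhythmia pattern recognition from single-lead ECG with
Hilbert–Huang features.

`ecghht` is for researchers and engineers who need to label short ECG
frames with one of five rhythm classes — normal sinus rhythm (NSR),
atrial premature complex (APC), atrial fibrillation (AFib), ventricular
premature complex (VPC) and ventricular tachycardia (VT), symptom IDs
1–5 — and to audit every step of the decision. It implements a complete
featuring–training–scanning pipeline for MLII-style records sampled at
360 Hz, plus a synthetic module so the whole pipeline runs with no
external database.

## The method

Each 3 s analysis frame `x(t)` is processed as:

1. **Noise filtering** — 5th-order low-pass Butterworth at 16 Hz,
   applied forward–backward (zero phase, magnitude response squared).
2. **Empirical mode decomposition (EMD)** — iterated sifting
   `h ← h − (upper envelope + lower envelope)/2` (cubic splines through
   the local extrema, boundary extrema mirrored) until the candidate is
   an intrinsic mode function (IMF): `|#extrema − #zero-crossings| ≤ 1`
   and the Cauchy criterion `Σ(h_prev − h)² / Σh_prev² < 0.2` holds.
   Modes are peeled off until the residue is monotonic, giving
   `x(t) = Σ_j s_j(t) + r(t)` exactly.
3. **Hilbert spectral analysis** — per IMF, the analytic signal yields
   the instantaneous amplitude `a_j(t)` and frequency `ω_j(t)` (phase
   derivative). The Hilbert spectrum `H(ω, t) = a_j(t)` at
   `ω = ω_j(t)` is integrated along time into the marginal Hilbert
   spectrum `MHS(ω) = ∫ H(ω, t) dt`.
4. **Features** — the MHS **area centroid** of IMF1–IMF3: mean frequency
   `x̄ = Σ ω·MHS(ω) / Σ MHS(ω)` (Hz) and power
   `ȳ = Σ MHS(ω) / T` (energy per second). Six numbers per frame.
5. **Classification** — a bank of four classifiers (multilayer
   perceptron with 10 hidden units; adaptively boosted decision trees,
   100 cycles, ≤ 10 split nodes; SVM, linear kernel, Platt posteriors;
   Gaussian naive Bayes) under one-versus-one (OVO) coding — `C(k,2)`
   binary learners whose pairwise posteriors are summed into normalized
   class scores.
6. **Evaluation / scanning** — sensitivity `TP/(TP+FN)`, specificity
   `1 − FP/(FP+TN)`, accuracy `(TP+TN)/total`, ROC/AUC with the
   Youden-optimal operating point, stratified 5-fold cross-validation,
   and a record scanner that labels sliding 3 s frames with 1 s overlap
   into a traceable annotation track.

A Gaussian feature simulator (`default_table1_model()`,
`simulate_features()`) reproduces the published per-class feature
distribution and builds balanced simulative training sets (1000 records
per symptom by default); `simulate_ecg()` generates waveform-level
fixture records for all five classes.

## Worked example

```r
library(ecghht)

# featuring one annotated frame of a synthetic VT record
rec <- simulate_ecg(5, duration_s = 30, seed = 1)
fr  <- frame_at_annotation(rec, rec$annotations$time_s[5])
extract_features_frame(fr)
#>   f1_freq f1_pow f2_freq f2_pow f3_freq f3_pow label
#> 1    2.67  0.815       1  0.116       0      0     5

# train an NSR-vs-VT pattern model on fixture-derived features and scan
feats <- do.call(rbind, lapply(c(1, 5), function(s) {
  r <- simulate_ecg(s, duration_s = 30, seed = 100 + s)
  f <- extract_features(sliding_frames(r)); f$label <- s; f
}))
model <- train_model(feats, model_config("rf", seed = 1))
scan_record(simulate_ecg(5, duration_s = 30, seed = 202), model)
#> Scan of 'sim_VT_seed202' by rf: 14 frames
#>  NSR  APC AFib  VPC   VT
#>    0    0    0    0   14
```

The VT frame shows the expected signature — low IMF1 centroid frequency
(2.67 Hz) with high power (0.82), where NSR frames sit near 7 Hz at a
tenth of the power — and all 14 sliding frames of the 30 s VT record are
labelled VT (ID 5). Pattern evaluation on the simulative Gaussian sets
yields the familiar ordering, e.g. for a linear SVM:

```r
tr <- simulate_features(default_table1_model(), 1000, seed = 1)
te <- simulate_features(default_table1_model(), 400, seed = 2)
rep <- evaluate_patterns(tr, te, model_config("svm", seed = 1))
head(rep[order(-rep$auc), ], 3)
#>    pattern method sensitivity specificity accuracy   auc n_test
#> 4   NSR-VT    svm       0.935       0.973    0.954 0.981    800
#> 7   APC-VT    svm       0.920       0.985    0.953 0.978    800
#> 2 NSR-AFib    svm       0.892       0.920    0.906 0.963    800
```

A thin command-line front end (`exec/ecghht`) wraps the same functions:
`simulate`, `simulate-ecg`, `features`, `train`, `evaluate`, `scan`.

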