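# shockable

Shockable-rhythm detection from short ECG segments: the full experimental
protocol behind shock-advise algorithms (SAAs) for automated external
defibrillators, as a tested R package.

An AED must decide from a few seconds of surface ECG whether to deliver a
shock: ventricular fibrillation (VF) and rapid ventricular tachycardia
(VT ≥ 150 bpm) are shockable (Sh, +1); sinus rhythm, supraventricular
arrhythmias, pulseless electrical activity and other organized rhythms are
not (NSh, −1). The package implements, end to end:

* **Preprocessing** — mean subtraction, 5-point moving average, 1 Hz
  high-pass, 30 Hz Butterworth low-pass (the 1–30 Hz monitor bandwidth),
  at 250 Hz with zero-phase filtering; 500 Hz input is decimated.
* **AHA-style labelling** — non-overlapping 4-s / 8-s single-rhythm
  windows; exclusion of noise, rhythm transitions, fine VF
  (peak-to-peak < 200 µV), slow VT (< 150 bpm) and asystole-level
  segments (< 100 µV or < 12 bpm), with a full audit trail.
* **30 VF-detection features** — temporal (TCI, TCSC, Exp, Expmod, MAV,
  Count1–3, x1, x2, bCP), spectral (vFleak, M, A1–A3, x3–x5, bWT, bW),
  time-frequency (Li) and complexity (CM, CVbin, abin, Frqbin, Kurt, PSR,
  HILB, SamEn) measures, each pinned to an independent brute-force oracle
  in the tests.
* **Five classifier harnesses** — L1-regularized logistic regression,
  bagging, random forest, boosting (weighted vote
  `sign(Σ α_m f_m(x))`) and a Gaussian-kernel SVM, with patient-grouped
  10-fold CV (or out-of-bag) model selection.
* **Patient-wise bootstrap evaluation** — Se, Sp and the balanced error
  rate `BER = 100 − (Se + Sp)/2`, estimated over B = 500 resamples of
  test *patients* with replacement; paired comparisons share patient
  draws and use the percentile 95% CI rule for significance.
* **Bootstrap-embedded feature selection** — recursive feature
  elimination ranked by boosting importance (BSTsel) or |w_k| (L1-LRsel)
  inside a patient-wise bootstrap, with the one-standard-error subset
  rule and selection-frequency scoring.
* **A synthetic corpus generator** — patient-structured, annotated ECG
  with `public_like` (Holter-like: coarse fast VF, narrow-QRS rhythms)
  and `ohca_like` (cardiac-arrest-like: degraded slow VF, bradycardic
  wide-QRS PEA) profiles and a class-separability dial, so the entire
  protocol runs with no data download.

## Worked example

Simulate a Holter-like corpus, run the whole protocol, and read the
report:

```r
library(shockable)

cfg <- study_config(
  input = list(type = "synthetic", profile = "public_like",
               n_patients = 24, records_per_patient = 2),
  durations  = c(4, 8),
  algorithms = c("L1LR", "BST"),
  B = 200,
  selection = "L1LRsel", selection_B = 20,
  rfe_hyper = list(L1LRsel = list(lambda = 0.01)),
  single_feature = TRUE,
  seed = 1
)
bundle <- run_study(cfg)
report_study(bundle)$performance
#>  duration algorithm  se    sp ber   ber_sd
#>         4      L1LR 100  95.7 2.2 1.559248
#>         4       BST 100  96.1 1.9 1.557466
#>         8      L1LR 100 100.0 0.0 0.000000
#>         8       BST 100  95.6 2.2 1.767481
```

Each row is the mean over 200 patient-wise bootstrap resamples of the
held-out test patients: sensitivity (percent of shockable segments
correctly flagged), specificity (percent of non-shockable segments
correctly cleared) and the balanced error rate. On this clean
Holter-like world both algorithms sit near the AHA recommendations
(Se > 90, Sp > 95), 4-s windows perform on par with 8-s ones, and the
embedded selection keeps two features:

```r
report_study(bundle)$subsets
#>  duration  method K_s   subset
#>         4 L1LRsel   2 Kurt, x3
#>         8 L1LRsel   2 Kurt, x3

head(report_study(bundle)$single_feature[, c("feature", "se", "sp", "ber")], 3)
#>  feature  se sp   ber
#>     abin 100 99 0.495
#>     TCSC 100 98 0.990
#>      MAV 100 98 0.990
```

The single-feature rows use the maximum-likelihood threshold classifier
(densities crossing at f(x|Sh) = f(x|NSh)), fitted on training patients
and scored held-out. `autoplot()` methods draw the bootstrap box plots,
the BER-versus-subset-size curve with its one-SE threshold, and paired
difference histograms; `tidy()`/`glance()` return the underlying tables.

Individual stages are plain functions over tibbles and compose with the
pipe: `gen_corpus() |> preprocess_records() |> segment_records(4) |>
label_segments() |> extract_features()`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — synthetic corpus generation, preprocessing, labelling, feature
extraction, patient split, training, bootstrap evaluation, feature
selection and subset comparison — prints the resulting tables, and writes
the machine-readable results object:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.

## Scope notes

The synthetic generator is a phenomenological stated world (no chest
compression artifacts, no device saturation); green tests certify the
protocol machinery, not clinical performance. WFDB support is a minimal
single-signal format-16 reader/writer with a plain-text annotation
sidecar. See `vignettes/shockable-methods.Rmd` for the model choices,
constants and their rationale.
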