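---
title: "Methods: shockable-rhythm detection, evaluation and feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shockable-rhythm detection, evaluation and feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockable)
```

## The problem

An automated external defibrillator (AED) must decide, from a few seconds
of single-lead surface ECG, whether the rhythm is *shockable* (ventricular
fibrillation, rapid ventricular tachycardia, flutter) or *non-shockable*
(sinus rhythm, supraventricular arrhythmias, pulseless electrical
activity, and other organized rhythms). The accepted performance framework
asks for sensitivity above 90% on shockable rhythms and specificity above
95% on non-shockable ones, assessed on artifact-free single-rhythm
segments. `shockable` implements the full experimental protocol used to
study this problem: signal conditioning, AHA-style segment labelling with
exclusion rules, a 30-feature parametrization drawn from the VF-detection
literature, five classifier families with patient-grouped model selection,
patient-wise bootstrap evaluation, and bootstrap-embedded recursive
feature elimination -- plus a synthetic corpus generator so that the whole
protocol is exercisable without any ECG download.

## Preprocessing

Four stages, applied per record: mean subtraction; a 5-point moving
average (interpreted as the standard 5-tap smoother); a first-order
Butterworth high-pass at 1 Hz for drift suppression; and a fourth-order
Butterworth low-pass at 30 Hz. This realizes the typical 1--30 Hz AED
monitor bandwidth at the 250 Hz analysis rate; 500 Hz recordings are
first decimated by two behind an anti-alias low-pass. The high- and
low-pass stages are applied forward-backward (zero phase) so that QRS
morphology is not skewed; filter orders are package conventions because
the chain's source does not state them, and the coefficients are
reproducible from `butter_filter()`.

Two numerical consequences are worth knowing. First, the composite
passband gain is about 0.93--0.95 across the VF band (the squared
magnitude of the 1 Hz high-pass plus the moving average), so preprocessing
is only *nearly* idempotent: a second pass removes about 5% RMS while
leaving the waveform essentially collinear (correlation > 0.999). The
property test asserts this achievable version. Second, amplitude-based
exclusion thresholds are measured on the *filtered* signal by default
(`amplitude_on` documents the convention); applying them pre-filter is the
documented alternative.

## Labelling and exclusions

Records are tiled per annotation interval with non-overlapping,
left-aligned windows of 4 or 8 s (half-open, 0-based); remainders are
dropped and windows never span a rhythm transition. Retained segments are
labelled +1 (VF, VT at or above 150 bpm) or -1 (organized non-shockable
rhythms). Excluded, with reason codes: annotated noise; asystole-level
windows (peak-to-peak under 100 uV or estimated rate under 12 bpm); fine
VF (VF under 200 uV peak-to-peak); slow VT (under 150 bpm, using the
annotated rate when present); and unknown rhythm labels, which are
rejected explicitly rather than silently. The audit trail
(`segment_audit()`) reconciles candidate counts with exclusions, including
the number of would-be windows of a continuous record tiling that straddle
annotation boundaries.

Rates for the exclusion logic come from a deliberately simple peak picker
(local maxima of |x| above 40% of the segment maximum, 200 ms refractory).
It is a utility for exclusion decisions on synthetic or annotated data,
not a general QRS detector.

## The 30 features

Each retained segment yields 30 real-valued features; every constant sits
in `feature_constants()` so tests can pin them, and each feature has an
independently coded brute-force oracle in the test suite (agreement within
1e-9 on 20 stored fixtures).

* *Temporal*: TCI (threshold-crossing intervals over 1-s stages at 20% of
  the stage maximum), TCSC (fraction above a 0.2 relative threshold in
  cosine-tapered 3-s sub-windows), Exp and Expmod (crossings of |x|
  against decaying/resetting exponential envelopes, per second), MAV
  (max-normalized mean absolute value over 2-s tiles), Count1--3
  (occupancy of the 13--16.5 Hz band output above thresholds relative to
  the segment amplitude), x1 and x2 (amplitude statistics of the same
  narrow-band output), bCP (normalized mean absolute slope).
* *Spectral*: vFleak (VF-filter leakage at the estimated mean half
  period), M (spectral centroid normalized by the dominant frequency in
  0.5--9 Hz), A1--A3 (amplitude-spectrum shares below, around and above
  the dominant peak), x3--x5 (band-power ratios), bWT and bW
  (wavelet-approximation and wavelet high-band energy shares).
* *Time-frequency*: Li (energy share below 7.8 Hz in a 5-level Daubechies-4
  decomposition).
* *Complexity*: CM (normalized Lempel-Ziv complexity of the
  mean-thresholded binary sequence), CVbin/abin/Frqbin (statistics of the
  0.2-relative-threshold binary signal), Kurt (m4/m2^2), PSR and HILB
  (occupied fraction of a 40x40 grid over the 0.5 s delay embedding and
  the analytic-signal phase plane), SamEn (sample entropy, m = 2,
  r = 0.2 SD).

bCP, bWT and bW are only characterized qualitatively in the literature
this library follows (slope content, time-domain baseline content,
wavelet band content); the definitions here are documented
reinterpretations, flagged as such, with the registry in `feature_funs()`
as the hook for alternatives. The Count1--3 and x1--x5 thresholds are
package conventions on the 13--16.5 Hz narrow-band analysis.

Counts are normalized by the window length, and Kurt, M, A1, x1, x3, x5
and Count3 pass through `log(1 + v)` -- a fixed strictly monotone map that
de-skews their histograms without affecting rank-based analyses. Features
are standardized to zero mean and unit variance using *training-set*
statistics only (population SD; constant columns map to zero with a
warning).

One caveat the tests encode honestly: features built from duty cycles of
relative thresholds (TCSC, MAV) are invariant under time dilation for pure
sinusoids, so "higher frequency implies larger value" holds for the count,
rate and spectral-moment features but *not* for TCSC; the test suite
asserts the orderings that actually follow from the definitions.

## Classifiers and model selection

Five families: L1-regularized logistic regression (glmnet), bagged
classification trees, random forests (`p = floor(sqrt(K))` features per
node), exponential-loss boosting of shallow trees with the weighted vote
`sign(sum alpha_m f_m(x))`, and a Gaussian-kernel soft-margin SVM. The
trees, the AdaBoost loop and the SVM's SMO solver are compiled in the
package (the image provides no tree or SVM package); the SMO solution is
cross-checked against an independent quadratic-programming solve in the
tests. Attribution vectors -- |w_k| for L1LR, impurity improvements for
the ensembles, mean absolute decision-function gradient for the SVM --
support the feature-selection machinery.

Tuning is by patient-grouped 10-fold cross-validation (no patient ever
straddles folds) minimizing the balanced error rate of pooled out-of-fold
predictions, except for bagging/random forests, where tree complexity is
chosen by out-of-bag error. Grids are package conventions: lambda
logarithmic 1e-4..10 (20 points); C in 1e-2..1e3, gamma in 1e-3..10;
boosting depth {1,2,3} with up to 500 iterations; 300 trees for the
bagged ensembles. Decision-score ties break to +1, documented.

The single-feature reference classifier is the maximum-likelihood
threshold: Gaussian-kernel densities (Silverman bandwidth) per class on a
common 2000-point grid, threshold at their crossing, polarity chosen so
both Se and Sp exceed 50% when achievable; with multiple crossings the one
maximizing training Se + Sp is kept.

## Evaluation

Se, Sp and `BER = 100 - (Se + Sp)/2` are reported in percent. Uncertainty
comes from the patient-wise bootstrap: B resamples (default 500) each draw
N patients with replacement from the N test patients -- so on average
`1 - (1 - 1/N)^N`, about two thirds, of the patients enter each resample
-- and a duplicated patient contributes duplicated segments. Resamples
missing a class yield undefined metrics, recorded as missing and excluded
from summaries. Paired comparisons evaluate both models on identical
patient draws (shared master seed) and declare a difference significant
exactly when the percentile 95% CI of the per-resample difference excludes
zero. Percentile CIs were chosen because the protocol names only "95%
confidence interval"; endpoints are order statistics of the stored
resample values.

## Feature selection

`rfe_bootstrap()` runs recursive feature elimination inside a patient-wise
bootstrap of the training set: per resample, fit the ranking model on the
in-bag segments, evaluate BER on out-of-bag patients at every subset size,
and drop the least important feature until one remains. Hyperparameters
are reused across resamples rather than retuned (the retune-per-resample
variant would multiply cost for little stated benefit; the hook is the
`hyper` argument).

The subset size comes from the one-standard-error rule: the smallest k
whose mean BER is within one band of the minimum. The band is a genuinely
open choice: the bootstrap SD of the out-of-bag BER at the minimizer
(matching the error bars one would plot) or the literal standard error
SD/sqrt(B). The default is the SD band; `band = "se"` gives the literal
reading, which with hundreds of resamples reduces to "where the curve
stops improving" and therefore yields larger subsets on noisy, hard
datasets -- the behavior that reproduces the observation that harder
(arrest-like) data needs roughly twice as many features as clean
Holter-like data. The final subset is the K_s features most often
surviving to size K_s across resamples; ties break by mean elimination
step, then name.

## The synthetic corpus generator

The generator is a *stated world*, not a biophysical simulation. VF is a
phenomenological oscillation: 3--5 sinusoidal components detuned within
+/-0.35 Hz of a slowly drifting instantaneous frequency, randomly phased
and amplitude-modulated; its spectral peak stays within about +/-0.3 Hz of
the requested dominant frequency and its realized peak-to-peak amplitude
within +/-15% of the requested one. Organized rhythms are trains of
biphasic Gaussian-derivative complexes with RR jitter, optional P/T-like
components for narrow-complex rhythms, and a widened, distorted kernel for
aberrant conduction. Noise epochs are band-limited Gaussian noise with
baseline wander; asystole is a near-flat trace well under the 100 uV
floor.

Two profiles encode the populations of interest. `public_like` (Holter
databases near arrhythmia onset): coarse VF at 400--1500 uV and 3.5--6.5
Hz, mostly narrow-QRS organized rhythms at 50--160 bpm, 10% aberrant.
`ohca_like` (out-of-hospital arrest, minutes in): degraded VF at 150--600
uV and 2--4.5 Hz, bradycardic wide-QRS PEA/PR down to very low rates, 40%
aberrant, more asystole. These ranges are conventions motivated by the
deterioration of untreated VF (amplitude and frequency fall over time) and
by what arrest rhythms look like; they are not measured parameters.

Patients draw persistent morphology (amplitude scale, VF frequency offset,
QRS width, rate, aberrancy) once, which makes segments within a patient
correlated -- exactly the dependence patient-wise resampling exists to
respect, and the tests assert the resulting intra- versus inter-patient
variance ordering.

The `separability` knob (0..1) injects cross-class morphology:
organized complexes inside VF epochs and fibrillatory baseline inside
organized epochs, with amplitude `min(1.6 * (1 - s), 1)` relative to the
host rhythm, and a per-patient contamination type (VF-side, organized-side
or both) so that different patients defeat different feature families --
this heterogeneity is what makes harder profiles require *combinations* of
features rather than one dominant cue. `public_like` defaults to 0.9,
`ohca_like` to 0.55. The dial was fixed from the stated phenomenology
before the acceptance thresholds were evaluated, and its monotonicity
(lower separability never lowers error, in means over seeds) is asserted
in the responsive range 0.5--0.9; below that the contamination saturates.

What a green test does *not* establish: the generator has no chest
compression artifacts, no electrode motion or device saturation, no
12-lead morphology, no real inter-patient pathology spectrum -- so passing
tests certify the protocol machinery and the stated world, not clinical
performance.

## Numerical and scale choices

* Segments are half-open `[t, t + d)` windows, 0-based; ties in decision
  scores go to +1; `which.min` tie-breaks take the first (most
  regularized) grid point.
* The bootstrap default is B = 500 everywhere in the package; the test
  suite scales B down (20--200 depending on the check) purely for CPU
  budget, which widens Monte-Carlo error but changes no contract.
* Zero-variance segments raise a dedicated degenerate-input condition;
  upstream exclusion rules should make them unreachable on real corpora.
* Sample entropy and Lempel-Ziv parsing are exact counts (no
  approximation); the DWT zero-pads to the next power of two with
  periodic boundary handling.
* `stats::fft` backs the spectra (Hamming window over the full segment);
  the oracles recompute them by direct DFT summation.

## Known limitations

The WFDB support covers single-signal format-16 records with a plain-text
annotation sidecar -- enough for interchange, not a full PhysioNet client
(binary `.atr` annotations belong to the out-of-scope public-database
reproduction). bCP/bWT/bW and the count/x-family constants are
reinterpretations as documented above. The SVM holds a dense kernel
matrix, which is fine for segment-level datasets up to a few thousand
rows but not beyond. Processing-time comparisons are represented by the
dimensionless `feature_cost()` proxy, deliberately not wall-clock.
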