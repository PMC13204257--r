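---
title: "Screening carotid vibration recordings with wavelet scalogram biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening carotid vibration recordings with wavelet scalogram biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidscreen)
```

## The problem

Hemodynamically significant carotid artery disease — atherosclerotic
stenosis at or above the 50% diameter-reduction threshold, dissection,
fibromuscular dysplasia — disturbs blood flow in ways that imprint faint
mechano-acoustic vibrations on the skin of the neck. A wearable
accelerometer patch can record these vibrations; the question is whether a
compact, interpretable analysis of their time–frequency structure can flag
the carotid sides where clinical management may change.

`carotidscreen` implements that analysis end to end:

1. **synthesis** of a bilateral cohort of vibration recordings with a
   controlled ground truth (clinical recordings of this kind are not openly
   deposited, so a simulator with the same class-conditional spectral
   structure is the test bed);
2. **preprocessing** into normalized 4 s analysis segments;
3. **analytic Morse wavelet scalograms** restricted to 5–60 Hz;
4. **six interpretable biomarkers** per segment, plus an extended
   screening set;
5. **univariate screening** and **grouped, stratified cross-validation**
   at the patient-side level with an L2-regularized logistic model,
   probability aggregation from segments to sides, and a prespecified
   operating threshold;
6. **exact additive attribution** (linear SHAP) of the fitted model.

## The signal model behind the simulator

Each recording is built on a cardiac-cycle-locked template:

* **Systolic pulses.** At each beat time (heart rate per patient, mean 70,
  SD 8 bpm; beat-to-beat interval jitter 3%) an exponentially damped
  oscillation is emitted at the patient's pulse frequency (uniform
  6–10.5 Hz), with patient-specific decay time (60–160 ms) and second and
  third harmonic content. Harmonics reach at most about 31.5 Hz, below the
  32.5 Hz upper-band cut: benign pulse morphology varies *where* the
  low-frequency energy sits without crossing into the upper half-band.
* **Benign systolic murmur.** Every patient carries a label-independent
  band-limited noise component windowed over systole, in a
  patient-specific band inside 8–30 Hz with amplitude 0.4–0.9 relative to
  the unit pulse. Its purpose is realism of the *location* variability of
  lower-band energy: global spectral-shape statistics (centroid, roll-off,
  entropy) vary between healthy patients, as they do clinically.
* **Pathological turbulence.** Each carotid side draws a severity: sides
  labeled positive (probability 0.3, matching a side-level prevalence of
  39/128 in the clinical cohort this pipeline models) draw severity in
  [0.5, 1], others in [0, 0.35]; the label is severity ≥ 0.5, the analogue
  of the ≥50% stenosis cut. The side emits bursts of band-limited Gaussian
  noise windowed over the systolic interval, scaled by
  `severity × turbulence_gain` (default gain 1.2) with a per-recording
  log-normal coupling factor. The burst band is a per-side sub-band of the
  configured 20–40 Hz range whose upper edge always reaches 34–40 Hz —
  stenosis-like narrow elevations through dissection-like broader bands.
* **Sensor floor.** White noise (SD 0.3 relative to the unit pulse) and a
  slow sinusoidal drift below 0.5 Hz.

Band-limited noise is synthesized by spectral masking (FFT, raised-cosine
band edges 1 Hz wide, inverse FFT), which is numerically stable at any
sampling rate — a very narrow IIR band-pass designed at 24 kHz is not.

Randomness is organized as one master seed plus per-recording substreams
derived by stable hashing of (patient, side, position), so a cohort is
reproducible bit for bit and independent of generation order, and two
recordings differing only in severity share every other random component.

**What the simulator does not model:** vessel-wall mechanics or
computational fluid dynamics, motion/swallowing artifacts (excluded
recordings are simply not generated), contralateral cross-talk between
sides, and the absolute amplitude scale of a real accelerometer. Passing
tests on synthetic cohorts therefore demonstrate that the *pipeline*
recovers the structure the features were designed for — not that clinical
performance is reproduced.

### Calibration of the defaults

Effect sizes (burst gain, noise floor, murmur level) are not published for
this class of signals. The defaults were fixed once, during generator
development, so that the synthetic cohorts satisfy the pipeline's
pre-registered property suite: class-separated 20–40 Hz band energy,
severity monotonicity of the high-frequency fraction, and the
high-frequency fraction emerging as the top-ranked univariate biomarker —
the qualitative structure reported for the clinical cohort. The essential
insight from calibration: the class-discriminative energy must sit mostly
*above* the 32.5 Hz cut while benign between-patient variability moves
energy around *below* it; otherwise the spectral centroid and roll-off —
monotone relatives of band balance — tie with or beat the band-energy
fraction.

## Preprocessing

The chain mirrors standard mechano-acoustic practice: two's-complement
wrap-around correction for integer input, anti-aliased decimation by 10
(24 kHz → 2.4 kHz; the anti-alias filter is a maximally flat Butterworth
at 0.8 of the target Nyquist applied forward–backward, so the passband is
ripple-free), a 4th-order Butterworth band-pass with −3 dB points at 0.5
and 75 Hz, per-channel z-scoring, Savitzky–Golay smoothing (21 ms window,
order 3) followed by a 5 ms centered moving average, a 2 s head discard,
and segmentation into 4 s windows with a 2 s hop keeping only complete
windows (a 60 s recording yields 28 segments).

Two numerical choices deserve note. *Zero-phase filtering:* the band-pass
is applied forward–backward to preserve pulse morphology; the −3 dB design
property holds for the single-pass response, and the double pass squares
the small mid-band droop (about 2.5% at 30 Hz — accounted for in the
tests, irrelevant to the scale-invariant features). *Total order four* is
read as two poles per band edge; an order-4-per-edge variant is a
configuration away.

## The Morse scalogram

The analytic Morse wavelet with symmetry parameter γ = 3 and
time–bandwidth product P² = 60 (β = P²/γ = 20) has frequency-domain form

$$\Psi(\omega) = U(\omega)\, c\, \omega^{\beta} e^{-\omega^{\gamma}},$$

zero for negative frequencies and peaking at
ω_peak = (β/γ)^{1/γ}. The filter bank places 12 voices per octave
between 5 and 60 Hz (44 rows), each row a scaled copy of Ψ sampled on the
FFT grid. Segments are extended to double length by symmetric reflection,
multiplied in the frequency domain, inverse-transformed, and the central
half retained — suppressing circular wrap-around at the 4 s boundaries.
Wavelets are peak (L∞) normalized; every downstream feature is a ratio or
normalized moment, so the amplitude convention cannot matter, and a
property test recomputes the core features under a rescaled convention to
prove it.

## The biomarkers

With S(f, t) the squared magnitude, E the total energy over the 5–60 Hz
grid and P(f) the frequency marginal, the core six are:

| feature | definition | units |
|---|---|---|
| `hf_fraction_top50` | energy at or above 32.5 Hz / E | unitless [0, 1] |
| `gini_sparsity` | Gini index of the magnitude distribution | unitless [0, 1) |
| `spectral_centroid_hz` | Σ f·P(f) | Hz |
| `sobel_edge_energy` | mean 3×3 Sobel gradient magnitude of the [0, 1]-scaled image | normalized |
| `image_entropy` | Shannon entropy of S over cells / log(#cells) | unitless [0, 1] |
| `spectral_spread_hz` | √Σ (f − centroid)²·P(f) | Hz |

The 32.5 Hz cut is the *fractional upper band* rule f_hi − q(f_hi − f_lo)
at q = 0.5 on the 5–60 Hz band. The extended screening set adds the
q ∈ {0.3, 0.4, 0.5} ratios against total and against the complementary
lower band, 85%/95% roll-offs, upper/lower entropy and Sobel ratios, and
the upper-half-band proportion. Centroid, spread and roll-off use the
actual row frequencies in Hz — the grid is logarithmic, so row indices
would be wrong. Energies integrate |W|² even though the scalogram stores
|W|.

Three definitions are open in the source material and were fixed here:
the core "high-frequency fraction (top 50%)" is the ratio *to total* (the
to-lower variant stays in the extended set); the core entropy is the
full-band normalized variant; Sobel gradients are taken on raw (not
log-compressed) magnitude scaled to [0, 1], with a log variant behind a
configuration flag. The Gini sparsity uses the standard formula
G = 2Σ k·x₍ₖ₎ / (N Σx) − (N+1)/N on ascending-sorted magnitudes.

## Screening and the classifier

The unit of inference is the **patient side** (patient × L/R): all
segments of both recording positions of a side share one group key, and
every split — the fixed 15% stratified holdout and the stratified 5-fold
CV inside the training groups — operates on whole groups. Stratification
uses a seeded greedy round-robin of shuffled groups within class, which is
reproducible and balances class counts across folds.

Univariate screening scores each feature (and its negation, keeping the
better orientation) as a held-out continuous score by AUROC and AUPR
averaged over folds, then ranks features per metric and averages the two
ranks. Exact ties share the best rank (competition ranking): several
screening features are monotone transforms of one another and tie exactly
on rank-based metrics, where average-tie ranking would misleadingly push
all of them down. A secondary Mann–Whitney U test (two-sided, patient-side
aggregated means to avoid repeated-measures pseudo-replication) with
Benjamini–Hochberg correction checks distributional separation.

The classifier is an L2-regularized logistic regression fitted by damped
Newton iteration on standardized features (statistics from training rows
only; λ = 1 on the standardized scale; inverse-frequency class weights
normalized to mean 1; intercept unpenalized; convergence at gradient
max-norm 1e−8). Segment probabilities are averaged within each group to
give the patient-side prediction — the primary endpoint. The operating
threshold is prespecified from *out-of-fold* training-side predictions as
the candidate (midpoints of adjacent distinct probabilities plus
sentinels) with maximum specificity among those reaching sensitivity
≥ 0.90, ties resolved toward the lower threshold, and then applied
unchanged to the held-out test set. AUROC uses the rank statistic (ties
half-counted); AUPR uses step-wise integration with tied scores processed
as one block, which avoids the optimism of linear PR interpolation.

Tree ensembles are deliberately out of the core: the logistic model is the
headline, from-scratch model; anything else can be plugged in around the
same split plan.

## Attribution

For a linear model on the log-odds scale, Shapley values under the
independent-feature convention have the closed form
φᵢ = wᵢ(xᵢ − μᵢ) with the training feature means as background, and
base + Σφ equals the predicted log-odds *exactly* — the package asserts
this to machine precision rather than approximating. Log-odds is the
scale on which additivity is exact; the sigmoid maps monotonically to
probability. Global importance is the mean |φ| per feature with a
sign-consistency summary.

## Problem sizes used by the test suite

The simulator defaults describe 60 s recordings at 24 kHz. The package's
own test suite runs its large experiments at the generator's fast mode
(direct synthesis at the 2.4 kHz analysis rate, flagged in the cohort
manifest) with 8–10 s recordings, which preserves every structural
property being tested — segment counts scale with duration, nothing else
changes — while keeping the suite's runtime in minutes: the end-to-end
study uses 10 cohorts of 60 patients (240 recordings, 120 sides each);
the permutation-null calibration uses 100 label permutations of a
16-patient cohort; the severity sweep uses 11 severities × 4 seeds. The
full-rate decimation front end is exercised separately on 24 kHz input.

## Known limitations

* The synthetic cohort is a structural stand-in, not a clinical claim;
  absolute performance numbers on it say nothing about patients.
* The wrap-around rule (two's-complement reinterpretation plus half-range
  jump unwrapping) is one standard reading of fixed-width counter
  overflow; hardware with a different overflow discipline would need its
  own converter.
* Contralateral coupling between sides is not simulated; in real bilateral
  disease the "healthy" side may carry echoes of the diseased one.
* The Mann–Whitney normal approximation (tie-corrected, with continuity
  correction) is used for the group sizes the pipeline produces; exact
  enumeration applies only to very small classes without ties.
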