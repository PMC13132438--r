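---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pneumabio` computes multimodal digital biomarkers for pneumonia
mortality studies from three low-resource data streams — scanned paper
ECGs, Spanish clinical notes, and lung segmentation masks paired with
classifier activation maps — and provides the statistical layer that
relates them to a binary in-hospital mortality outcome. This vignette
documents the models, the tunable parameters and why their defaults
are what they are, the numerical decisions, and what the synthetic
generators do and do not establish.

## 1. Paper-ECG digitisation

**Model.** A scanned ECG page is a grayscale raster in `[0,1]`
(1 = white). Clinical ECG paper has a 1 mm grid with a darker line
every 5 mm, and is printed at 25 mm/s and 10 mm/mV. Digitisation
proceeds in four stages:

1. *Grid calibration* (`calibrate_grid`). The pixel pitch of the grid
   is the dominant periodicity of the row/column mean-intensity
   projections, found as the first strong autocorrelation peak with
   parabolic sub-pixel interpolation, then refined against a distant
   harmonic (the peak near `m` periods estimates `m` periods at once,
   dividing the pixel-level uncertainty by `m`). A 5× harmonic — the
   big box — must be present or calibration fails with a classed
   error. Paper speed and mV scale cannot be read off a raster; they
   are configuration (defaults 25 mm/s, 10 mm/mV).
2. *Trace extraction* (`extract_trace`). Grid ink is printed lighter
   than trace ink, so a luminance threshold (default 0.5) separates
   them; within each pixel column the trace ordinate is the
   intensity-weighted centroid of the remaining dark pixels. This
   makes thick-trace and tie handling continuous (a two-pixel trace
   yields the midpoint). Columns with no ink are linearly interpolated
   from neighbours; more than 50% empty columns is a failure.
3. *Calibration to physical units* (`to_signal`). `(column, row)`
   becomes `(ms, mV)` with `ms_per_px = 1000/(speed·px_per_mm_x)` and
   `mv_per_px = 1/(scale·px_per_mm_y)`; the irregular pixel samples
   are linearly resampled to 500 Hz.
4. *Band-pass filtering*. A zero-phase 0.5–40 Hz filter of Butterworth
   character, order 5. Because no IIR filtering infrastructure is
   available in the dependency set (and high-order band-pass
   polynomials are ill-conditioned anyway), the forward–backward
   Butterworth cascade is applied in the frequency domain: the squared
   magnitude response of the analogue prototype is multiplied onto the
   FFT of the mirror-padded signal. This has exactly zero phase (so
   beat-template timing is unbiased), the same pass-band behaviour as
   `filtfilt` with Butterworth coefficients, and no stability issues.

**Fidelity.** On clean synthetic pages at ≥5 px/mm the render →
digitise round trip achieves RMSE ≤ 0.05 mV against the ground-truth
signal *in the shared pass-band* (the reference is passed through the
same 0.5–40 Hz filter before comparison: the band-pass deliberately
removes the DC and drift components of the trace, and digitisation
fidelity should not be confounded with the intentional filter), and
R-peak timing errors of 1–2 ms. The residual error is pixel
quantisation at steep QRS slopes.

**Panel localisation** comes from the render manifest for synthetic
pages; for real scans a rectangular panel configuration must be
supplied. Automatic layout detection, lead-label OCR and rotation
correction are out of scope.

## 2. Beat detection and morphological features

**R-peak detection** is classic Pan-Tompkins: 5–15 Hz band-pass,
derivative, squaring, 150 ms moving-window integration, adaptive
SPKI/NPKI dual thresholds with search-back at 1.66× the running RR
average, 200 ms refractory period, and final refinement to the local
maximum of the input signal within ±25 ms. Peaks within 150 ms of the
record edges are not reported (the integration window is incomplete
there, and edge beats are dropped downstream anyway).

**RR artefact filtering** retains a beat iff both its adjacent RR
intervals lie in 300–2000 ms; first/last beats lack one RR and are
always dropped. NN intervals are the retained RRs — exclusion only, no
ectopy interpolation.

**Beat segmentation** extracts −200..+340 ms windows around each
R-peak (271 samples at 500 Hz, R at index 101), baseline-subtracted
using the per-beat TP-segment mean (from +340 ms after the current R
to −200 ms before the next; global median fallback when tachycardia
empties the window).

**The 17-feature registry.** The measurement windows partition the
beat segment: P wave −200..−60 ms (signed extremum), QRS −60..+60 ms
(R = maximum; Q/S = minima before/after R), ST level and slope over
+60..+100 ms, T wave +120..+340 ms (signed extremum). Durations use
10%-of-peak threshold crossings; QT runs from Q onset to T end;
`beat_rms` summarises the whole window. These boundaries are fixed
configuration constants — field conventions vary and no single
published standard pins them down; the choice here simply partitions
the printed segment window. The registry is an explicit ordered list
(`feature_registry()`) so alternative counts (e.g. a 16-feature
variant) can be reproduced by subsetting.

**Ultra-short HRV.** From ≤10 s of NN intervals: MeanNN, SDNN (sample
SD), RMSSD, Poincaré `SD1 = RMSSD/√2` and
`SD2 = √(max(0, 2·SDNN_pop² − SD1²))` (population SD inside the SD2
identity, the standard Poincaré geometry), approximate entropy with
`m = 2`, `r = 0.2·SDNN_pop`, and mean HR `60000/MeanNN`. The `/√2`
form of SD1 is used rather than the occasionally-printed `/2`: it is
the geometric identity, and typical reported median pairs (e.g.
RMSSD 4.1 → SD1 3.0; 23.5 → 17.6) are consistent with `/√2` only.
Ultra-short windows make RMSSD/SD1 reliable but SDNN/SD2 unstable;
interpret accordingly.

## 3. Spanish IDSA/ATS criterion extraction

Notes are normalised (lowercasing; folding of accented vowels, ñ
preserved because it is semantic in Spanish; unicode subscript digits
to plain digits; punctuation runs to single spaces) with an offset map
so matched spans can be reported against the raw text.

Detection is two-tier: **V1** fires iff any dictionary regex matches;
**V2** additionally fires when a context rule's anchor and companion
co-occur within a token distance (default 5 tokens — compound
expressions like a numeric PaO2/FiO2 value near its anchor). Context
rules only add recall, so V2 detections are a superset of V1's on
every note, and — the central structural property — no detection is
possible without a lexical match: an absent keyword yields a false
negative, never a false positive. The test suite verifies FP = 0 on
corpora whose gold-negative criteria contain no dictionary token.

Negation is deliberately *not* handled; the synthetic corpus can plant
negated distractors (`negation_rate > 0`) which then produce
measurable false positives, documenting this known limitation as a
test rather than hiding it.

The severity score is `Σ weights of detected criteria + age
component`; weights (default 1 each) and the age rule (default +1 at
age ≥ 65) live in the YAML dictionary, because published severity
scorers of this family do not disclose their exact weighting — the
score definition is therefore explicit and swappable. The shipped
dictionary (3–8 patterns per criterion) is illustrative, assembled
from standard Spanish clinical phrasing; it is not any study's
production lexicon.

Agreement statistics report per-criterion confusion matrices, raw
agreement, and Cohen's κ with the simple large-sample standard error
`SE = √(p_o(1−p_o)/(n(1−p_e)²))` and κ ± 1.96·SE intervals; the
overall κ pools all criteria's labels. Degenerate margins (`p_e = 1`)
return an undefined-κ status rather than a number.

## 4. CAM lung-compromise quantification

The module contract starts at a `(mask, activation map)` pair — the
upstream classifier is out of scope, which makes the ratio statistic
testable without model weights. A pixel is *activated* when its value
strictly exceeds the threshold `T` ("exceeds" is read as strict, so
boundary pixels at exactly `T` do not count — documented because it
matters for planted fixtures). Per-lung compromise ratio and total
compromise ratio are reported in percent (the ×100 convention).

Lungs are split by connected components when the mask has exactly two
(sides assigned by centroid column under the radiographic convention:
image-left = patient right; a flag flips this), else at the
bounding-box midline with midline pixels going left — a deterministic
tie-break.

Threshold selection is leave-one-out: for each held-out image the grid
threshold (default 0.05..0.95 step 0.05; the grid is a choice, not a
published value) maximising mean Dice over the remaining images is
chosen and the held-out Dice recorded; pixelwise AUROC is threshold-
free (rank statistic of raw activations vs gold labels within the
lung). Dice of empty-vs-empty masks is defined as 1 — both raters
agree on absence; the alternative (0 or NaN) would penalise correct
negatives.

## 5. Association statistics

* **Per-SD logistic ORs** (`logistic_or_per_sd`): continuous features
  are standardised by the *sample* SD before a maximum-likelihood
  simple logistic fit; binary features are unscaled, making the OR the
  familiar contingency cross-product (verified to 1e-6 in tests).
  Wald 95% CIs throughout — the primary bivariate table carries no
  multiplicity correction by design (FDR belongs to the analyses that
  use it: mixed-model features, lead-by-lead tests, pointwise tests).
  Detected separation returns a status directing the caller to the
  Firth fit.
* **Firth penalised logistic regression**: Newton iteration on the
  Jeffreys-modified score `U*(β) = X'(y − π + h(½ − π))` with
  step-halving on the penalised likelihood; convergence at gradient
  max-norm < 1e-8. For a saturated 2×2 design this is exactly the
  Haldane +0.5-per-cell corrected cross-product, which the tests
  verify along with a brute-force grid maximisation of the written
  penalised likelihood. Wald CIs by default (profile intervals were
  considered and left out: the sensitivity-model role here needs
  finite, stable estimates more than exact coverage).
* **Random-intercept LMM** (`lme4::lmer`, REML): each standardised
  feature is regressed on the outcome with a patient random intercept.
  The *response* is standardised (not the predictor) — with a binary
  fixed effect this makes β a standardised group difference, which is
  the natural reading of "standardised β". p-values use the Wald
  normal approximation (no Satterthwaite machinery in the dependency
  set; with hundreds of beats the difference is negligible).
* **Pointwise patient-label permutation test**: group mean difference
  of patient templates at each time sample; labels are permuted at the
  patient level only (beats within a patient are never exchangeable).
  When the number of distinct label assignments is ≤ `n_perm` the test
  enumerates them exhaustively (exact for small cohorts, p =
  count/total including the observed assignment); otherwise seeded
  Monte-Carlo with the add-one estimator `p = (1 + #{|Δ*| ≥
  |Δ|})/(B + 1)`, which is never zero and is exactly valid under the
  null. BH-FDR across time samples.
* **BH-FDR** is implemented directly (step-up with cumulative minima)
  and property-tested against a literal double-loop of the
  definition.
* **Rank comparison**: Mann-Whitney, exact when `n_A·n_B ≤ 400`
  without ties, normal approximation otherwise. The rank-biserial
  effect size is `r = 1 − 2U/(n_A n_B)` with `U = #{a > b}`; under
  this convention `r = +1` when A is stochastically *smaller*. The
  convention is stated because the sign is reported inconsistently
  across the literature; what matters and is tested is the magnitude
  and the documented direction.
* **Table-1 builder**: Shapiro-Wilk normality screen per group
  (means + t-test when both pass, medians \[Q1, Q3\] + Mann-Whitney
  otherwise); categorical cells use Fisher's exact test when any
  expected count is below 5, chi-squared otherwise.

## 6. What the synthetic generators state, and what a green test means

The generators are a *stated world*, not tuning knobs; their defaults
encode the conditions of the emulated clinical setting and are not moved
to make tests pass.

* `gen_ecg_signal`: sum-of-Gaussians PQRST beats (P at −160 ms,
  σ 25 ms; Q/R/S at −30/0/+30 ms; T at +230 ms, σ 40 ms; smoothed ST
  plateau over ~+40..+120 ms) on a flat TP baseline at 500 Hz. The RR
  process is either a deterministic alternation (`±RMSSD/2`, whose
  sample RMSSD equals the target exactly — the closed-form oracle) or
  AR(1) jitter (φ = 0.5) with hard clipping to 300–2000 ms so the
  physiological filter is exercisable. Infeasible combinations
  (mean RR ± jitter outside the range) are rejected. Default
  amplitudes (P 0.15, R 1.0, S 0.25, T 0.3 mV) are ordinary adult
  lead-II magnitudes. This is *not* a pathophysiological simulator: no
  respiratory modulation, no ectopy, no noise unless requested — a
  green round-trip test establishes digitisation fidelity, not
  clinical realism.
* `render_ecg_page`: standard grid (1 mm light / 5 mm darker lines),
  dark polylines with Bresenham-style stroke splitting so per-column
  ink centroids track the sampled ordinate, 3×4 + rhythm-strip or
  stacked single-panel layouts, manifest with exact panel origins. The
  page geometry is a stand-in, not a reconstruction of any specific
  device's printout.
* `gen_notes_corpus`: gold criterion flags drawn per prevalence;
  positives receive a dictionary plant phrase except with probability
  `fn_plant_rate` (planted false negatives — the mechanism behind
  downward-biased severity scores); gold negatives never receive a
  token unless `negation_rate > 0` inserts negated distractors. Plant
  phrases come from the same YAML the scorer reads (single source of
  truth).
* `gen_lung_activation`: two disjoint elliptical lungs; exactly
  `round(fraction · n)` pixels per lung are drawn strictly above the
  threshold — the planted fraction is recoverable by counting to
  within one pixel.
* `gen_cohort`: iid standard-normal features, logistic outcome with
  slopes `log(OR)` and the intercept solved by `uniroot` so the
  expected event rate hits the target (default 15.7%, a typical severe
  pneumonia in-hospital mortality). Parameter-recovery tests fit one
  planted feature at a time: fitting marginal one-feature models in a
  multi-feature world would confound the check with logistic
  non-collapsibility, which is a property of the estimand, not an
  implementation defect.

All generators restore the caller's RNG state and are bit-reproducible
under a fixed seed; the pipeline derives per-stage seeds from the
master seed, so whole-run outputs are byte-identical across runs.

## 7. The end-to-end pipeline

`run_pipeline` generates a cohort with three latent per-SD effects
(total compromise ratio, severity, heart rate; defaults 2.0 / 1.5 /
1.5 — moderate, detectable-at-scale effects), synthesises each
modality's raw data *from the latent values* (consolidation fraction
via a probit link capped at 60% involvement; criterion count
proportional to latent severity; simulated heart rate 85 + 12·z bpm
clipped to 45–150), then recomputes every feature from the raw data
through the full analysis chain — digitisation included — before the
association layer runs. The ECG sub-cohort (default 27 of 121)
mirrors the typical availability of archived paper ECGs and makes the
missingness report meaningful (ECG columns ~78% missing in the full
cohort, flagged by the strict >20% rule).

## 8. Known limitations

* The digitiser assumes axis-aligned pages (skew beyond ±2° is out of
  scope) and panel locations from a manifest/config; no OCR.
* The regex NLP layer cannot resolve negation, abbreviation ambiguity
  or regional terminology variation; V2 context rules only add recall.
* Approximate entropy on <10 intervals is noisy; SDNN/SD2 from 10 s
  windows are reported but unreliable by construction.
* LMM p-values are Wald-normal; for very small patient counts they are
  anti-conservative relative to Satterthwaite/Kenward-Roger.
* The synthetic world is idealised (clean traces, disjoint elliptical
  lungs, template notes); green tests establish computational
  correctness and statistical calibration, not performance on real
  scans or prose.
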