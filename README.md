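# pneumabio

Multimodal digital biomarkers for in-hospital pneumonia mortality
analysis.

Severe pneumonia outcomes are routinely assessed from three data
streams that low-resource hospitals already have: chest radiographs,
unstructured Spanish clinical notes, and paper ECG printouts archived
as scans. `pneumabio` implements, as tested reusable R components, the
full computational chain that turns those raw artefacts into
quantitative mortality-associated biomarkers:

* **Paper-ECG digitisation** — grid-based scale calibration
  (autocorrelation of intensity projections, 25 mm/s and 10 mm/mV
  clinical calibration), grid-suppressed trace extraction by
  intensity-weighted centroids, resampling to 500 Hz, and zero-phase
  0.5–40 Hz Butterworth band-pass filtering.
* **Beat morphology and ultra-short HRV** — Pan-Tompkins R-peak
  detection, physiological RR filtering (300–2000 ms), beat
  segmentation over −200..+340 ms around the R-peak, a 17-feature
  morphology registry (RR context, P/QRS/T amplitudes and durations,
  ST level/slope, QT), group beat templates, and 10-second HRV metrics
  (MeanNN, SDNN, RMSSD, Poincaré SD1 = RMSSD/√2, SD2, ApEn).
* **Spanish IDSA/ATS severity scoring** — text normalisation
  (lowercasing, diacritic folding), dictionary regular expressions for
  the nine modified IDSA/ATS criteria (V1) plus context-window rules
  (V2), a configurable severity score with age component, and
  agreement statistics (confusion matrices, Cohen's κ with 95% CI).
  The matcher is structurally conservative: an absent keyword can only
  produce a false negative, never a false positive.
* **CAM lung-compromise quantification** — per-lung compromise ratio
  `CR_L = 100 · #{activation > T within lung L} / #lung L pixels`,
  total compromise ratio over both lungs, midline/component lung
  splitting, and leave-one-out cross-validated threshold selection
  (Dice + pixelwise AUROC) against gold consolidation masks.
* **Association statistics** — per-SD simple logistic odds ratios with
  Wald CIs, Firth penalised logistic regression (finite under
  separation), random-intercept linear mixed models for beat-level
  features, pointwise patient-label permutation tests, Benjamini–
  Hochberg FDR, Mann-Whitney tests with rank-biserial effect sizes,
  and a Table-1 style descriptive comparison builder.
* **Synthetic data generators** for every input (ECG pages rendered on
  a standard mm grid, Spanish notes with gold labels, lung
  masks/activation maps with planted fractions, cohorts with planted
  per-SD logistic effects), so the entire pipeline is testable with
  known ground truth and no patient data.

## Worked example

```r
library(pneumabio)

## ECG branch: simulate a tachycardic low-HRV patient, print the page,
## digitise it back, and compute HRV
tr <- gen_ecg_signal(ecg_sim_params(mean_hr = 110, rmssd_target = 6,
                                    duration = 10, seed = 1))
page <- render_ecg_page(tr, page_render_spec(px_per_mm = 5))
sig  <- digitise_page(page$image, page$manifest)[["II"]]
beats <- filter_rr(detect_r_peaks(sig))
hrv <- hrv_metrics(beats$rr_prev)
#> detected 16 beats; mean HR 109.8 bpm; RMSSD 5.9 ms; SD1 4.2 ms

## CXR branch: planted consolidation fractions are recovered by Eq.-style
## pixel counting at threshold T = 0.20
lung <- gen_lung_activation(c(128, 128), 0.42, 0.31, seed = 2)
cr <- compromise_ratios(lung$activation, split_lungs(lung$mask), 0.20)
#> CR left 42.0%, CR right 31.0%, TCR 36.5%

## NLP branch: criterion detection + severity score
m <- match_criteria("paciente con taquipnea y choque séptico, pafi de 230")
names(which(m$detected))
#> "septic_shock" "tachypnea" "pao2_fio2"
severity_score(m, age = 72)
#> 4        # three criteria + age >= 65 component

## Association: a planted per-SD OR of 2.0 is recovered
co <- gen_cohort(cohort_sim_params(n = 2000, or_per_sd = c(tcr = 2.0),
                                   seed = 3))
logistic_or_per_sd(co$tcr, co$death, name = "tcr")
#>   feature   or    ci_lo    ci_hi      p_raw
#>       tcr 1.99     1.74     2.27    9.0e-25
```

The digitised mean HR (109.8 bpm) and RMSSD (5.9 ms) recover the
planted simulation parameters (110 bpm, 6 ms) through the full
print-scan-digitise loop; the compromise ratios match the planted
fractions exactly up to pixel rounding; and the per-SD odds ratio CI
brackets the planted effect.

An end-to-end synthetic study (cohort generation, all three branches,
association report) runs with:

```r
report <- run_pipeline(run_config(seed = 1, n = 121, ecg_n = 27))
report$association     # per-SD ORs with CIs and q-values
report$firth           # 3-predictor penalised sensitivity model
report$permutation     # pointwise beat-template permutation test
```

## Layout

* `R/` — implementation; one file per analysis stage.
* `inst/extdata/idsa_dictionary.yaml` — illustrative Spanish criterion
  dictionary (patterns, weights, context rules, plant phrases).
* `inst/cli/pneumabio` — small command-line front end
  (`synth-notes`, `synth-cohort`, `synth-cam`, `cxr-ratio`,
  `idsa-score`, `run`).
* `vignettes/methods.Rmd` — model assumptions, parameter choices,
  numerical decisions and limitations.
* `tests/testthat/` — unit, property and acceptance suites.
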