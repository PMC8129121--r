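---
title: "Resting-state alpha biomarkers of schizotypy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state alpha biomarkers of schizotypy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Individuals with high schizotypal personality traits carry an elevated
risk of developing schizophrenia-spectrum psychosis. Resting
(eyes-closed) EEG offers a cheap, task-free window on the alpha rhythm
(7–13 Hz), whose generators and long-range fronto-parietal coupling are
altered in schizophrenia. `restingalpha` implements a complete analysis
that asks whether four alpha-band quantities separate high- (HSG) from
low-schizotypy (LSG) individuals:

* **IAF** — the individual alpha frequency, the peak of the resting
  power spectrum in 7–13 Hz, per region of interest;
* **alpha amplitude** — the maximum alpha-band power, expressed as
  $10\log_{10}(\mu V^2)$;
* **wPLI** — the weighted phase lag index between frontal and
  parieto-occipital electrode clusters,
  $\mathrm{wPLI} = |\langle \Im S_{xy}\rangle| / \langle |\Im
  S_{xy}|\rangle$ over 2500 ms windows, a phase-coupling measure in
  $[0,1]$ that discards zero-lag (volume-conduction) interactions;
* **TLI** — the time lag index, the circular-mean cross-spectral phase
  converted to milliseconds at the evaluation frequency,
  $\mathrm{TLI} = 1000\,\arg(\sum_w S_{xy})/(2\pi f)$; its sign encodes
  which signal leads.

Features feed a mixed-design ANOVA / planned-comparison battery and a
nested stratified cross-validated pattern classifier.

## Regions of interest

Four electrode clusters over a 10–20 montage: left frontal
(F1, FC1, C1, FC3), right frontal (F2, FC2, C2, FC4), left
parieto-occipital (PO7, PO3, O1), right parieto-occipital
(PO8, PO4, O2). ROI time series come either from the raw cluster mean
(`mode = "cluster-average"`, the default) or from decomposition
components matched to spatial templates at |Pearson r| ≥ 0.80 (one to
three components per template) and back-projected
(`mode = "backprojection"`). The decomposition itself (e.g. ICA) is not
performed by this package; precomputed component sets are accepted. The
two modes agree closely (series correlation > 0.9) on data whose
sources are genuinely cluster-localised.

## Signal processing parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| band-pass | 6–14 Hz, Hamming FIR, zero phase | order `3.3·fs/2 Hz` | alpha band with margin; forward–backward filtering leaves zero group delay |
| resampling | 500 Hz | polyphase | common acquisition rate for the analysis |
| spectral epochs | 2000 ms, non-overlapping | — | resolves the alpha peak while averaging noise |
| periodogram | Hann taper, zero-padded to 0.05 Hz grid | — | a 0.24 Hz smoother needs a grid finer than the native 0.5 Hz epoch resolution |
| SG smoothing | ±0.24 Hz window, order 5 | `signal::sgolayfilt` | standard alpha-peak preprocessing |
| peak rule | strict local maximum of the smoothed dB curve in 7–13 Hz | — | a monotone 1/f spectrum yields a missing IAF, not a spurious edge value |
| amplitude | max of the *raw* dB spectrum in 7–13 Hz | — | amplitude is defined as maximum power, not smoothed power |
| connectivity windows | 2500 ms, non-overlapping | — | 48 windows from a 120 s recording |
| evaluation frequency | nearest FFT bin to the mean posterior IAF | 10 Hz fallback | connectivity is evaluated at the subject's own alpha frequency |

Subjects with no detectable alpha peak in any ROI are excluded listwise
(with a logged count) before statistics and classification.

The three wPLI features are means of electrode-pair wPLI over
inter-cluster pairs (left intra-hemispheric 4×3, right intra-hemispheric
4×3, inter-hemispheric posterior 3×3); the full 14×14 matrix is kept for
reporting. TLI is computed once per pair on cluster-mean series —
averaging phase *signals*, not phases — because circular averaging of
near-antiphase pairwise lags is unstable. The first signal is the
frontal one within hemispheres and the left posterior for the
inter-hemispheric pair, so positive TLI means the first (frontal / left)
signal lags.

## The synthetic cohort generator

The package ships a generative model whose sole purpose is to exercise
every pipeline stage against known ground truth, emulating the group
effects the analysis is designed to detect:

* each ROI carries a narrow-band alpha source: white noise spectrally
  shaped by a Gaussian mask (σ = 0.25 Hz) around the subject's IAF,
  scaled to a configured RMS amplitude (a pure-sinusoid mode exists for
  exact oracle tests);
* within each hemisphere the frontal alpha component mixes a
  time-shifted copy of the posterior driver (weight = coupling
  strength, shift applied as an exact frequency-domain fractional
  delay) with an independent component; positive lag ⇒ frontal lags
  posterior;
* every source receives an independent 1/f background (exponent 1,
  5 µV RMS) and every channel independent white sensor noise (1.5 µV);
* sources project to the montage through fixed Gaussian-falloff
  topographies (σ = 0.25 planar units) peaking over their own cluster —
  deliberately sharper than real volume conduction so that
  backprojection and cluster averaging agree, as the pipeline assumes;
* per-subject parameters are drawn independently per ROI/hemisphere
  from configured normal distributions; IAFs are clipped to 7–13 Hz and
  lags to the half-period wrap-ambiguity bound.

### Shipped group configurations

The default `default_group_configs()` encode the reported group-level
contrasts. Printed cell means are used directly; unprinted cells are
derived from the printed marginal means under the assumption that they
carry no group asymmetry (e.g. frontal IAF, HSG posterior-left IAF, LSG
posterior amplitude). Dispersions:

* IAF SDs convert the printed standard errors (SD = SE·√24:
  0.69–0.83 Hz);
* amplitude SD is 20% of the mean (≈1.7 dB). The printed amplitude SEs
  (≈1.5 dB → SD ≈ 7.4 dB) are dominated by a global per-subject
  amplitude factor shared across ROIs; with the generator's independent
  per-ROI draws that value would contradict every printed
  within-subject contrast (the posterior L–R asymmetry of d ≈ 0.43
  pins the per-ROI dispersion near 1.7 dB), so the within-subject
  contrasts were taken as binding;
* lag means are +7.04 ms (HSG right), −11.21 ms (LSG right) and −8 ms
  (both groups left, unreported — frontal leading as in the LSG right),
  with SDs from SE·√24 (≈21–23 ms);
* coupling strengths (L = 0.30 both groups; R = 0.12 HSG, 0.40 LSG)
  were calibrated once so the right-hemisphere wPLI contrast matches
  the reported effect size (d ≈ 0.9) and ~2× group ratio. The reported
  absolute wPLI means (0.08 / 0.15) lie *below* the small-sample bias
  floor of the plain wPLI estimator at 48 windows (≈0.11 for
  independent signals), so absolute levels are not reproducible at this
  recording length — direction and ratio are.

What the generator does **not** emulate: ocular/muscle artifacts,
volume-conduction mixing beyond the Gaussian falloff, non-alpha
rhythms, non-stationarity, or a shared per-subject amplitude factor.
Passing tests on synthetic cohorts therefore demonstrate estimator and
protocol correctness, not robustness to real-world artifacts.

## Group statistics

`mixed_anova_222()` fits the 2 (group) × 2 (hemisphere) × 2 (region)
mixed design through `stats::aov` error strata
(`Error(subject/(hemisphere*region))`); partial
$\eta^2 = SS_e/(SS_e + SS_{err})$ with 90% CIs from noncentral-F
inversion. Both within factors have two levels, so no sphericity
correction is required. `group_ttest()` wraps pooled-variance /
paired `t.test` and adds Cohen's d via the t-conversion
($d = t\sqrt{1/n_1+1/n_2}$ independent, $t/\sqrt n$ paired — the
conversion that reproduces every printed effect size) with
noncentral-t 90% CIs. One-tailed directions are explicit arguments.
Dunn–Šidák thresholds $1-(1-\alpha)^{1/k}$ use k = 4 for the alpha
activity family and k = 3 for connectivity.

## Nested stratified cross-validation

The classifier protocol selects, in an inner stratified 10-fold loop on
each outer training set, the (feature combination, family, C) triple
maximising mean balanced accuracy; families are an L2-regularised
logistic regression (`glmnet`, λ = 1/(nC)) and a linear C-SVM
(`e1071`), C ∈ {0.1, 0.2, 0.3}. The winner is refit on the outer
training set and scored once on the untouched outer fold;
standardisation is fit on training rows only at every level. Ties
prefer fewer features, then lower C, then logistic regression
(parsimony, determinism). The 15-entry combination catalogue is the
product of hemisphere scope {left, right, both} and five feature-family
sets; it is config-driven because the original list is not fully
recoverable. Inner fold counts shrink automatically when a stratum is
too small; the procedure repeats `n_repeats` times with fresh
stratified folds.

Two structural guarantees are asserted by tests: corrupting an outer
test fold's feature values never changes that fold's selected model,
and the scaler applied to a test fold is computed from training rows
only.

A statistical point worth recording: nested CV evaluated on a *fixed
label permutation* of one cohort is biased below chance, because a
chance association in a training split implies the opposite association
in the held-out remainder of the finite cohort. Null calibration
therefore uses independently drawn null cohorts (features carrying no
group information), for which the outer estimate is exactly unbiased at
0.5.

## Problem sizes used by the shipped tests and acceptance script

Simulated cohorts are 24 subjects per group, 120 s eyes-closed
recordings at 500 Hz over the 14 cluster electrodes (feature extraction
touches only those; sensor noise is independent per channel, so omitting
the other channels of a dense montage changes nothing statistically).
Direction-recovery checks use 20 seeded cohorts; CV checks use 1–10
repetitions of the nested procedure (the full 1000-repetition protocol
is available through `n_repeats`). On one CPU a cohort takes ~15 s to
generate and extract and a CV repetition ~9 s.

## Known limitations

* The CORRMAP-style template matching is single-pass at the 0.80
  threshold; the original multistep refinement is not reconstructable.
* Multiple matched components are summed before back-projection; the
  original combination rule is unstated.
* The plain (not debiased) wPLI is used, so short recordings carry a
  positive bias floor; group *contrasts* remain valid.
* The strict-local-maximum IAF rule omits the gradient-based peak
  quality criteria of larger peak-fitting toolchains.
* EDF/BrainVision ingestion is not included; recordings enter as
  delimited channel×time text with a JSON sidecar (the package's
  canonical interchange format) or as in-memory matrices.
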