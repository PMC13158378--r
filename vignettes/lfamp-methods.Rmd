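---
title: "Low-frequency amplitude mapping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-frequency amplitude mapping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfamp)
```

`lfamp` implements a complete resting-state BOLD amplitude analysis: spectral
amplitude metrics (ALFF, fALFF, tSNR) with confound regression, motion quality
control by framewise displacement, test–retest repeatability (ICC and
Bland–Altman), voxelwise two-group inference with permutation-based
family-wise-error control, and seed-based functional connectivity with a
per-region mixed-effects group model. A synthetic cohort generator with known
ground truth makes every stage testable without real imaging data. This
vignette explains the models, the fixed numerical conventions, and the design
decisions that were genuinely open.

## Spectral amplitude metrics

For a voxel time-series $x_t$, $t = 0, \dots, N-1$, sampled at repetition
time $\Delta t$, let $X_k$ be the DFT of the demeaned series and
$f_k = k/(N\Delta t)$. The contribution of positive-frequency bin $k$ to the
time-domain mean square is $w_k |X_k|^2$ with $w_k = 2/N^2$ (halved at the
Nyquist bin for even $N$). With the low-frequency band
$B = \{k : 0.008 \le f_k \le 0.1\ \mathrm{Hz}\}$ (inclusive edges, DC always
excluded):

$$\mathrm{ALFF} = \Big(\sum_{k \in B} w_k |X_k|^2\Big)^{1/2}, \qquad
\mathrm{fALFF} = \Big(\sum_{k \in B} w_k |X_k|^2 \Big/
\sum_{k > 0} w_k |X_k|^2\Big)^{1/2}.$$

ALFF is therefore the RMS amplitude of the ideally band-limited signal (a
pure in-band sinusoid of amplitude $A$ gives $A/\sqrt 2$), and fALFF is the
fractional band amplitude, bounded in $[0,1]$ before normalization.
"Average power" phrasings of these metrics are ambiguous between the power
and amplitude scales; the RMS (amplitude) scale is the convention of the
original ALFF literature and of the widely used toolboxes, so it is the
default here, with `power_scale = "power"` available. Whole-brain
normalization divides each map by its in-mask mean, which makes monotone
scale choices irrelevant for group contrasts — but the scale must be fixed
and stated, and it is.

Fixed numerical conventions:

* plain periodogram, no taper; Welch-style averaging is out of scope;
* band edges inclusive (`low <= f <= high`), so the bin assignment is
  deterministic at exact band-edge frequencies;
* the fALFF denominator is every positive-frequency bin up to and including
  Nyquist, DC excluded (a DC term would make the ratio mean-dependent);
* zero-variance voxels get fALFF 0 (flagged) and a `+Inf` tSNR sentinel that
  downstream stages mask out;
* voxel indices and frame indices are 0-based in all reports; time windows
  are half-open.

## Confound regression without detrending

Candidate nuisance regressors — six rigid-body motion parameters plus mean
CSF-like and white-matter-like series — are centered, variance-scaled, and
jointly reduced to six principal components, which are projected out of every
voxel (OLS, intercept included). Polynomial detrending is deliberately
absent: detrending biases amplitude metrics and lowers their repeatability,
so slow drift must be tolerated by the metrics themselves (drift below
0.008 Hz leaves ALFF untouched and lowers fALFF, a direction asserted in the
tests). The voxel mean is re-added after regression so tSNR remains defined
on denoised data. Whether motion parameters should enter the PCA jointly
with the tissue series or be passed through raw is not settled usage; the
joint reading is the default and `joint_pca = FALSE` provides the
alternative.

## Motion quality control

Framewise displacement uses the bounding-box control-point method: six
control points at the face centers of a 140 × 180 × 115 mm box, each frame's
rigid transform applied to them, FD(t) the largest point displacement
between consecutive frames. Conventions fixed here: intrinsic rotations
about x, y, z in that order; rotation origin at the box center; the box
center defaults to the brain-mask centroid (deterministic and data-driven —
the method is usually described only as a box "around the brain");
FD(0) = 0. Under pure translations FD equals the step norm for any box
geometry, which the tests exploit as an exact oracle.

Frames are flagged when FD exceeds 0.5 mm or the frame-to-frame global
signal change exceeds 3 SD (union); sessions with more than 10% flagged
frames (strict inequality) exclude the subject. Flagged frames are retained
for the amplitude metrics by default — the exclusion operates at the subject
level, and frame censoring would change the spectral estimand; a censoring
variant can be layered on by callers if wanted.

## Group inference

Per voxel, an OLS model `value ~ intercept + group + covariates` gives the
group t statistic; scalar covariates (mean FD) enter per subject, voxelwise
covariates (gray-matter probability, global-BOLD coupling betas) per voxel.
The family-wise-error height threshold comes from a permutation maxT null:
group labels are permuted, the maximum |t| over the mask recorded, and the
(1−α) quantile taken. Random-field-theory corrections need a smoothness
model that nothing in this pipeline estimates; permutation is assumption-light
and exact under exchangeability, which is why it is the mechanism here (a
deliberate deviation from toolbox practice). Clusters are connected
components above the threshold (26-neighborhood by default, 6/18 available)
with a 10-voxel minimum extent. An optional uncorrected pre-mask exists but
is redundant whenever the FWE threshold is stricter.

Two calibration notes. First, the null condition for error-rate calibration
(`null_cohort_spec()`) sets a common TR in both groups as well as equal
effects: a TR difference alone changes the white-noise band fraction and is
a real, detectable acquisition effect — the acquisition-protocol confound
that two-site designs worry about — not a type-I error. Second, reported
confidence intervals for cluster summaries use the normal quantile
(mean ± 1.96 SD/√n), the convention under which published cluster summaries
of this kind reproduce exactly; Cohen's d uses the pooled-SD form.

## Repeatability

Maps are averaged within atlas regions (sentinel and non-finite voxels
excluded; an atlas-level exclusion list handles regions unresolvable at
acquisition resolution, rather than hard-coded labels). Test–retest
agreement uses ICC(2,1) — two-way random effects, absolute agreement,
single measure — computed from the two-way ANOVA mean squares. The citation
practice in this literature rarely names the form; ICC(2,1) is the form that
answers the absolute-agreement repeatability question two sessions pose.
Both "per region across subjects" and "per subject across regions" modes are
provided because both readings appear in applied work. Bland–Altman
differences are session 2 − session 1 (negative bias = decline), limits at
±1.96 SD.

## Seed connectivity and the mixed model

The seed is the largest surviving cluster from the fALFF group contrast
(falling back to the atlas seed region, with a warning, when nothing
survives). Correlation is computed on denoised, unsmoothed series; the
Fisher-z map is then smoothed at 6 mm FWHM — correlate, transform, then
smooth, in that order. Smoothing is mask-aware: the kernel is renormalized
over in-mask neighbors so values never bleed across the brain edge, plus a
global rescale that restores the in-mask mean exactly (the per-target
renormalization alone preserves uniform maps but not the mean at
boundaries; the rescale gives both).

Per region, connectivity is modeled as
`fc ~ group + sex + mfd + session + (1 | subject)` by REML, session
categorical with session 1 as reference, first group level and male-coded
sex as references. Wald p-values use a residual-df approximation
(observations minus fixed-effect count); with two observations per subject
and the sample sizes this model is meant for, the approximation is close to
normal and its exact flavor is immaterial — but it is fixed and documented.
Singular random-intercept fits fall back to OLS and are flagged. "One
multivariate model" phrasings of this analysis are implemented, as in
common practice, as one univariate model per region with FDR control across
regions; Benjamini–Yekutieli is the default (valid under dependence), with
Benjamini–Hochberg by flag. A positive group beta means the second group is
higher — the package fixes this convention explicitly because mixed
conventions (positive betas with negative t statistics) appear in published
tables of this kind and cannot be matched simultaneously.

## The synthetic cohort generator

`cohort_spec()` defines the emulated study: two groups of 70 (sex-balanced),
two sessions on separate days, TR 0.72 s (group 1) vs 0.8 s (group 2),
541-frame (~6.5 min) runs. Each in-mask voxel series is the sum of

* a **band-limited neural component** (Gaussian noise Fourier-restricted to
  0.008–0.1 Hz, SD `sigma_neural` = 10 au), scaled by `effect_band_amp`
  (default 1.2) for group 2 inside the designated regions;
* a **shared latent signal** coupling the seed region (strength 3) and two
  target regions (1.0 vs 1.5 by group) — the ground truth for the
  connectivity stage;
* **respiratory (0.3 Hz) and cardiac (1.1 Hz) sinusoids**; at TR 0.72/0.8 s
  the cardiac term aliases into low frequencies by construction, exercising
  the fALFF denominator exactly the way physiological aliasing does;
* a **global component** with voxelwise coupling betas ~ N(1, 0.3) — the
  target of the gBOLD control analysis;
* **slow drift** (0.003 Hz, on by default at small amplitude, because the
  pipeline never detrends and the fractional metric must tolerate it);
* **white noise** (SD `sigma_white` = 5 au), scaled by
  `effect_highfreq_amp` for group 2 — the second route by which a group can
  differ in fALFF (less high-frequency power raises the fraction), kept as
  its own knob;
* **motion spikes** (per-frame probability 0.01, 2 mm impulses) with
  coherent BOLD artifacts at the spiked frames;
* per-subject amplitude and noise factors (log-SD 0.1, stable across
  sessions — they carry the between-subject reliability) and a per-session
  gain factor (log-SD 0.05) that cancels in fALFF but not in raw ALFF,
  emulating scanner-gain variation between visits.

The physiological amplitudes are free parameters of the simulation — chosen
once at levels that leave the neural band component dominant, as in
reasonably clean 3T data — not claims about any real dataset. What the
generator does **not** emulate: anatomy, EPI distortion, T2* decay, k-space
artifacts, spatial autocorrelation of the noise floor. Passing tests
therefore demonstrate the correctness and calibration of the algorithms
under a controlled signal model, not performance on real scanner data.

The whole cohort is a deterministic function of the spec and one integer
seed, with per-stage/per-subject streams derived via `derive_seed()`, so any
stage can be rerun in isolation bit-identically.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script experiments are desk-scale by design:
error-rate calibration uses 10+10-subject null cohorts on a 16³ grid with
96-frame runs and 500 permutations (the calibration property does not depend
on run length); effect recovery uses the full 541-frame runs at 20 subjects
per group, where the planted 20% band-amplitude increase is comfortably
detectable; mixed-model recovery uses 30 subjects per group and 20 regions.
Full-size cohorts (70 per group) are generated the same way and are simply
larger.

## Known limitations

* Voxelwise covariates force a per-voxel OLS loop in the permutation step;
  fine at these grid sizes, slow for full-resolution brains.
* The mixed model's Wald p-values use a residual-df approximation rather
  than Satterthwaite/Kenward–Roger degrees of freedom.
* Mask-aware smoothing with the mean-preserving rescale slightly attenuates
  boundary gradients relative to infinite-support convolution.
* The generator's noise is white in space; spatial smoothness of real BOLD
  noise (and hence realistic cluster-size nulls) is not emulated.
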