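---
title: "Quantifying interictal iEEG to assess epileptic network focality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interictal iEEG to assess epileptic network focality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During presurgical evaluation of drug-resistant epilepsy, intracranial EEG
(iEEG) is used to decide whether the epileptic network is *focal* — a single
localized seizure-onset zone amenable to resection or ablation — or
*non-focal* (bilateral, multifocal, or broad), in which case neuromodulation
is usually preferred. This package implements a quantitative, interictal
(seizure-free) answer to that question: it maps spectral and connectivity
abnormalities of short interictal clips against a normative atlas, summarizes
their spatial dispersion over the electrode coordinates, and combines those
summaries with a pre-implant clinical score (the 5-SENSE score, consumed here
as a plain number) in a cross-validated classifier.

## The measures

**Per-clip features.** Each one-minute clip is re-referenced to a bipolar
montage along electrode shanks, band-pass filtered 0.5–80 Hz (3rd-order
Butterworth, applied forward–backward so the phase response is zero and the
effective roll-off doubles), notch filtered around 60 Hz, and resampled to
200 Hz. Relative band power and magnitude-squared coherence (MSC) are
estimated with Welch's method (2 s Hamming windows, 1 s overlap) in delta
(0.5–4 Hz), theta (4–8), alpha (8–12), beta (12–30) and gamma (30–80), plus
broadband (0.5–80).

**Abnormality z-scores.** A normative atlas stores, for every (ROI, band)
and (ROI-pair, band) cell, the mean and standard deviation of the feature
over contacts presumed healthy, pooled across subjects. A patient's contact
or contact-pair feature is converted to a z-score against the matching cell.
White-matter and outside-brain contacts are excluded before any feature is
computed. Only cells with at least two values and positive spread are
usable; unusable cells propagate as missing values, never as zeros.

**Spatial dispersion.** For contacts with coordinates $(x_i, y_i, z_i)$ the
*standard distance* (implant distance) is

$$\mathrm{SD} = \sqrt{\sum_i \frac{(x_i-\bar X)^2}{n}
  + \sum_i \frac{(y_i-\bar Y)^2}{n} + \sum_i \frac{(z_i-\bar Z)^2}{n}},$$

the 3-D standard deviation of the electrode cloud. The *weighted standard
distance* (abnormality distance) replaces the plain moments by moments
weighted with each contact's nonnegative abnormality $w_i$, about the
weighted mean center $\bar X_w = \sum_i w_i x_i / \sum_i w_i$. It reduces to
the SD for equal weights and contracts toward zero as abnormality
concentrates on one spot. Two numerical conventions deserve mention:

* **Square root.** The defining sums are variances (mm²); the statistic is
  reported as their square root so it is a distance in mm, consistent with
  its reading as a 3-D standard deviation. `sqrt = FALSE` returns the summed
  variance form.
* **Population variance.** The per-axis variance divides by $n$, not
  $n - 1$, matching the definition above.

Both statistics are translation- and rotation-invariant, scale-equivariant,
and invariant to rescaling of the weight vector; the test suite verifies
each property on random point clouds.

**Aggregation across clips.** Twenty clips give a distribution of z-scores
per contact. The per-contact weight used by the WSD is the median over clips
of $|z|$ (for node features), and the median over clips of the mean $|z|$
over incident edges (for coherence features). The reduction is the single
most consequential under-specified choice in this design: the weights must
be nonnegative for the WSD to be well defined, which forces $|z|$, and the
median is preferred for robustness to transient clips. Both reductions are
configurable (`median`/`mean`/`max`), and when patient data are actually
drawn from the atlas distribution the aggregated weights concentrate around
the half-normal median $\approx 0.674$, which the tests check by
simulation.

## Clip selection and wakefulness

Candidate windows tile the monitoring stay on a 60 s grid. Windows are
excluded inside the first 72 h after implantation and within ±2 h of any
seizure. Wakefulness is screened with the alpha/delta power ratio (ADR): the
log ratio of alpha to delta Welch power averaged over channels, z-normalized
across the patient's candidate windows; windows with normalized ADR ≥ −0.40
are eligible, and the requested number of clips is drawn uniformly among
eligible windows. The normalization scheme of the original detector is not
restated in the source describing this pipeline; per-patient z-scoring is
our concrete reading, and the threshold is exposed as configuration.

## The classifier

Three feature sets are compared: the clinical score alone; score + implant
distance; and score + the twelve abnormality distances (power and coherence
× six bands). The model is logistic regression with lasso (`l1`) penalty at
`C = 1` on the sklearn scale (`lambda = 1/(C·n)` in `glmnet`), evaluated by
leave-one-out cross-validation: each patient is predicted by a model trained
on all others, features are median-imputed and standardized with
training-fold statistics only, and the cross-validated AUC is computed on
the pooled out-of-fold probabilities. Ridge (`l2`) is available because both
penalties are plausible readings of the source pipeline's description; the
default is `l1`. A single-feature model (`sense_only`) is fit by unpenalized
`glm`, since a one-column penalized fit is not meaningful (and `glmnet`
requires two columns).

Model comparison uses DeLong's test for correlated ROC curves, implemented
via placement values and cross-checked in the tests against an independent
implementation (`pROC`) and a bootstrap oracle. The operating point reported
maximizes Youden's J, breaking ties toward the more sensitive threshold.

**A caution on null behavior.** Pooled leave-one-out probabilities are
pessimistically biased when there is no signal: the fold's intercept tracks
the held-out label (training on one fewer positive lowers every prediction
for held-out positives), so null-data AUCs center below 0.5 and spread
widely. This is a property of pooled LOOCV scoring itself, shared by any
faithful implementation of this evaluation scheme, not a defect of the
fitting code; the tests therefore check that the null seed-distribution
covers chance rather than that its mean equals 0.5. With genuine signal the
effect is negligible.

## The synthetic cohort generator

No patient data ship with the package; every downstream stage is exercised
on synthetic cohorts whose statistical structure mirrors the study
conditions the pipeline was designed for:

* 101 patients, 65 focal / 36 non-focal, allocated deterministically by
  rounded count so group sizes are exact;
* clinical score drawn from two unit-variance Gaussians separated by
  `effect_size_sense` (default 0.72, the strongest reported univariate
  separation);
* shank-structured electrode geometries (up to 8 contacts per shank, 4 mm
  pitch) inside a 140 × 170 × 120 mm bounding box — a plausible head scale,
  irrelevant to the invariance-tested statistics; focal implants are
  more compact (`implant_effect`, default 0.62 standardized units,
  equivalent to a univariate AUC of about 0.67), with a weak negative
  coupling to the clinical score that reproduces the observed score/implant
  correlation of about −0.2;
* abnormality weights: baseline half-normal $|z|$ noise at every contact,
  plus a boost on the gamma-power (and, attenuated, broadband-power and
  gamma/broadband-coherence) weights of ~15% of contacts — one tight
  cluster for focal patients, the *same total boost mass* split across two
  or more mutually distant clusters (or dispersed) for non-focal patients;
* therapy and 2-year ILAE outcome sampled at focality-conditional rates
  matching the reference cohort's characteristics table (surgery in 52/65
  focal, 11/36 non-focal; favorable outcome in 28/44 focal surgical and 5/8
  non-focal surgical patients; device patients draw ILAE 3–6, reflecting
  that neuromodulation rarely renders patients seizure-free);
* ECoG-implanted patients receive a larger abnormality boost
  (`ecog_effect_multiplier`, default 1.6), emulating the stronger effects
  observed with subdural implants.

`effect_size_wsd` (default 0.69) is the *standardized separation of the
gamma abnormality distance* between groups. The internal gain converting it
to a per-contact boost was calibrated once by simulating cohorts over a gain
grid (n = 1000–1500 patients) and matching the realized Cohen's d to the
requested value under the default conditions; the mapping saturates mildly
above ~1 (a requested 1.2 realizes ≈ 0.9–1.0) because the focal WSD cannot
contract below the cluster scale. Setting all effect parameters to zero
removes every group difference.

In `"feature"` mode the generator emits the contact-level weights directly —
cheap, and sufficient for testing dispersion, statistics and models. In
`"signal"` mode it synthesizes band-structured multichannel clips: each
channel sums band-limited Gaussian noise (FFT masking, exact band edges)
scaled to the requested relative band powers, with a per-band shared source
mixed in to induce coherence. With per-channel coherence level $c_i$, the
pair MSC is $\sqrt{c_i c_j}$; the mixing coefficient
$\alpha_i^2 = \sqrt{c_i}/(1-\sqrt{c_i})$ is exact for unit-variance private
noise, and abnormal channels receive a gamma-power multiplier and depressed
coherence.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no 1/f spectral background, spikes, high-frequency
oscillations or artifacts; no anatomically realistic parcellation (ROIs are
nearest-centroid cells of random points); abnormality distances are strongly
coupled to the implant distance (r ≈ 0.97) because the weighted dispersion
lives on the implant geometry, whereas real cohorts show the three measures
carrying more complementary information; and the therapy/outcome labels are
conditionally independent of the features given focality, so
therapy/outcome prediction runs at more attenuated AUCs than a real cohort
in which clinicians act on the same information the features encode.

## Numerical choices

* Band intervals are half-open $[lo, hi)$; on the 0.5 Hz Welch grid of a
  2 s window at 200 Hz, every band edge falls on a grid point, so
  trapezoidal band integrals share edge ordinates and the five narrow bands
  partition broadband to machine precision. The 60 Hz notch trough inside
  gamma is *not* excluded from the gamma integral.
* Band MSC is the unweighted mean of per-bin MSC over the band.
* The MSC bias floor for independent channels is $(1 + 2\rho)/K$ with
  $\rho \approx 0.054$ the squared window correlation of adjacent
  50%-overlapped Hamming segments — the plain $1/K$ floor understates the
  bias of overlapped Welch.
* Resampling to 200 Hz is exact Fourier (band-limited) resampling; the
  0.5–80 Hz band-pass provides the anti-aliasing margin. Upsampling is
  refused.
* Silent channels yield missing features, never 0/0; contacts with missing
  weights are dropped from the WSD rather than zero-weighted, since a zero
  weight would artificially shrink the dispersion; a feature with fewer
  than 3 weighted contacts yields a missing abnormality distance.
* One master seed fans out to per-stage seeds as
  `(seed + 7919 · stage) mod (2³¹−1)`, so pipeline stages are independently
  reproducible; a run directory's manifest records the configuration hash
  and an unchanged configuration reuses its simulated cohort.

## Problem sizes used by the test suite

The suite exercises dispersion oracles on 1,000 random clouds (3–200
points), spectral checks on 30–240 s synthetic recordings, the DeLong
bootstrap oracle at 10,000 resamples of a 50-subject sample, effect-size
fidelity at n = 2000 patients, and the model-improvement property on 20
cohorts of 100 patients — sizes chosen so each check is statistically
decisive while the whole suite stays lightweight.

## Limitations

Clip serialization is plain CSV (one channel per column, rate and onset in
a commented header); clinical-format I/O (EDF) and electrode localization
from imaging are out of scope, as are spike/HFO biomarkers, phase-based
connectivity, geodesic distances, and any harmonization across recording
sites. The atlas loader accepts the package's JSON schema, so externally
built atlases must be re-exported to it.
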