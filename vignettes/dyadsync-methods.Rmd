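---
title: "Models and methods behind dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dyadsync implements a complete analysis chain for studies of how observers
estimate movement synchrony in dyads: objective kinematic scoring of pose
time series, hierarchical Bayesian models of estimation error, an fNIRS
haemodynamic GLM, and models linking cortical responses to behaviour. Every
stage can be exercised on synthetic data with known ground truth. This
vignette explains the models, the defaults, and the design choices that were
genuinely open.

## Kinematic synchrony score

Each mover is tracked as seven upper-body joints (neck, shoulders, elbows,
hands) at 25 fps. Trajectories are smoothed with a Savitzky–Golay filter
(window 13 frames ≈ 0.5 s, polynomial order 2), which preserves quadratic
trends exactly while attenuating jitter. Per frame, the 21 pairwise
Euclidean distances between a mover's joints are computed (in a fixed
lexicographic joint-pair order, so serialisations are reproducible) and
divided by their sum. Distances remove absolute position; the L1
normalisation removes overall scale — so the representation is invariant to
a mover's height and distance from the camera.

The per-frame similarity between the two movers' normalised distance
vectors `a`, `b` is the total-variation similarity

    s = 1 − ½ Σ |a_i − b_i|,

which is exactly 1 for identical poses and exactly 0 for vectors with
disjoint support. Other choices (cosine, correlation) also map "identical"
to 1 but do not attain 0 at maximal disagreement on the simplex; the TV
form is the simplest metric-based function pinned down by both endpoints.
The synchrony score of a video is the mean similarity over frames, so it
lives in [0, 1].

Degenerate frames in which all joints coincide (tracking dropouts) yield
the uniform distance vector with a flag, rather than an error; this keeps
batch scoring robust.

Whether smoothing should precede metric computation is not fixed by the
stimulus pipeline (there it precedes rendering); the package smooths first
by default and exposes `presmooth = FALSE`.

## Movement complexity

Complexity is the sample entropy SampEn(m = 2, r = 0.2·SD), the standard
parameterisation of the estimator lineage, computed on each hand's x and y
trajectory for both movers — eight series — and averaged. Both template
counts use the first n − m start points, self-matches excluded. A constant
series returns 0 ("pure signal"); if no (m+1)-length template pair matches,
the estimator is undefined and `Inf` is returned rather than a silently
truncated value. The implementation is validated against exhaustive
brute-force template counting and against an independent established
implementation.

## Estimation error and the behavioural models

Estimation error is `D = 100·S − E`: measured synchrony scaled to the 0–100
slider, minus the observer's estimate. Positive values are
underestimation. All trait and kinematic predictors are z-scored (sample
SD, n − 1) before modelling; traits are standardised at the participant
level, once across the analysed sample rather than per condition, which
keeps interaction terms interpretable.

The trait model is a Gaussian hierarchical regression of trial-level error
on six traits, each crossed with condition, plus participant random
intercepts. Condition is coded performed = −½ / unknown = +½, so the
intercept is the grand-mean error; per-condition mean errors and their
contrast are derived draw-by-draw as linear combinations of coefficients.
The rating model has the same structure with enjoyment × condition,
complexity × condition and the recognition response as predictors.
Enjoyment and complexity enter in raw units by default (error units per
rating point and per entropy unit); a `standardize` argument applies
z-scoring, which is advisable for the entropy predictor whose raw-unit
slope can be large relative to the slope prior.

Priors are weakly informative at the 0–100 error scale: Normal(0, 20²) on
the intercept, Normal(0, 10²) on slopes, half-Student-t(3, 0, 10) on the
residual and random-intercept SDs. They are overridable per fit.

Sampling uses Gibbs updates with conjugate block updating of the linear
part (JAGS, glm module). Defaults are 4 chains × 1,000 post-warmup draws;
reduced, thinned runs (2 chains, 500 warmup, 1,000 kept draws) are used in
the package's own replicate studies. The group-level SD is the
slowest-mixing parameter when there are few groups; the `thin` option
exists for exactly that case. Convergence is checked with split-R̂ on every
parameter (threshold 1.01 at default settings; a failed check raises a
diagnostic error naming the parameters, and the threshold is configurable
because short exploratory runs can exceed it without being unusable).

All posteriors are summarised by the mean and the 95% highest-posterior-
density interval — the shortest contiguous window containing 95% of sorted
draws, never wider than the equal-tailed interval. An effect is
"substantial" when its HPD excludes 0, and a "trend" when the HPD overlaps
0 but less than 10% of posterior mass lies on the minority side — the
latter is an operationalisation choice, documented rather than claimed
exact.

## fNIRS signal chain

The chain mirrors standard continuous-wave processing:

1. **Optical density.** `OD(t) = −ln(I(t)/mean I)` per channel and
   wavelength, with the whole-recording mean as baseline. The package uses
   natural-log OD consistently in both the forward simulator and the
   inverse chain, so the two are exact mutual inverses.
2. **Motion-artifact repair (TDDR).** The signal is split into a
   low-frequency baseline and a residual; the residual's temporal
   derivative is iteratively reweighted with Tukey's biweight
   (4.685 × MAD-based SD) until the weights converge, reintegrated, and
   recombined. The baseline is a running median whose window matches a
   0.5 Hz passband rather than a linear low-pass: at a 2.6 Hz sampling
   rate a linear filter absorbs roughly a third of a one-sample spike into
   the baseline it keeps, while the median confines spikes entirely to the
   repaired residual and passes smooth haemodynamic signal through
   unchanged. A caveat that holds for any derivative-reweighting repair:
   on continuous Gaussian noise the reweighted increments no longer
   telescope, which injects a small low-frequency random-walk error and
   makes downstream GLM standard errors optimistic (about 2× in our
   simulations). The package therefore validates GLM error calibration
   with the repair stage disabled and keeps TDDR in the default chain for
   its artifact robustness.
3. **Modified Beer–Lambert law.** Per time point, a 2×2 linear system in
   the HbO/HbR concentration changes, using tabulated decadic extinction
   coefficients at 760 and 850 nm (shipped as a versioned table with
   source citation, scaled by ln 10 internally) and effective path
   `distance × PPF` with PPF = DPF/PVC = 6/60 = 0.1.
4. **GLM.** One regressor per condition — a 16-s boxcar at each event
   onset convolved with the canonical double-gamma HRF (response peak
   ≈ 6 s, undershoot 16 s, ratio 1/6), scaled to unit single-event peak so
   betas are amplitudes in µM; a discrete-cosine drift basis up to
   0.01 Hz; the leading principal components of the short-channel
   haemoglobin signals (as many as reach 95% cumulative variance, or a
   fixed count); and a constant. The noise model is AR(1) via
   Cochrane–Orcutt prewhitening: OLS, lag-1 residual autocorrelation,
   quasi-differencing, refit.
5. **ROI aggregation.** Channel estimates are combined per ROI with
   inverse-variance weights 1/SE² (SE_ROI = (Σ 1/SE²)^−½). "Weighted by
   the standard error" admits a 1/SE reading too; both are implemented,
   precision weighting is the default because it is the estimator-variance-
   minimising choice.
6. **HbO−HbR.** The difference codes response orientation: canonical
   (HbO up, HbR down), inverted, or same-sign (possibly extracerebral);
   same-sign estimates are retained by default (a flagging column supports
   exclusion downstream).

The scalp coupling index (cardiac-band correlation between a channel's two
wavelengths) is reported for every channel but never used for exclusion;
at 2.6 Hz the nominal 0.7–1.5 Hz cardiac band exceeds the 1.3 Hz Nyquist
frequency, so the upper edge is clipped just below Nyquist — SCI values at
this sampling rate are indicative only.

## Brain–behaviour models

Per-ROI HbO−HbR amplitudes are modelled as
`hbdiff ~ condition × ROI × mean estimation error + recognition rate +
mean enjoyment + (1 | participant)`, with behavioural predictors z-scored
across the analysed records, the participant × condition mean error
crossed with condition and ROI, the recognition rate defined as the
proportion of correct performed/unknown judgements, and condition coded
±½. Per-ROI error slopes for each condition, their average, and the
performed-minus-unknown contrast are formed as finite-difference contrasts
of the design matrix, so every reported slope is an exact linear
combination of coefficients and the contrast posterior equals the
difference of the condition-slope posteriors draw by draw.

The body-competence moderation model adds a body-competence × error
interaction and evaluates the error–activation slope at body competence
−1 SD, mean, and +1 SD, with pairwise differences.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated:

- **Dyads.** The leader's joint coordinates are rest positions plus
  mixtures of 3–6 random-phase sinusoids at ≤ 1 Hz — smooth, band-limited
  trajectories like improvised mirror-game arm movement, with trunk joints
  near-stationary (2–3 px amplitude) and hands mobile (40 px). The
  follower is the leader lagged, amplitude-scaled, plus i.i.d. Gaussian
  coordinate noise; this monotone mapping from coupling noise to synchrony
  is what makes score-monotonicity testable. What these dyads do **not**
  emulate: corrective coupling dynamics, occlusion artifacts, tracking
  noise correlated across joints.
- **Observers.** Latent error `D = intercept[condition] + Σ β_k z_k + u_i
  + ε`; estimates are `100·S − D` clamped to the slider range. Default
  intercepts (14.4/19.1 error units) and trait coefficients mirror the
  magnitudes reported for the study sample, so recovery studies run at
  realistic effect sizes; residual SD 10 and random-intercept SD 5 are
  plausible round numbers on the 0–100 scale (the study reports no
  generative values). Enjoyment is linearly linked to −D (slope 1, SD 10)
  and recognition is Bernoulli (hit rate 0.7, false-alarm 0.3); both links
  are stand-ins — the generative relation is not specified by any data we
  model — and are configurable.
- **fNIRS.** True HbO per long channel is amplitude × (boxcar ⊗ HRF),
  by the same regressor construction the GLM uses; HbR defaults to
  −HbO/3 (canonical polarity). Forward Beer–Lambert produces OD, then
  `I = I₀·exp(−OD)`. A shared superficial component (low-pass filtered
  noise, 0.3 µM SD, channel gains 0.5–1.5) appears in long and short
  channels alike; short channels carry no event-locked signal. White OD
  noise (5 × 10⁻⁴), linear drift (10⁻⁶ OD/s, random sign), and optional
  spike/shift artifacts complete the model. Defaults are magnitudes
  representative of a cooperative adult recording; evoked amplitudes
  default to 1.0 µM (performed) and 0.6 µM (unknown) across all ROIs.

## Problem sizes used in the package's own studies

Parameter-recovery and calibration studies run at the study's behavioural
scale (43 participants × 40 trials) with 20 replicates and reduced sampler
settings (2 chains, 500 warmup, 1,000 kept draws). fNIRS validation uses
compact montages (8–24 long channels covering the ROIs, 2–4 short
channels) and 8–12-video schedules, which exercise every code path at a
fraction of the full 78-channel cost; the full montage is the default for
real-scale runs. The demonstration pipeline configuration (`demo_config()`)
uses 12 videos, 12 observers and 3 fNIRS participants.

## Known limitations

- The 2-D pose representation ignores depth; no time-lagged or windowed
  synchrony measures are provided.
- The AR(1) noise model is an approximation; structured physiological
  noise that survives short-channel regression can leave standard errors
  optimistic (see the TDDR caveat above).
- SCI at 2.6 Hz cannot cover the full cardiac band.
- The observer simulator's enjoyment/recognition links are conveniences
  for testing, not claims about the generative process in humans.
- Passing recovery tests on these synthetic conditions demonstrates
  correctness of the estimators and plumbing, not robustness to every
  property of real recordings (motion coupling with true activation,
  optode drift, heterogeneous HRFs).
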