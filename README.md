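# dyadsync

Tools for studying how well observers estimate movement synchrony in dyads,
and what that estimation ability looks like in the brain. The package is
aimed at researchers in social neuroscience and movement science who work
with pose-keypoint time series, trial-level behavioural ratings, and
continuous-wave fNIRS recordings.

It provides four connected analysis stages, plus synthetic-data generators
with known ground truth for all of them:

1. **Kinematic metrics.** An objective movement-synchrony score from pose
   time series: per frame, each mover's 21 pairwise joint distances
   (7 upper-body joints) are L1-normalised — removing position and scale —
   and compared with total-variation similarity
   `s = 1 − ½ Σ|aᵢ − bᵢ|`; the frame average is the video's synchrony
   `S ∈ [0, 1]`. Movement complexity is the mean sample entropy
   SampEn(m = 2, r = 0.2·SD) over 2 hands × 2 axes × 2 movers.
2. **Estimation-error models.** The estimation error of an observer's
   0–100 rating `E` of a video with measured synchrony `S` is
   `D = 100·S − E` (positive = underestimation). Hierarchical Bayesian
   regressions (participant random intercepts, weakly informative priors,
   95% HPD summaries) link `D` to personality traits × condition, and to
   enjoyment, movement complexity and recognition.
3. **fNIRS GLM chain.** Raw two-wavelength intensities → optical density →
   motion-artifact repair (TDDR) → modified Beer–Lambert law (PPF =
   DPF/PVC = 0.1) → GLM with canonical-HRF condition regressors, cosine
   drifts ≤ 0.01 Hz, short-channel principal components, AR(1)
   prewhitening → inverse-variance ROI aggregation → HbO−HbR response
   amplitudes with canonical/inverted/same-sign categorisation.
4. **Brain–behaviour models.** `HbO−HbR ~ condition × ROI × mean
   estimation error + recognition rate + mean enjoyment +
   (1 | participant)`, with per-ROI condition slopes, aggregates and
   contrasts, plus a body-competence moderation analysis.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` for fitted models, `autoplot()` for results.

## Worked example

```r
library(dyadsync)

# a synthetic dyad: follower tracks the leader with coordinate noise
cfg  <- dyad_sim_config(n_frames = 250, follower_noise_sd = 6, seed = 3)
dyad <- generate_dyad(cfg)
synchrony_score(dyad$leader, dyad$follower)
#> [1] 0.9920721
synchrony_score(dyad$leader, dyad$leader)   # identical movers
#> [1] 1

movement_complexity(dyad$leader, dyad$follower)$value
#> [1] 0.5364344

estimation_error(measured = 0.70, estimate = 60)   # underestimation by 10
#> [1] 10

# estimation-error modelling on simulated observers at study scale
set.seed(1)
measured <- dplyr::mutate(generate_schedule(40, seed = 1)$videos,
                          synchrony = runif(40, 0.3, 0.95))
traits   <- simulate_traits(43, seed = 2)
trials   <- generate_observer_data(measured, traits,
                                   observer_sim_config(seed = 3))
fit <- fit_trait_model(trials, traits,
                       sampler = sampler_config(chains = 2, warmup = 500,
                                                iter = 1000, seed = 1,
                                                rhat_max = 1.05))
dplyr::filter(tidy(fit), grepl("mean_error|contrast", parameter))
#> # A tibble: 3 × 6
#>   parameter            estimate hpd_low hpd_high substantial trend
#>   <chr>                   <dbl>   <dbl>    <dbl> <lgl>       <lgl>
#> 1 mean_error_performed    14.2    12.5     15.6  TRUE        FALSE
#> 2 mean_error_unknown      18.9    17.4     20.5  TRUE        FALSE
#> 3 condition_contrast      -4.77   -5.74    -3.87 TRUE        FALSE
```

The simulated observers underestimate synchrony in both conditions (mean
errors ≈ 14 and 19 on the 0–100 scale, matching the generator's 14.4 and
19.1), and underestimate more for unknown than for performed movements
(contrast ≈ −4.8 error units, HPD excluding 0).

The full pipeline — dyads → metrics → observer trials → behaviour models →
fNIRS simulation and GLM → brain–behaviour model — runs from one config:

```r
manifest <- run_pipeline(demo_config(seed = 1), outdir = "demo_run")
```

writing five output tables and a `manifest.json` whose config hash makes
the run byte-for-byte reproducible.

See `vignettes/dyadsync-methods.Rmd` for the models, defaults, numerical
choices and limitations.

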