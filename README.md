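# indecision

Analysis tools for two-interval contrast judgments with an explicit
"don't know" opt-out (2-AFC-DK), built around the
**difference-with-indecision** signal-detection model. The package is aimed
at visual psychophysicists studying contextual effects on perceived
contrast — e.g. orientation-tuned surround suppression and its modulation by
binocular disparity — who need to turn trial-level categorical responses
into bias-robust estimates of perceived-contrast shifts and within-subject
group statistics.

## The model

On each trial the observer compares the contrast of a test grating and a
reference grating shown in two intervals, responding "reference higher",
"reference lower", or "don't know" (DK). The internal evidence is the
perceived contrast of the second interval minus the first,

    D ~ Normal( ±(x − μ), σ² ),

with `x` the physical reference-minus-test contrast (% Michelson), `μ` the
perceived-contrast shift of the test induced by its surround, and the sign
set by the presentation order. Two criteria δ₁ ≤ δ₂ partition `D` into the
three responses, giving six psychometric functions from four parameters
(μ, σ, δ₁, δ₂). The DK probability averaged over the two presentation
orders peaks exactly at `x = μ`, so the fitted `μ` estimates the perceived
contrast difference uninfluenced by interval or response bias.

The package provides:

* `response_probabilities()`, `indecision_nll()`, `fit_indecision()` — the
  closed-form model, multinomial likelihood, and constrained
  maximum-likelihood fit with multi-start; broom-style `tidy()`/`glance()`
  and `autoplot()` methods;
* `dk_peak()` — the order-averaged DK-curve maximum, with bimodality
  detection;
* `design_preset()`, `simulate_trials()`, `simulate_observers()`,
  `aggregate_counts()` — generative simulation of the balanced training and
  main-experiment designs (432 / 3,520 / 2,772 trials);
* `bump_spec()`, `bump_profile()`, `region_mean_disparity()`,
  `make_nonoriented_texture()`, `render_stereo_pair()` — deterministic
  stimulus geometry: the 21-ring quantized depth bump, disparity annuli,
  isotropic filtered-noise textures, and stereo-pair rasterisation;
* `rm_anova_2x2()`, `rm_anova_oneway()`, `posthoc_paired_bonferroni()` —
  within-subject group statistics on fitted parameters;
* `run_synthetic_study()`, `run_reanalysis()` — end-to-end reproducible
  pipelines (simulation-based, or re-analysis of deposited CSV data via a
  column mapping).

## Worked example

Simulate one observer under the 2 x 2 surround-suppression design, fit one
condition, then run a full 8-observer synthetic study:

```r
library(indecision)

trials <- simulate_trials(design_preset("exp1"), truth_preset("exp1"), seed = 7)
fit <- fit_indecision(dplyr::filter(aggregate_counts(trials),
                                    condition == "IsoFlat"))
fit
#> <indecision_fit>
#>   delta perceived contrast (mu): -9.387 %
#>   sigma: 5.147  delta1: -1.837  delta2: 1.890
#>   -logLik: 508.333  converged: TRUE  trials: 880
```

The fitted `mu` says this simulated observer perceives the 30%-contrast
test grating as about 9.4% lower in contrast than the bare reference when
embedded in an iso-oriented, same-depth surround (the generating value was
−9.25%); `sigma` is the internal noise and δ₁/δ₂ bracket the indecision
zone. A full group study chains simulation, fitting and inference:

```r
report <- run_synthetic_study("exp1", n_observers = 8, seed = 7)
report
#> <study_report> exp1
#>   seed: 7  config hash: 70260acc  version: 0.1.0
#>   group means (delta perceived contrast, % +/- SEM):
#>     CrossDepth    -4.39 +/- 0.34 (n = 8)
#>     CrossFlat     -4.50 +/- 0.43 (n = 8)
#>     IsoDepth      -7.11 +/- 0.35 (n = 8)
#>     IsoFlat       -8.29 +/- 0.41 (n = 8)
#>   ANOVA:
#>     factor_a                 F(1,7) = 134.53, p = 7.986e-06
#>     factor_b                 F(1,7) = 2.75, p = 0.1411
#>     factor_a:factor_b        F(1,7) = 2.74, p = 0.1416
#>   post-hoc paired t (Bonferroni):
#>     IsoFlat vs IsoDepth          t(7) = -1.78, p = 0.2354
#>     CrossFlat vs CrossDepth      t(7) = -0.38, p = 1
```

Iso-oriented surrounds suppress perceived contrast far more than
cross-oriented ones (the large `factor_a` effect); with the default
between-observer heterogeneity the smaller depth effect is not reliably
detected at n = 8 in every simulated replicate — a useful reminder of the
power limits of this design. `autoplot(fit)` draws the six psychometric
functions; `autoplot(report)` the condition means.

See `vignettes/indecision-model.Rmd` for the model's assumptions, the
geometry conventions (pixel pitch, bump quantization and calibration,
texture normalisation) and all numerical choices.

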