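---
title: "The difference-with-indecision model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The difference-with-indecision model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indecision)
```

## The model

In a two-interval contrast judgment with an opt-out (2-AFC-DK), the observer
sees a reference grating and a test grating in successive intervals and
reports which was higher in contrast, or "don't know" (DK). The
difference-with-indecision model assumes the internal evidence is the
perceived contrast of the **second** interval minus that of the first,

$$D \sim \mathcal{N}\big(\pm(x - \mu),\ \sigma^2\big),$$

where $x$ is the physical contrast of the reference minus that of the test
(percent Michelson), $\mu$ is the shift in the test's perceived contrast
induced by its surround, and the sign is $+$ when the reference comes second
and $-$ when it comes first. Two fixed criteria partition $D$: below
$\delta_1$ the observer reports "second interval lower", above $\delta_2$
"second interval higher", and in between DK. Mapping these interval-frame
reports back to reference-frame responses by presentation order yields six
psychometric functions (three response categories by two orders) governed by
four parameters $(\mu, \sigma, \delta_1, \delta_2)$.

Two properties make $\mu$ a bias-robust estimate of the perceived-contrast
difference:

* the DK probability averaged over the two orders is an even function of
  $x - \mu$, so when that averaged curve is unimodal its peak sits exactly at
  $\mu$ regardless of where the criteria sit;
* a shift of the criterion midpoint (an interval/response bias) moves the two
  order-specific curves in opposite directions but leaves the order-averaged
  curve, and hence $\mu$, unchanged.

`dk_peak()` computes the averaged-curve maximum numerically and flags the
degenerate regime in which the midpoint lies so far from zero relative to the
criterion separation that the averaged curve splits into two symmetric peaks
at $\mu \pm u^\*$; in that regime the "peak = $\mu$" reading is no longer
meaningful, so both locations are returned with a `bimodal` flag instead of a
silently averaged answer.

We model the verbal decision rule in the interval frame rather than the
reference frame: a literal reference-frame reading would make the two
presentation orders statistically identical and could not express the
interval bias the order-averaging is designed to cancel. With a single
presentation order the criterion midpoint and $\mu$ trade off exactly (the
Fisher information for the midpoint vanishes), which is why
`fit_indecision()` refuses single-order data outright.

## Fitting

`fit_indecision()` minimises the multinomial negative log-likelihood of the
per-cell response counts (the multinomial coefficient, constant in the
parameters, is omitted). Numerical choices:

* **Probability floor.** Probabilities are floored at `prob_floor = 1e-9`
  inside the logarithm only, keeping the objective finite at boundary
  parameter values; the floor is exposed as an argument.
* **Reparameterisation.** The search runs unconstrained over
  $(\mu, \log\sigma, c, \log h)$ with $\delta_{1,2} = c \mp h$, enforcing
  $\sigma > 0$ and $\delta_1 \le \delta_2$ by construction.
* **Starts.** A deterministic start is derived from the data ($\mu_0$ =
  DK-count-weighted mean of $x$; $\sigma_0$ = a quarter of the $x$ range;
  $h_0$ from the overall DK rate via the Gaussian quantile; $c_0 = 0$), plus
  8 jittered restarts drawn from a fixed internal seed, independent of any
  simulation seed. BFGS runs from each start (Nelder-Mead as fallback); the
  best objective wins, ties broken by first found.
* **Zero-DK observers.** When no DK responses exist the half-width $h$ is
  not identified from above; it is pinned to 0 and a 3-parameter fit is
  performed, flagged `pinned_zero_dk` in the result.
* **Lapse.** No lapse parameter is fitted by default; a fixed lapse rate can
  be mixed in via the `lapse` argument as an opt-in extension. One $\sigma$
  is fitted per data set (no dependence on $x$).

## The synthetic-data generator

`design_preset()` enumerates the balanced designs of the training task and
the three main experiments: the reference-contrast ladders (9 levels,
21–39% in steps of 2.25%, for training; 11 levels — 14, 18–34 in steps of
2, 38 — for the main experiments), the condition sets, both presentation
orders, and the session structure (440-trial sessions repeated 8 times for
the 2 x 2 experiments; 396-trial sessions repeated 7 times for the
three-condition experiment; 432 trials for training). The repeats-per-session
values (5, 5, 6) are back-derived from the session totals, which the
experiments report directly. Trial order is a uniform shuffle within session
from the seeded generator; the balancing is exact within each session.

`simulate_trials()` draws $D$ from the generative rule above and applies the
criteria, so simulated response fractions converge to the closed-form
probabilities at rate $1/\sqrt{n}$ — a property the test suite checks at
$n = 10^5$ alongside a Monte-Carlo validation of the closed forms themselves.

`simulate_observers()` adds between-observer heterogeneity: Normal jitter on
$\mu$ (sd 1% contrast) and $\sigma$ (sd 0.75, floored at 0.5), and a shared
Normal criterion-bias shift (sd 0.5) applied to both criteria so the
indecision-zone width is an observer trait. The group studies report only
group mean effects, so these hyper-parameters are our choice of a realistic
spread bracketing those means; they are arguments, not constants.

The default generating means mirror the reported condition effects. For the
2 x 2 designs only marginal means are published, so the default cell means
are back-solved from the margins plus the reported post-hoc pattern (a depth
release for iso-oriented surrounds, essentially none for cross-oriented):
IsoFlat $-9.25$, IsoDepth $-7.01$, CrossFlat $-4.95$, CrossDepth $-4.83$ for
the first experiment. The three-condition experiment uses the published
means directly (Bump $0.89$, Average $2.1$, Near $1.7$).

What the simulator does **not** emulate: learning or fatigue across
sessions, serial dependence between trials, lapses, reaction times, and any
image-computable route from the stimuli to the decision variable. Passing
recovery tests therefore shows that the estimator is consistent and unbiased
*under the model's own assumptions* at the experiments' trial counts — not
that real observers satisfy those assumptions.

## Stimulus geometry

All conversions use the linear pixel pitch $36.5^\circ/1600\,\text{px} =
0.0228^\circ$/px; the published pixel-degree pairs (5 px = 0.11°) are
consistent with this convention and not with a tangent-corrected pitch.

The depth bump's disparity follows a cumulative Gaussian of the radial
coordinate, normalised to run from 0 at the center to $-0.5^\circ$ at the
base with steepness $\sigma = 0.5^\circ$, then quantized to integer pixels.
Two conventions needed fixing where the source description is ambiguous:

* **Quantization.** We floor the disparity magnitude:
  $|{-0.5^\circ}| = 21.9$ px floors to 21, reproducing the stimulus's
  21 circles; round-half-up would give 22.
* **CDF mean placement.** The mean radius is calibrated so that the
  *quantized* disparity is zero over a plateau of exactly the stated flat-top
  diameter (2.26°): $m = 1.13^\circ - \sigma\,\Phi^{-1}(\text{pitch}/0.5)
  \approx 1.97^\circ$. Placing the mean at the flat-top edge instead makes
  the near-surround average about $-18$ px, far from the published $-5$ px;
  placing it at $1.13^\circ + 2\sigma$ widens the quantized plateau to
  2.57°, contradicting the stated flat-top size.

Under this calibration, the radially unweighted mean disparity over the
1°-wide ring surrounding the 2° center grating is $-4.55$ px $\to -5$ px at
nearest integer, matching the disc used in the Near condition. The published
whole-bump average of $-10$ px is not reproduced by any spatial average we
examined (radial and area-weighted means give $-14$ to $-17$ px); the
unweighted mean over the 22 quantized ring levels (0 through $-21$) gives
$-10.5$ px, so `region_mean_disparity()` exposes the averaging convention
(`radial_unweighted`, `area_weighted`, `ring_level_mean`) as a parameter
rather than hard-coding a guess.

The non-oriented surround texture filters seeded Gaussian noise through a
bank of orientation-selective band-pass filters (default 18 orientations
over 0–180°, log-Gaussian radial band of 1-octave bandwidth at 2 cyc/deg,
wrapped-Gaussian orientation tuning with sd equal to the 10° spacing — the
bandwidth is unspecified in the source, so we use the standard 1-octave
choice). Contrast normalisation maps the 0.1–99.9 luminance percentiles to
the target Michelson range and clips, so the realised Michelson contrast
equals the target to within half a percentage point while staying robust to
Gaussian tails. Isotropy is verified via the orientation-energy spectrum
with the radial power profile divided out; at 512 x 512 the coefficient of
variation across 18 orientation bins is well below 0.15 for the full bank
and above 2 for a single band.

`render_stereo_pair()` realises disparity as an integer-pixel horizontal
shift of each element in the right-eye image only (the one-eye convention of
the experiments), with no sub-pixel interpolation; the bump is drawn as
concentric circles each displaced by its own quantized disparity, far rings
first. The annular surround of the three-condition experiment has no stated
outer diameter; we default to the 8° of the other experiments.

## Group statistics

Fitted $\mu$ values feed within-subject analyses:

* `rm_anova_2x2()` computes each effect from per-subject contrasts
  ($\pm 1$ coding, halved); $F = n\bar c^2 / s_c^2$ on $(1, n-1)$ df, which
  is exactly the squared paired $t$ — and is verified in the tests against
  an independent `aov()` Error-strata decomposition.
* `rm_anova_oneway()` uses the classical condition vs condition-by-subject
  decomposition with uncorrected degrees of freedom; no sphericity
  correction is applied, matching the reported df.
* `posthoc_paired_bonferroni()` multiplies raw paired-$t$ p-values by the
  size of the comparison family, capped at 1. The default families mirror
  the reported analyses: the depth effect within each orientation (2
  comparisons) for the 2 x 2 designs, all three pairs for the
  three-condition design.
* Zero-variance contrasts (possible in degenerate synthetic input) return a
  flagged $F = \infty$ (or 0 when the mean is also zero) rather than an
  exception, so simulation sweeps do not abort.

The suite checks the empirical type-I error of both ANOVAs at
$\alpha = 0.05$ over 10,000 exchangeable-null simulations (8 observers by 4
cells, and 7 by 3), requiring rates in $[0.04, 0.06]$.

## Problem sizes used in the tests

Monte-Carlo validations of the closed-form probabilities use $10^6$ draws
per checked cell at 20+ parameter points. Parameter recovery runs 100
replicates of one 880-trial condition (the per-condition trial count of the
2 x 2 experiments) at $(\mu, \sigma, \delta_1, \delta_2) =
(-8.13, 5, -1.5, 2.5)$, requiring mean bias within $\pm 0.3$ and every
replicate within $\pm 2$ percent contrast; these sizes give comfortable
statistical margins (observed per-replicate sd $\approx 0.22$) while keeping
the suite quick to run.

## Limitations

* Whether the original analysis placed the criteria in the reference frame
  with an additive order-bias term is not fully determined by the published
  description; the interval-frame construction used here is the standard
  one and is observationally similar but not guaranteed identical.
* The likelihood is per-cell multinomial and unweighted; any trial
  weighting in the original fits is unknown.
* Reproducing the published per-condition group means requires the public
  raw-data deposit, which this package ingests via
  `run_reanalysis()` with a column mapping (the deposit's schema is not
  described in the publication); no attempt is made to bundle or fetch it.
* The renderer is a geometric rasteriser: no gamma model, no temporal
  sequence, no dot-overlay density calibration for the bump (the published
  description does not specify it).
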