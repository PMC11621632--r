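---
title: "Random-walk statistics of fixational drift and retina-contingent stimulus motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk statistics of fixational drift and retina-contingent stimulus motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftgain)
```

## The problem

Between microsaccades, the fixating eye drifts along a two-dimensional
random-walk-like trajectory. Gaze-contingent display systems can present a
stimulus whose motion in the world is a *gain* multiple of that eye motion:
gain 0 is an ordinary world-fixed object, gain +1 is retinally stabilized,
and negative gains amplify retinal slip. Quantifying what observers perceive
under such conditions requires a common statistical language for four
motions — the eye's (EM), the stimulus's in the world (WM), the stimulus's
across the retina (RM), and the random-walk comparison stimulus an observer
adjusts to match the percept (PM). `driftgain` implements that language: the
gain transform and its exact scaling identities, mean-square-displacement
(MSD) diffusion statistics, the quality-control filters that isolate drift,
a synthetic-motion generator for end-to-end simulation, and an MSD-matching
model observer that predicts perceived-to-world diffusion ratios.

## The motion model

A trace is a sequence of gaze positions $(x_j, y_j)$ in arcminutes sampled
at 60 Hz. Under gain $g$, per frame,

* world displacement of the stimulus $= g \times$ eye displacement;
* retinal displacement $=$ world $-$ eye $= (g - 1) \times$ eye displacement.

Both transforms are exact per-frame scalings, so they carry exact
consequences for the diffusion statistics: $D_{WM} = g^2 D_{EM}$ and
$D_{RM} = (g-1)^2 D_{EM}$, with the scaling exponent $\alpha$ unchanged.
For $g = -1.5$ the stimulus slips 2.5 times more across the retina than a
world-fixed object; for $g = +1.5$, half as much. These identities hold to
machine precision in the package and serve as pipeline regression guards.

All trajectories are displacement-based (anchored at the origin): only
displacements ever enter the analysis, so absolute screen coordinates are
irrelevant. Coordinates are x-rightward, y-upward, isotropic in the gain.
The gain is applied to per-frame increments; for saccade-free drift this is
identical to scaling displacement from the trace start, and traces
containing saccades are removed rather than transformed, so the distinction
never matters in practice.

## Diffusion statistics

For a trace of $N$ frames the MSD at lag $\Delta T$ frames averages the
squared Euclidean displacement over *nonoverlapping* sample pairs,

$$\mathrm{MSD}(\Delta T) = \frac{1}{\lfloor (N-1)/\Delta T \rfloor}
\sum_{j=1}^{\lfloor (N-1)/\Delta T \rfloor}
\left[(x_{j\Delta T+1}-x_{(j-1)\Delta T+1})^2 +
      (y_{j\Delta T+1}-y_{(j-1)\Delta T+1})^2\right],$$

for $\Delta T = 1 \ldots \lfloor N/4 \rfloor$. Overlapping pairs are highly
correlated and bias $\alpha$ upward when few traces are pooled; lags beyond
a quarter of the trace average too few pairs to be reliable. The index
upper bound is $\lfloor (N-1)/\Delta T \rfloor$ so that the last pair never
reads past the trace (a naive $\lfloor N/\Delta T \rfloor$ bound would, by
one sample, at $\Delta T = 1$). The minimum analysable trace is 8 frames,
the shortest length with two lags.

The anomalous-diffusion law $\mathrm{MSD} = 2\,d\,D\,\Delta T^{\alpha}$
(dimension $d = 2$) is fitted by unweighted ordinary least squares of
$\log_{10}\mathrm{MSD}$ on $\log_{10}\Delta T$ with the lag in seconds: the
slope is $\alpha$ and the intercept is $\log_{10}(2 d D)$, so
$D = 10^{\text{intercept}}/4$ in arcmin²/s. (Solving the intercept for $D$
must include the $2d$ factor; dropping it would be inconsistent with the
step-length calibration below.) $\alpha = 1$ is Brownian motion, $\alpha >
1$ persistence, $\alpha < 1$ antipersistence; a constant-velocity
trajectory fits $\alpha = 2$ exactly. Zero-MSD lags are excluded from the
log fit, and a trial's presentations are combined by averaging their MSD
curves at each common lag, weighted by pair counts, before a single fit
(`pooled_stats()`). The per-trace alternative — fit each presentation and
average the parameters — is exposed via `method = "per_trace"` as a
sensitivity check; pooling the curves first has measurably lower $\alpha$
RMSE because single-trace high-lag points average very few pairs. Mean
drift speed is the average frame-to-frame displacement per unit time.

## Synthetic motion

The generator provides every input the pipeline consumes, with the
statistical structure the analysis assumes:

* **Drift** (`generate_drift_trace()`): independent fractional Gaussian
  noise per axis with Hurst exponent $H = \alpha/2$, sampled exactly by
  Davies–Harte circulant embedding (with an exact Cholesky fallback should
  the embedding ever fail to be nonnegative definite; eigenvalues are
  memoised per trace length). The amplitude is calibrated at the one-frame
  lag — $\mathrm{E}[\mathrm{MSD}(1\ \text{frame})] = 2 d D
  (1/60)^{\alpha}$ — which makes the expected MSD an exact power law at
  *every* lag, so fits recover $(D, \alpha)$ without discretisation bias.
  At $\alpha = 1$ this is an ordinary Brownian walk with per-axis step SD
  $\sqrt{D/30}$ at 60 Hz.
* **Matching-stimulus library** (`generate_walk_library()`): 32 step
  lengths from 0.05 to 1.6 arcmin in 0.05 steps; each step length's
  analytic diffusion constant is $\text{step}^2 \times 30$ (1.6 arcmin
  $\rightarrow$ 76.8 arcmin²/s); 100 candidate Brownian paths per level, of
  which the 10 with fitted $D$ closest to the analytic value are retained
  (ties broken by candidate index, for determinism). Retained paths have
  mean fitted $\alpha \approx 1$.
* **Microsaccades** (`inject_microsaccades()`): linear ballistic segments
  of 10 arcmin over 2 frames by default, at Poisson times, with ground
  truth attached — a fixture for the detector, not a model of main-sequence
  dynamics.
* **Delivery jitter** (`inject_delivery_jitter()`): i.i.d. Gaussian
  per-axis error between targeted and delivered stimulus positions,
  emulating tracking/delivery imperfection.

What the generator does *not* emulate: tremor, binocular coordination,
oculomotor drift curvature at sub-frame timescales, blink artefacts, or any
spatial structure of real retinal imagery. Passing tests therefore
demonstrate the correctness and calibration of the analysis chain on
motion with known $(D, \alpha, S)$ — not that real eyes satisfy the fBm
model.

## Quality control

Three screens, all removal-only (retained traces are never edited):

* **Delivery accuracy**: per presentation, the SD of the misdelivery
  (delivered minus targeted position) over presentation frames, screened at
  0.9 arcmin. The default statistic is the total SD of the 2-D error
  vector, $\sqrt{\mathrm{var}(e_x) + \mathrm{var}(e_y)}$: a constant
  delivery bias passes (it does not corrupt *motion*), while per-axis
  jitter of SD 1.2 arcmin fails and 0.3 arcmin passes essentially always
  over 200-frame records. An SD-of-magnitudes alternative
  (`method = "magnitude"`) is exposed; note it is less sensitive, since the
  SD of Rayleigh-distributed magnitudes at per-axis jitter $\sigma$ is only
  $\sigma\sqrt{2-\pi/2} \approx 0.79\sigma$.
* **Trial removal**: a trial is dropped when strictly more than half its
  presentations fail the delivery screen.
* **Microsaccade filter**: a speed-threshold detector (default 180
  arcmin/s = 3°/s, minimum run 1 frame, events padded one frame each side).
  Any trace containing an event is removed whole — excising and splicing
  would manufacture artificial displacement steps and bias the random-walk
  statistics. On synthetic drift ($D = 5$, $\alpha = 1$) the false-positive
  trace rate is at most 1%, and injected 10-arcmin/2-frame events are
  recovered with sensitivity above 0.95.

## The MSD-matching model observer

Observers adjusting a Brownian comparison stimulus ($\alpha_{PM} = 1$)
cannot independently signal $\alpha$; if they equate mean square
displacements at a single interval $\Delta T$,

$$\frac{D_{PM}}{D_{WM}} =
\frac{(\Delta T)^{\alpha_{WM}}}{(\Delta T)^{1}} =
\left(\frac{60}{\Delta T_{\text{frames}}}\right)^{1-\alpha_{WM}},$$

which with the 2-frame matching interval is $30^{1-\alpha_{WM}}$: an
exponential decay in $\alpha_{WM}$, equal to 1 for Brownian world motion,
below 1 for persistent motion (which covers more ground at short intervals
than its $D$ alone implies) and above 1 for antipersistent motion.
`fit_match_interval()` recovers the matching interval from observed
(ratio, $\alpha_{WM}$) pairs by grid search over integer intervals 1–15
frames, minimising unweighted raw-space squared residuals, ties toward the
smaller interval. Observations with $\alpha_{WM}$ near 1 are uninformative
— every interval predicts a ratio near 1 — so the estimator is
well-determined only when world motion deviates from Brownian; with twelve
persistent observations ($\alpha_{WM}$ 1.2–1.8) and 10% multiplicative
ratio noise it recovers a 2-frame interval in about 97% of replicates,
whereas observation sets straddling $\alpha_{WM} = 1$ recover it far less
often. An all-Brownian input is flagged degenerate rather than fitted.
Fractional intervals are out of scope; the model assumes isotropy and no
directional bias.

## The simulated experiment

`run_experiment()` reproduces the full design in silico: subjects ×
background conditions × gains × trials, each trial pooling several
presentations through generation, gain transform, jitter injection, QC, and
the model observer, with every trial on its own seed derived from the
master seed (single-threaded, bit-for-bit reproducible). Three observers
are available — `"msd_matcher"` (default), `"veridical"`
($D_{PM} = D_{WM}$), and `"retinal"` ($D_{PM} = D_{RM}$) — spanning the
hypotheses a matching experiment can distinguish. Matched diffusion
constants can optionally be snapped to the nearest walk-library level,
mirroring the 32-level quantisation a human observer faced; the default
leaves them unquantised, which is cleaner for analysis.

Background condition affects only generator parameters, never the analysis
path. Defaults: background-present, $D = 6$ arcmin²/s, $\alpha = 1.05$,
90-frame (1,500 ms) presentations; background-absent, $D = 15$ arcmin²/s,
$\alpha = 1.25$, 45-frame (750 ms) presentations. The durations are the
study's; the drift parameters express its qualitative description —
uniformly faster, more persistent drift without a fixation reference — with
magnitudes typical of fixational drift, and are configuration values, not
empirical claims. Per-subject parameters scatter around the condition means
(lognormal SD 0.2 on $D$, SD 0.08 on $\alpha$) so simulated subjects differ
the way real eyes do. World-fixed trials ($g = 0$) have $D_{WM} = 0$;
their world-motion $\alpha$ and ratio are reported as `NA` since motion
statistics do not apply.

```{r experiment}
cfg <- experiment_config(n_subjects = 3L, trials_per_gain = 2L,
                         presentations_per_trial = 4L, seed = 11L)
res <- run_experiment(cfg)
res$ratio_summary
```

Inferential statistics (repeated-measures ANOVA, post hoc contrasts) are
deliberately out of scope; `write_tables()` emits per-trial and aggregate
CSVs in a layout any statistics package consumes directly.

## Numerical choices and problem sizes

* Log-log fits use base-10 logs and unweighted OLS over all positive-MSD
  lags; weighting by pair counts is applied when *averaging* curves, not
  when fitting.
* The circulant-embedding sampler restores the session RNG after seeded
  calls, so seeded generation never perturbs an enclosing stream.
* Walk-library selection and interval fitting break ties
  deterministically (candidate index; smaller interval).
* Test-suite and verification problem sizes — e.g. 200 traces of 90 frames
  per parameter-recovery cell, 400 paths for the step-length calibration
  check, 100 seeded traces for detector sensitivity — were chosen so that
  Monte-Carlo error sits comfortably inside the tolerances being asserted
  while the whole suite runs in well under a minute.

## Limitations

* The fBm drift model is statistically, not physiologically, motivated;
  real drift shows timescale-dependent correlation structure that a single
  $\alpha$ summarises only coarsely.
* The delivery-SD statistic treats bias as harmless; if absolute position
  accuracy mattered (it does not for motion statistics), a different screen
  would be needed.
* The matching-interval fit is weakly identified near Brownian world
  motion, as noted above.
* Perceptual suppression mechanisms (why backgrounds reverse perceived
  motion) are not modelled; the model observer is a measurement-matching
  account, not a mechanistic one.
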