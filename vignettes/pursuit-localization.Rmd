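---
title: "Relative flash localization during smooth pursuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative flash localization during smooth pursuit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitloc)
```

## The paradigm and its coordinate conventions

An observer fixates, or tracks a target moving horizontally at 10 deg/s,
while two small squares are flashed for one frame each at 7.5 deg
eccentricity: a reference, timed to the moment the pursuit target crosses
the screen centre (1250 ms into the trial), and a test flash offset
horizontally from it, shown at a stimulus onset asynchrony (SOA) of -200, 0,
or +200 ms. The observer reports which flash appeared further to the right.
In a companion task, a single flash is shown and the observer reports its
absolute position on a 51-line ruler spanning -20..20 deg (0.8-deg spacing,
labels 00-99 randomly reassigned every trial, and a 0.4-deg global ruler
shift on half the trials so that averaging the halves doubles the effective
resolution).

Three axes are distinguished. The *screen axis* is signed positive rightward
from the screen centre; everything is stored on it. The *eccentricity axis*
is positive away from the centre within the stimulus hemifield — a pure sign
flip for left-hemifield stimuli — and is the axis on which left and right
conditions pool. The *retinal axis* is eccentricity relative to the fovea.
Geometry is flat-screen per-point arctangent (`cm_to_deg()`): the default
120 x 90 cm screen at 70 cm subtends about 81 x 65 deg, which a small-angle
linearization would not reproduce. Only the horizontal coordinate is
modelled; the small vertical separation of the two flashes plays no
analytical role. Configured degree positions (e.g. the 7.5-deg reference)
are treated as exact rather than re-derived from a pixel mapping, since the
screen mapping of any particular rig is not part of the design.

## The psychometric model

Responses are modelled as a lapse-augmented cumulative Gaussian on the
eccentricity axis,

$$\psi(x) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\left(\frac{x - m}{\sigma}\right),$$

with the PSE defined as `m`, the point halfway between the asymptotes.
`fit_psychometric()` maximizes the binomial likelihood with `m` free within
the level range plus 5 deg, `sigma` on a log scale, and the asymptote
parameters free within [0, 0.06]. The bound keeps the PSE identifiable with
the 8-17 levels a pooled condition provides while still absorbing
occasional lapses; fixing the asymptotes at zero instead biases `sigma`
upward whenever a single far-tail error occurs. Optimization is L-BFGS-B
with an analytic gradient and five starts seeded from quantile heuristics
(the interpolated 50% crossing for `m`, the 25-75% spread for `sigma`), so
translation equivariance holds to optimizer precision. Degenerate cells
(all responses identical) are reported as non-converged with an infinite
confidence interval rather than silently fitted.

Confidence intervals come from a nonparametric bootstrap (999 resamples by
default): per-level binomial counts are redrawn at the observed proportions,
refit, and the 2.5/97.5 percentiles taken. If more than 20% of refits fail
to converge the interval is widened by 50% about the point estimate and a
warning raised. A fully Bayesian treatment in the style of the
psignifit toolbox is deliberately out of scope: only point PSEs and 95%
intervals enter the downstream analysis, and bootstrap MLE reproduces both.

Pooling follows the paradigm's two distinct rules on purpose: fixation
trials are mirrored onto the eccentricity axis and pooled across hemifields
*before* fitting (one fit per SOA), whereas pursuit trials are fitted per
direction and the fitted parameters averaged across leftward/rightward
afterwards (`average_lr()`), with the two fine-grid phases pooled per
(SOA x placement) cell.

## The reference-frame models

The absolute-localization task yields, per subject and placement, an
ordinary least-squares regression of mislocalization (perceived minus
actual, eccentricity axis) on retinal eccentricity; its slope `a` is the
*eccentricity effect*: degrees of mislocalization per degree of retinal
eccentricity. The regression is fit on trial-level data rather than
per-position means — for the balanced designs generated here the two
coincide, and trial-level weighting has lower variance when counts differ.

Because the eye travels `v |SOA|` (2 deg at 10 deg/s, 200 ms) between the
flashes, each candidate reference frame predicts the pursuit PSE from the
fixation PSE of the same SOA:

* **A** (screen-centered, no eccentricity effect): unchanged.
* **B** (eye-centered): plus the full retinal displacement
  `s * v * |SOA|`.
* **C** (screen-centered plus eccentricity effect):
  plus `s * v * |SOA| * a`.
* **D** (eye-centered plus eccentricity effect): both shifts.

The sign `s` is +1 for (positive SOA, ahead of the target) and (negative
SOA, behind), -1 for the other two cells, and 0 at SOA 0 — where all four
models collapse onto fixation, which is why simultaneous cells are excluded
from model evaluation. The shift formulas are written in `v` and `|SOA|`
(with an optional fractional-compensation parameter in `retinal_shift()`)
so the module works at other speeds and asynchronies, reducing exactly to
the familiar 2-deg and `2a` constants at the standard task parameters.

`evaluate_model()` scores each model by regressing predicted on measured
PSEs (slope, Pearson r) and by the mean pointwise distance of the
(measured, predicted) points to the identity line. "Distance to the
identity line" is read geometrically — the perpendicular distance
`|p - m| / sqrt(2)` — as the default; the vertical reading `|p - m|` is
available via `distance = "vertical"`, since the phrase does not fix the
convention. The regression is unconstrained (not forced through
the origin), the other undetermined convention. Ranking is by ascending mean
distance with |slope - 1| as tie-break, and the full ranking is always
returned.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known ground truth; its defaults are the reference conditions of the
paradigm. Each synthetic
observer carries fixation PSEs per SOA (population means 0.00 / -0.02 /
+0.75 deg for -200 / 0 / +200 ms), a psychometric spread, asymptote rates,
eccentricity slopes and intercepts, and pursuit-gain parameters; subject
draws scatter around the means with reported between-subject SDs for this
paradigm where available (0.42 / 0.17 / 0.55 deg for the fixation PSEs; slope
SDs 0.335 / 0.19 implied by the compensation-shift SDs via shift = 2a). A
`frame_model` switch (A-D) selects which regime the observer's *relative*
judgments actually obey, so model-selection can be validated against a
known generating frame.

Values without a reported counterpart were fixed once at field-plausible numbers:
psychometric spread 0.8 deg (between the fine2 grid step of 0.5 deg and its
half-span, the regime an adaptive grid targets); ruler report noise 1.0 deg
SD; tracker position noise 0.02 deg RMS per 500-Hz sample; catch-up
saccades as Poisson arrivals at 0.5 /s with amplitudes 0.8-2.5 deg, a
200-ms refractory period, and an 80% bias in the pursuit direction; blinks
in 5% of trials as 60-200 ms invalid runs; frame drops in 0.5% of trials.
The absolute-mislocalization intercepts are anchored to two reported
behavioural anchors (+2.75 deg mislocalization at 7.5 deg retinal
eccentricity ahead; perception of a 7.5-deg flash at 6.55 deg behind),
giving 0.95 and -2.90 deg at slopes 0.24 / 0.26.

Eye traces are sampled at 500 Hz (1750-ms fixation trials, 2500-ms pursuit
trials). The pursuit trajectory is anchored to the centre crossing at
1250 ms with slope `10 * gain` deg/s: anchoring at the trial start instead
would displace the eye from the target by `12.5 * (gain - 1)` deg at the
flash — about 0.25 deg at gain 1.02 on average, and far more in the gain
tail — turning a realistic 2% gain error into a flood of deviation
exclusions that steady-state pursuit does not show; catch-up saccades,
which the generator injects separately, are precisely the mechanism that
keeps real pursuit centred. Saccades are injected as instantaneous
position steps, the worst case for a velocity-based detector at 2-ms
sampling; the detector's Savitzky-Golay differentiation (5-sample window)
spreads a step over four samples at well above threshold, which is why the
default minimum event duration is 8 ms.

The coarse-to-fine procedure is simulated: a coarse grid (0, +/-2 ... +/-8
deg) is run first, the fine1 grid (+/-4 deg in 1-deg steps) is centred on
the coarse PSE rounded to 1 deg, and the fine2 grid (+/-2 deg in 0.5-deg
steps) on the fine1 PSE rounded to 0.5 deg — grid-aligned rounding keeps
offsets on round values, as an experimenter would. Interim centring uses a
fast empirical-probit regression; the final analysis always uses the full
MLE. The number of coarse trials is a parameter (`counts$coarse`), since
the appropriate count depends on the experiment. Trials are generated until the requested
*valid* counts per cell survive QC (defaults: 75 per hemifield x SOA
fixation cell, 75 per pursuit cell per fine phase — i.e. 150 over the two
fine phases — and 50 per absolute cell, the paradigm's usual collection criteria).
A single master seed drives per-trial derived streams, so datasets are
reproducible and insensitive to generation order; `simulate_traces =
FALSE` produces clean, exclusion-free data for fast recovery studies.

What the generator does *not* emulate: 2-D gaze and vertical eye position,
pupil dynamics and the main-sequence kinematics of saccades, reaction
times, serial dependencies between trials, and any attention-based
mechanism behind the eccentricity effect — mislocalization is linear in
retinal eccentricity by construction, because that is the descriptive model
the analysis fits. Passing recovery tests therefore shows that the pipeline
is a consistent estimator of its own generative family, not that real data
obey that family.

## Quality control choices

The exclusion rules are: logged frame drops; eye position deviating more
than 2 deg from the *instantaneous* pursuit-target (or fixation-point)
position at any point within 50 ms of the reference flash; and a detected
saccade or blink within 100 ms of either stimulus, a union spanning 400 ms
at |SOA| = 200 ms and 200 ms at SOA 0. The deviation reference is the
nominal target trajectory, not the recorded eye path. Tracker
saccade parsers differ between systems, so detection parameters are
explicit arguments: velocity threshold 30 deg/s *relative to the expected
pursuit velocity* (the conventional default), minimum duration 8 ms,
events merged across gaps under 20 ms. Blinks are invalid-sample runs of
at least 20 ms padded by 20 ms on each side. Pursuit gain is the
20%-trimmed mean of sample velocities in the flash +/- 100 ms window over
the signed target velocity — trimming guards against residual micro-events
without modelling them. Trials with missing traces are flagged and
reported, never dropped silently.

## Problem sizes used by the test suite

The suite validates at sizes chosen to exercise the full pipeline while
keeping a complete run comfortably reproducible on a laptop: PSE recovery
over 500 condition cells at 150 trials each (median absolute error bound
0.15 deg); eccentricity-slope recovery over 8 subjects at 100 absolute
trials per cell (group mean within 0.02 of the generating slopes); and
end-to-end model selection over 100 replicate experiments of 8 subjects
each per generating frame (B and C), at reduced per-cell trial counts, with
the generating frame required to rank first in at least 95. Bootstrap
coverage is spot-checked at 199 resamples over 40 replicates.

## Known limitations

* The relative-judgment simulation draws responses directly from the
  observer's condition-level psychometric function; it does not couple
  single-trial responses to the simulated trace's momentary gain, so
  trace-level and response-level variability are independent.
* The package fits no intermediate reference frames beyond the fractional
  retinal shift, and no hierarchical (mixed-effects) pooling across
  subjects; per-subject fits are combined by averaging.
* Ruler decoding assumes the label assignment seed is available (as the
  generator records it); hand-collected data would instead store decoded
  positions directly.
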