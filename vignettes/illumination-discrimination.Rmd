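---
title: "Chromatic illumination discrimination: models, simulations and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatic illumination discrimination: models, simulations and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illumdisc)
```

## The problem

Human observers can tell when the light illuminating a scene changes
spectrally, even when every surface in view stays put. `illumdisc` implements
the complete computational pipeline of a three-interval forced-choice
illumination discrimination experiment over tiled indoor scenes, in which the
assignment of surface reflectances to scene locations is either held fixed
across all stimuli or re-shuffled for every scene. Everything runs on
synthetic observers and synthetic gaze, with known ground truth, so every
stage of the analysis is testable end to end: stimulus colorimetry, adaptive
staircases, psychometric fitting and exclusion rules, and eye-fixation
statistics with permutation nulls.

## Stimulus colorimetry

Spectra live on a 31-sample grid (400–700 nm, 10 nm steps). The target
illuminant is a metamer of daylight at 6700 K, reconstructed from the CIE
daylight basis (`S0 + M1 S1 + M2 S2`) and scaled to luminance `Y = 100`. Test
illuminants form four series of 50 steps: *blue* and *yellow* walk along the
daylight locus (arc-length spaced in u'v' chromaticity), *red* and *green*
along the normal to the locus tangent at the target. Because all spectra are
scaled to the target luminance, `L* = 100` throughout and the CIELUV distance
to the target (white point: the target's own XYZ) reduces to
`1300 × (u'v' distance)`; one nominal step is one ΔE unit. Each step's
*actual* ΔE is computed from the generated spectrum and used everywhere
downstream — nominal steps are only staircase bookkeeping.

Off-locus chromaticities at the far red/green steps are not reachable with
non-negative power from the two daylight principal components alone; a single
smooth mid-wavelength Gaussian basis function (530 nm, 45 nm width) is mixed
in with the smallest weight that restores non-negativity. Spectra remain
smooth and physically plausible.

The construction is deterministic: the original 201 spectra are not printed
in any accessible source, so the series here matches the *stated* geometry
(CCT, directions, ~1 ΔE spacing, equiluminance) rather than any particular
spectra. Actual-vs-nominal deviations are below 0.4% in every direction —
comfortably inside the ±15% tolerance the tests assert.

## Scenes

The scene is a wall of 77 tiles (7 × 11) and a floor of 63 tiles (7 × 9);
the outermost columns are partially visible (visible-area fraction 0.85 by
default) to represent tiles cut by the image boundary. Each tile carries one
of 14 surface reflectances. Within each region every reflectance covers
either ⌊N/14⌋ or ⌈N/14⌉ tiles, and same-reflectance tiles form contiguous
patches: a serpentine path through the region lattice is cut into runs of
quota length (consecutive path cells are lattice neighbours, so runs are
contiguous by construction) and the banded shapes are then scrambled by
boundary swaps that preserve both connectivity and counts. We chose this
over naive multi-source region growing, which deadlocks on enclosed pockets.

The 14 reflectances are regenerated (the originals are unprinted): ten
chromatic Gaussian-bump samples spanning the spectrum plus near-neutrals,
and four designated pale samples (pale-green, pale-blue, light-gray,
pale-orange) that are the four brightest surfaces under the target
illuminant — mirroring the structure real observers preferentially fixate.

Colors come from a flat forward model — illuminant × reflectance × per-tile
gain — rather than path tracing, because every analysis in scope consumes
tile colors or image means. The gain field is a vertical gradient (floor 1.0
to wall-top 0.85 by default) standing in for the ceiling light's uneven
illumination. A stimulus set is 230 scenes per condition: 30 target versions
plus one test scene per (direction, step). In the fixed condition all 230
share one canonical assignment; in the shuffled condition each draws its own.

**Calibration of shuffling variance.** Shuffling perturbs the mean image
because tile *visible areas* are not exactly equal across reflectances (the
±1-tile count imbalance and the partial edge tiles). With the default edge
fraction 0.85 the 30 shuffled target scenes show mean pairwise ΔE ≈ 2.5–3.0
(SD ≈ 1.0–1.3, max ≈ 6–8), matching the 2.7–3.2 range reported for rendered
stimuli. The gain-field amplitude, although exposed as a knob, has almost no
leverage on this quantity here because assignments are count-balanced within
each region; the edge-tile visibility fraction is the effective calibration
parameter.

## Observers and the trial engine

A parametric observer answers the 2AFC task correctly with probability

$$p(x) = 0.5 + (0.5 - \lambda)\,\bigl(1 - e^{-(x/\alpha)^\beta}\bigr)$$

at actual stimulus difference `x` (ΔE), with guess rate fixed at 0.5, scale
`α > 0`, slope `β` (default 3), and lapse `λ ∈ [0, 0.05]` (default 0.01).
`alpha_for_threshold()` inverts the function so simulation studies can plant
a known threshold. A random responder answers Bernoulli(0.5) regardless of
the stimulus.

A session runs a 12-trial training block (one 3-trial staircase per
direction, start level 31–40, fixed 10-unit step, flagged and excluded from
analysis) followed by 12 interleaved 1-up-2-down staircases — three per
direction with start levels drawn from 11–20, 21–30 and 31–40. Steps begin
at 15 nominal units and shrink to 10/5/3/1 after reversals one through four;
a staircase ends at its 8th reversal or 50th trial. Levels clamp to [1, 50].

Three bookkeeping conventions are not dictated by standard descriptions of
the procedure and are fixed here as follows: a *reversal* is a move whose
direction differs from the previous move's (the first move establishes
direction without counting); clamping at a range boundary is not by itself a
reversal (otherwise random responders pinned at level 50 would accumulate
spurious reversals and mask the out-of-range signature the exclusion rules
depend on); and a step-size change triggered by a reversal takes effect from
the next move. `replay_log()` re-derives every trajectory from the trial
records and errors on any inconsistent level, so logs are verifiable.

At the equilibrium of the 1-up-2-down rule, two consecutive corrects balance
one error: `p² = 0.5`, i.e. `p = 0.7071`. The tests verify this by running
2000 staircases against a known observer and checking the model probability
correct at each staircase's converged level; the trial-weighted probability
sits slightly higher (~0.72) because high-`p` levels consume two trials per
move, which is why the converged level, not the pooled trial stream, is the
right probe of the equilibrium.

## Threshold extraction and exclusions

Per direction, a session's trials pool across the three staircases, sort by
actual ΔE, and group into 10-trial bins with the remainder merged into the
last bin. The cumulative Weibull above is fitted to the binned binomial
counts by maximum likelihood (L-BFGS-B on (log α, log β, λ) with analytic
gradients, λ box-bounded in [0, 0.05], multistart over α ∈ {5, 15, 30, 60} ×
β ∈ {0.5, 2, 4}); the threshold is the analytic inverse at 70.71% correct.
Bin-level rather than trial-level likelihood is the default — the two give
statistically indistinguishable thresholds here — and α is capped at 10⁴, so
flat-at-chance data drive the threshold far beyond the stimulus range
rather than erroring. Non-converged fits count as out of range
(conservative: they mimic a flat psychometric function).

A threshold is *in range* when it does not exceed the direction's maximal
actual test ΔE. Out-of-range session thresholds are replaced by that maximal
value — a lower bound on the session's true threshold — before averaging the
two sessions; a direction out of range in *both* sessions yields a sentinel
consumed by the exclusion rules: observers are excluded and replaced if any
fixed-condition session threshold is out of range or any threshold falls
below 1 ΔE, and excluded without replacement if any direction is out of
range in both shuffled-condition sessions.

Calibration of these rules is simulation-based: 5000 random responders run
through two full sessions each (≈40,000 Weibull fits). Essentially all of
them (≥ 99.9%) are excluded by the both-sessions rule, so surviving the rule
is strong evidence of above-chance performance. `scripts/acceptance.R`
reproduces this number from scratch.

Parameter recovery closes the loop: for observers with planted thresholds
uniform in 5–20 ΔE, the full pipeline recovers thresholds with ~5% median
absolute relative error over 200 replicates. There is a small systematic
*positive* bias (~+2% median, identical under bin- and trial-level
likelihood) — the familiar small-sample bias of ML threshold estimates from
adaptive procedures; the tests bound its magnitude rather than pretending
it is exactly zero.

## Synthetic gaze and fixation analysis

Gaze streams are generated at 1000 Hz for the three stimulus intervals
(2370 / 870 / 870 ms in the eye-tracking profile; 2100 / 600 / 600 ms in the
stereo profile). A planner lays down fixations (gamma-distributed durations,
mean 250 ms, minimum 120 ms) connected by minimum-jerk saccades with
main-sequence-like kinematics (peak velocity `max(150, 75·A^0.7)` deg/s);
successive plans that land within 0.5° merge into one longer fixation, so
the planted ground truth is well defined. Blinks are invalid runs (120 ms,
Poisson rate per second) flanked by 20 ms position artifacts; isolated
dropouts and isotropic position noise complete the stream. Two strategy
knobs shape comparison-interval fixations: `location_reuse` re-fixates
target-interval screen positions; `reflectance_tracking` seeks tiles whose
reflectance was fixated in the target interval. These are free simulation
knobs for exercising the analysis — not claims about human behavior.

Detection is the adaptive velocity-based scheme: Savitzky–Golay smoothing
and differentiation (20 ms window, order 2), an iterated data-driven peak
threshold starting at 80 deg/s (mean + 6 SD of sub-threshold velocity, with
a 10 deg/s floor so noise-free signals cannot collapse the threshold),
saccade extension down to a mean + 3 SD onset/offset threshold, blink/noise
labeling (invalid samples, or raw or smoothed velocity above 1000 deg/s —
raw velocity matters because smoothing averages single-sample artifacts
below any threshold), and a 100 ms minimum fixation duration. On synthetic
traces with 0.1° noise and realistic blink rates the detector recovers ≥95%
of planted fixations of ≥150 ms with median centroid error below 0.01°.

Trial QC excludes a trial when any interval has >5% missing/outside-display
samples, >20% blink/noise samples, or no within-display fixation. Retained
fixations are filtered — outside-display first, then any fixation within 1°
of the previously retained one — and attributed to the containing tile and
its reflectance.

Statistics over kept trials: mean fixation counts per interval; the joint
spread `sqrt(sd_x² + sd_y²)` over pooled centroids (population-SD
convention, recorded so either convention is reproducible); the reflectance
overlap (proportion of unique reflectances fixated in a comparison interval
that were also fixated in the target interval, averaged over trials); a
radius-based location overlap (default 1.5°, a reconstruction — the
criterion radius is configurable); the trial-shuffled permutation null
(comparison-interval fixation sets re-paired with target intervals across
trials, independently per comparison interval); per-reflectance fixation
distributions; and Spearman correlations between per-observer overlap and
threshold, with exact permutation p for n ≤ 8 and the t approximation
above (full enumeration beyond 8! permutations buys no accuracy at these
sample sizes).

## What the synthetic data do and do not show

The generators reproduce the *structure* of the experiment — trial design,
staircase dynamics, chance-level responders, fixation/saccade/blink
kinematics sufficient for the detector, strategy-dependent cross-interval
gaze statistics — with known ground truth, which is exactly what is needed
to validate the analysis code. They do not model human psychometric slopes
across directions, realistic oculomotor noise spectra, microsaccades, pupil
dynamics, or rendering phenomena (interreflections, stereo disparity, tone
mapping). Passing tests therefore certify the pipeline, not any claim about
human vision; the human effect sizes in the literature require the original
raw data.

## Problem sizes and numerical choices

The test suite runs the random-responder null at n = 500 (the acceptance
script at the full n = 5000), staircase equilibrium at 2000 staircases,
parameter recovery at 200 replicates, and detector ground truth at ~100
intervals — sizes chosen so the whole suite completes in a few minutes while
keeping Monte-Carlo error well inside the asserted bands. Optimizer
tolerances (`factr 1e7`), the multistart grid, the α cap, the detector
floors, and the 0.5° plan-merge radius are implementation constants
documented above; all seeds are explicit and every derived seed stays below
2^31.
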