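---
title: "Measuring patellar tendon mechanics from synchronized dynamometry and ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring patellar tendon mechanics from synchronized dynamometry and ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonmech)
```

## The measurement problem

In-vivo tendon stiffness cannot be measured directly: what can be
recorded during a ramped isometric knee extension is (i) the force at a
cuff above the ankle, sampled at 1,000 Hz, and (ii) a sagittal B-mode
ultrasound video showing the patella apex and the tibial plateau. The
chain from raw recordings to a stiffness value is long, and every link
has conventions that affect the number at the end. This package
implements that chain as testable units and ships a synthetic-data
generator with known ground truth, so the whole chain can be validated
end to end — something impossible with real recordings, where the true
force–elongation law of the tendon is unknown.

The processing model is:

1. **Force conditioning.** The cuff force is lowpass filtered
   (Butterworth, 30 Hz cutoff, applied forward–backward so the filtered
   signal has zero phase lag relative to the frames). The knee-extension
   moment is the cuff force times the external moment arm (cuff
   mid-width to knee axis); the tendon force is that moment divided by
   the internal moment arm (tendon frontal edge to lateral epicondyle),
   a per-participant constant reused pre- and post-training.
2. **Elongation.** Both landmarks are tracked with a pyramidal
   Lucas–Kanade tracker; elongation at frame $t$ is the change, relative
   to frame 0, of the inter-landmark Euclidean distance, scaled to mm.
   Because it is a distance, whole-image rigid motion cancels.
3. **Stiffness.** Per trial, tendon force is read at each frame time via
   the hardware trigger, pairs are restricted to the loading ramp (5 %
   of peak force to peak), resampled to 100 points evenly spaced in
   force, and fitted with a 2nd-degree polynomial. Trials with
   $R^2 < 0.90$ are excluded. Curves from both sessions of a participant
   are standardized to a common force — the lowest included peak force
   in either session — averaged pointwise, and stiffness is the
   least-squares slope $dF/de$ of the mean curve over 60–100 % of the
   common force, in N/mm.
4. **Shear-wave elastography QC.** A recording (per-frame pixel maps of
   shear-wave velocity, instrument-capped at 20 m/s) is discarded when
   more than 5 % of pixels, averaged across frames, exceed 90 % of the
   cap; surviving recordings are summarized by their pooled mean
   velocity, per side and as the unweighted mean of the medial and
   lateral sides.
5. **Reliability and inference.** Test–retest tables yield ICC(3,1)
   (two-way mixed, consistency, single measure), typical error
   $\mathrm{TE} = \mathrm{sd}(\Delta)/\sqrt{2}$ and
   $\mathrm{CV} = 100\,\mathrm{TE}/\bar{y}$. Cohort outcomes are tested
   with mixed-design ANOVAs — training (within) × group (between),
   plus location (within, 3 levels) for CSA — with partial
   $\eta^2_p = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$ per
   stratum and Bonferroni post hocs, alongside Student's t,
   Mann–Whitney U, Wilcoxon signed-rank and Pearson correlations.

## What the synthetic generator emulates

`trial_spec()` + `generate_force_trace()` + `generate_frame_sequence()`
produce one trial with a fully known truth:

* a knee-extension moment rising at 70 N·m/s (the protocol's target
  loading rate) to a prescribed peak, recorded as cuff force at
  1,000 Hz with additive Gaussian sensor noise (default SD 3 N) and a
  0.2 s zero-force lead-in ahead of the trigger;
* a speckle-textured grayscale stack in which the plateau landmark is
  static and the apex landmark displaces along $+x$ so that the
  inter-landmark distance follows $e(F(t))$, the inverse of the trial's
  true law $F = a e^2 + b e$ ($a \ge 0$, $b > 0$, so the law is
  monotonically stiffening and invertible for $F \ge 0$). Landmarks are
  bright Gaussian blobs (SD 2.5 px) on local speckle, composited as
  rigidly translated continuous patches with a smooth mask whose flat
  top (15 px) covers the tracker window, so motion inside the window is
  exactly the prescribed sub-pixel translation. Image noise (default
  SD 3 on a 0–255 scale) is added after warping so it does not move
  with the tissue.

`generate_swv_map()` emulates velocity maps with a controllable
saturated fraction (the requested count is hit exactly, which makes the
QC boundary testable), and `generate_cohort()` draws pre/post cohorts
from an additive model with subject random effects, a training effect,
and an optional group × training interaction defined as the group
difference in the post−pre change.

The generator is deliberately not a physical ultrasound simulator: no
point-spread function, attenuation, out-of-plane motion, probe pressure
changes, or tissue decorrelation. Passing tests therefore demonstrate
that the *processing chain* is correct and numerically stable — not
that the tracker is robust to every artifact of real B-mode imaging.

Defaults the protocol leaves open were fixed once at plausible values
and exposed as parameters: frame rate 50 Hz (≈150 frames over a 3 s
ramp), 96 × 224 px frames at 0.1 mm/px, rest length 100 px.

## Numerical and design choices

**Quadratic orientation.** The per-trial polynomial is fitted as
$F = A e^2 + B e + C$ (force as a function of elongation), matching the
physiological family in which tendons stiffen with load. Fitting the
transposed model $e(F)$ with a quadratic was considered and rejected:
when the underlying curve is quadratic in $e$, $e(F)$ is a square-root
function, and its quadratic approximation biases the 60–100 % slope by
about 10 % even on noise-free data, while the $F(e)$ fit recovers the
truth to within grid resolution (≈0.2 %). Evaluating a fitted trial at
the common-force grid inverts the parabola analytically, choosing the
root on the branch the data occupy (nearest to the linearly
interpolated resampled curve).

**Resampling and the rest point.** The resampling grid is uniform in
force from 0 to the trial peak, since force is the controlled axis of
the protocol. The loading-phase onset threshold (5 % of peak) trims
low-force samples, so the rest point (0 N, 0 mm) — true by the
zero-referenced definition of elongation — anchors the interpolation
below the onset. $R^2$ is computed on the resampled points; the
inclusion rule keeps $R^2 \ge 0.90$ and excludes only strictly smaller
values, and the same strictness holds for the shear-wave rule (a
saturation fraction of exactly 0.05 passes).

**Slope definition.** "Slope of the mean curve over 60–100 %" is an
ordinary least-squares line over the grid points in that force range,
not a two-point difference; the analytic oracle used in tests applies
the same definition on a dense grid of the true curve. Non-monotonic
elongation or a non-positive slope flags the result rather than
silently reporting it.

**Filter.** The family and order are not dictated by the protocol; a
4th-order Butterworth run forward–backward was chosen so the filtered
force stays phase-aligned with the frames. The input is extended by
mirrored reflection (12 cutoff periods) before filtering: the slowest
filter pole needs roughly 0.3 s to settle to 10⁻⁹, and shorter pads
leak a visible transient into the ramp ends. DC gain is 1 within 10⁻⁹,
a 5 Hz component passes within 1 %, and 200 Hz noise is attenuated by
more than 99.9 %.

**Tracker settings.** Window 21 × 21 px, 3 pyramid levels, at most 30
iterations, convergence at 0.01 px, gradients by central differences on
a Gaussian-smoothed frame (σ = 1 px). These are standard Lucas–Kanade
settings for speckle; all are exposed. Tracking accumulates
frame-to-frame (matching the frame-to-frame definition of elongation)
rather than anchoring to frame 0, which keeps each step small but lets
drift grow on long sequences — on the ~150-frame ramps used here,
measured drift is three orders of magnitude below the 0.05 mm
acceptance bound. A near-singular structure tensor or a diverging
iteration flags the frame and carries the position forward instead of
inventing a displacement.

**Mixed ANOVA.** Sums of squares are the classical weighted
decomposition with each within-subject effect tested against its own
effect × subjects-within-group stratum. With balanced groups this
coincides with every SS type; with unbalanced groups (15/17 in the
motivating design) the within-subject cells are still complete, which
is where type choices matter least. The implementation is explicit
mean-squares arithmetic and is cross-checked in the tests against
`stats::aov` with `Error()` strata to 10⁻⁸ on balanced and unbalanced
tables. Sphericity for the 3-level location factor is assumed (no
Greenhouse–Geisser correction), and participants with any missing cell
are dropped listwise per outcome with logged counts.

**Interaction power.** Because the interaction is defined as the group
difference in post−pre change and residual noise is drawn per
observation, the interaction test is algebraically a two-sample t-test
on change scores with SD $\sqrt{2}\sigma_w$. At 15 + 17 participants an
interaction of one within-subject SD is therefore an effect size of
$1/\sqrt{2}$ with analytic power near 0.5 — the design detects a
homogeneous training effect of the same size with power above 0.95, but
is underpowered for group-modulation of that effect. The calibration
tests compute both rates by simulation.

## Problem sizes

The test-suite and acceptance runs use: single trials of ~100 frames at
96 × 224 px for tracking accuracy; participants with 2 (noise-free) or
4 (noisy) trials per session for end-to-end stiffness; retest tables of
n = 500 for ICC convergence; 2,000 replicate cohorts of 15 + 17 for
type-I error and power; and a miniature full study of 2 + 2
participants with one trial per session for byte-level determinism.
These sizes were chosen so each property is measured with adequate
precision while the whole suite remains quick to run.

## Known limitations

* The tracker assumes locally translational motion and differentiable
  intensity; it is not an affine or descriptor-based tracker, and
  initial landmark positions must be supplied.
* Antagonist co-contraction and joint-rotation corrections are out of
  scope, as is Young's modulus (stress–strain) normalization.
* ICC confidence intervals are not reported; the coefficient is a point
  estimate.
* The synthetic cohort draws residuals independently per observation;
  real repeated measures can show correlated errors within a session
  that the generator does not emulate.
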