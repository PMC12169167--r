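# tendonmech

Patellar tendon mechanics from synchronized dynamometry and B-mode
ultrasound, implemented as a tested R pipeline with a synthetic-data
generator that knows the ground truth.

During a ramped isometric knee extension, the only recordings available
are the cuff force at the ankle (1,000 Hz) and an ultrasound video of
the patella apex and tibial plateau. Tendon stiffness is derived as

```
F_tendon(t) = lowpass30(F_cuff(t)) · r_ext / r_int          (moment arms)
e(t)        = ( ‖apex(t) − plateau(t)‖ − ‖apex(0) − plateau(0)‖ ) · s
k           = OLS slope dF/de of the mean F–e curve over 60–100 %
              of the common (lowest pre/post) peak force   [N/mm]
```

with per-trial curves resampled to 100 points, fitted with a 2nd-degree
polynomial, and excluded when R² < 0.90. Landmarks are tracked with a
sub-pixel pyramidal Lucas–Kanade tracker written for this package. The
same toolbox covers shear-wave-velocity QC (discard when > 5 % of
pixels, averaged over frames, exceed 90 % of the 20 m/s ceiling),
test–retest reliability (ICC(3,1), typical error, CV), and the
cohort-level mixed two-/three-way ANOVAs with partial η² and Bonferroni
post hocs used in pre/post training designs with an oral-contraceptive
user (OC) versus non-user (NOC) grouping.

Because no real recordings ship with the package, every input is
produced by the `synthgen` functions (`trial_spec()`,
`generate_force_trace()`, `generate_frame_sequence()`,
`generate_swv_map()`, `generate_cohort()`) with a known true
force–elongation law `F = a·e² + b·e`, known saturation fractions and
known cohort effects — so the full chain is validated against analytic
oracles rather than against itself.

## Worked example

The numbered scripts under `analysis/` run the study end to end;
`analysis/01_simulate_trials.R` writes four noisy synthetic trials
(force TSV + multi-frame TIFF + truth JSON) and
`analysis/02_track_stiffness.R` processes them:

```
$ Rscript analysis/01_simulate_trials.R
trial 1: 101 frames, peak tendon force 3944 N, peak elongation 3.36 mm
...
$ Rscript analysis/02_track_stiffness.R
trial01: RMS tracking error 0.0024 mm, fit R^2 1.0000 (included)
trial02: RMS tracking error 0.0022 mm, fit R^2 1.0000 (included)
trial03: RMS tracking error 0.0031 mm, fit R^2 1.0000 (included)
trial04: RMS tracking error 0.0023 mm, fit R^2 1.0000 (included)

common force 3937 N; stiffness 1661 N/mm (analytic truth 1656, error 0.31%)
```

Each trial's tracker follows the apex to a few thousandths of a mm
(pixel scale 0.1 mm/px); all four fits clear the R² ≥ 0.90 gate; the
mean-curve slope over 60–100 % of the 3937 N common force reproduces
the analytic slope of the generating law within 0.31 %. The remaining
scripts cover shear-wave QC (`03`), reliability statistics (`04`),
cohort ANOVAs and the simple tests (`05`), and a miniature fully
simulated study through `run_study()` (`06`), each writing tidy TSVs
under `results/`.

The same chain is available programmatically:

```r
library(tendonmech)
pd  <- simulate_participant("P01", "OC", seed = 1, n_trials = 4)
res <- run_participant(pd)   # stiffness, SWV, CSA, strength per session
res$outcomes
```

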