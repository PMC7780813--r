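---
title: "Models and conventions of the cardiomap pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions of the cardiomap pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the waveform models, the measurement
conventions, the numerical choices, and the design decisions behind
`cardiomap`, in the order the pipeline runs: synthesis, conditioning,
per-beat metrics, restitution, dose–response statistics.

## The synthetic recording model

Optical mapping of a paced monolayer produces, per region of interest,
a voltage-dye trace and a Ca²⁺-dye trace sampled at ~100 frames/s. The
generator emulates exactly this observable — not the underlying
biophysics. There is no ion-channel model, no spatial conduction, no
motion artifact (experiments of this type pharmacologically uncouple
contraction, so motion is deliberately out of scope).

**Action potential.** Each beat is the product of a logistic upstroke
with time constant `ap_upstroke_tau` (6 ms in both presets; optical
upstrokes are slower than patch-clamp ones because they average many
cells) and a two-phase repolarization envelope: a fraction
`ap_plateau_fraction` of the amplitude is held through a plateau of
`ap_plateau_dur` ms and then decays exponentially with `ap_repol_tau`,
while the remaining `1 − fraction` decays from the peak immediately.
A small plateau fraction gives the short, triangular atrial-like
morphology; a large one the long ventricular-like plateau. The presets
are calibrated so the dense-grid APD₈₀ at 1 Hz is ≈179 ms (atrial:
fraction 0.55, plateau 95 ms, repolarization τ 75.61 ms) and ≈251 ms
(ventricular: 0.80, 140 ms, 91.01 ms). A new stimulus takes over the
membrane: each beat's waveform occupies the window up to the next
captured stimulus, and a stimulus arriving within 40 ms of the previous
APD₈₀ point fails to capture (refractoriness), which is flagged rather
than raised.

**Ca²⁺ transient.** A cosine-bell rise followed by a mono-exponential
decay with `cat_decay_tau`, starting `cat_onset_delay` (20 ms) after
the stimulus. The rise duration is calibrated by root-solving so that
the *measured* time-to-peak (10% upstroke crossing → refined peak) on a
0.01 ms grid equals `cat_ttp` exactly. A softplus blend of width 8 ms
keeps the peak C¹-smooth — a kinked peak biases sub-sample peak
refinement by several ms at 10 ms sampling — while the decay segment
stays exactly exponential, so the manifest τ is exact. Transients sum
additively across beats (diastolic Ca²⁺ accumulation), which keeps the
trace continuous at every pacing rate; because all tails share one τ,
the summed decay segment is still exactly exponential.

The atrial preset uses TTP 116 ms and τ 350 ms. The ventricular preset
uses TTP 246 ms and τ 400 ms: a strictly mono-exponential transient
with a several-hundred-ms τ must still recover within the 1 Hz cycle
(TTP + τ·ln 5 < 1000 ms) for late-recovery metrics to exist at all, and
400 ms is the largest round value that satisfies this while keeping the
ventricular decay slower than the atrial one. Real transients decay
faster than exponentially early on, which is why experimentally fitted
τ values can exceed what their CaTD₈₀ would allow under a pure
exponential; the generator trades that realism for an exact oracle.

**Ground truth.** The manifest reports, per beat, every metric computed
on a 0.01 ms grid of the *full contextual signal* using exactly the
analyzer's windowing conventions (stimulus-aligned window to the next
stimulus; baseline = median of the pre-stimulus margin, margin
inclusive of the stimulus sample). Defining truth this way makes
"recovery within 2 ms of the manifest" a statement about sampling and
interpolation error alone, not about baseline-convention mismatches —
important at 1 Hz, where a τ = 350–400 ms transient still sits ~10–20%
of amplitude above rest when the next beat arrives. Closed-form anchors
remain available where conventions coincide (isolated beats): the
spacing CaTD₈₀ − CaTD₅₀ equals τ·ln(5/2) exactly, and τ is the preset
parameter by construction.

**Generator-side restitution.** When enabled, the target APD₈₀ of beat
*n* is `a − b·exp(−DI_n/c)` with `DI_n` the activation-referenced
diastolic interval against the previous beat's measured APD₈₀ end. The
repolarization envelope is time-scaled to meet the target: an initial
scale comes from inverting a monotone spline of dense APD₈₀ versus
scale, then up to three secant refinements against the contextual
dense measurement land the *measured* APD₈₀ on the curve (tolerance
0.05 ms). Presets `(a, b, c)` = (179, 880, 60) ms atrial and
(251, 405, 70) ms ventricular were chosen so that a 60–200 bpm ramp
analyzed by this package yields maximum slopes near 0.91 and 1.26 —
the atrial-flat / ventricular-steep ordering reported for these cell
types — with the ventricular curve mildly unstable (alternans) at the
top rates, as a slope above 1 implies.

**Noise.** Additive Gaussian noise (`gaussian_sd`, default 3% of
amplitude) plus a linear baseline drift (`drift_slope`, default
−0.008 of amplitude per second) emulating photobleaching. Defaults keep
the detrend stage's job nontrivial (up to ~10% drift over a 10 s well)
but solvable. A fixed seed gives bit-identical noise; the clean signal
does not depend on the seed.

What the generator does **not** emulate: spatial heterogeneity and
conduction, motion, multi-phase Ca²⁺ decay, dye internalization
nonlinearity, rate-dependent CaT amplitude adaptation. Passing tests
therefore demonstrate correctness of the measurement chain under the
stated signal model, not robustness to every artifact of real
recordings.

## Conditioning

`detrend()` (percentile method, the default) tracks the diastolic floor
with a rolling 20th percentile over a window that should span two beats
(default 2000 ms), then fits a robust Theil–Sen straight line through
that series and subtracts it, re-anchoring so the tracked percentile
sits at zero. The line — rather than the raw rolling percentile — is
subtracted because a percentile track follows beat-scale structure
(most visibly the slow Ca²⁺ tail) and would distort exponential decays;
the generator's photobleaching model is linear, so a line is the
matched correction, and Theil–Sen resists the floor dipping at the
quiet start/end of a recording (the pairwise-slope median tolerates
~29% outlying points). Pairwise slopes are computed on at most 400
evenly thinned points to bound the O(n²) cost deterministically. A
global polynomial (order 2) alternative is available. Degenerate
inputs: windows under 3 samples are errors, as is a window shorter than
one declared cycle length.

`normalize_and_orient()` rescales to the robust 1st/99th-percentile
range and, in `auto` mode, flips the trace when the skewness of the
first difference is negative — an upright transient has few large
positive increments (the steep upstroke) and many small negative ones.
This makes the whole downstream chain invariant to positive affine
transforms of raw counts, including the inverted polarity of
voltage-dye recordings. Constant traces are errors.

`smooth_trace()` is Savitzky–Golay (default 50 ms ≈ 5 samples, cubic):
enough to contract white noise, small enough to move noiseless APD₈₀ by
well under 1 ms. Smoothing is off by default for noiseless work and on
in the noisy-analysis configurations.

## Per-beat metrics

Segmentation is stimulus-aligned under fixed/ramp pacing (one window
per protocol stimulus, reaching to the next stimulus, with a
pre-stimulus margin of `min(100 ms, 0.25·CL)` supplying the baseline)
or derivative-threshold-based with a 200 ms refractory lockout for
spontaneous activity. Windows with amplitude below 20% of the trace's
robust amplitude are "not captured" (failed stimuli); beats cut by the
end of the recording are "truncated"; both are excluded from metrics,
and undefined metrics propagate as flagged `NA`, never as zeros.

Conventions, configurable but fixed by default:

* **APD reference** = time of maximal upstroke derivative (finite
  differences at sample midpoints, quadratic sub-sample refinement,
  ties broken earliest). The alternative upstroke-midpoint convention
  exists in the field; the maximal-derivative one is dominant and is
  what the ground truth uses.
* **CaT reference** = 10% upstroke crossing; TTP = refined peak − that
  onset. Multi-peaked beats use the first global maximum and set an
  ambiguity flag.
* **Levels** — APD_x / CaTD_x end at the first downward crossing of
  `baseline + (1 − x/100)·amplitude`, linearly interpolated; amplitude
  is per beat (refined peak minus margin median). The margin includes
  the stimulus sample so that the median of a monotone diastolic tail
  is centred on the margin midpoint — without this, a half-sample
  asymmetry biases slow-tail baselines by ~0.3% of amplitude, which an
  exponential tail amplifies into a ~3 ms CaTD₈₀ error at 100 frames/s.
* **Decay τ** — `A·exp(−t/τ) + C` by Levenberg–Marquardt over the decay
  segment from 90% down to 10% of amplitude, *excluding the first
  50 ms after the peak*: the release-to-decay transition there is not
  mono-exponential, and on noisy traces the max-based peak estimate
  pulls the 90% crossing into it, which biased τ upward by ~8% at 5%
  noise in development experiments (0.3% with the exclusion).
  Initialization is log-linear; τ is bounded to (1 ms, 10× segment
  length). If the optimizer fails on a (near-)zero-residual segment —
  a known failure mode — the log-linear solution is accepted only when
  its RMSE is below 10⁻⁵ of the amplitude (where it *is* the
  least-squares optimum); otherwise one perturbed restart is tried and
  failure is reported as `converged = FALSE`, never as the initializer.

## Electrical restitution

`compute_di()` builds the dynamic-restitution point cloud with
`DI_n = activation_n − (activation_{n−1} + APD80_{n−1})`, the standard
dynamic convention (equivalently CL − preceding APD₈₀). The first two
beats of each ramp step are discarded as non-steady (the ramp default:
60→200 bpm in 10 bpm steps, 8 beats per step — plausible values for a
protocol whose published descriptions rarely state them). A pair only
counts as a diastolic interval if no *captured* beat lies between its
two beats: a failed stimulus is genuine diastole, an unmeasurable beat
is not. Non-positive DIs are dropped and counted.

`fit_restitution()` fits `a − b·exp(−DI/c)` (monotone saturating, the
shape these curves take) by Levenberg–Marquardt and evaluates the
maximum slope `(b/c)·exp(−DI_min/c)` at the smallest retained DI, where
restitution is steepest. If the parametric fit misfits (RMSE above
8 ms) or fails, the maximum slope falls back to the steepest local
linear regression over a sliding window of 5 DI-sorted points. A curve
whose APD₈₀ variance is below 1 ms² is treated as flat (slope from the
local fallback, ~0). The fitted object carries `print`, `coef`,
`predict`, `residuals` and `plot` methods.

## Dose–response statistics

Percent change is `100·(post − pre)/pre`, signed, per well against that
well's own predrug (dose 0) baseline; baselines must be positive and
unique per well/metric, and baseline percent change is identically 0.
Group summaries average per-well percent changes (mean ± SEM across
wells) rather than forming percent-of-means: the SEM of a percent
change only exists at the well level. The two aggregations differ
slightly in general; this package reports mean-of-percents everywhere.

Between-group comparisons are Welch t tests by default (pooled-variance
Student by flag): with 6 wells per group and no variance-homogeneity
guarantee, Welch is the safer default where the protocol just says
"unpaired t test". Stars follow the .05/.01/.001 convention.

Within-group dose trends use one-way ANOVA across dose levels plus
Dunnett many-to-one comparisons of each dose against baseline. The
critical value and adjusted p values come from numerical integration of
the equicorrelated multivariate-t distribution (correlation ½ under
equal n; `sqrt(λ_i λ_j)` with `λ_i = n_i/(n_i + n₀)` for unbalanced
designs), with integration accuracy 10⁻⁴ and a fixed internal
integration seed, memoised per design. The k = 1 case reduces exactly
to the pooled two-sided t test. Two caveats are deliberate and
documented rather than patched: (i) sequential dosing in the same well
is treated as independent per-dose contrasts, not as a repeated-measures
model — the convention of the assay, at the cost of ignoring
within-well correlation; (ii) on the percent-change scale the baseline
group is the constant 0, so the pooled variance is deflated and Dunnett
there is conservative; the null-calibration checks therefore run on the
raw-duration scale, where the test suite verifies the familywise
type-I error sits within the binomial band around α = .05 over 1000
seeded replicates. Statistical validation of the screen runs on a
well-level simulator (lognormal well effects, CV 8%; multiplicative
measurement noise, CV 5%; Hill-scaled effects, optionally
chamber-specific) — the trace-level route through `run_pipeline()`
exercises the same statistics end-to-end at small n.

## Reproducibility and problem sizes

Every stochastic element (noise, simulated screens, null calibrations)
is seeded; `run_pipeline()` reproduces byte-identical tables from
(config, seed). The test suite and the acceptance script use problem
sizes chosen to exercise every stage while staying desk-scale: 8–10
beats per paced recording at 100 frames/s, 15-step ramps (~120 beats),
6 wells per cohort, 1000-replicate null calibrations, and a 10⁶-draw
Monte-Carlo oracle for the Dunnett critical value.

## Known limitations

* The waveform model is phenomenological; absolute CaTD values under
  pure-exponential decay differ from experimentally printed ones whose
  decays are multi-phase.
* No spatial analysis: activation maps, conduction velocity and
  per-pixel APD maps are out of scope.
* Restitution above slope 1 produces alternans in the memoryless
  generator (no short-term memory/accommodation), so point clouds at
  the fastest steps spread along the curve rather than sitting at a
  steady state.
* The screen statistics inherit the assay's independence conventions;
  no mixed models, and no EC₅₀ estimation from the screen.
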