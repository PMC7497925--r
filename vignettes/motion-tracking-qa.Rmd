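---
title: "Simulating respiratory-motion tracking and dose delivery for helical tomotherapy QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating respiratory-motion tracking and dose delivery for helical tomotherapy QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomomotion)
```

## What the package models

Helical tomotherapy delivers intensity-modulated radiation with a
continuously rotating gantry and a continuously translating couch.
Intrafraction respiratory motion of a thoracic or abdominal target blurs
the delivered dose and, when the target motion interferes with the
time-modulated collimation, produces interplay patterns that margins cannot
fix. Real-time tracking systems address this by modeling the target
position from two information streams — sparse kV radiographic fixes
acquired while the gantry rotates, and a continuous optical (LED) surrogate
on the chest — and steering the jaws and MLC to follow the modeled motion.

`tomomotion` is a desk-scale simulation of that entire loop, built for QA
reasoning and method study rather than for any commercial system: it
generates stochastic 3D breathing traces, emulates surrogate-correlation
tracking, quantifies tracking error, accumulates dose under three delivery
scenarios, and compares the resulting distributions with the standard
gamma-index machinery. All dosimetric claims are model-level: the delivery
is a parametric helical sweep, not a treatment-planning-system plan.

## The breathing model

Each channel (target X, Y, Z and the surrogate S) follows the Lujan
waveform

$$A(t) = \bar{A}\,\sin^{2n}\!\left(\pi t/\bar{T} - \varphi\right),$$

which spends more time at exhale than inhale; the exponent $n$ (1–3,
default 2) controls that asymmetry. Phase shifts are expressed as cycle
fractions, so a shift of 0.5 equals $\pi/2$ radians; positive shifts delay
a channel. X and Y are in phase; hysteresis of the sagittal plane is a
constant phase shift $\varphi_Z$; the surrogate has its own amplitude and
phase shift (with LEDs riding on the phantom, the surrogate *is* the Z
channel).

Stochasticity enters per breath: each respiration's period and amplitude
factor are drawn from normal distributions and smoothed with a moving
average so consecutive breaths change gradually. The defaults —
`period_sd = 0.1 * mean_period`, `amplitude_rel_sd = 0.1`, a 5-breath
window — are literature-typical magnitudes for free breathing; they are
deliberately small enough that the 3D RMS displacement of a mean-centered
trace stays governed by the $\sin^{2n}$ moments. For $n = 2$ the per-axis
RMS of a mean-centered constant-amplitude channel is
$\sqrt{35/128 - (3/8)^2}\,\bar{A} \approx 0.3644\,\bar{A}$, which is what
makes the published per-case RMS values reproducible. A single accumulated
phase advances by $\pi$ per breath and drives all channels, so
phase-shifted channels stay continuous across breath boundaries; one
shared amplitude factor scales all axes, preserving the trajectory shape.
Baseline drift is a slow half-cosine of configurable amplitude (0–2.5 mm,
default 0) added to the target axes. Every channel is registered to its
temporal mean, the convention under which a target is set up at the mean
position of its motion envelope.

```{r}
params <- breathing_parameters(mean_amplitude_x = 13, mean_amplitude_y = 12,
                               mean_amplitude_z = 13, mean_period = 5,
                               duration = 120, seed = 1)
trace <- generate_trace(params, case = "example")
trace
```

What the generator does *not* emulate: cardiac and digestive motion,
rotations and deformation, breath holds, coughs, and the long-tailed
irregularity of genuinely dyspneic patients. Tests passing under this
generator therefore validate the pipeline's mechanics and its behavior
under well-characterized quasi-periodic motion, not performance on every
clinical breathing pattern.

## The tracking emulator

The commercial motion model is proprietary; this package implements a
documented stand-in with the same information structure. At every kV
acquisition (3–5 per gantry rotation; times and angles from the delivery
configuration) the target is localized with isotropic Gaussian noise
(default 0.3 mm). The motion model regresses, per axis, the measured
target positions of the most recent `model_window` fixes (default 10) on
the surrogate displacement and its first three time derivatives evaluated
at the fix times. Between fixes the model predicts continuously on the LED
grid (12.5 ms).

The derivative count is the one genuinely open design choice, and it
matters. For $n = 2$ the waveform's harmonic content spans a
four-dimensional space (sine and cosine of twice and four times the
breathing phase). Surrogate position, velocity and acceleration span only
three of those dimensions — position and acceleration both live in the
cosine subspace — so an affine model in position and velocity (or even
acceleration) cannot represent a large fixed phase shift between surrogate
and target, and its error grows with the hysteresis angle. Adding the
third derivative completes the span: any constant phase shift of an
$n = 2$ waveform then has an exact linear representation, and the residual
error comes only from fix noise, per-breath irregularity, and $n = 3$'s
small sixth harmonic. A phase-estimation alternative (explicit breathing
phase from surrogate peak detection, harmonic regression on that phase)
was evaluated and rejected: causal phase extrapolation between peaks
contributes more error than it removes.

Predictions before `warmup_fixes` fixes (default 6, enough to identify the
five-parameter basis) are flagged invalid; models whose fit residual
exceeds 3 mm are flagged low-quality. Rank-deficient designs — a constant
surrogate, or kV times aliased onto a single breathing phase — degrade to
the identifiable subspace, which is exactly how the aliasing failure mode
reproduces: with one image per breath all fixes sample one phase, the
basis collapses, and the model cannot extrapolate across the cycle.
`choose_kv_per_rotation()` implements the clinical remedy, adding an image
per rotation when the images-per-respiration ratio falls near an integer.

Compensation geometry: the jaws track the longitudinal (Y) prediction at
every angle, the MLC tracks the transverse component perpendicular to the
beam axis, and motion along the beam axis is not compensated — its
dosimetric weight defaults to 0 (first-order depth insensitivity) and is
configurable. Before the model is valid the full displacement passes
through uncompensated; the pipeline assumes the model is built before
beam-on, so compensated deliveries start at the first model-valid time.

```{r}
cs <- builtin_case("Lung 4", seed = 1, duration = 120)
res <- run_case(cs, with_dose = FALSE)
res$tracking_summary
```

## Tracking-error statistics

Tracking error is the Euclidean norm of (predicted − true) position per
LED sample, summarized by its root mean square and by nearest-rank
quantiles: a $\delta_{95\%}$ of 1 mm means the error was 1 mm or less for
95% of the tracked treatment time. Cumulative curves report the
probability of exceeding each error level. By default only model-valid
samples enter, matching the build-model-then-treat convention; a flag
includes the warmup with the prediction pinned to the origin.

## Dose accumulation and the three scenarios

The delivery model is a parametric helical sweep: a jaw-collimated
longitudinal profile (FWHM 25 mm, Gaussian penumbra, default
$\sigma = 3$ mm) translating in Y at constant couch speed across the
target, a transverse smoothed top-hat aperture rotating with the gantry,
and a per-step output factor (uniform, or an alternating interplay-prone
preset). Output is normalized so the static delivery accumulates dose 1.0
at the target center; the dose grid defaults to 2 mm isotropic spacing
over 120 × 120 × 160 mm. Motion is applied as a rigid translation of the
phantom, and dose is scored in the phantom frame, so a phantom displaced
by $d$ receives at point $q$ the machine-frame fluence at $q + d$.

Three scenarios reuse one delivery sequence: `M0S0` (static), `M1S0` (the
raw motion trace applied), and `M1S1` (the compensation residual of a
tracking run applied). Because the kernel is flat along the beam axis,
uncompensated along-beam motion has no dosimetric effect, consistent with
the zero default weight in the residual.

Numerical choices: dose is deposited at 0.25 s steps by default (each
step's kernel is evaluated analytically, so no motion sub-sampling bias
accumulates); time-homogeneous deliveries reproduce the
static-dose-convolved-with-motion-density limit to within interpolation
error; tie-breaks in profile extraction go toward the lower index; the
gamma search interpolates the evaluated dose on a 0.2 mm lattice inside a
search radius of three distance criteria, scanning offsets in shells of
increasing distance with an exact stopping rule (a shell whose distance
term alone exceeds the current minimum cannot improve it). Pipeline tables
additionally stop once a point is proven to fail ($\gamma > 1$), which
leaves pass rates unchanged while bounding the search; oracle-grade exact
minima are available with `cap = Inf`.

## Dose comparison

Gamma analysis uses global normalization (dose differences as a percent of
the maximum reference dose) with 3%/2 mm criteria and a 10% lower dose
threshold by default; median dose difference uses a 50% threshold to focus
on the target region, positive meaning the evaluated distribution is
hotter. Comparisons default to Delta4-style orthogonal diode planes
(2.5 mm central, 5 mm peripheral spacing) sampled from the grids, with a
full-grid mode for small grids and tests. Population comparisons across
cases use two-tailed paired t-tests via `stats::t.test()`.

## Problem sizes

The packaged study cases carry their published delivery times (126–694 s),
and tracking always runs full length — it is cheap. Dose accumulation
defaults to a 120 s beam-on window (configurable); the test suite uses
30–90 s deliveries and 2–3 mm grids, sizes chosen so the full suite runs
in minutes on one core while every mechanism under test (blurring,
interplay, scenario ordering, penumbra broadening) is still well resolved.

## Known limitations

The motion model is an emulator: quantitative agreement with any
commercial tracking system beyond published accuracy envelopes is neither
expected nor claimed. The delivery model has no TPS plan, no MLC leaf
sequences, no depth dose, no heterogeneity, and no absolute calibration;
gamma pass rates from it characterize the simulation, not a clinic. One
published per-case motion magnitude ("Lung 5", 5.6 mm RMS) is not
reproducible from its printed amplitude and period parameters alone — the
constant-amplitude value implied by its amplitudes is about 4.3 mm — and
the generator makes no attempt to match it; the case is retained with its
parameters as printed.
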