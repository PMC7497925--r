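# tomomotion

Simulation and analysis of real-time respiratory-motion tracking for
helical tomotherapy delivery QA.

Intrafraction breathing motion blurs helical tomotherapy dose
distributions and, through interplay with the time-modulated collimation,
can distort them in ways margins cannot repair. Tracking systems counter
this by modeling target position from sparse intra-rotation kV position
fixes plus a continuous chest-surrogate (LED) stream and steering the
jaws/MLC accordingly. `tomomotion` reproduces that whole loop at desk
scale for medical-physics QA reasoning: it is aimed at researchers and
physicists who want a controlled, fully synthetic testbed for tracking
accuracy and motion-compensated dosimetry rather than access to any
proprietary system.

The pipeline:

- **Breathing traces** — stochastic 3D Lujan motion per channel,
  `A(t) = Ā·sin^(2n)(πt/T̄ − φ)`, with per-breath normal variation of
  period and amplitude (moving-average smoothed), sagittal hysteresis as a
  constant Z phase shift, a surrogate channel with its own amplitude and
  phase, optional baseline drift (0–2.5 mm half-cosine), and mean-position
  registration. For `n = 2` the mean-centered per-axis RMS is
  `0.3644·Ā`, so the 3D RMS of a case is `0.3644·‖Ā‖` — the quantity the
  packaged cases reproduce.
- **Delivery geometry** — gantry rotation, kV schedules (3–5 images per
  rotation), images-per-respiration ratio `T̄/(T_gantry/k)` and a circular
  aliasing index of the sampled breathing phases.
- **Tracking emulator** — per-axis linear regression of kV-measured target
  position on the surrogate and its first three derivatives over a sliding
  window of fixes, predicting continuously on the 12.5 ms LED grid;
  compensation residuals follow the beam geometry (jaws in Y, MLC
  transverse, nothing along the beam axis).
- **Error metrics** — δ_RMS, nearest-rank δ_50/δ_95, cumulative error
  curves.
- **Dose simulation** — parametric helical sweep (25 mm jaw FWHM, Gaussian
  penumbra, rotating transverse aperture, optional output modulation) with
  time-resolved rigid-motion accumulation for the M0S0 / M1S0 / M1S1
  scenarios (static / motion uncompensated / motion compensated).
- **Dose comparison** — global gamma index (3%/2 mm, 10% threshold by
  default) on Delta4-style orthogonal diode planes or full grids, median
  dose difference above 50% of the maximum, and paired two-tailed t-tests
  across cases.

## Worked example

```r
library(tomomotion)

cs  <- builtin_case("Liver 2", seed = 1, duration = 150)  # packaged case
res <- run_case(cs, dose_duration = 90)
print(res)
#> case_result 'Liver 2' (seed 1849958876)
#>   images/respiration 1.33, aliasing index 0.01
#> tracking error over 10560 samples: delta_RMS 0.83 mm, delta_50 0.48 mm, delta_95 1.73 mm
#>   M1S0_vs_M0S0: gamma pass 90.6%, median dose diff -3.0%
#>   M1S1_vs_M0S0: gamma pass 100.0%, median dose diff -0.1%
```

Reading this: the emulated tracker followed a large hysteretic liver
motion (11/14/5 mm amplitudes, 60% Z phase lag) with 0.83 mm RMS error;
without compensation the delivered dose agreed with the static delivery at
only 90.6% gamma pass rate and ran 3% cold in the target, while the
compensated delivery restored 100% agreement. `run_study()` aggregates
many cases into a per-case table plus paired t-tests;
`lung5_variants()` provides the surrogate-on-a-separate-stage parameter
sweep (amplitude, phase shift, waveform exponent).

Case configurations are plain YAML (`inst/extdata/cases/`), traces and
tracking logs are CSV, and `inst/scripts/` has thin command-line wrappers
(`simulate-trace.R`, `run-case.R`).

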