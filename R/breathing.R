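#' Breathing parameter set for the Lujan motion model
#'
#' Bundles everything needed to simulate one subject's respiratory target
#' motion: per-axis mean amplitudes of the sin^(2n) waveform, mean breathing
#' period, the exhale-weighting exponent `n`, the hysteresis phase shift of
#' the anterior/posterior (Z) axis, the chest-surrogate channel parameters,
#' per-breath stochastic variability, baseline drift, and the sampling grid.
#'
#' Phase shifts are cycle fractions: a shift of 0.5 corresponds to pi/2
#' radians in the waveform argument. Positive shifts delay the motion of that
#' channel relative to the X/Y axes (which are always in phase).
#'
#' @param mean_amplitude_x,mean_amplitude_y,mean_amplitude_z Mean peak
#'   amplitude per IEC axis (mm). X is lateral, Y longitudinal
#'   (jaw-compensated), Z vertical.
#' @param mean_period Mean breathing period (s).
#' @param n Exhale-weighting exponent of the sin^(2n) waveform; integer 1-3.
#' @param phase_shift_z Hysteresis phase shift of the Z axis, cycle fraction
#'   in \[-1, 1\].
#' @param surrogate_mean_amplitude Mean amplitude of the surrogate (chest LED)
#'   channel (mm). Defaults to `mean_amplitude_z`, i.e. LEDs riding on the
#'   phantom itself.
#' @param surrogate_phase_shift Phase shift of the surrogate channel, cycle
#'   fraction. Defaults to `phase_shift_z` (surrogate identical to the Z
#'   channel).
#' @param amplitude_rel_sd Relative standard deviation of the per-breath
#'   amplitude factor (dimensionless, default 0.1).
#' @param period_sd Standard deviation of the per-breath period (s); default
#'   0.1 * `mean_period`.
#' @param smoothing_window Moving-average window, in breaths, applied to the
#'   per-breath period and amplitude sequences (default 5).
#' @param drift_amplitude Amplitude of the low-frequency baseline-drift cosine
#'   (mm), in \[0, 2.5\]; default 0.
#' @param drift_period Period of the drift cosine (s); `NULL` (default) uses
#'   the trace duration, giving one slow half-cycle over the treatment.
#' @param duration Trace duration (s); must cover at least two mean periods.
#' @param sample_interval Uniform sampling interval (s); default 0.0125,
#'   matching an LED camera acquiring about one sample per 12.5 ms.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#'
#' @return An object of class `breathing_parameters` (a validated list).
#' @seealso [generate_trace()], [lujan_displacement()]
#' @export
breathing_parameters <- function(mean_amplitude_x = 0,
                                 mean_amplitude_y = 0,
                                 mean_amplitude_z = 0,
                                 mean_period = 4,
                                 n = 2,
                                 phase_shift_z = 0,
                                 surrogate_mean_amplitude = mean_amplitude_z,
                                 surrogate_phase_shift = phase_shift_z,
                                 amplitude_rel_sd = 0.1,
                                 period_sd = 0.1 * mean_period,
                                 smoothing_window = 5,
                                 drift_amplitude = 0,
                                 drift_period = NULL,
                                 duration = 300,
                                 sample_interval = 0.0125,
                                 seed = NULL) {
  p <- list(
    mean_amplitude_x = mean_amplitude_x,
    mean_amplitude_y = mean_amplitude_y,
    mean_amplitude_z = mean_amplitude_z,
    mean_period = mean_period,
    n = n,
    phase_shift_z = phase_shift_z,
    surrogate_mean_amplitude = surrogate_mean_amplitude,
    surrogate_phase_shift = surrogate_phase_shift,
    amplitude_rel_sd = amplitude_rel_sd,
    period_sd = period_sd,
    smoothing_window = smoothing_window,
    drift_amplitude = drift_amplitude,
    drift_period = drift_period,
    duration = duration,
    sample_interval = sample_interval,
    seed = seed
  )
  class(p) <- "breathing_parameters"
  validate_breathing_parameters(p)
  p
}

validate_breathing_parameters <- function(p) {
  stopifnot(inherits(p, "breathing_parameters"))
  amps <- c(p$mean_amplitude_x, p$mean_amplitude_y, p$mean_amplitude_z,
            p$surrogate_mean_amplitude)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("amplitudes must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(p$mean_period) || p$mean_period <= 0) {
    stop("mean_period must be > 0", call. = FALSE)
  }
  if (!(p$n %in% 1:3)) stop("n must be 1, 2 or 3", call. = FALSE)
  if (abs(p$phase_shift_z) > 1 || abs(p$surrogate_phase_shift) > 1) {
    stop("phase shifts must be cycle fractions in [-1, 1]", call. = FALSE)
  }
  if (p$amplitude_rel_sd < 0 || p$period_sd < 0) {
    stop("variability parameters must be >= 0", call. = FALSE)
  }
  if (p$smoothing_window < 1 || p$smoothing_window != round(p$smoothing_window)) {
    stop("smoothing_window must be a positive integer number of breaths",
         call. = FALSE)
  }
  if (p$drift_amplitude < 0 || p$drift_amplitude > 2.5) {
    stop("drift_amplitude must lie in [0, 2.5] mm", call. = FALSE)
  }
  if (!is.null(p$drift_period) && p$drift_period <= 0) {
    stop("drift_period must be > 0", call. = FALSE)
  }
  if (p$sample_interval <= 0) stop("sample_interval must be > 0", call. = FALSE)
  if (p$duration < 2 * p$mean_period) {
    stop("duration must be at least two mean breathing periods", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.breathing_parameters <- function(x, ...) {
  cat(sprintf(
    "breathing_parameters: A = (%.1f, %.1f, %.1f) mm (X,Y,Z), T = %.1f s, n = %d\n",
    x$mean_amplitude_x, x$mean_amplitude_y, x$mean_amplitude_z,
    x$mean_period, x$n))
  cat(sprintf("  phase shifts: Z %+.0f%%, surrogate %+.0f%% (A_S = %.1f mm)\n",
              100 * x$phase_shift_z, 100 * x$surrogate_phase_shift,
              x$surrogate_mean_amplitude))
  cat(sprintf("  variability: period sd %.2f s, amplitude rel sd %.2f, window %d breaths\n",
              x$period_sd, x$amplitude_rel_sd, x$smoothing_window))
  cat(sprintf("  drift %.2f mm; duration %.0f s @ %.4g s\n",
              x$drift_amplitude, x$duration, x$sample_interval))
  invisible(x)
}

#' Lujan sin^(2n) displacement waveform
#'
#' Evaluates `amplitude * sin^(2n)(pi * t / period - phase_fraction * pi)`,
#' the standard model for respiratory displacement spending more time at
#' exhale than inhale. The returned displacement is bounded in
#' \[0, amplitude\].
#'
#' @param t Time (s); vectorized.
#' @param amplitude Peak displacement (mm).
#' @param period Breathing period (s), > 0.
#' @param n Exhale-weighting exponent (integer >= 1).
#' @param phase_fraction Starting phase as a cycle fraction (0.5 = pi/2).
#' @return Displacement (mm), same length as `t`.
#' @examples
#' lujan_displacement(1, amplitude = 10, period = 4, n = 2)  # 10 * sin^4(pi/4) = 2.5
#' @export
lujan_displacement <- function(t, amplitude, period, n = 2, phase_fraction = 0) {
  if (!is.finite(period) || period <= 0) stop("period must be > 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  amplitude * sin(pi * t / period - phase_fraction_to_radians(phase_fraction))^(2 * n)
}

#' Convert a phase shift from cycle fraction to radians
#'
#' Phase shifts are specified as cycle fractions ("percent" shifts): a shift
#' of 0.5 (50%) corresponds to pi/2 radians in the sin^(2n) argument.
#'
#' @param p Cycle fraction(s) with |p| <= 1.
#' @return Phase in radians: `p * pi`.
#' @export
phase_fraction_to_radians <- function(p) {
  if (any(!is.finite(p)) || any(abs(p) > 1)) {
    stop("phase fractions must be finite with |p| <= 1", call. = FALSE)
  }
  p * pi
}
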