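# Motion-trace generation: stochastic per-breath sampling, accumulated phase,
# hysteresis and surrogate channels, baseline drift, mean-position registration.

# moving average with partial windows at the edges (centered)
moving_average <- function(x, w) {
  if (w < 1 || w != round(w)) stop("smoothing window must be a positive integer",
                                   call. = FALSE)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (w - 1) %/% 2
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + (w - 1 - h), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Sample a smoothed per-breath period/amplitude sequence
#'
#' Draws one period and one amplitude factor per breath from normal
#' distributions (`Normal(mean_period, period_sd)` and
#' `Normal(1, amplitude_rel_sd)`), truncated positive by resampling, then
#' smooths both sequences with a centered moving average of
#' `smoothing_window` breaths so consecutive respirations change gradually.
#' Enough breaths are drawn to cover `duration` (plus one spare breath).
#'
#' @param params A [breathing_parameters()] object. If `params$seed` is not
#'   `NULL` the RNG is seeded, making the sequence reproducible.
#' @return A data frame with one row per breath: `period` (s) and
#'   `amplitude_factor` (dimensionless, mean ~1).
#' @export
generate_breath_sequence <- function(params) {
  validate_breathing_parameters(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  draw_pos <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  # draw generously, extend if an unlucky sequence of short breaths falls short
  n0 <- ceiling(params$duration / params$mean_period * 1.5) +
    params$smoothing_window + 2
  periods <- draw_pos(n0, params$mean_period, params$period_sd)
  amps <- draw_pos(n0, 1, params$amplitude_rel_sd)
  while (sum(periods) < params$duration + params$mean_period) {
    periods <- c(periods, draw_pos(8, params$mean_period, params$period_sd))
    amps <- c(amps, draw_pos(8, 1, params$amplitude_rel_sd))
  }
  periods <- moving_average(periods, params$smoothing_window)
  amps <- moving_average(amps, params$smoothing_window)
  keep <- which(cumsum(periods) >= params$duration + params$mean_period)[1]
  if (is.na(keep)) keep <- length(periods)
  data.frame(period = periods[seq_len(keep)],
             amplitude_factor = amps[seq_len(keep)])
}

#' Generate a 3D target + surrogate respiratory motion trace
#'
#' Builds the full stochastic phantom motion for one subject case. A single
#' accumulated breathing phase advances by pi per breath (piecewise linearly
#' in time), so all channels stay continuous across breath boundaries. The
#' X and Y axes are evaluated in phase, the Z axis with the hysteresis shift
#' `phase_shift_z`, and the surrogate channel with `surrogate_phase_shift`
#' and `surrogate_mean_amplitude`. One shared per-breath amplitude factor
#' (linearly interpolated between breath midpoints) scales all channels. A
#' low-frequency baseline-drift cosine is added to the three target axes.
#' Finally every channel is registered to its temporal mean position
#' (mean-centered), the convention under which a static target is aligned to
#' the mean of its motion envelope.
#'
#' @param params A [breathing_parameters()] object.
#' @param case Optional case label stored in the trace metadata.
#' @return A `motion_trace`: list with `times`, `x`, `y`, `z`, `s` (all mm,
#'   mean-centered), and `metadata` (case label, parameters, breath sequence
#'   and breath boundary times).
#' @export
generate_trace <- function(params, case = NA_character_) {
  validate_breathing_parameters(params)
  breaths <- generate_breath_sequence(params)
  t_breaks <- c(0, cumsum(breaths$period))
  times <- seq(0, params$duration, by = params$sample_interval)
  # accumulated phase: pi per breath, linear within each breath
  phase <- pi * stats::approx(t_breaks, seq_along(t_breaks) - 1, times)$y
  mids <- (t_breaks[-length(t_breaks)] + t_breaks[-1]) / 2
  factor <- stats::approx(mids, breaths$amplitude_factor, times, rule = 2)$y
  wave <- function(shift) sin(phase - phase_fraction_to_radians(shift))^(2 * params$n)
  x <- params$mean_amplitude_x * factor * wave(0)
  y <- params$mean_amplitude_y * factor * wave(0)
  z <- params$mean_amplitude_z * factor * wave(params$phase_shift_z)
  s <- params$surrogate_mean_amplitude * factor * wave(params$surrogate_phase_shift)
  if (params$drift_amplitude > 0) {
    dp <- if (is.null(params$drift_period)) params$duration else params$drift_period
    drift <- params$drift_amplitude * cos(pi * times / dp)
    x <- x + drift; y <- y + drift; z <- z + drift
  }
  trace <- list(
    times = times,
    x = x - mean(x), y = y - mean(y), z = z - mean(z), s = s - mean(s),
    metadata = list(case = case, params = params, breaths = breaths,
                    breath_times = t_breaks)
  )
  class(trace) <- "motion_trace"
  trace
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("motion_trace '%s': %d samples over %.1f s (dt = %.4g s)\n",
              x$metadata$case, length(x$times), max(x$times) - min(x$times),
              x$times[2] - x$times[1]))
  cat(sprintf("  peak-to-peak (mm): X %.1f, Y %.1f, Z %.1f, S %.1f; 3D RMS %.2f mm\n",
              diff(range(x$x)), diff(range(x$y)), diff(range(x$z)),
              diff(range(x$s)), rms_displacement_from_origin(x)))
  invisible(x)
}

#' @export
as.data.frame.motion_trace <- function(x, ...) {
  data.frame(time_s = x$times, x_mm = x$x, y_mm = x$y, z_mm = x$z, s_mm = x$s)
}

#' RMS displacement from the registered origin
#'
#' The 3D magnitude-of-motion metric for a mean-registered trace:
#' `sqrt(mean(x^2 + y^2 + z^2))` over all samples. With tracking disabled,
#' the tracking error delta_RMS of a delivery equals this value.
#'
#' @param trace A `motion_trace`.
#' @return RMS displacement (mm).
#' @export
rms_displacement_from_origin <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  if (length(trace$times) == 0) stop("empty trace", call. = FALSE)
  sqrt(mean(trace$x^2 + trace$y^2 + trace$z^2))
}

#' Resample a motion trace onto a new uniform grid
#'
#' Linear interpolation of every channel onto a uniform grid with the given
#' interval, spanning the original time range. Used to match a trace to the
#' LED camera acquisition rate before comparison with a tracking log.
#'
#' @param trace A `motion_trace`.
#' @param interval New sampling interval (s).
#' @return A resampled `motion_trace`.
#' @export
resample_trace <- function(trace, interval) {
  stopifnot(inherits(trace, "motion_trace"))
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  span <- max(trace$times) - min(trace$times)
  if (interval > span) stop("interval exceeds trace span", call. = FALSE)
  new_t <- seq(min(trace$times), max(trace$times), by = interval)
  out <- trace
  out$times <- new_t
  for (ch in c("x", "y", "z", "s")) {
    out[[ch]] <- stats::approx(trace$times, trace[[ch]], new_t)$y
  }
  out
}

#' Check trace motion against the jaw-compensation limit
#'
#' Longitudinal (IEC-Y) motion can only be jaw-compensated if its
#' peak-to-peak span stays below the jaw width with the target aligned to
#' the mean position. Reports the Y span and a pass/fail flag.
#'
#' @param trace A `motion_trace` (assumed mean-registered).
#' @param jaw_width Jaw width projected to isocenter (mm), default 25.
#' @return List with `peak_to_peak_y` (mm), `jaw_width` and logical `pass`.
#' @export
validate_motion_limits <- function(trace, jaw_width = 25) {
  stopifnot(inherits(trace, "motion_trace"))
  if (jaw_width <= 0) stop("jaw_width must be > 0", call. = FALSE)
  p2p <- if (length(trace$y)) diff(range(trace$y)) else 0
  list(peak_to_peak_y = p2p, jaw_width = jaw_width, pass = p2p < jaw_width)
}

#' Write / read a motion trace as CSV
#'
#' Plain CSV with header `time_s,x_mm,y_mm,z_mm,s_mm`, '.' decimal separator,
#' values written with six decimals (round trips are lossless to 1e-6).
#'
#' @param trace A `motion_trace`.
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `motion_trace` (metadata restricted to the case label).
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df[] <- lapply(df, function(v) sprintf("%.6f", v))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trace_csv
#' @param case Case label to attach on read.
#' @export
read_trace_csv <- function(path, case = NA_character_) {
  df <- utils::read.csv(path)
  expected <- c("time_s", "x_mm", "y_mm", "z_mm", "s_mm")
  if (!all(expected %in% names(df))) {
    stop("trace CSV must have columns ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  trace <- list(times = df$time_s, x = df$x_mm, y = df$y_mm, z = df$z_mm,
                s = df$s_mm, metadata = list(case = case, params = NULL,
                                             breaths = NULL,
                                             breath_times = NULL))
  class(trace) <- "motion_trace"
  trace
}
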