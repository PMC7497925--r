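# Delivery timeline: gantry rotation, kV acquisition schedule, LED sampling,
# and breathing/imaging aliasing diagnostics.

#' Delivery configuration
#'
#' Timing and geometry of one helical delivery as seen by the tracking
#' emulator: gantry rotation period, number of kV position fixes per
#' rotation, LED sampling interval, jaw width, kV localization noise and the
#' motion-model fitting window.
#'
#' @param gantry_period Gantry rotation period (s), default 12.
#' @param kv_per_rotation kV acquisitions per gantry rotation (typically 3-5).
#' @param treatment_duration Delivery time (s).
#' @param led_interval LED camera sampling interval (s), default 0.0125.
#' @param jaw_width_iso Jaw width projected to isocenter (mm), default 25.
#' @param couch_speed Couch speed (mm/s); `NULL` leaves it to the dose stage.
#' @param kv_noise_sd Isotropic Gaussian noise of a kV 3D position fix (mm),
#'   default 0.3.
#' @param model_window Number of most recent kV fixes used to refit the
#'   correlation model (default 10).
#' @param warmup_fixes Number of fixes required before the model is
#'   considered built (default 6; predictions earlier are flagged invalid).
#' @param fit_residual_threshold Fit RMS residual (mm) above which a model is
#'   flagged low-quality in the tracking log (default 3).
#' @return A `delivery_config` object.
#' @export
delivery_config <- function(gantry_period = 12,
                            kv_per_rotation = 4,
                            treatment_duration = 120,
                            led_interval = 0.0125,
                            jaw_width_iso = 25,
                            couch_speed = NULL,
                            kv_noise_sd = 0.3,
                            model_window = 10,
                            warmup_fixes = 6,
                            fit_residual_threshold = 3) {
  stopifnot(gantry_period > 0, kv_per_rotation >= 1, treatment_duration > 0,
            led_interval > 0, jaw_width_iso > 0, kv_noise_sd >= 0,
            model_window >= 1, warmup_fixes >= 1)
  structure(list(gantry_period = gantry_period,
                 kv_per_rotation = as.integer(kv_per_rotation),
                 treatment_duration = treatment_duration,
                 led_interval = led_interval,
                 jaw_width_iso = jaw_width_iso,
                 couch_speed = couch_speed,
                 kv_noise_sd = kv_noise_sd,
                 model_window = as.integer(model_window),
                 warmup_fixes = as.integer(warmup_fixes),
                 fit_residual_threshold = fit_residual_threshold),
            class = "delivery_config")
}

#' kV acquisition schedule
#'
#' Acquisition times and gantry angles for a delivery: `kv_per_rotation`
#' evenly spaced acquisitions per rotation (starting one interval into the
#' delivery, i.e. times k * gantry_period / kv_per_rotation for k = 1, 2,
#' ...), repeating until `treatment_duration`. Angles advance by
#' 360 / kv_per_rotation degrees and wrap to \[0, 360).
#'
#' @param config A [delivery_config()].
#' @param angle_offset Optional starting angle (degrees).
#' @return Data frame with `time` (s) and `gantry_angle` (degrees).
#' @export
kv_schedule <- function(config, angle_offset = 0) {
  stopifnot(inherits(config, "delivery_config"))
  dt <- config$gantry_period / config$kv_per_rotation
  times <- seq(dt, config$treatment_duration, by = dt)
  angles <- (angle_offset + 360 * times / config$gantry_period) %% 360
  data.frame(time = times, gantry_angle = angles)
}

#' Images per respiration
#'
#' Ratio of the mean respiratory period to the average time between kV
#' acquisitions. Values near 1 (one image per breath) indicate that the
#' imaging can alias with the breathing, sampling only one respiratory
#' phase.
#'
#' @param mean_period Mean breathing period (s).
#' @param gantry_period Gantry rotation period (s).
#' @param kv_per_rotation kV acquisitions per rotation.
#' @return Dimensionless ratio `mean_period / (gantry_period / kv_per_rotation)`.
#' @examples
#' images_per_respiration(3, 11.8, 4)  # ~1.0: aliasing-prone
#' images_per_respiration(3, 11.8, 5)  # ~1.3
#' @export
images_per_respiration <- function(mean_period, gantry_period, kv_per_rotation) {
  if (any(c(mean_period, gantry_period, kv_per_rotation) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  mean_period / (gantry_period / kv_per_rotation)
}

#' Choose a kV-per-rotation count that avoids breathing aliasing
#'
#' Picks the first candidate count whose images-per-respiration ratio is not
#' within `margin` of an integer (an integer ratio means successive images
#' land on the same respiratory phase). Mirrors the clinical remedy of
#' adding an image per rotation when aliasing is observed.
#'
#' @param mean_period Mean breathing period (s).
#' @param gantry_period Gantry rotation period (s).
#' @param candidates Candidate counts tried in order (default 4, 5, 3).
#' @param margin Exclusion half-width around integer ratios (default 0.2).
#' @return An integer from `candidates` (the last one if all are aliased).
#' @export
choose_kv_per_rotation <- function(mean_period, gantry_period,
                                   candidates = c(4L, 5L, 3L), margin = 0.2) {
  for (k in candidates) {
    ipr <- images_per_respiration(mean_period, gantry_period, k)
    if (abs(ipr - round(ipr)) >= margin || round(ipr) < 1) return(as.integer(k))
  }
  as.integer(candidates[length(candidates)])
}

#' Respiratory phase at given times
#'
#' Evaluates the accumulated breathing phase of a generated trace, modulo one
#' cycle, at the query times. One cycle is one breath; the returned phase is
#' a fraction in \[0, 1). Requires a trace produced by [generate_trace()]
#' (whose metadata stores the breath boundary times).
#'
#' @param trace A `motion_trace` from [generate_trace()].
#' @param times Query times (s) within the trace span.
#' @return Phase fractions in \[0, 1).
#' @export
respiratory_phase_at <- function(trace, times) {
  stopifnot(inherits(trace, "motion_trace"))
  tb <- trace$metadata$breath_times
  if (is.null(tb)) stop("trace has no breath metadata", call. = FALSE)
  if (any(times < min(tb) - 1e-9) || any(times > max(tb) + 1e-9)) {
    stop("query times outside trace span", call. = FALSE)
  }
  breaths <- stats::approx(tb, seq_along(tb) - 1, times, rule = 2)$y
  breaths %% 1
}

#' Circular aliasing index of sampled respiratory phases
#'
#' Mean resultant length of the sampled phases mapped onto the unit circle:
#' 1 when every image lands on the same respiratory phase (fully aliased),
#' near 0 when the phases are spread evenly over the cycle. Invariant to a
#' global rotation of all phases.
#'
#' @param phases Phase fractions (cycle units), length >= 2.
#' @return Index in \[0, 1\].
#' @export
aliasing_index <- function(phases) {
  if (length(phases) < 2) stop("need at least 2 phases", call. = FALSE)
  ang <- 2 * pi * phases
  sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
}
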