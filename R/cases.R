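# Built-in study cases: 13 subject parameter sets (lung/liver/pancreas) and
# the nine Lung 5 surrogate-stage variants used for separate LED/target motion.

#' Built-in subject motion cases
#'
#' The thirteen subject parameter sets used throughout the package: per-axis
#' mean amplitudes (mm), mean period (s), hysteresis phase shift of the Z
#' axis (cycle fraction), the waveform exponent `n = 2`, the published 3D RMS
#' displacement of the resulting mean-registered trace, and the plan delivery
#' time (s). `rms_published` for "Lung 5" is not reproducible from its
#' amplitude/period parameters alone (the implied constant-amplitude value is
#' about 4.3 mm) and is retained for reference only.
#'
#' @return A data frame with one row per case.
#' @export
study_cases <- function() {
  df <- read.table(header = TRUE, text = "
case        a_y a_z a_x rms_published period phase_z delivery_time
'Lung 1'     16  10   6  6.9          5       0.20   126
'Lung 2'      5  10   9  5.4          5      -0.10   677
'Lung 3'      7  14  13  7.4          5      -0.20   694
'Lung 4'     12  13  13  8.0          5       0.00   536
'Lung 5'     10   6   2  5.6          5       0.00   252
'Liver 1'     9   2   1  3.4          3      -0.50   462
'Liver 2'    11  14   5  6.8          4      -0.60   253
'Liver 3'    16   5   1  6.1          4       0.10   556
'Liver 4'    18  16   6  9.4          3       0.00   568
'Pancreas 1' 13   3   1  5.4          3       0.20   287
'Pancreas 2' 14  11   5  6.8          5      -0.50   289
'Pancreas 3' 14   3   1  5.3          4      -0.10   208
'Pancreas 4' 10   6   6  5.1          4      -0.20   246")
  df$n <- 2L
  df
}

#' Lung 5 surrogate-stage variants
#'
#' Nine variants of the Lung 5 case with the LED surrogate on a separate 1D
#' stage. The base variant (a) uses a 5 mm surrogate amplitude, zero
#' surrogate phase shift, `n = 2` and a 5 s period; each subsequent variant
#' changes exactly one parameter (surrogate amplitude, surrogate phase
#' shift, or the waveform exponent of both target and surrogate).
#'
#' @return A data frame with one row per variant: `case`,
#'   `surrogate_amplitude` (mm), `surrogate_phase` (cycle fraction), `n`.
#' @export
lung5_variants <- function() {
  read.table(header = TRUE, text = "
case      surrogate_amplitude surrogate_phase n
'Lung 5a'  5                  0.0             2
'Lung 5b' 10                  0.0             2
'Lung 5c'  3                  0.0             2
'Lung 5d'  5                  0.1             2
'Lung 5e'  5                  0.2             2
'Lung 5f'  5                 -0.1             2
'Lung 5g'  5                 -0.2             2
'Lung 5h'  5                  0.0             1
'Lung 5i'  5                  0.0             3")
}

#' Assemble a case study definition
#'
#' Combines breathing parameters, delivery configuration, LED placement mode
#' and the scenario list into one unit the pipeline can run. In
#' `led_mode = "phantom"` the surrogate channel is the target's Z channel
#' (LEDs placed on the phantom); in `led_mode = "surrogate-stage"` the
#' surrogate follows its own amplitude/phase parameters, which must then be
#' supplied in `params`.
#'
#' @param id Case label.
#' @param params A [breathing_parameters()] object.
#' @param config A [delivery_config()] object.
#' @param led_mode `"phantom"` or `"surrogate-stage"`.
#' @param scenarios Character subset of `c("M0S0", "M1S0", "M1S1")`.
#' @param seed Master seed for the case (integer).
#' @return A `case_study` object.
#' @export
case_study <- function(id, params, config,
                       led_mode = c("phantom", "surrogate-stage"),
                       scenarios = c("M0S0", "M1S0", "M1S1"),
                       seed = 1L) {
  led_mode <- match.arg(led_mode)
  stopifnot(inherits(params, "breathing_parameters"),
            inherits(config, "delivery_config"))
  if (!all(scenarios %in% c("M0S0", "M1S0", "M1S1"))) {
    stop("scenarios must be a subset of M0S0, M1S0, M1S1", call. = FALSE)
  }
  if (led_mode == "phantom") {
    # LEDs ride on the phantom: surrogate == target Z channel
    params$surrogate_mean_amplitude <- params$mean_amplitude_z
    params$surrogate_phase_shift <- params$phase_shift_z
  }
  structure(list(id = id, params = params, config = config,
                 led_mode = led_mode, scenarios = scenarios,
                 seed = as.integer(seed)),
            class = "case_study")
}

#' Build a case study from a built-in case row
#'
#' Convenience constructor: looks up `id` in [study_cases()] (or
#' [lung5_variants()], which reuse the Lung 5 target motion), fills in the
#' breathing parameters, sets the treatment duration to the published plan
#' delivery time (unless overridden) and picks a kV schedule with
#' [choose_kv_per_rotation()] to avoid breathing/imaging aliasing.
#'
#' @param id A case label present in [study_cases()] or [lung5_variants()].
#' @param seed Master seed.
#' @param duration Treatment duration override (s); `NULL` uses the published
#'   delivery time.
#' @param drift_amplitude Baseline drift amplitude (mm), default 0.
#' @param ... Passed on to [delivery_config()].
#' @return A `case_study`.
#' @export
builtin_case <- function(id, seed = 1L, duration = NULL, drift_amplitude = 0,
                         ...) {
  cases <- study_cases()
  variants <- lung5_variants()
  if (id %in% cases$case) {
    row <- cases[cases$case == id, ]
    led_mode <- "phantom"
    surr_amp <- row$a_z; surr_phase <- row$phase_z
    n <- row$n
  } else if (id %in% variants$case) {
    v <- variants[variants$case == id, ]
    row <- cases[cases$case == "Lung 5", ]
    led_mode <- "surrogate-stage"
    surr_amp <- v$surrogate_amplitude; surr_phase <- v$surrogate_phase
    n <- v$n
  } else {
    stop("unknown case id: ", id, call. = FALSE)
  }
  dur <- if (is.null(duration)) row$delivery_time else duration
  params <- breathing_parameters(
    mean_amplitude_x = row$a_x, mean_amplitude_y = row$a_y,
    mean_amplitude_z = row$a_z, mean_period = row$period, n = n,
    phase_shift_z = row$phase_z,
    surrogate_mean_amplitude = surr_amp, surrogate_phase_shift = surr_phase,
    drift_amplitude = drift_amplitude, duration = dur, seed = NULL)
  config <- delivery_config(treatment_duration = dur, ...)
  config$kv_per_rotation <- choose_kv_per_rotation(row$period,
                                                   config$gantry_period)
  case_study(id, params, config, led_mode = led_mode, seed = seed)
}

#' Read / write case configuration files
#'
#' Case configurations are stored as YAML (or JSON) with a `case` block
#' mirroring the breathing-parameter fields, a `delivery` block for the
#' delivery configuration, plus `led_mode`, `scenarios` and `seed`. The
#' packaged configurations under `inst/extdata/cases/` cover the thirteen
#' built-in subject cases and the nine surrogate-stage variants.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config.
#' @return `load_case_config` returns a `case_study`.
#' @export
load_case_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  b <- cfg$case
  params <- breathing_parameters(
    mean_amplitude_x = b$mean_amplitude_x,
    mean_amplitude_y = b$mean_amplitude_y,
    mean_amplitude_z = b$mean_amplitude_z,
    mean_period = b$mean_period,
    n = b$n,
    phase_shift_z = b$phase_shift_z,
    surrogate_mean_amplitude = b$surrogate_mean_amplitude %||% b$mean_amplitude_z,
    surrogate_phase_shift = b$surrogate_phase_shift %||% b$phase_shift_z,
    amplitude_rel_sd = b$amplitude_rel_sd %||% 0.1,
    period_sd = b$period_sd %||% (0.1 * b$mean_period),
    smoothing_window = b$smoothing_window %||% 5,
    drift_amplitude = b$drift_amplitude %||% 0,
    drift_period = b$drift_period,
    duration = b$duration,
    sample_interval = b$sample_interval %||% 0.0125)
  d <- cfg$delivery %||% list()
  config <- delivery_config(
    gantry_period = d$gantry_period %||% 12,
    kv_per_rotation = d$kv_per_rotation %||% 4,
    treatment_duration = d$treatment_duration %||% b$duration,
    led_interval = d$led_interval %||% 0.0125,
    jaw_width_iso = d$jaw_width_iso %||% 25,
    kv_noise_sd = d$kv_noise_sd %||% 0.3,
    model_window = d$model_window %||% 10,
    warmup_fixes = d$warmup_fixes %||% 6)
  case_study(cfg$id %||% tools::file_path_sans_ext(basename(path)),
             params, config,
             led_mode = cfg$led_mode %||% "phantom",
             scenarios = cfg$scenarios %||% c("M0S0", "M1S0", "M1S1"),
             seed = cfg$seed %||% 1L)
}

#' @rdname load_case_config
#' @param case A `case_study` to serialise.
#' @export
write_case_config <- function(case, path) {
  stopifnot(inherits(case, "case_study"))
  p <- case$params; d <- case$config
  cfg <- list(
    id = case$id,
    led_mode = case$led_mode,
    scenarios = case$scenarios,
    seed = case$seed,
    case = list(
      mean_amplitude_x = p$mean_amplitude_x,
      mean_amplitude_y = p$mean_amplitude_y,
      mean_amplitude_z = p$mean_amplitude_z,
      mean_period = p$mean_period, n = p$n,
      phase_shift_z = p$phase_shift_z,
      surrogate_mean_amplitude = p$surrogate_mean_amplitude,
      surrogate_phase_shift = p$surrogate_phase_shift,
      amplitude_rel_sd = p$amplitude_rel_sd, period_sd = p$period_sd,
      smoothing_window = p$smoothing_window,
      drift_amplitude = p$drift_amplitude,
      duration = p$duration, sample_interval = p$sample_interval),
    delivery = list(
      gantry_period = d$gantry_period, kv_per_rotation = d$kv_per_rotation,
      treatment_duration = d$treatment_duration,
      led_interval = d$led_interval, jaw_width_iso = d$jaw_width_iso,
      kv_noise_sd = d$kv_noise_sd, model_window = d$model_window,
      warmup_fixes = d$warmup_fixes))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
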