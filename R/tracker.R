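# Emulated surrogate-correlation tracking: sparse kV target fixes + a
# continuous LED surrogate stream drive a per-axis linear motion model.
#
# The model regresses each target axis on the surrogate displacement and its
# first `n_derivatives` time derivatives. For a sin^(2n) waveform with n = 2
# the harmonic content lives in a four-dimensional space (cos/sin of twice
# and four times the breathing phase); {s, s', s''} spans only three of those
# dimensions, so the third derivative is included by default, which gives an
# exact linear representation of any fixed phase shift between surrogate and
# target. This is a documented simplified emulator, not the commercial
# algorithm.

# surrogate feature matrix: columns 1, s, s', s'', s''' (finite differences,
# each derivative smoothed over `smooth_n` samples)
surrogate_features <- function(s, dt, n_derivatives = 3, smooth_n = 9) {
  cols <- list(rep(1, length(s)), s)
  d <- s
  if (n_derivatives >= 1) {
    for (k in seq_len(n_derivatives)) {
      d <- c(0, diff(d)) / dt
      d[1] <- d[2]
      d <- moving_average(d, smooth_n)
      cols[[k + 2]] <- d
    }
  }
  m <- do.call(cbind, cols)
  nm <- c("intercept", "position", "velocity", "acceleration", "jerk")
  colnames(m) <- nm[seq_len(ncol(m))]
  m
}

# least squares with graceful rank handling: rank-deficient columns get zero
# coefficients (pivoted QR); a constant surrogate degrades to intercept-only
fit_axis <- function(X, y) {
  qx <- qr(X)
  cf <- qr.coef(qx, y)
  cf[is.na(cf)] <- 0
  cf
}

#' Simulate a kV localization of the target
#'
#' Interpolates the true target position from the motion trace at the
#' acquisition time and adds isotropic Gaussian localization noise,
#' emulating a 3D position fix reconstructed from kV radiographs. Uses the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param trace A `motion_trace`.
#' @param time Acquisition time (s), within the trace span.
#' @param noise_sd Isotropic noise standard deviation (mm).
#' @param gantry_angle Gantry angle (degrees) stored with the fix.
#' @return A one-row data frame: `time`, `gantry_angle`, measured and true
#'   x/y/z (mm).
#' @export
localize_target <- function(trace, time, noise_sd = 0.3, gantry_angle = 0) {
  stopifnot(inherits(trace, "motion_trace"))
  if (time < min(trace$times) - 1e-9 || time > max(trace$times) + 1e-9) {
    stop("localization time outside trace span", call. = FALSE)
  }
  true <- vapply(c("x", "y", "z"),
                 function(ch) stats::approx(trace$times, trace[[ch]], time)$y,
                 numeric(1))
  meas <- true + stats::rnorm(3, 0, noise_sd)
  data.frame(time = time, gantry_angle = gantry_angle %% 360,
             meas_x = meas[1], meas_y = meas[2], meas_z = meas[3],
             true_x = true[1], true_y = true[2], true_z = true[3])
}

#' Fit the surrogate-correlation motion model
#'
#' Per-axis least-squares fit of the measured target positions (from kV
#' fixes) on the surrogate displacement and its first `n_derivatives` time
#' derivatives, evaluated at the fix times from the LED surrogate history.
#' With a noiseless linear target-surrogate relation the fit interpolates
#' exactly. If the design is rank deficient (e.g. a constant surrogate) the
#' unidentifiable coefficients are set to zero, degrading gracefully to an
#' intercept-only model, and a warning is issued.
#'
#' @param fixes Data frame of kV fixes as returned by [localize_target()]
#'   (columns `time`, `meas_x`, `meas_y`, `meas_z`).
#' @param surrogate_history Data frame with `time` and `s` (mm): the LED
#'   surrogate record, uniformly sampled.
#' @param n_derivatives Number of surrogate derivatives in the basis (0-3,
#'   default 3).
#' @param smooth_n Moving-average width (samples) used when estimating
#'   derivatives (default 9).
#' @return A `correlation_model`: coefficient matrix (basis x axis), number
#'   of fixes used, fit time, and per-axis fit RMS residual (mm).
#' @export
fit_correlation_model <- function(fixes, surrogate_history, n_derivatives = 3,
                                  smooth_n = 9) {
  if (nrow(fixes) < 2) stop("need at least 2 fixes", call. = FALSE)
  dt <- surrogate_history$time[2] - surrogate_history$time[1]
  B <- surrogate_features(surrogate_history$s, dt, n_derivatives, smooth_n)
  idx <- round((fixes$time - surrogate_history$time[1]) / dt) + 1
  if (any(idx < 1 | idx > nrow(B))) {
    stop("fix times outside surrogate history", call. = FALSE)
  }
  X <- B[idx, , drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    warning("rank-deficient surrogate design; dropping unidentifiable terms",
            call. = FALSE)
  }
  Y <- as.matrix(fixes[, c("meas_x", "meas_y", "meas_z")])
  coefs <- apply(Y, 2, function(y) fit_axis(X, y))
  rownames(coefs) <- colnames(B)
  colnames(coefs) <- c("x", "y", "z")
  resid <- Y - X %*% coefs
  structure(list(coefficients = coefs,
                 n_fixes_used = nrow(fixes),
                 fit_time = max(fixes$time),
                 n_derivatives = n_derivatives,
                 smooth_n = smooth_n,
                 fit_rms = sqrt(colMeans(resid^2))),
            class = "correlation_model")
}

#' Predict target position from the correlation model
#'
#' Evaluates the fitted per-axis linear map at the given surrogate feature
#' rows (as built by the tracking loop: intercept, position, and derivative
#' columns matching the model's basis).
#'
#' @param object A `correlation_model`.
#' @param features Numeric matrix whose columns match the model basis.
#' @param ... Unused.
#' @return Matrix with columns x, y, z (mm), one row per feature row.
#' @export
predict.correlation_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(object$coefficients)) {
    stop("feature columns do not match model basis", call. = FALSE)
  }
  features %*% object$coefficients
}

#' Run the emulated tracking loop over a delivery
#'
#' Event loop on the LED grid: the surrogate channel is sampled continuously
#' at `led_interval`; at each kV schedule time a noisy 3D target fix is
#' added and the correlation model is refitted over the most recent
#' `model_window` fixes; between fixes the current model predicts the target
#' from the surrogate features. Predictions before `warmup_fixes` fixes are
#' flagged invalid (`model_valid = FALSE`). Models whose fit RMS residual
#' exceeds the configured threshold are flagged low-quality in the log.
#'
#' @param trace A `motion_trace` spanning at least the treatment duration.
#' @param config A [delivery_config()].
#' @param n_derivatives Surrogate derivative count of the model basis
#'   (default 3).
#' @param seed Optional RNG seed for the kV noise.
#' @return A `tracked_trace`: LED-grid `times`, `predicted` and `true`
#'   position matrices (mm), `model_valid` and `low_quality` flags,
#'   `gantry_angle` per sample, and the fix table.
#' @export
run_tracking <- function(trace, config, n_derivatives = 3, seed = NULL) {
  stopifnot(inherits(trace, "motion_trace"), inherits(config, "delivery_config"))
  if (max(trace$times) < config$treatment_duration - 1e-9) {
    stop("trace shorter than the treatment duration", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- config$led_interval
  times <- seq(0, config$treatment_duration, by = dt)
  led <- resample_trace(trace, dt)
  keep <- seq_along(times)
  s <- led$s[keep]
  truth <- cbind(x = led$x[keep], y = led$y[keep], z = led$z[keep])
  B <- surrogate_features(s, dt, n_derivatives = n_derivatives)
  sched <- kv_schedule(config)
  sched <- sched[sched$time <= max(times), , drop = FALSE]
  fix_idx <- round(sched$time / dt) + 1
  noise <- matrix(stats::rnorm(3 * nrow(sched), 0, config$kv_noise_sd), ncol = 3)
  fixes <- data.frame(time = times[fix_idx],
                      gantry_angle = sched$gantry_angle,
                      meas_x = truth[fix_idx, 1] + noise[, 1],
                      meas_y = truth[fix_idx, 2] + noise[, 2],
                      meas_z = truth[fix_idx, 3] + noise[, 3],
                      true_x = truth[fix_idx, 1],
                      true_y = truth[fix_idx, 2],
                      true_z = truth[fix_idx, 3])
  n <- length(times)
  predicted <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  model_valid <- rep(FALSE, n)
  low_quality <- rep(FALSE, n)
  for (j in seq_len(nrow(fixes))) {
    if (j < config$warmup_fixes) next
    wi <- max(1, j - config$model_window + 1):j
    X <- B[fix_idx[wi], , drop = FALSE]
    Y <- as.matrix(fixes[wi, c("meas_x", "meas_y", "meas_z")])
    coefs <- apply(Y, 2, function(y) fit_axis(X, y))
    if (fix_idx[j] >= n) next
    seg <- (fix_idx[j] + 1):(if (j < nrow(fixes)) min(fix_idx[j + 1], n) else n)
    predicted[seg, ] <- B[seg, , drop = FALSE] %*% coefs
    model_valid[seg] <- TRUE
    fit_rms <- sqrt(mean((Y - X %*% coefs)^2))
    low_quality[seg] <- fit_rms > config$fit_residual_threshold
  }
  structure(list(times = times,
                 predicted = predicted,
                 true = truth,
                 model_valid = model_valid,
                 low_quality = low_quality,
                 gantry_angle = (360 * times / config$gantry_period) %% 360,
                 fixes = fixes,
                 config = config),
            class = "tracked_trace")
}

#' @export
print.tracked_trace <- function(x, ...) {
  nv <- sum(x$model_valid)
  cat(sprintf("tracked_trace: %d LED samples, %d kV fixes, %.1f%% model-valid\n",
              length(x$times), nrow(x$fixes), 100 * nv / length(x$times)))
  if (nv > 0) {
    err <- error_series(x)
    cat(sprintf("  delta_RMS %.2f mm, delta_95 %.2f mm\n",
                delta_rms(err), delta_quantile(err, 0.95)))
  }
  invisible(x)
}

#' Effective residual displacement after beam compensation
#'
#' Decomposes the per-sample prediction error into the components the
#' delivery can act on. The jaws compensate longitudinal (Y) motion at every
#' gantry angle, so the Y residual is the Y prediction error. In the
#' transverse plane the MLC compensates the component perpendicular to the
#' beam axis (residual = prediction error in that component); motion along
#' the beam axis cannot be compensated, and its dosimetric effect is scaled
#' by `along_beam_weight` (default 0: first-order depth insensitivity).
#' Before the model is valid no compensation occurs and the residual is the
#' full true displacement.
#'
#' @param tracked A `tracked_trace` (with gantry angles).
#' @param along_beam_weight Dosimetric weight of uncompensated along-beam
#'   true displacement (default 0).
#' @return Matrix of effective residual displacement (mm), columns x, y, z.
#' @export
compensation_residual <- function(tracked, along_beam_weight = 0) {
  stopifnot(inherits(tracked, "tracked_trace"))
  if (is.null(tracked$gantry_angle)) stop("missing gantry angles", call. = FALSE)
  th <- tracked$gantry_angle * pi / 180
  bx <- sin(th); bz <- cos(th)  # beam axis in the transverse plane (0 deg -> Z)
  err <- tracked$true - tracked$predicted
  res <- matrix(0, nrow(err), 3, dimnames = list(NULL, c("x", "y", "z")))
  v <- tracked$model_valid
  # perpendicular (MLC-compensated) component of the transverse error
  e_par <- err[v, "x"] * bx[v] + err[v, "z"] * bz[v]
  res[v, "x"] <- err[v, "x"] - e_par * bx[v]
  res[v, "z"] <- err[v, "z"] - e_par * bz[v]
  res[v, "y"] <- err[v, "y"]
  if (along_beam_weight != 0) {
    d_par <- tracked$true[v, "x"] * bx[v] + tracked$true[v, "z"] * bz[v]
    res[v, "x"] <- res[v, "x"] + along_beam_weight * d_par * bx[v]
    res[v, "z"] <- res[v, "z"] + along_beam_weight * d_par * bz[v]
  }
  res[!v, ] <- tracked$true[!v, , drop = FALSE]
  res
}

#' Write a tracking log CSV
#'
#' Column layout `time_s,pred_x,pred_y,pred_z,true_x,true_y,true_z,
#' model_valid,gantry_deg`, one row per LED sample.
#'
#' @param tracked A `tracked_trace`.
#' @param path Output path.
#' @export
write_tracking_log <- function(tracked, path) {
  df <- data.frame(time_s = tracked$times,
                   pred_x = tracked$predicted[, 1],
                   pred_y = tracked$predicted[, 2],
                   pred_z = tracked$predicted[, 3],
                   true_x = tracked$true[, 1],
                   true_y = tracked$true[, 2],
                   true_z = tracked$true[, 3],
                   model_valid = tracked$model_valid,
                   gantry_deg = tracked$gantry_angle)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
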