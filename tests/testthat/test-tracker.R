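test_that("kV localization interpolates truth and adds unbiased noise", {
  t <- seq(0, 10, by = 0.05)
  tr <- make_trace(t, x = 2 * t, y = sin(t), z = -t)
  f0 <- localize_target(tr, 1.234, noise_sd = 0)
  expect_equal(f0$meas_x, 2 * 1.234, tolerance = 1e-9)
  expect_equal(f0$meas_y, sin(1.234), tolerance = 1e-3)  # linear interp of sine
  expect_equal(f0$meas_z, -1.234, tolerance = 1e-9)

  set.seed(1)
  m <- replicate(1e4, localize_target(tr, 5, noise_sd = 0.3)$meas_x)
  expect_lt(abs(mean(m) - 10), 3 * 0.3 / sqrt(1e4))

  set.seed(42); a <- localize_target(tr, 5, 0.3)
  set.seed(42); b <- localize_target(tr, 5, 0.3)
  expect_identical(a, b)
  expect_error(localize_target(tr, 99), "span")
})

test_that("correlation model interpolates exact linear relations", {
  t <- seq(0, 30, by = 0.0125)
  s <- 5 * sin(pi * t / 4)^4
  hist <- data.frame(time = t, s = s)
  # irregular acquisition times so the fix phases span the breathing cycle
  ft <- c(1.2, 3.5, 6.1, 8.8, 11.4, 14.9)
  si <- 5 * sin(pi * ft / 4)^4
  fixes <- data.frame(time = ft, meas_x = 0 * ft, meas_y = 2 * si,
                      meas_z = -0.5 * si + 1)
  m <- fit_correlation_model(fixes, hist)
  expect_equal(unname(m$coefficients["position", "y"]), 2, tolerance = 1e-6)
  expect_equal(unname(m$coefficients["intercept", "y"]), 0, tolerance = 1e-6)
  expect_equal(unname(m$coefficients["position", "z"]), -0.5, tolerance = 1e-6)
  expect_equal(unname(m$fit_rms), rep(0, 3), tolerance = 1e-9,
               ignore_attr = TRUE)

  # constant target, varying surrogate: intercept-only solution
  fixes$meas_y <- 7
  m2 <- fit_correlation_model(fixes, hist)
  expect_equal(unname(m2$coefficients["position", "y"]), 0, tolerance = 1e-8)
  expect_equal(unname(m2$coefficients["intercept", "y"]), 7, tolerance = 1e-8)
})

test_that("noisy fits agree with an independent normal-equations solve", {
  t <- seq(0, 200, by = 0.0125)
  s <- 10 * sin(pi * t / 4)^4
  hist <- data.frame(time = t, s = s)
  ft <- seq(2, 150, by = 2.96)[1:50]
  idx <- round(ft / 0.0125) + 1
  set.seed(8)
  noise <- rnorm(50, 0, 0.3)
  fixes <- data.frame(time = ft, meas_x = 0, meas_y = 2 * s[idx] + noise,
                      meas_z = 0)
  m <- fit_correlation_model(fixes, hist)
  # oracle: explicit normal equations on the same design
  B <- tomomotion:::surrogate_features(s, 0.0125, 3, 9)
  X <- B[idx, ]
  beta <- solve(t(X) %*% X, t(X) %*% fixes$meas_y)
  expect_equal(unname(m$coefficients[, "y"]), as.numeric(beta),
               tolerance = 1e-8)
  # position + velocity form recovers a known linear map: slope within 2%
  m1 <- fit_correlation_model(fixes, hist, n_derivatives = 1)
  expect_lt(abs(m1$coefficients["position", "y"] - 2) / 2, 0.02)
})

test_that("a constant surrogate degrades to an intercept-only model", {
  t <- seq(0, 30, by = 0.0125)
  hist <- data.frame(time = t, s = rep(1.5, length(t)))
  fixes <- data.frame(time = seq(3, 18, by = 3), meas_x = 3, meas_y = 3,
                      meas_z = 3)
  expect_warning(m <- fit_correlation_model(fixes, hist), "rank-deficient")
  expect_equal(unname(predict(m, cbind(1, 1.5, 0, 0, 0))[1, ]), rep(3, 3),
               ignore_attr = TRUE)
})

test_that("model prediction is the fitted affine map", {
  m <- structure(list(coefficients = rbind(intercept = c(1, 2, 3),
                                           position = c(2, 0, 0))),
                 class = "correlation_model")
  colnames(m$coefficients) <- c("x", "y", "z")
  out <- predict(m, cbind(1, 3))
  expect_equal(unname(out[1, ]), c(1 + 2 * 3, 2, 3))
  expect_error(predict(m, cbind(1, 3, 0)), "basis")
})

test_that("tracking a static phantom yields zero error after warmup", {
  p <- breathing_parameters(duration = 60, mean_period = 4, seed = 1)
  tr <- generate_trace(p)
  cfg <- delivery_config(treatment_duration = 60, kv_noise_sd = 0)
  suppressWarnings(tk <- run_tracking(tr, cfg, seed = 1))
  expect_true(any(tk$model_valid))
  expect_equal(delta_rms(error_series(tk)), 0, tolerance = 1e-12)
  # log-grid contract
  expect_equal(unique(round(diff(tk$times), 10)), cfg$led_interval)
})

test_that("perfect surrogate correlation drives the error to numerical zero", {
  # surrogate identical to Z, all channels linearly related (no phase shifts)
  p <- breathing_parameters(mean_amplitude_x = 4, mean_amplitude_y = 9,
                            mean_amplitude_z = 6, mean_period = 4,
                            phase_shift_z = 0, duration = 120, seed = 13)
  tr <- generate_trace(p)
  cfg <- delivery_config(treatment_duration = 120, kv_noise_sd = 0)
  tk <- run_tracking(tr, cfg, seed = 2)
  expect_lt(delta_rms(error_series(tk)), 1e-6)
})

test_that("tracking error grows monotonically with kV localization noise", {
  p <- tracker_params(duration = 120)
  tr <- generate_trace(p)
  mean_rms <- sapply(c(0.1, 0.3, 0.6), function(ns) {
    cfg <- delivery_config(treatment_duration = 120, kv_noise_sd = ns)
    mean(sapply(1:3, function(s) {
      delta_rms(error_series(run_tracking(tr, cfg, seed = s)))
    }))
  })
  expect_true(all(diff(mean_rms) > 0))
})

test_that("imaging that aliases with the breathing degrades the model", {
  # constant 3 s breathing; 4 images per 12 s rotation sample one phase
  p <- breathing_parameters(mean_amplitude_x = 4, mean_amplitude_y = 9,
                            mean_amplitude_z = 6, mean_period = 3,
                            period_sd = 0, amplitude_rel_sd = 0,
                            phase_shift_z = -0.2, duration = 120, seed = 3)
  tr <- generate_trace(p)
  rms_for <- function(kv) {
    cfg <- delivery_config(gantry_period = 12, kv_per_rotation = kv,
                           treatment_duration = 120)
    suppressWarnings(delta_rms(error_series(run_tracking(tr, cfg, seed = 4))))
  }
  expect_gt(rms_for(4), rms_for(5))
})

test_that("compensation residual follows the beam-projection geometry", {
  n <- 4
  mk <- function(err_true, pred_err, angles, valid = rep(TRUE, n)) {
    true <- matrix(rep(err_true, each = n), n, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
    structure(list(times = seq_len(n), true = true,
                   predicted = true - matrix(rep(pred_err, each = n), n, 3),
                   model_valid = valid, gantry_angle = angles),
              class = "tracked_trace")
  }
  # zero prediction error -> zero residual at every angle
  tk <- mk(c(3, -2, 5), c(0, 0, 0), c(0, 45, 90, 270))
  expect_true(all(compensation_residual(tk) == 0))
  # pure Y prediction error passes through at any angle
  tk <- mk(c(0, 2, 0), c(0, 2, 0), c(0, 30, 90, 200))
  expect_equal(unname(compensation_residual(tk)[, "y"]), rep(2, n))
  # pure Z error: hidden along the beam at gantry 0, fully visible at 90
  tk <- mk(c(0, 0, 4), c(0, 0, 4), rep(0, n))
  expect_equal(max(abs(compensation_residual(tk))), 0, tolerance = 1e-12)
  tk <- mk(c(0, 0, 4), c(0, 0, 4), rep(90, n))
  expect_equal(unname(compensation_residual(tk)[, "z"]), rep(4, n),
               tolerance = 1e-12)
  # before the model is valid the full displacement passes through
  tk <- mk(c(1, 2, 3), c(0, 0, 0), rep(0, n), valid = rep(FALSE, n))
  expect_equal(unname(compensation_residual(tk)[1, ]), c(1, 2, 3))
})

test_that("tracking log CSV has the documented layout", {
  p <- breathing_parameters(mean_amplitude_y = 8, duration = 30,
                            mean_period = 4, seed = 6)
  tr <- generate_trace(p)
  tk <- run_tracking(tr, delivery_config(treatment_duration = 30), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_tracking_log(tk, path)
  log <- read.csv(path)
  expect_named(log, c("time_s", "pred_x", "pred_y", "pred_z",
                      "true_x", "true_y", "true_z", "model_valid",
                      "gantry_deg"))
  expect_equal(nrow(log), length(tk$times))
  unlink(path)
})
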