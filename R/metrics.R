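# Tracking-error statistics: delta_RMS, percentile errors and cumulative
# error curves over a tracking log.

#' Per-sample tracking error magnitude
#'
#' Euclidean norm of (predicted - true) target position per LED sample.
#' By default only model-valid samples enter (warmup excluded), matching the
#' convention that the model is built before beam-on.
#'
#' @param tracked A `tracked_trace`.
#' @param valid_only Drop samples without a valid model (default `TRUE`).
#' @return Numeric vector of error magnitudes (mm).
#' @export
error_series <- function(tracked, valid_only = TRUE) {
  stopifnot(inherits(tracked, "tracked_trace"))
  keep <- if (valid_only) tracked$model_valid else rep(TRUE, length(tracked$times))
  if (!any(keep)) stop("no valid samples", call. = FALSE)
  pred <- tracked$predicted[keep, , drop = FALSE]
  pred[is.na(pred)] <- 0  # no model yet: predicted position is the origin
  d <- pred - tracked$true[keep, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Root-mean-square tracking error
#'
#' `sqrt(mean(e_i^2))` over the error magnitudes.
#'
#' @param errors Error magnitudes (mm), length >= 1.
#' @return delta_RMS (mm).
#' @export
delta_rms <- function(errors) {
  if (length(errors) < 1) stop("empty error series", call. = FALSE)
  sqrt(mean(errors^2))
}

#' Empirical tracking-error quantile
#'
#' Nearest-rank empirical quantile of the error magnitudes: delta_q is the
#' smallest observed error e such that at least a fraction q of the samples
#' are <= e. delta_95 = 1 mm means that for 95% of the (tracked) treatment
#' time the error was 1 mm or less.
#'
#' @param errors Error magnitudes (mm).
#' @param q Quantile in (0, 1].
#' @return Error quantile (mm).
#' @export
delta_quantile <- function(errors, q) {
  if (length(errors) < 1) stop("empty error series", call. = FALSE)
  if (!is.finite(q) || q <= 0 || q > 1) stop("q must be in (0, 1]", call. = FALSE)
  sorted <- sort(errors)
  sorted[ceiling(q * length(sorted))]
}

#' Cumulative tracking-error curve
#'
#' For a grid of error values e, the fraction of samples strictly greater
#' than e (1 - ECDF): the probability of observing a tracking error larger
#' than e during treatment.
#'
#' @param errors Error magnitudes (mm).
#' @param grid Error grid (mm); default 200 steps from 0 to the maximum.
#' @return Data frame with `error_mm` and `prob_exceed` (non-increasing).
#' @export
cumulative_error_curve <- function(errors, grid = NULL) {
  if (length(errors) < 1) stop("empty error series", call. = FALSE)
  if (is.null(grid)) grid <- seq(0, max(errors), length.out = 200)
  ecdf_fun <- stats::ecdf(errors)
  data.frame(error_mm = grid, prob_exceed = 1 - ecdf_fun(grid))
}

#' Summary of tracking accuracy for one delivery
#'
#' Bundles delta_RMS, delta_50, delta_95 and the cumulative error curve.
#'
#' @param tracked A `tracked_trace`.
#' @param valid_only Restrict to model-valid samples (default `TRUE`).
#' @return A `tracking_error_summary` list: `delta_rms`, `delta_50`,
#'   `delta_95` (mm), `curve`, `n_samples`.
#' @export
tracking_error_summary <- function(tracked, valid_only = TRUE) {
  e <- error_series(tracked, valid_only = valid_only)
  structure(list(delta_rms = delta_rms(e),
                 delta_50 = delta_quantile(e, 0.5),
                 delta_95 = delta_quantile(e, 0.95),
                 curve = cumulative_error_curve(e),
                 n_samples = length(e)),
            class = "tracking_error_summary")
}

#' @export
print.tracking_error_summary <- function(x, ...) {
  cat(sprintf("tracking error over %d samples: delta_RMS %.2f mm, delta_50 %.2f mm, delta_95 %.2f mm\n",
              x$n_samples, x$delta_rms, x$delta_50, x$delta_95))
  invisible(x)
}
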