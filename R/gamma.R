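# Dose comparison: global gamma index (dose-difference / distance-to-
# agreement), median dose difference, and the paired t-test used for
# population-level scenario comparison.

#' Gamma analysis criteria
#'
#' Global-normalization gamma criteria: dose difference as a percent of the
#' maximum reference dose, distance to agreement in mm, and a lower dose
#' threshold (percent of the maximum reference dose) below which reference
#' points are excluded. Default 3%/2 mm with a 10% threshold, the TG-218
#' style criteria for IMRT plan evaluation.
#'
#' @param dose_percent Dose-difference criterion (% of global max), default 3.
#' @param distance_mm Distance-to-agreement criterion (mm), default 2.
#' @param threshold_percent Lower dose threshold (% of global max), default 10.
#' @param search_radius Search radius (mm), default 3 * `distance_mm`.
#' @param step Spatial interpolation step of the search (mm), default 0.2.
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_percent = 3, distance_mm = 2,
                           threshold_percent = 10,
                           search_radius = 3 * distance_mm, step = 0.2) {
  stopifnot(dose_percent > 0, distance_mm > 0, threshold_percent >= 0,
            threshold_percent < 100, search_radius > 0, step > 0)
  structure(list(dose_percent = dose_percent, distance_mm = distance_mm,
                 threshold_percent = threshold_percent,
                 search_radius = search_radius, step = step),
            class = "gamma_criteria")
}

# offsets lattice within the search radius, grouped into shells of
# increasing distance so the per-point search can stop as soon as the
# distance term alone exceeds the best gamma found
gamma_offsets <- function(radius, step) {
  v <- seq(-radius, radius, by = step)
  g <- as.matrix(expand.grid(dx = v, dy = v, dz = v))
  r <- sqrt(rowSums(g^2))
  keep <- r <= radius + 1e-9
  g <- g[keep, , drop = FALSE]
  r <- r[keep]
  o <- order(r)
  list(offsets = g[o, , drop = FALSE], r = r[o],
       shell = findInterval(r[o], seq(0, radius + step, by = step),
                            left.open = TRUE))
}

#' Gamma index of reference points against an evaluated dose grid
#'
#' For each reference point above the dose threshold, the gamma value is the
#' minimum over evaluated positions within the search radius of
#' `sqrt((dDose / (dose_percent% of max ref))^2 + (dr / distance_mm)^2)`,
#' with the evaluated dose interpolated trilinearly on a lattice of spacing
#' `step`. The search proceeds over shells of increasing distance and stops
#' for a point once no farther shell can improve its gamma (an exact
#' stopping rule). With a finite `cap`, the search additionally stops once
#' the point's gamma is proven to exceed `cap`; reported values above `cap`
#' are then lower bounds, which leaves any pass-rate at gamma <= 1
#' unaffected for `cap >= 1`.
#'
#' @param ref_pos n x 3 matrix of reference point coordinates (mm).
#' @param ref_dose Reference dose at those points.
#' @param eval_grid Evaluated `dose_grid`.
#' @param criteria A [gamma_criteria()].
#' @param max_ref Global maximum reference dose for normalization; defaults
#'   to `max(ref_dose)`.
#' @param cap Early-stop bound (default `Inf`: exact minima everywhere).
#' @return A `gamma_result`: per-point `gamma`, `pass_rate` (%),
#'   `n_evaluated`, and the criteria used.
#' @export
gamma_index_points <- function(ref_pos, ref_dose, eval_grid, criteria = gamma_criteria(),
                               max_ref = NULL, cap = Inf) {
  stopifnot(inherits(eval_grid, "dose_grid"), inherits(criteria, "gamma_criteria"))
  ref_pos <- as.matrix(ref_pos)
  if (is.null(max_ref)) max_ref <- max(ref_dose)
  if (!is.finite(max_ref) || max_ref <= 0) {
    stop("reference maximum dose must be positive", call. = FALSE)
  }
  keep <- ref_dose >= criteria$threshold_percent / 100 * max_ref
  if (!any(keep)) stop("no reference points above the dose threshold",
                       call. = FALSE)
  pos <- ref_pos[keep, , drop = FALSE]
  dref <- ref_dose[keep]
  npt <- nrow(pos)
  dd_norm <- criteria$dose_percent / 100 * max_ref
  off <- gamma_offsets(criteria$search_radius, criteria$step)
  gamma2 <- rep(Inf, npt)
  active <- rep(TRUE, npt)
  for (sh in unique(off$shell)) {
    rows <- which(off$shell == sh)
    r_min2 <- (off$r[rows[1]] / criteria$distance_mm)^2
    # exact stop: no farther offset can beat the current minimum;
    # capped stop: failure at `cap` is already proven for the point
    active <- active & (gamma2 > r_min2) & !(gamma2 > cap^2 & r_min2 > cap^2)
    act <- which(active)
    if (!length(act)) break
    # evaluate the whole shell for all active points in chunks
    K <- length(rows)
    chunk <- max(1L, floor(2e6 / K))
    for (start in seq(1, length(act), by = chunk)) {
      ids <- act[start:min(start + chunk - 1, length(act))]
      m <- length(ids)
      pts <- cbind(rep(pos[ids, 1], times = K) + rep(off$offsets[rows, 1], each = m),
                   rep(pos[ids, 2], times = K) + rep(off$offsets[rows, 2], each = m),
                   rep(pos[ids, 3], times = K) + rep(off$offsets[rows, 3], each = m))
      de <- trilinear_interp(eval_grid, pts)
      g2 <- (matrix(de, m, K) - dref[ids])^2 / dd_norm^2 +
        matrix((off$r[rows] / criteria$distance_mm)^2, m, K, byrow = TRUE)
      best <- suppressWarnings(apply(g2, 1, min, na.rm = TRUE))
      upd <- is.finite(best) & best < gamma2[ids]
      gamma2[ids[upd]] <- best[upd]
    }
  }
  gamma <- sqrt(gamma2)
  structure(list(gamma = gamma,
                 pass_rate = 100 * mean(gamma <= 1),
                 n_evaluated = npt,
                 criteria = criteria,
                 max_ref = max_ref),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma %g%%/%g mm/%g%%T: pass rate %.1f%% (%d points, max gamma %.2f)\n",
              x$criteria$dose_percent, x$criteria$distance_mm,
              x$criteria$threshold_percent, x$pass_rate, x$n_evaluated,
              max(x$gamma)))
  invisible(x)
}

#' Gamma pass rate between two dose distributions
#'
#' Compares an evaluated dose distribution to a reference under global
#' gamma criteria. With `points = "detector"` (default) the reference is
#' sampled at Delta4-style diode positions and the evaluated grid is
#' searched continuously around each diode; with `points = "grid"` every
#' above-threshold reference voxel is a reference point (intended for small
#' grids). Normalization uses the reference distribution's global maximum.
#'
#' @param reference,evaluated `dose_grid` objects on the same frame.
#' @param criteria A [gamma_criteria()].
#' @param points `"detector"` or `"grid"`.
#' @param det A [detector_geometry()] (used for `points = "detector"`).
#' @param cap Early-stop gamma bound passed to [gamma_index_points()]
#'   (default 1.05; use `Inf` for exact gamma values everywhere).
#' @return A `gamma_result`.
#' @export
gamma_pass_rate <- function(reference, evaluated, criteria = gamma_criteria(),
                            points = c("detector", "grid"),
                            det = detector_geometry(), cap = 1.05) {
  points <- match.arg(points)
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (points == "detector") {
    smp <- sample_detector(reference, det)
    smp <- smp[smp$in_grid, ]
    gamma_index_points(as.matrix(smp[, c("x", "y", "z")]), smp$dose, evaluated,
                       criteria, max_ref = max(reference$values), cap = cap)
  } else {
    sp <- reference$spec
    g <- expand.grid(x = sp$x, y = sp$y, z = sp$z)
    gamma_index_points(as.matrix(g), as.vector(reference$values), evaluated,
                       criteria, max_ref = max(reference$values), cap = cap)
  }
}

#' Median dose difference above a dose threshold
#'
#' Median of (evaluated - reference) over reference points above the
#' threshold, expressed as a percent of the global maximum reference dose.
#' Positive values mean the evaluated distribution is hotter. The default
#' 50% threshold restricts the comparison to the target region.
#'
#' @param reference,evaluated `dose_grid` objects, or data frames of matched
#'   point doses (columns `dose`).
#' @param threshold_percent Threshold (% of max reference), default 50.
#' @param points `"detector"` or `"grid"` (for `dose_grid` inputs).
#' @param det A [detector_geometry()].
#' @return Median dose difference (% of global max reference dose).
#' @export
median_dose_difference <- function(reference, evaluated, threshold_percent = 50,
                                   points = c("detector", "grid"),
                                   det = detector_geometry()) {
  points <- match.arg(points)
  if (inherits(reference, "dose_grid")) {
    max_ref <- max(reference$values)
    if (points == "detector") {
      r <- sample_detector(reference, det); e <- sample_detector(evaluated, det)
      ok <- r$in_grid & e$in_grid
      dref <- r$dose[ok]; dev <- e$dose[ok]
    } else {
      dref <- as.vector(reference$values); dev <- as.vector(evaluated$values)
    }
  } else {
    dref <- reference$dose; dev <- evaluated$dose
    max_ref <- max(dref)
  }
  if (max_ref <= 0) stop("reference maximum dose must be positive", call. = FALSE)
  keep <- dref >= threshold_percent / 100 * max_ref
  if (!any(keep)) stop("no points above the dose threshold", call. = FALSE)
  100 * stats::median(dev[keep] - dref[keep]) / max_ref
}

#' Two-tailed paired t-test between two metric series
#'
#' Thin wrapper around [stats::t.test()] for paired scenario comparisons
#' (e.g. per-case gamma pass rates under two delivery scenarios). Guards the
#' degenerate zero-variance case.
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("need two equal-length series with n >= 2", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t-test degenerate", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = unname(ht$estimate))
}
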