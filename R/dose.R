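# Time-resolved dose accumulation on a 3D grid with a parametric helical
# delivery model: a jaw-collimated longitudinal profile sweeping in Y at
# couch speed, a transverse aperture rotating with the gantry, and optional
# output modulation. Deliberately first-order: flat depth dose, no
# heterogeneity, dose in units normalized to the static target-center dose.

#' Define a 3D dose grid
#'
#' Regular grid centered on the origin. Defaults: 2 mm isotropic spacing,
#' 120 x 120 x 160 mm extent (X x Y x Z).
#'
#' @param spacing Voxel spacing (mm), length 1 or 3.
#' @param extent Full extent per axis (mm), length 3.
#' @return A `dose_grid_spec`: axis coordinate vectors `x`, `y`, `z` (mm),
#'   `spacing`, `origin` (coordinate of the first voxel).
#' @export
dose_grid_spec <- function(spacing = 2, extent = c(120, 120, 160)) {
  spacing <- rep(spacing, length.out = 3)
  stopifnot(all(spacing > 0), all(extent > 0))
  ax <- function(ext, sp) seq(-ext / 2, ext / 2, by = sp)
  structure(list(x = ax(extent[1], spacing[1]),
                 y = ax(extent[2], spacing[2]),
                 z = ax(extent[3], spacing[3]),
                 spacing = spacing,
                 origin = c(-extent[1] / 2, -extent[2] / 2, -extent[3] / 2)),
            class = "dose_grid_spec")
}

new_dose_grid <- function(values, spec, label = "phantom") {
  structure(list(values = values, spec = spec, label = label),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid '%s': %s voxels, spacing (%g, %g, %g) mm, max %.3f\n",
              x$label, paste(dim(x$values), collapse = " x "),
              x$spec$spacing[1], x$spec$spacing[2], x$spec$spacing[3],
              max(x$values)))
  invisible(x)
}

# smoothed top-hat: plateau of half-width hw with Gaussian-integrated penumbra
smoothed_tophat <- function(u, hw, sigma) {
  if (sigma <= 0) return(as.numeric(abs(u) <= hw))
  stats::pnorm((hw - u) / sigma) + stats::pnorm((hw + u) / sigma) - 1
}

#' Build a parametric helical delivery sequence
#'
#' Discretizes one delivery into uniform time steps. The longitudinal beam
#' profile is a jaw top-hat of FWHM `jaw_width` with Gaussian penumbra
#' `penumbra_sigma`, whose center sweeps in Y from one side of the target to
#' the other at constant couch speed. The transverse aperture is a smoothed
#' top-hat of half-width `aperture_halfwidth` in the beam's-eye transverse
#' coordinate, rotating with the gantry. Output per step is constant
#' (`modulation = "uniform"`) or switches between high and low at
#' `modulation_period` (`"alternating"`, an intentionally interplay-prone
#' pattern). Output is normalized so that the static delivery accumulates
#' dose 1.0 at the target center.
#'
#' @param duration Delivery (beam-on) time (s).
#' @param time_step Discretization step (s), default 0.25.
#' @param gantry_period Gantry rotation period (s), default 12.
#' @param jaw_width Longitudinal FWHM at isocenter (mm), default 25.
#' @param penumbra_sigma Gaussian penumbra sigma (mm), default 3.
#' @param aperture_halfwidth Transverse aperture half-width (mm), default 18.
#' @param target_length Longitudinal target extent swept by the beam (mm),
#'   default 30.
#' @param modulation `"uniform"` or `"alternating"`.
#' @param modulation_period Period of the alternating output (s), default 5.
#' @param modulation_depth Fractional output swing of the alternating
#'   pattern (0-1, default 0.8).
#' @return A `delivery_sequence`: data frame `steps` (time, beam_y, angle,
#'   output) plus the geometric parameters and derived `couch_speed` (mm/s).
#' @export
build_delivery_sequence <- function(duration = 120,
                                    time_step = 0.25,
                                    gantry_period = 12,
                                    jaw_width = 25,
                                    penumbra_sigma = 3,
                                    aperture_halfwidth = 18,
                                    target_length = 30,
                                    modulation = c("uniform", "alternating"),
                                    modulation_period = 5,
                                    modulation_depth = 0.8) {
  modulation <- match.arg(modulation)
  stopifnot(duration > 0, time_step > 0, gantry_period > 0, jaw_width > 0)
  t <- seq(0, duration - time_step, by = time_step) + time_step / 2
  sweep_half <- target_length / 2 + jaw_width / 2
  beam_y <- -sweep_half + (t / duration) * 2 * sweep_half
  couch_speed <- 2 * sweep_half / duration
  angle <- (360 * t / gantry_period) %% 360
  output <- rep(1, length(t))
  if (modulation == "alternating") {
    phase <- (t %/% (modulation_period / 2)) %% 2
    output <- ifelse(phase == 0, 1 + modulation_depth, 1 - modulation_depth)
  }
  # normalize: static dose at the target center (origin) must reach 1.0
  hw_y <- jaw_width / 2
  center_dose <- sum(output * smoothed_tophat(-beam_y, hw_y, penumbra_sigma))
  output <- output / center_dose
  structure(list(steps = data.frame(time = t, beam_y = beam_y, angle = angle,
                                    output = output),
                 duration = duration, time_step = time_step,
                 gantry_period = gantry_period,
                 jaw_width = jaw_width, penumbra_sigma = penumbra_sigma,
                 aperture_halfwidth = aperture_halfwidth,
                 target_length = target_length,
                 couch_speed = couch_speed,
                 modulation = modulation),
            class = "delivery_sequence")
}

#' Accumulate dose over a delivery with rigid target motion
#'
#' Deposits the instantaneous beam kernel into the phantom frame at each
#' time step, displaced by the instantaneous rigid displacement of the
#' phantom, and sums over steps. A phantom displaced by `d` receives, at
#' phantom point `q`, the machine-frame fluence evaluated at `q + d`. Pass a
#' zero displacement for a static (M0S0) delivery, the raw motion trace for
#' an uncompensated (M1S0) delivery, or the [compensation_residual()] of a
#' tracking run for a compensated (M1S1) delivery.
#'
#' @param sequence A [build_delivery_sequence()] result.
#' @param displacement Either `NULL`/zeros (static) or an n_steps x 3 matrix
#'   of (x, y, z) displacement (mm) at the step times (see
#'   [displacement_at_times()]).
#' @param spec A [dose_grid_spec()].
#' @return A `dose_grid`. If deposits were pushed substantially off-grid a
#'   warning is issued and the grid is flagged `truncated`.
#' @export
accumulate_dose <- function(sequence, displacement = NULL, spec = dose_grid_spec()) {
  stopifnot(inherits(sequence, "delivery_sequence"),
            inherits(spec, "dose_grid_spec"))
  st <- sequence$steps
  ns <- nrow(st)
  if (is.null(displacement)) displacement <- matrix(0, ns, 3)
  displacement <- as.matrix(displacement)
  if (nrow(displacement) != ns || ncol(displacement) != 3) {
    stop("displacement must be an n_steps x 3 matrix", call. = FALSE)
  }
  xg <- spec$x; yg <- spec$y; zg <- spec$z
  hw_y <- sequence$jaw_width / 2
  acc <- array(0, dim = c(length(xg), length(zg), length(yg)))  # (x, z, y)
  th <- st$angle * pi / 180
  truncated <- FALSE
  for (i in seq_len(ns)) {
    # transverse beam's-eye coordinate (perpendicular to the beam axis,
    # which at gantry 0 points along Z); along-beam position has no effect
    # on the flat-depth kernel
    du <- displacement[i, 1] * cos(th[i]) - displacement[i, 3] * sin(th[i])
    U <- outer(xg * cos(th[i]), zg * sin(th[i]), "-") + du
    A <- smoothed_tophat(U, sequence$aperture_halfwidth, sequence$penumbra_sigma)
    L <- smoothed_tophat(yg + displacement[i, 2] - st$beam_y[i], hw_y,
                         sequence$penumbra_sigma)
    acc <- acc + st$output[i] * outer(A, L)
  }
  if (max(abs(displacement)) > min(diff(range(xg)), diff(range(zg))) / 2) {
    warning("displacement comparable to grid extent; dose truncated",
            call. = FALSE)
    truncated <- TRUE
  }
  g <- new_dose_grid(aperm(acc, c(1, 3, 2)), spec)
  g$truncated <- truncated
  g
}

#' Interpolate a displacement series onto delivery step times
#'
#' Linearly interpolates per-axis displacement (e.g. a trace or a
#' compensation residual on the LED grid) onto the mid-step times of a
#' delivery sequence. Times outside the series range take the edge values.
#'
#' @param times Source times (s).
#' @param disp n x 3 displacement matrix (mm).
#' @param sequence A `delivery_sequence`.
#' @param offset Time offset (s) added to the step times before lookup
#'   (e.g. the beam-on time within a longer tracking run).
#' @return n_steps x 3 matrix.
#' @export
displacement_at_times <- function(times, disp, sequence, offset = 0) {
  tq <- sequence$steps$time + offset
  apply(as.matrix(disp), 2, function(v) stats::approx(times, v, tq, rule = 2)$y)
}

#' Add or subtract the kV imaging dose
#'
#' The kV acquisitions of a tracked delivery deposit a small extra dose that
#' a static delivery does not receive. Modeled as spatially uniform per
#' image by default. `subtract_kv_dose` is the exact inverse of
#' `add_kv_dose`; negative results are clipped to zero with a warning.
#'
#' @param grid A `dose_grid`.
#' @param n_images Number of kV images delivered.
#' @param kv_dose_per_image Dose per image (normalized units).
#' @return A `dose_grid`.
#' @export
add_kv_dose <- function(grid, n_images, kv_dose_per_image) {
  stopifnot(inherits(grid, "dose_grid"), kv_dose_per_image >= 0, n_images >= 0)
  grid$values <- grid$values + n_images * kv_dose_per_image
  grid
}

#' @rdname add_kv_dose
#' @export
subtract_kv_dose <- function(grid, n_images, kv_dose_per_image) {
  stopifnot(inherits(grid, "dose_grid"), kv_dose_per_image >= 0, n_images >= 0)
  v <- grid$values - n_images * kv_dose_per_image
  if (any(v < 0)) {
    warning("negative dose after kV subtraction clipped to 0", call. = FALSE)
    v[v < 0] <- 0
  }
  grid$values <- v
  grid
}

#' Extract a 1D dose profile through the grid center
#'
#' Nearest grid line through the geometric center (ties broken toward the
#' lower index) along the requested axis.
#'
#' @param grid A `dose_grid`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Data frame with `pos_mm` and `dose`.
#' @export
extract_profile <- function(grid, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  stopifnot(inherits(grid, "dose_grid"))
  if (any(dim(grid$values) < 2)) stop("degenerate grid", call. = FALSE)
  ctr <- function(v) which(abs(v) == min(abs(v)))[1]
  ix <- ctr(grid$spec$x); iy <- ctr(grid$spec$y); iz <- ctr(grid$spec$z)
  switch(axis,
         x = data.frame(pos_mm = grid$spec$x, dose = grid$values[, iy, iz]),
         y = data.frame(pos_mm = grid$spec$y, dose = grid$values[ix, , iz]),
         z = data.frame(pos_mm = grid$spec$z, dose = grid$values[ix, iy, ]))
}

#' 80-20% penumbra width of a profile edge
#'
#' Mean distance between the 80% and 20% crossings (of the profile maximum)
#' on the two outer edges; a measure of dose blurring.
#'
#' @param profile Data frame from [extract_profile()].
#' @return Penumbra width (mm).
#' @export
profile_penumbra_width <- function(profile) {
  d <- profile$dose / max(profile$dose)
  p <- profile$pos_mm
  cross <- function(level, side) {
    idx <- which(d >= level)
    if (!length(idx)) return(NA_real_)
    if (side == "left") {
      i <- idx[1]
      if (i == 1) return(NA_real_)
      stats::approx(d[c(i - 1, i)], p[c(i - 1, i)], level, ties = "ordered")$y
    } else {
      i <- idx[length(idx)]
      if (i == length(d)) return(NA_real_)
      stats::approx(d[c(i + 1, i)], p[c(i + 1, i)], level, ties = "ordered")$y
    }
  }
  w_left <- cross(0.2, "left") - cross(0.8, "left")
  w_right <- cross(0.2, "right") - cross(0.8, "right")
  mean(abs(c(w_left, w_right)), na.rm = TRUE)
}

#' Delta4-style orthogonal diode-plane geometry
#'
#' Two orthogonal planar diode grids through the phantom center: one in the
#' X-Y plane (Z = 0) and one in the Z-Y plane (X = 0). Diode spacing is
#' `central_spacing` inside `central_halfwidth` of the center and
#' `peripheral_spacing` outside, up to `halfwidth`.
#'
#' @param central_spacing,peripheral_spacing Diode spacings (mm), defaults
#'   2.5 and 5.
#' @param central_halfwidth,halfwidth Extents (mm), defaults 30 and 55.
#' @return A `detector_geometry`: matrix `positions` (n x 3, mm) and a
#'   `plane` label per diode.
#' @export
detector_geometry <- function(central_spacing = 2.5, peripheral_spacing = 5,
                              central_halfwidth = 30, halfwidth = 55) {
  stopifnot(central_spacing > 0, peripheral_spacing > 0,
            central_halfwidth < halfwidth)
  coords <- sort(unique(c(
    seq(-central_halfwidth, central_halfwidth, by = central_spacing),
    seq(-halfwidth, -central_halfwidth, by = peripheral_spacing),
    seq(central_halfwidth, halfwidth, by = peripheral_spacing))))
  g <- expand.grid(a = coords, b = coords)
  pos <- rbind(cbind(g$a, g$b, 0),   # X-Y plane at Z = 0
               cbind(0, g$b, g$a))   # Z-Y plane at X = 0
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos,
                 plane = rep(c("xy", "zy"), each = nrow(g))),
            class = "detector_geometry")
}

# vectorized trilinear interpolation of a dose grid at arbitrary points;
# points outside the grid return NA
trilinear_interp <- function(grid, pts) {
  sp <- grid$spec
  v <- grid$values
  fx <- (pts[, 1] - sp$x[1]) / sp$spacing[1]
  fy <- (pts[, 2] - sp$y[1]) / sp$spacing[2]
  fz <- (pts[, 3] - sp$z[1]) / sp$spacing[3]
  nx <- length(sp$x); ny <- length(sp$y); nz <- length(sp$z)
  ok <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1 & fz >= 0 & fz <= nz - 1
  i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
  k0 <- pmin(floor(fz), nz - 2)
  i0[!ok] <- 0; j0[!ok] <- 0; k0[!ok] <- 0
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  idx <- function(i, j, k) i + 1 + nx * (j + ny * k)
  out <- (1 - tx) * ((1 - ty) * ((1 - tz) * v[idx(i0, j0, k0)] +
                                 tz * v[idx(i0, j0, k0 + 1)]) +
                     ty * ((1 - tz) * v[idx(i0, j0 + 1, k0)] +
                           tz * v[idx(i0, j0 + 1, k0 + 1)])) +
    tx * ((1 - ty) * ((1 - tz) * v[idx(i0 + 1, j0, k0)] +
                      tz * v[idx(i0 + 1, j0, k0 + 1)]) +
          ty * ((1 - tz) * v[idx(i0 + 1, j0 + 1, k0)] +
                tz * v[idx(i0 + 1, j0 + 1, k0 + 1)]))
  out[!ok] <- NA_real_
  out
}

#' Sample a dose grid at the diode positions
#'
#' Trilinear interpolation of the grid at each diode coordinate. Diodes
#' outside the grid are flagged and return `NA`.
#'
#' @param grid A `dose_grid`.
#' @param det A [detector_geometry()].
#' @return Data frame with diode positions, `plane`, `dose` and
#'   `in_grid` flag.
#' @export
sample_detector <- function(grid, det) {
  stopifnot(inherits(grid, "dose_grid"), inherits(det, "detector_geometry"))
  dose <- trilinear_interp(grid, det$positions)
  data.frame(x = det$positions[, 1], y = det$positions[, 2],
             z = det$positions[, 3], plane = det$plane,
             dose = dose, in_grid = !is.na(dose))
}
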