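# Shared helpers: independent interpolation oracle, hand-built traces and
# small dose grids used across test files.

# independent trilinear interpolation (separate code path from the package's
# internal interpolator): nested 1D linear interpolation along x, then z,
# then y, per query point
oracle_trilinear <- function(grid, pts) {
  sp <- grid$spec
  v <- grid$values
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]; pz <- pts[i, 3]
    if (px < min(sp$x) || px > max(sp$x) || py < min(sp$y) || py > max(sp$y) ||
        pz < min(sp$z) || pz > max(sp$z)) return(NA_real_)
    ix <- findInterval(px, sp$x, all.inside = TRUE)
    iy <- findInterval(py, sp$y, all.inside = TRUE)
    iz <- findInterval(pz, sp$z, all.inside = TRUE)
    tx <- (px - sp$x[ix]) / (sp$x[ix + 1] - sp$x[ix])
    ty <- (py - sp$y[iy]) / (sp$y[iy + 1] - sp$y[iy])
    tz <- (pz - sp$z[iz]) / (sp$z[iz + 1] - sp$z[iz])
    c00 <- v[ix, iy, iz] * (1 - tx) + v[ix + 1, iy, iz] * tx
    c10 <- v[ix, iy + 1, iz] * (1 - tx) + v[ix + 1, iy + 1, iz] * tx
    c01 <- v[ix, iy, iz + 1] * (1 - tx) + v[ix + 1, iy, iz + 1] * tx
    c11 <- v[ix, iy + 1, iz + 1] * (1 - tx) + v[ix + 1, iy + 1, iz + 1] * tx
    e0 <- c00 * (1 - tz) + c01 * tz
    e1 <- c10 * (1 - tz) + c11 * tz
    e0 * (1 - ty) + e1 * ty
  }, numeric(1))
}

# wrap raw channel vectors into a motion_trace (for hand-built inputs)
make_trace <- function(times, x = 0 * times, y = 0 * times, z = 0 * times,
                       s = 0 * times, case = "synthetic") {
  structure(list(times = times, x = x, y = y, z = z, s = s,
                 metadata = list(case = case, params = NULL, breaths = NULL,
                                 breath_times = NULL)),
            class = "motion_trace")
}

# wrap an array into a dose_grid on a small symmetric grid
make_grid <- function(values, spacing = 2) {
  d <- dim(values)
  spec <- structure(list(
    x = seq(-(d[1] - 1) / 2, (d[1] - 1) / 2) * spacing,
    y = seq(-(d[2] - 1) / 2, (d[2] - 1) / 2) * spacing,
    z = seq(-(d[3] - 1) / 2, (d[3] - 1) / 2) * spacing,
    spacing = rep(spacing, 3),
    origin = -c(d[1] - 1, d[2] - 1, d[3] - 1) / 2 * spacing),
    class = "dose_grid_spec")
  structure(list(values = values, spec = spec, label = "test"),
            class = "dose_grid")
}

# smooth 3D Gaussian dose bump centered at the origin
gaussian_grid <- function(n = 21, spacing = 2, sigma = 15, peak = 1) {
  ax <- seq(-(n - 1) / 2, (n - 1) / 2) * spacing
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  make_grid(peak * exp(-r2 / (2 * sigma^2)), spacing)
}

# independent grid-shift oracle for rigid constant displacement: trilinear
# resample of the whole array at q + d, built from the eight integer-shifted
# copies with edge clamping (values replicate beyond the grid). A different
# algorithm from the package's per-point interpolator.
oracle_shift_grid <- function(grid, d) {
  v <- grid$values
  dims <- dim(v)
  sp <- grid$spec$spacing
  f <- d / sp
  i0 <- floor(f); tfrac <- f - i0
  idx <- function(n, shift) pmin(pmax(seq_len(n) + shift, 1), n)
  out <- array(0, dims)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) tfrac[1] else 1 - tfrac[1]) *
      (if (cy) tfrac[2] else 1 - tfrac[2]) *
      (if (cz) tfrac[3] else 1 - tfrac[3])
    if (w == 0) next
    out <- out + w * v[idx(dims[1], i0[1] + cx),
                       idx(dims[2], i0[2] + cy),
                       idx(dims[3], i0[3] + cz)]
  }
  out
}

# brute-force gamma: exhaustive minimum over the full offset lattice,
# using the independent interpolation oracle
oracle_gamma <- function(ref_pos, ref_dose, eval_grid, criteria, max_ref) {
  v <- seq(-criteria$search_radius, criteria$search_radius, by = criteria$step)
  off <- as.matrix(expand.grid(v, v, v))
  r <- sqrt(rowSums(off^2))
  keep <- r <= criteria$search_radius + 1e-9
  off <- off[keep, , drop = FALSE]; r <- r[keep]
  dd <- criteria$dose_percent / 100 * max_ref
  vapply(seq_len(nrow(ref_pos)), function(i) {
    pts <- sweep(off, 2, as.numeric(ref_pos[i, ]), "+")
    de <- oracle_trilinear(eval_grid, pts)
    g2 <- ((de - ref_dose[i]) / dd)^2 + (r / criteria$distance_mm)^2
    sqrt(min(g2, na.rm = TRUE))
  }, numeric(1))
}

# parameter set used by several tracker tests: moderate 3-axis motion with
# hysteresis, surrogate on the phantom (s == z)
tracker_params <- function(duration = 150, seed = 42, ...) {
  breathing_parameters(mean_amplitude_x = 5, mean_amplitude_y = 11,
                       mean_amplitude_z = 14, mean_period = 4,
                       phase_shift_z = -0.6, duration = duration,
                       seed = seed, ...)
}
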