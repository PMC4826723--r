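# Shared fixtures: small, fast phantom specs and synthetic velocity series.

# compact two-slice phantom for fast module tests
two_slice_spec <- function(...) {
  args <- utils::modifyList(
    list(
      rows = 48, cols = 48,
      slices = list(
        base = list(position_mm = 0, r_endo_mm = 14, r_epi_mm = 22,
                    amp_dps = 25),
        apex = list(position_mm = -40, r_endo_mm = 10, r_epi_mm = 16,
                    amp_dps = -25)
      ),
      n_frames = 20
    ),
    list(...)
  )
  do.call(phantom_spec, args)
}

# phantom family used for parameter-recovery studies: basal rotation with
# amplitude `dw` (deg/s), a non-rotating apical slice at distance `h` (mm),
# transmural gradient `g`
grid_spec <- function(dw, h, g, noise = 0, seed = 1L, n_frames = 24) {
  phantom_spec(
    slices = list(
      base = list(position_mm = 0, r_endo_mm = 18, r_epi_mm = 30,
                  amp_dps = dw),
      apex = list(position_mm = -h, r_endo_mm = 12, r_epi_mm = 22,
                  amp_dps = 0)
    ),
    gamma = g, noise_sd_mm_s = noise, seed = seed, n_frames = n_frames
  )
}

# uniform rigid-rotation velocity series (deg/s, clockwise in the display
# convention); the field is linear in position, so bilinear interpolation of
# the velocity is exact everywhere
rigid_rotation_series <- function(omega_dps = 30, rows = 64, cols = 64,
                                  pixel_mm = 1, dt_ms = 20, n_frames = 51,
                                  venc_mm_s = 250) {
  w <- omega_dps * pi / 180
  center <- c((rows - 1) / 2, (cols - 1) / 2)
  d_row <- (matrix(rep(seq_len(rows) - 1, cols), rows, cols) - center[1]) * pixel_mm
  d_col <- (matrix(rep(seq_len(cols) - 1, each = rows), rows, cols) - center[2]) * pixel_mm
  velocity <- array(0, c(rows, cols, n_frames, 3))
  for (k in seq_len(n_frames)) {
    velocity[, , k, 1] <- -w * d_row # v_x (column axis)
    velocity[, , k, 2] <- w * d_col  # v_y (row axis)
  }
  tpm_series(array(100, c(rows, cols, n_frames)), velocity,
             pixel_spacing = rep(pixel_mm, 2), dt_ms = dt_ms,
             venc_mm_s = venc_mm_s, slice_label = "mid")
}

# analytic clockwise rotation of points about a center (display convention)
rotate_points <- function(pts, center, angle_deg) {
  a <- angle_deg * pi / 180
  dr <- pts[, 1] - center[1]
  dc <- pts[, 2] - center[2]
  cbind(center[1] + dr * cos(a) + dc * sin(a),
        center[2] + dc * cos(a) - dr * sin(a))
}

# random small tpm_series for round-trip/property tests
random_series <- function(seed, rows = 10, cols = 12, frames = 4) {
  set.seed(seed)
  magnitude <- array(runif(rows * cols * frames, 0, 300), c(rows, cols, frames))
  velocity <- array(runif(rows * cols * frames * 3, -200, 200),
                    c(rows, cols, frames, 3))
  tpm_series(magnitude, velocity, pixel_spacing = c(2.2, 2.2), dt_ms = 20.8,
             venc_mm_s = 250, slice_label = "mid", slice_position_mm = -25)
}
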