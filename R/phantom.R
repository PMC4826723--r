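# Synthetic rotating-annulus phantom: a parameterized TPM acquisition with
# closed-form rotation angles and torsion, used as ground truth for the whole
# pipeline. Kinematics: per slice and transmural layer, angular velocity
# follows a half-sine systolic twist with an opposite-sign half-sine diastolic
# untwist; radial contraction scales the annulus; bulk translation,
# first-order eddy-current offset planes, static surrounding tissue and
# Gaussian velocity noise emulate the acquisition corruptions.

#' Parameterize a synthetic TPM acquisition
#'
#' Default geometry and timing mirror a clinical TPM protocol (2.2 mm
#' in-plane pixels, 20.8 ms temporal resolution, venc 250 mm/s, three
#' short-axis slices spanning 50 mm). Angular-velocity amplitudes produce a
#' basal-apical counter-rotation whose base-apex peak torsion is about
#' 0.34 deg/mm, a typical value for healthy ventricles; the transmural
#' gradient makes the endocardial amplitude `(1 + gamma)` times the
#' epicardial one.
#'
#' @param rows,cols grid size in pixels.
#' @param pixel_mm square pixel size, mm.
#' @param slices named list (`base`, `mid`, `apex`, or any subset) of lists
#'   with `position_mm`, `r_endo_mm`, `r_epi_mm`, `amp_dps` (epicardial
#'   angular-velocity amplitude, deg/s; sign = rotation sense).
#' @param t_sys_ms,t_dia_ms systolic and diastolic half-sine durations, ms.
#' @param gamma transmural gradient: endo amplitude = `(1 + gamma) * epi`.
#' @param radial_contraction fractional radius reduction at end-systole.
#' @param translation_mm_s bulk in-plane drift `(v_x, v_y)`, mm/s, applied to
#'   the moving tissue.
#' @param eddy_plane 3 x 3 matrix (components x, y, z by coefficients a, b, c)
#'   of static offset planes `a + b*col + c*row`, mm/s and mm/s per pixel.
#' @param noise_sd_mm_s Gaussian velocity noise SD, mm/s.
#' @param vz_amp_mm_s longitudinal velocity amplitude, mm/s.
#' @param dt_ms,n_frames temporal resolution and frame count.
#' @param venc_mm_s encoding velocity, mm/s.
#' @param margin_mm the motion field extends this far beyond the annulus
#'   (co-moving peri-myocardial tissue), so contours advected along the
#'   annulus edge see the true velocity under bilinear interpolation.
#' @param seed RNG seed; a fixed seed makes [generate_phantom()] bit-identical.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 64, cols = 64, pixel_mm = 2.2,
                         slices = list(
                           base = list(position_mm = 0, r_endo_mm = 18,
                                       r_epi_mm = 30, amp_dps = 30),
                           mid = list(position_mm = -25, r_endo_mm = 16,
                                      r_epi_mm = 27, amp_dps = -10),
                           apex = list(position_mm = -50, r_endo_mm = 12,
                                       r_epi_mm = 22, amp_dps = -60)
                         ),
                         t_sys_ms = 300, t_dia_ms = 500, gamma = 0.5,
                         radial_contraction = 0.10,
                         translation_mm_s = c(0, 0),
                         eddy_plane = matrix(0, 3, 3),
                         noise_sd_mm_s = 0, vz_amp_mm_s = 30,
                         dt_ms = 20.8, n_frames = 40, venc_mm_s = 250,
                         margin_mm = 3, seed = 1L) {
  stopifnot(t_sys_ms > 0, t_dia_ms > 0, dt_ms > 0, n_frames >= 2,
            radial_contraction >= 0, radial_contraction < 1, gamma >= 0)
  half_fov <- min(rows, cols) / 2 * pixel_mm
  for (nm in names(slices)) {
    s <- slices[[nm]]
    if (s$r_endo_mm >= s$r_epi_mm) {
      stop("slice ", nm, ": r_endo must be smaller than r_epi")
    }
    if (s$r_epi_mm + margin_mm >= half_fov) {
      stop("slice ", nm, ": annulus (plus motion margin) exceeds the grid")
    }
  }
  structure(
    list(rows = rows, cols = cols, pixel_mm = pixel_mm, slices = slices,
         t_sys_ms = t_sys_ms, t_dia_ms = t_dia_ms, gamma = gamma,
         radial_contraction = radial_contraction,
         translation_mm_s = translation_mm_s, eddy_plane = eddy_plane,
         noise_sd_mm_s = noise_sd_mm_s, vz_amp_mm_s = vz_amp_mm_s,
         dt_ms = dt_ms, n_frames = as.integer(n_frames),
         venc_mm_s = venc_mm_s, margin_mm = margin_mm, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# half-sine twist waveform and its time integral --------------------------------

# angular velocity (deg/s) at time t (ms) for amplitude amp (deg/s); the
# diastolic amplitude is scaled so one cycle integrates to zero net rotation
.omega_wave <- function(t_ms, amp, t_sys, t_dia) {
  amp_d <- amp * t_sys / t_dia
  ifelse(t_ms <= t_sys,
         amp * sin(pi * t_ms / t_sys),
         ifelse(t_ms <= t_sys + t_dia,
                -amp_d * sin(pi * (t_ms - t_sys) / t_dia),
                0))
}

# closed-form rotation angle (deg): integral of .omega_wave from 0 to t
.theta_wave <- function(t_ms, amp, t_sys, t_dia) {
  amp_d <- amp * t_sys / t_dia
  th_sys_end <- 2 * amp * (t_sys / 1000) / pi
  ifelse(t_ms <= t_sys,
         amp * (t_sys / 1000) / pi * (1 - cos(pi * t_ms / t_sys)),
         ifelse(t_ms <= t_sys + t_dia,
                th_sys_end - amp_d * (t_dia / 1000) / pi *
                  (1 - cos(pi * (t_ms - t_sys) / t_dia)),
                0))
}

# radius scale factor (radial contraction) and its logarithmic rate (per s)
.radial_scale <- function(t_ms, frac, t_sys, t_dia) {
  u <- ifelse(t_ms <= t_sys, (1 - cos(pi * t_ms / t_sys)) / 2,
              ifelse(t_ms <= t_sys + t_dia,
                     (1 + cos(pi * (t_ms - t_sys) / t_dia)) / 2, 0))
  1 - frac * u
}

.radial_scale_rate <- function(t_ms, frac, t_sys, t_dia) {
  ifelse(t_ms <= t_sys,
         -frac * pi / (2 * t_sys / 1000) * sin(pi * t_ms / t_sys),
         ifelse(t_ms <= t_sys + t_dia,
                frac * pi / (2 * t_dia / 1000) * sin(pi * (t_ms - t_sys) / t_dia),
                0))
}

# layer amplitudes; "full" is the pixel-count-weighted effective amplitude of
# the annulus mean (mean v_phi / mean r), using integral r dA over each band
.layer_amp <- function(slice, gamma, layer) {
  amp <- slice$amp_dps
  r1 <- slice$r_endo_mm; r2 <- slice$r_epi_mm
  rm <- (r1 + r2) / 2
  switch(layer,
    endo = (1 + gamma) * amp,
    epi = amp,
    full = amp * ((1 + gamma) * (rm^3 - r1^3) + (r2^3 - rm^3)) / (r2^3 - r1^3),
    stop("unknown layer: ", layer)
  )
}

#' Analytic rotation angle of a phantom slice layer
#'
#' @param spec a [phantom_spec()].
#' @param slice slice label.
#' @param layer `"full"`, `"endo"` or `"epi"`.
#' @param t_ms time(s) in ms.
#' @return rotation angle(s), degrees.
#' @export
analytic_theta <- function(spec, slice, layer = "full", t_ms) {
  s <- spec$slices[[slice]]
  if (is.null(s)) stop("unknown slice: ", slice)
  amp <- .layer_amp(s, spec$gamma, layer)
  .theta_wave(t_ms, amp, spec$t_sys_ms, spec$t_dia_ms)
}

#' Analytic torsion of a phantom slice pair
#'
#' Exact torsion from the closed-form rotation-angle difference divided by
#' the slice separation.
#'
#' @param spec a [phantom_spec()].
#' @param pair `c(upper, lower)` slice labels (upper = more basal).
#' @param layer `"full"`, `"endo"` or `"epi"`.
#' @param t_ms time(s) in ms.
#' @return torsion, deg/mm.
#' @export
analytic_torsion <- function(spec, pair = c("base", "apex"), layer = "full",
                             t_ms) {
  if (!all(pair %in% names(spec$slices))) {
    stop("unknown slice pair: ", paste(pair, collapse = "-"))
  }
  h <- abs(spec$slices[[pair[1]]]$position_mm - spec$slices[[pair[2]]]$position_mm)
  (analytic_theta(spec, pair[1], layer, t_ms) -
      analytic_theta(spec, pair[2], layer, t_ms)) / h
}

#' Analytic (ground-truth) contours of a phantom slice at one frame
#'
#' @param spec a [phantom_spec()].
#' @param slice slice label.
#' @param frame frame index (1-based).
#' @param n_vertices vertices per contour.
#' @return a [contour_pair()] of concentric circles at the contracted radii.
#' @export
analytic_contours <- function(spec, slice, frame, n_vertices = 100L) {
  s <- spec$slices[[slice]]
  if (is.null(s)) stop("unknown slice: ", slice)
  t_ms <- (frame - 1) * spec$dt_ms
  sc <- .radial_scale(t_ms, spec$radial_contraction, spec$t_sys_ms, spec$t_dia_ms)
  center <- c((spec$rows - 1) / 2, (spec$cols - 1) / 2)
  contour_pair(
    epi = circle_contour(center, s$r_epi_mm * sc / spec$pixel_mm, n_vertices),
    endo = circle_contour(center, s$r_endo_mm * sc / spec$pixel_mm, n_vertices),
    frame_index = frame, check = FALSE
  )
}

#' Heart region of interest of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return `c(row0, col0, row1, col1)`, 0-based inclusive, enclosing the
#'   largest annulus plus the motion margin.
#' @export
phantom_roi <- function(spec) {
  center <- c((spec$rows - 1) / 2, (spec$cols - 1) / 2)
  rmax <- max(vapply(spec$slices, function(s) s$r_epi_mm, numeric(1)))
  half <- ceiling((rmax + spec$margin_mm) / spec$pixel_mm) + 2
  c(max(0, floor(center[1] - half)), max(0, floor(center[2] - half)),
    min(spec$rows - 1, ceiling(center[1] + half)),
    min(spec$cols - 1, ceiling(center[2] + half)))
}

#' Generate the synthetic TPM acquisition
#'
#' Builds one [tpm_series()] per requested slice: rotational plus radial
#' myocardial velocities on the (contracting) annulus, bulk translation,
#' static eddy-current offset planes, static surrounding tissue, Gaussian
#' velocity noise, and a three-class magnitude image (background / soft
#' tissue / myocardium) for mixture-model testing. With a fixed seed the
#' output is bit-identical across calls.
#'
#' @param spec a [phantom_spec()].
#' @param slices which slice labels to generate (default: all in the spec).
#' @return An object of class `tpm_phantom`: list with `slices` (a
#'   [slice_set()]), `spec`, `roi`, and `soft_truth` (the true static
#'   soft-tissue mask).
#' @export
generate_phantom <- function(spec, slices = names(spec$slices)) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$rows; nc <- spec$cols
  center <- c((nr - 1) / 2, (nc - 1) / 2)
  rowc <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  colc <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  d_row <- (rowc - center[1]) * spec$pixel_mm
  d_col <- (colc - center[2]) * spec$pixel_mm
  r_mm <- sqrt(d_row^2 + d_col^2)
  roi <- phantom_roi(spec)
  in_roi <- rowc >= roi[1] & rowc <= roi[3] & colc >= roi[2] & colc <= roi[4]
  border_band <- rowc < 4 | rowc > nr - 5 | colc < 4 | colc > nc - 5
  # a "solid tissue" block outside the ROI (spine-like), static
  solid_block <- rowc >= nr - 12 & rowc <= nr - 7 & colc >= round(nc / 2) - 4 &
    colc <= round(nc / 2) + 4 & !in_roi
  soft_truth <- !in_roi & !border_band & !solid_block
  t_ms <- (seq_len(spec$n_frames) - 1) * spec$dt_ms
  eddy_offsets <- lapply(1:3, function(k) {
    spec$eddy_plane[k, 1] + spec$eddy_plane[k, 2] * colc + spec$eddy_plane[k, 3] * rowc
  })

  # magnitude image (time-constant): three intensity classes
  mag0 <- matrix(rnorm(nr * nc, 10, 1), nr, nc)
  mag0[soft_truth] <- rnorm(sum(soft_truth), 100, 5)
  mag0[solid_block] <- rnorm(sum(solid_block), 200, 5)

  series <- list()
  for (lab in slices) {
    s <- spec$slices[[lab]]
    sc <- .radial_scale(t_ms, spec$radial_contraction, spec$t_sys_ms, spec$t_dia_ms)
    sc_rate <- .radial_scale_rate(t_ms, spec$radial_contraction,
                                  spec$t_sys_ms, spec$t_dia_ms)
    w_endo <- .omega_wave(t_ms, (1 + spec$gamma) * s$amp_dps,
                          spec$t_sys_ms, spec$t_dia_ms) * pi / 180 # rad/s
    w_epi <- .omega_wave(t_ms, s$amp_dps, spec$t_sys_ms, spec$t_dia_ms) * pi / 180
    vz_wave <- .omega_wave(t_ms, spec$vz_amp_mm_s, spec$t_sys_ms, spec$t_dia_ms)
    velocity <- array(0, c(nr, nc, spec$n_frames, 3))
    magnitude <- array(0, c(nr, nc, spec$n_frames))
    mag_t <- mag0
    for (tt in seq_len(spec$n_frames)) {
      r_in <- max(0, s$r_endo_mm * sc[tt] - spec$margin_mm)
      r_out <- s$r_epi_mm * sc[tt] + spec$margin_mm
      moving <- r_mm >= r_in & r_mm <= r_out
      r_mid <- (s$r_endo_mm + s$r_epi_mm) / 2 * sc[tt]
      w <- ifelse(r_mm < r_mid, w_endo[tt], w_epi[tt])
      k_rad <- sc_rate[tt] / sc[tt]
      vx <- ifelse(moving, -w * d_row + k_rad * d_col + spec$translation_mm_s[1], 0)
      vy <- ifelse(moving, w * d_col + k_rad * d_row + spec$translation_mm_s[2], 0)
      vz <- ifelse(moving, vz_wave[tt], 0)
      velocity[, , tt, 1] <- vx + eddy_offsets[[1]]
      velocity[, , tt, 2] <- vy + eddy_offsets[[2]]
      velocity[, , tt, 3] <- vz + eddy_offsets[[3]]
      annulus <- r_mm >= s$r_endo_mm * sc[tt] & r_mm <= s$r_epi_mm * sc[tt]
      mframe <- mag_t
      mframe[in_roi] <- rnorm(sum(in_roi), 10, 1)
      mframe[annulus] <- rnorm(sum(annulus), 200, 5)
      magnitude[, , tt] <- mframe
    }
    if (spec$noise_sd_mm_s > 0) {
      velocity <- velocity + array(
        rnorm(length(velocity), 0, spec$noise_sd_mm_s), dim(velocity))
    }
    vmax <- max(abs(velocity))
    if (vmax > spec$venc_mm_s) {
      stop(sprintf("phantom velocities exceed venc (%.1f > %.1f mm/s); reduce amplitudes",
                   vmax, spec$venc_mm_s))
    }
    series[[lab]] <- tpm_series(
      magnitude = magnitude, velocity = velocity,
      pixel_spacing = rep(spec$pixel_mm, 2), dt_ms = spec$dt_ms,
      venc_mm_s = spec$venc_mm_s, slice_label = lab,
      slice_position_mm = s$position_mm
    )
  }
  structure(list(slices = slice_set(series), spec = spec, roi = roi,
                 soft_truth = soft_truth),
            class = "tpm_phantom")
}

#' @export
print.tpm_phantom <- function(x, ...) {
  cat(sprintf("<tpm_phantom> %s; %d x %d px @ %.2f mm, %d frames @ %.1f ms, noise SD %.1f mm/s, seed %d\n",
              paste(names(x$slices$series), collapse = "/"),
              x$spec$rows, x$spec$cols, x$spec$pixel_mm, x$spec$n_frames,
              x$spec$dt_ms, x$spec$noise_sd_mm_s, x$spec$seed))
  invisible(x)
}
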