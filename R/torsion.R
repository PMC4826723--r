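# Torsion quantification: translation correction, cylindrical velocity
# decomposition, angular velocity and rotation angle per slice and layer,
# torsion curves between slice pairs, peak and transmural summaries.

#' Remove bulk in-plane translation of the heart
#'
#' Per frame, subtracts the myocardial-mask mean of the in-plane velocity
#' components (x and y) from those components everywhere; the through-plane
#' component is untouched.
#'
#' @param series a [tpm_series()].
#' @param masks logical array `rows x cols x frames` (e.g. `seg$mask`), or a
#'   `myo_segmentation`.
#' @return corrected [tpm_series()].
#' @export
correct_translation <- function(series, masks) {
  if (inherits(masks, "myo_segmentation")) masks <- masks$mask
  stopifnot(inherits(series, "tpm_series"))
  d <- dim(series$magnitude)
  if (!all(dim(masks) == d)) stop("mask array must match series dimensions")
  vel <- series$velocity
  for (t in seq_len(d[3])) {
    m <- masks[, , t]
    if (!any(m)) stop("empty myocardial mask at frame ", t)
    for (k in 1:2) {
      v <- vel[, , t, k]
      vel[, , t, k] <- v - mean(v[m])
    }
  }
  .with_velocity(series, vel)
}

#' Centroid of a mask in 0-based pixel coordinates
#' @param mask logical matrix.
#' @return numeric (row, col).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
}

#' Cylindrical decomposition of one in-plane velocity frame
#'
#' For each pixel with offset d from the centre (in mm), decomposes the
#' in-plane velocity into a radial component `v_r` (positive toward the
#' centre: contraction) and a rotational component `v_phi` (positive for
#' visually clockwise motion under the row-down display convention); `v_z`
#' passes through. The pixel at the exact centre gets `v_r = v_phi = 0`.
#'
#' @param v_x,v_y,v_z numeric matrices, mm/s (`x` = column axis, `y` = row
#'   axis).
#' @param center (row, col), 0-based pixels; must lie inside the grid.
#' @param pixel_spacing (row_mm, col_mm).
#' @return An object of class `cylindrical_frame`: list of matrices `v_r`,
#'   `v_phi`, `v_z` plus `center`.
#' @export
to_cylindrical <- function(v_x, v_y, v_z, center, pixel_spacing = c(1, 1)) {
  nr <- nrow(v_x); nc <- ncol(v_x)
  if (center[1] < 0 || center[1] > nr - 1 || center[2] < 0 || center[2] > nc - 1) {
    stop("center must lie inside the grid")
  }
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  d_row <- (matrix(rep(seq_len(nr) - 1, nc), nr, nc) - center[1]) * pixel_spacing[1]
  d_col <- (matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - center[2]) * pixel_spacing[2]
  r <- sqrt(d_row^2 + d_col^2)
  safe_r <- ifelse(r > 0, r, 1)
  v_r <- -(v_y * d_row + v_x * d_col) / safe_r
  v_phi <- (v_y * d_col - v_x * d_row) / safe_r
  v_r[r == 0] <- 0
  v_phi[r == 0] <- 0
  structure(list(v_r = v_r, v_phi = v_phi, v_z = v_z, center = center),
            class = "cylindrical_frame")
}

#' Mean myocardial radius
#'
#' Mean Euclidean distance (mm) of mask pixel centres to the rotation centre.
#'
#' @param mask logical matrix.
#' @param center (row, col), 0-based pixels.
#' @param pixel_spacing (row_mm, col_mm).
#' @return radius in mm.
#' @export
mean_radius <- function(mask, center, pixel_spacing = c(1, 1)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  dr <- (idx[, 1] - 1 - center[1]) * pixel_spacing[1]
  dc <- (idx[, 2] - 1 - center[2]) * pixel_spacing[2]
  mean(sqrt(dr^2 + dc^2))
}

#' Slice angular velocity in degrees per second
#'
#' Mask-mean rotational velocity divided by the mean myocardial radius,
#' converted from rad/s to deg/s.
#'
#' @param cyl a `cylindrical_frame` from [to_cylindrical()].
#' @param mask logical matrix selecting myocardial (or layer) pixels.
#' @param R_mm mean myocardial radius, mm (> 0).
#' @return angular velocity, deg/s.
#' @export
angular_velocity <- function(cyl, mask, R_mm) {
  if (!any(mask)) stop("empty mask")
  if (!is.finite(R_mm) || R_mm <= 0) stop("R_mm must be > 0")
  mean(cyl$v_phi[mask]) / R_mm * 180 / pi
}

#' Rotation angle by cumulative integration of angular velocity
#'
#' Cumulative trapezoidal time integral; the angle at the first frame is 0.
#'
#' @param omega_dps angular velocities, deg/s, one per frame.
#' @param dt_ms frame interval, ms.
#' @return rotation angles in degrees, same length as `omega_dps`.
#' @export
rotation_angle <- function(omega_dps, dt_ms) {
  if (length(omega_dps) < 2) stop("need at least 2 frames")
  t_s <- (seq_along(omega_dps) - 1) * dt_ms / 1000
  as.numeric(pracma::cumtrapz(t_s, omega_dps))
}

#' Rotation trace of one slice and layer
#'
#' Computes, per frame: the rotation centre (full-mask centroid), the
#' cylindrical decomposition, the layer mean radius, the angular velocity and
#' the cumulative rotation angle.
#'
#' @param series a preprocessed, translation-corrected [tpm_series()].
#' @param seg a `myo_segmentation` from [segment_series()].
#' @param layer `"full"`, `"endo"` or `"epi"` (layers require
#'   `seg$layer_map`).
#' @param layer_radius use the layer-specific mean radius (default) or the
#'   whole-mask radius (`"full"`).
#' @return a tibble of class `rotation_trace` with columns `frame`, `t_ms`,
#'   `omega_dps`, `theta_deg`, `R_mm`, `n_px`; attributes `slice_label`,
#'   `layer`, `dt_ms`, `slice_position_mm`.
#' @export
slice_rotation <- function(series, seg, layer = c("full", "endo", "epi"),
                           layer_radius = c("layer", "full")) {
  layer <- match.arg(layer)
  layer_radius <- match.arg(layer_radius)
  n <- series$n_frames
  if (layer != "full" && is.null(seg$layer_map)) {
    stop("segmentation has no layer map; rerun segment_series(layers = TRUE)")
  }
  omega <- R <- npx <- numeric(n)
  for (t in seq_len(n)) {
    full_mask <- seg$mask[, , t]
    lmask <- switch(layer,
      full = full_mask,
      endo = seg$layer_map[, , t] == 1L,
      epi = seg$layer_map[, , t] == 2L
    )
    if (!any(lmask)) stop("empty ", layer, " mask at frame ", t)
    center <- mask_centroid(full_mask)
    cyl <- to_cylindrical(series$velocity[, , t, 1], series$velocity[, , t, 2],
                          series$velocity[, , t, 3], center,
                          series$pixel_spacing)
    rmask <- if (layer_radius == "layer") lmask else full_mask
    R[t] <- mean_radius(rmask, center, series$pixel_spacing)
    omega[t] <- angular_velocity(cyl, lmask, R[t])
    npx[t] <- sum(lmask)
  }
  out <- tibble::tibble(
    frame = seq_len(n),
    t_ms = frame_times(series),
    omega_dps = omega,
    theta_deg = rotation_angle(omega, series$dt_ms),
    R_mm = R,
    n_px = npx
  )
  structure(out, class = c("rotation_trace", class(out)),
            slice_label = series$slice_label, layer = layer,
            dt_ms = series$dt_ms,
            slice_position_mm = series$slice_position_mm)
}

#' Torsion curve between two slices
#'
#' Torsion at each time point is the rotation-angle difference between the
#' upper (more basal) and lower (more apical) slice, normalized by their
#' separation: `T(t) = (theta_upper - theta_lower) / h`. Positive torsion
#' means the basal slice rotates clockwise relative to the apical slice
#' (display convention, row axis down). Traces with different temporal
#' resolutions (within 10%) are linearly resampled onto the coarser grid.
#'
#' @param trace_upper,trace_lower `rotation_trace` tibbles from
#'   [slice_rotation()] (same layer).
#' @param h_mm inter-slice distance, mm (> 0); defaults to the difference of
#'   the traces' slice positions when available.
#' @return a tibble of class `torsion_curve` with columns `t_ms`,
#'   `torsion_deg_per_mm`; attributes `slice_pair`, `layer`, `h_mm`, `T_max`
#'   (signed maximum) and `t_peak_ms`.
#' @export
torsion_curve <- function(trace_upper, trace_lower, h_mm = NULL) {
  dt_u <- attr(trace_upper, "dt_ms") %||% diff(trace_upper$t_ms[1:2])
  dt_l <- attr(trace_lower, "dt_ms") %||% diff(trace_lower$t_ms[1:2])
  if (max(dt_u, dt_l) / min(dt_u, dt_l) > 1.1) {
    stop("slice temporal resolutions differ by more than 10%")
  }
  if (is.null(h_mm)) {
    pu <- attr(trace_upper, "slice_position_mm")
    pl <- attr(trace_lower, "slice_position_mm")
    if (is.null(pu) || is.null(pl)) stop("h_mm required: traces carry no slice positions")
    h_mm <- abs(pu - pl)
  }
  if (!is.finite(h_mm) || h_mm <= 0) stop("h_mm must be > 0")
  dt <- max(dt_u, dt_l)
  t_end <- min(max(trace_upper$t_ms), max(trace_lower$t_ms))
  grid <- seq(0, t_end, by = dt)
  th_u <- approx(trace_upper$t_ms, trace_upper$theta_deg, xout = grid)$y
  th_l <- approx(trace_lower$t_ms, trace_lower$theta_deg, xout = grid)$y
  if (anyNA(th_u) || anyNA(th_l)) stop("trace lengths mismatched after resampling")
  torsion <- (th_u - th_l) / h_mm
  k <- which.max(torsion)
  out <- tibble::tibble(t_ms = grid, torsion_deg_per_mm = torsion)
  structure(out, class = c("torsion_curve", class(out)),
            slice_pair = c(attr(trace_upper, "slice_label") %||% "upper",
                           attr(trace_lower, "slice_label") %||% "lower"),
            layer = attr(trace_upper, "layer") %||% "full",
            h_mm = h_mm, T_max = torsion[k], t_peak_ms = grid[k])
}

#' Peak-torsion summary of a curve
#'
#' @param x a `torsion_curve`.
#' @param ... unused.
#' @return one-row tibble: `slice_pair`, `layer`, `h_mm`, `T_max`
#'   (deg/mm, signed maximum of the curve), `t_peak_ms`.
#' @export
glance.torsion_curve <- function(x, ...) {
  tibble::tibble(
    slice_pair = paste(attr(x, "slice_pair"), collapse = "-"),
    layer = attr(x, "layer"),
    h_mm = attr(x, "h_mm"),
    T_max = attr(x, "T_max"),
    t_peak_ms = attr(x, "t_peak_ms")
  )
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Transmural torsion summary
#'
#' Difference between the maxima of the endocardial and epicardial torsion
#' curves (the layer peaks occur concomitantly, so the absolute maxima are
#' subtracted directly), in absolute (`dT_max`, deg/mm) and relative
#' (`dPctT_max`, percent of the endocardial maximum) form.
#'
#' @param endo_curve,epi_curve `torsion_curve` objects for the same slice
#'   pair.
#' @return one-row tibble: `slice_pair`, `T_max_endo`, `T_max_epi`, `dT_max`,
#'   `dPctT_max`.
#' @export
transmural_summary <- function(endo_curve, epi_curve) {
  sp_e <- attr(endo_curve, "slice_pair"); sp_p <- attr(epi_curve, "slice_pair")
  if (!is.null(sp_e) && !is.null(sp_p) && !identical(sp_e, sp_p)) {
    stop("curves come from different slice pairs: ",
         paste(sp_e, collapse = "-"), " vs ", paste(sp_p, collapse = "-"))
  }
  t_endo <- attr(endo_curve, "T_max") %||% max(endo_curve$torsion_deg_per_mm)
  t_epi <- attr(epi_curve, "T_max") %||% max(epi_curve$torsion_deg_per_mm)
  d <- t_endo - t_epi
  pct <- if (t_endo == 0) {
    warning("endocardial T_max is zero; relative difference undefined")
    NA_real_
  } else d / t_endo * 100
  tibble::tibble(
    slice_pair = paste(sp_e %||% c("upper", "lower"), collapse = "-"),
    T_max_endo = t_endo, T_max_epi = t_epi,
    dT_max = d, dPctT_max = pct
  )
}

#' Resample torsion curves to a common grid and average
#'
#' Each curve is linearly interpolated onto a zero-anchored grid with
#' `dt_out` spacing; per grid point the mean and SD over the curves covering
#' that point are returned. The grid is truncated where no more than half of
#' the curves have support.
#'
#' @param curves list of `torsion_curve` objects (>= 1).
#' @param dt_out output grid spacing, ms (default 5).
#' @return tibble: `t_ms`, `mean_torsion`, `sd_torsion`, `n`.
#' @export
resample_and_average <- function(curves, dt_out = 5) {
  if (inherits(curves, "torsion_curve")) curves <- list(curves)
  if (length(curves) < 1) stop("need at least one curve")
  t_maxes <- vapply(curves, function(cv) max(cv$t_ms), numeric(1))
  grid <- seq(0, max(t_maxes), by = dt_out)
  vals <- vapply(curves, function(cv) {
    approx(cv$t_ms, cv$torsion_deg_per_mm, xout = grid)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n_cov <- rowSums(!is.na(vals))
  keep <- n_cov > length(curves) / 2
  tibble::tibble(
    t_ms = grid[keep],
    mean_torsion = rowMeans(vals[keep, , drop = FALSE], na.rm = TRUE),
    sd_torsion = apply(vals[keep, , drop = FALSE], 1, sd, na.rm = TRUE),
    n = n_cov[keep]
  )
}
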