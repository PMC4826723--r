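#' Tissue-phase-mapping velocity cine for one short-axis slice
#'
#' Bundles the magnitude cine and the three-directional velocity cine of a
#' single short-axis slice together with its geometry and timing metadata.
#' Velocities are stored in mm/s, times in ms, lengths in mm.
#'
#' Array layout follows the usual R image convention: `magnitude` is
#' `rows x cols x frames`, `velocity` is `rows x cols x frames x 3` with the
#' last dimension ordered (x, y, z) = (column axis, row axis, through-plane).
#'
#' @param magnitude numeric array, `rows x cols x frames`.
#' @param velocity numeric array, `rows x cols x frames x 3`, mm/s.
#' @param pixel_spacing numeric length-2, (row_mm, col_mm).
#' @param dt_ms temporal resolution, ms.
#' @param venc_mm_s velocity-encoding limit, mm/s; all velocities must satisfy
#'   `|v| <= venc_mm_s`.
#' @param slice_label one of `"base"`, `"mid"`, `"apex"`.
#' @param slice_position_mm slice position along the LV long axis, mm.
#' @return An object of class `tpm_series`.
#' @export
tpm_series <- function(magnitude, velocity, pixel_spacing, dt_ms, venc_mm_s,
                       slice_label = c("base", "mid", "apex"),
                       slice_position_mm = 0) {
  slice_label <- match.arg(slice_label)
  magnitude <- as.array(magnitude)
  velocity <- as.array(velocity)
  if (length(dim(magnitude)) != 3) stop("magnitude must be rows x cols x frames")
  if (length(dim(velocity)) != 4 || dim(velocity)[4] != 3) {
    stop("velocity must be rows x cols x frames x 3 (components x, y, z); got ",
         length(dim(velocity)), " dims with last = ",
         dim(velocity)[length(dim(velocity))])
  }
  if (!all(dim(velocity)[1:3] == dim(magnitude))) {
    stop("magnitude and velocity must share row/col/frame dimensions")
  }
  n_frames <- dim(magnitude)[3]
  if (n_frames < 2) stop("a TPM series needs at least 2 frames; got ", n_frames)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be strictly positive")
  }
  if (!is.finite(dt_ms) || dt_ms <= 0) stop("dt_ms must be strictly positive")
  if (!is.finite(venc_mm_s) || venc_mm_s <= 0) stop("venc_mm_s must be strictly positive")
  if (any(!is.finite(velocity))) stop("velocity contains non-finite values")
  vmax <- max(abs(velocity))
  if (vmax > venc_mm_s * (1 + 1e-9)) {
    stop(sprintf("%d voxel(s) exceed venc (max |v| = %.3f mm/s > %.3f mm/s)",
                 sum(abs(velocity) > venc_mm_s * (1 + 1e-9)), vmax, venc_mm_s))
  }
  structure(
    list(
      slice_label = slice_label,
      magnitude = magnitude,
      velocity = velocity,
      pixel_spacing = pixel_spacing,
      dt_ms = as.numeric(dt_ms),
      slice_position_mm = as.numeric(slice_position_mm),
      venc_mm_s = as.numeric(venc_mm_s),
      n_frames = as.integer(n_frames)
    ),
    class = "tpm_series"
  )
}

#' @export
print.tpm_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "<tpm_series> %s slice: %d x %d px, %d frames\n  pixel %.2f x %.2f mm, dt %.1f ms, venc %.0f mm/s, position %.1f mm\n",
    x$slice_label, d[1], d[2], x$n_frames,
    x$pixel_spacing[1], x$pixel_spacing[2], x$dt_ms, x$venc_mm_s,
    x$slice_position_mm
  ))
  invisible(x)
}

#' @export
dim.tpm_series <- function(x) dim(x$magnitude)

#' Extract one velocity component as a rows x cols x frames array
#'
#' @param series a [tpm_series()].
#' @param component `"x"` (column axis), `"y"` (row axis) or `"z"`.
#' @return numeric array, mm/s.
#' @export
velocity_component <- function(series, component = c("x", "y", "z")) {
  component <- match.arg(component)
  series$velocity[, , , match(component, c("x", "y", "z")), drop = FALSE][, , , 1]
}

#' Frame times in ms (frame 1 at t = 0)
#' @param series a [tpm_series()].
#' @return numeric vector of length `n_frames`.
#' @export
frame_times <- function(series) (seq_len(series$n_frames) - 1) * series$dt_ms

#' Convert stored phase to velocity
#'
#' Phase-contrast scanners store velocity as signal phase; with the standard
#' linear dialect a phase of +/- pi corresponds to +/- venc, so
#' `v = phase / pi * venc`.
#'
#' @param stored_phase numeric array of phase values in radians, in
#'   `[-pi, pi)`.
#' @param venc_mm_s velocity-encoding limit in mm/s.
#' @return velocity array in mm/s, same shape as `stored_phase`.
#' @export
#' @examples
#' phase_to_velocity(pi / 2, 250) # 125 mm/s
phase_to_velocity <- function(stored_phase, venc_mm_s) {
  if (!is.finite(venc_mm_s) || venc_mm_s <= 0) stop("venc_mm_s must be > 0")
  bad <- which(!is.finite(stored_phase))
  if (length(bad) > 0) {
    loc <- arrayInd(bad[1], dim(stored_phase) %||% length(stored_phase))
    stop("non-finite phase value at index (", paste(loc, collapse = ", "),
         ") and ", length(bad) - 1, " other location(s)")
  }
  stored_phase / pi * venc_mm_s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Slice set: several short-axis slices plus their separations
#'
#' @param ... named or unnamed [tpm_series()] objects (names default to their
#'   slice labels).
#' @return An object of class `slice_set` with elements `series` (a named
#'   list) and `h_mm()` accessible via [slice_distance()].
#' @export
slice_set <- function(...) {
  series <- list(...)
  if (length(series) == 1 && is.list(series[[1]]) &&
      !inherits(series[[1]], "tpm_series")) {
    series <- series[[1]]
  }
  stopifnot(all(vapply(series, inherits, logical(1), "tpm_series")))
  labs <- vapply(series, function(s) s$slice_label, character(1))
  if (anyDuplicated(labs)) stop("duplicate slice labels: ", paste(labs, collapse = ", "))
  names(series) <- labs
  dts <- vapply(series, function(s) s$dt_ms, numeric(1))
  if (max(dts) / min(dts) > 1.1) {
    stop("slice temporal resolutions differ by more than 10%")
  }
  structure(list(series = series), class = "slice_set")
}

#' Inter-slice distance in mm
#' @param slices a [slice_set()].
#' @param upper,lower slice labels; `upper` is the more basal slice.
#' @return positive distance h in mm.
#' @export
slice_distance <- function(slices, upper, lower) {
  s <- slices$series
  if (!upper %in% names(s) || !lower %in% names(s)) {
    stop("unknown slice pair: ", upper, "-", lower)
  }
  h <- abs(s[[upper]]$slice_position_mm - s[[lower]]$slice_position_mm)
  if (h <= 0) stop("slices ", upper, " and ", lower, " have identical positions")
  h
}
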