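# Reading and writing TPM velocity cines.
#
# Container format: a directory holding four uncompressed NIfTI files
# (magnitude.nii, vel_x.nii, vel_y.nii, vel_z.nii; each rows x cols x frames,
# velocities in mm/s) plus meta.json with the acquisition metadata. The JSON
# block is authoritative; the NIfTI pixdims are cross-checked against it.

.tpm_meta <- function(series) {
  list(
    format = "tpm-container",
    version = 1L,
    slice_label = series$slice_label,
    pixel_spacing_mm = series$pixel_spacing,
    dt_ms = series$dt_ms,
    slice_position_mm = series$slice_position_mm,
    venc_mm_s = series$venc_mm_s,
    n_frames = series$n_frames,
    dim = dim(series$magnitude)
  )
}

.write_nii <- function(arr, path, pixdim3) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdim3
  RNifti::writeNifti(img, path, datatype = "double")
}

.container_files <- c("magnitude.nii", "vel_x.nii", "vel_y.nii", "vel_z.nii")

#' Write a TPM series to disk
#'
#' @param series a [tpm_series()].
#' @param path for `format = "container"` a directory (created if needed); for
#'   `format = "nifti"` a file-name prefix.
#' @param format `"container"` (directory of NIfTI arrays + `meta.json`) or
#'   `"nifti"` (per-component NIfTI files + a JSON sidecar).
#' @return `path`, invisibly.
#' @seealso [read_tpm()]
#' @export
write_tpm <- function(series, path, format = c("container", "nifti")) {
  format <- match.arg(format)
  if (!inherits(series, "tpm_series")) stop("`series` must be a tpm_series")
  n_over <- sum(abs(series$velocity) > series$venc_mm_s * (1 + 1e-9))
  if (n_over > 0) {
    stop(n_over, " voxel(s) exceed venc; refusing to write an invalid series")
  }
  pd <- c(series$pixel_spacing, series$dt_ms)
  if (format == "container") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    arrays <- list(series$magnitude, velocity_component(series, "x"),
                   velocity_component(series, "y"), velocity_component(series, "z"))
    for (i in seq_along(arrays)) {
      .write_nii(arrays[[i]], file.path(path, .container_files[i]), pd)
    }
    json <- jsonlite::toJSON(.tpm_meta(series), auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, file.path(path, "meta.json"))
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    files <- paste0(path, c("_mag.nii", "_vx.nii", "_vy.nii", "_vz.nii"))
    arrays <- list(series$magnitude, velocity_component(series, "x"),
                   velocity_component(series, "y"), velocity_component(series, "z"))
    for (i in seq_along(arrays)) .write_nii(arrays[[i]], files[i], pd)
    json <- jsonlite::toJSON(.tpm_meta(series), auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a TPM series from disk
#'
#' Velocities are returned in mm/s. Metadata (pixel spacing, temporal
#' resolution) stored in the JSON block is cross-checked against the NIfTI
#' headers; a mismatch or missing venc/pixel-spacing is a hard error — the
#' reader never guesses.
#'
#' @param path directory (container) or file-name prefix (nifti).
#' @param format `"container"`, `"nifti"`, or `"dicom"` (not supported; see
#'   Details).
#' @details DICOM phase-contrast input is not supported by this package;
#'   convert series to NIfTI or the container format first (any standard
#'   DICOM-to-NIfTI converter, with venc and slice position recorded in the
#'   JSON sidecar).
#' @return a [tpm_series()].
#' @export
read_tpm <- function(path, format = c("container", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom") {
    stop("DICOM input is not supported; convert the series to NIfTI or the ",
         "container format (see ?read_tpm) and record venc in the JSON sidecar")
  }
  meta_file <- if (format == "container") file.path(path, "meta.json") else paste0(path, ".json")
  if (!file.exists(meta_file)) stop("metadata file not found: ", meta_file)
  meta <- jsonlite::fromJSON(meta_file)
  for (field in c("venc_mm_s", "pixel_spacing_mm", "dt_ms")) {
    if (is.null(meta[[field]])) {
      stop("metadata is missing required field '", field, "'; never guessed")
    }
  }
  files <- if (format == "container") {
    file.path(path, .container_files)
  } else {
    paste0(path, c("_mag.nii", "_vx.nii", "_vy.nii", "_vz.nii"))
  }
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("expected 1 magnitude and 3 velocity components; missing: ",
         paste(basename(missing), collapse = ", "))
  }
  imgs <- lapply(files, RNifti::readNifti)
  arrs <- lapply(imgs, function(x) {
    a <- as.array(x)
    attributes(a) <- list(dim = dim(a))
    a
  })
  pd <- RNifti::pixdim(imgs[[1]])
  expect_pd <- c(meta$pixel_spacing_mm, meta$dt_ms)
  if (length(pd) >= 3 &&
      any(abs(pd[1:3] - expect_pd) > 1e-4 * pmax(1, abs(expect_pd)))) {
    stop("NIfTI header pixdim disagrees with JSON metadata (",
         paste(signif(pd[1:3], 6), collapse = " x "), " vs ",
         paste(signif(expect_pd, 6), collapse = " x "), ")")
  }
  d <- dim(arrs[[1]])
  velocity <- array(0, c(d, 3))
  for (k in 1:3) velocity[, , , k] <- arrs[[k + 1]]
  tpm_series(
    magnitude = arrs[[1]],
    velocity = velocity,
    pixel_spacing = meta$pixel_spacing_mm,
    dt_ms = meta$dt_ms,
    venc_mm_s = meta$venc_mm_s,
    slice_label = meta$slice_label %||% "mid",
    slice_position_mm = meta$slice_position_mm %||% 0
  )
}

#' Read/write contour pairs as JSON
#'
#' Contour JSON layout: `{"frame_index": k, "epi": [[row, col], ...],
#' "endo": [[row, col], ...]}` with 0-based pixel coordinates.
#'
#' @param pair a [contour_pair()].
#' @param path JSON file path.
#' @return `read_contours()` returns a [contour_pair()]; `write_contours()`
#'   returns `path` invisibly.
#' @export
write_contours <- function(pair, path) {
  stopifnot(inherits(pair, "contour_pair"))
  json <- jsonlite::toJSON(
    list(frame_index = pair$frame_index,
         epi = unname(pair$epi), endo = unname(pair$endo)),
    auto_unbox = TRUE, digits = NA
  )
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  obj <- jsonlite::fromJSON(path)
  contour_pair(epi = obj$epi, endo = obj$endo,
               frame_index = obj$frame_index %||% 1L)
}
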