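# Preprocessing: soft-tissue classification, stationary-pixel detection,
# first-order eddy-current (baseline) plane fit and subtraction, and 3x3
# low-pass velocity filtering.

# replace the velocity array without re-running venc validation (corrections
# may legitimately move values across the raw encoding limit)
.with_velocity <- function(series, velocity) {
  series$velocity <- velocity
  series
}

#' Classify stationary soft tissue from the magnitude image
#'
#' Fits a three-class Gaussian mixture (background / soft tissue / solid
#' tissue) to the magnitude intensities outside a user-drawn rectangular
#' region of interest around the heart, and returns the middle-mean class
#' ("soft tissue") by maximum posterior. Pixels inside the ROI are never
#' labelled.
#'
#' @param magnitude_frame numeric matrix (one cine frame).
#' @param roi heart rectangle `c(row0, col0, row1, col1)` (0-based,
#'   inclusive); classification runs on its complement.
#' @return logical matrix, `TRUE` on soft tissue outside the ROI.
#' @export
classify_soft_tissue <- function(magnitude_frame, roi) {
  nr <- nrow(magnitude_frame); nc <- ncol(magnitude_frame)
  roi <- as.numeric(roi)
  if (length(roi) != 4 || roi[1] < 0 || roi[2] < 0 ||
      roi[3] > nr - 1 || roi[4] > nc - 1 || roi[1] > roi[3] || roi[2] > roi[4]) {
    stop("roi (row0, col0, row1, col1) must be a valid rectangle inside the image")
  }
  in_roi <- matrix(FALSE, nr, nc)
  in_roi[(roi[1] + 1):(roi[3] + 1), (roi[2] + 1):(roi[4] + 1)] <- TRUE
  candidates <- which(!in_roi)
  if (length(candidates) < 300) {
    stop("need at least 300 pixels outside the heart ROI; got ", length(candidates))
  }
  vals <- magnitude_frame[candidates]
  rng <- diff(range(vals))
  if (rng <= 0) {
    stop("degenerate intensity histogram (constant image); ",
         "supply a manual soft-tissue threshold instead")
  }
  fit <- suppressWarnings(
    mclust::Mclust(vals, G = 3, modelNames = "V", verbose = FALSE,
                   x = mclust::mclustBIC(vals, G = 3, modelNames = "V",
                                         verbose = FALSE))
  )
  if (is.null(fit)) {
    stop("3-class Gaussian mixture failed to fit; ",
         "supply a manual soft-tissue threshold instead")
  }
  mu <- sort(fit$parameters$mean)
  if (min(diff(mu)) < 0.01 * rng) {
    stop("Gaussian mixture degenerate: class means separated by less than 1% ",
         "of the intensity range; supply a manual soft-tissue threshold instead")
  }
  middle <- order(fit$parameters$mean)[2]
  soft <- matrix(FALSE, nr, nc)
  soft[candidates] <- fit$classification == middle
  soft
}

# per-pixel temporal SD of one velocity component (rows x cols)
.temporal_sd <- function(comp_array) {
  d <- dim(comp_array)
  m <- matrix(comp_array, d[1] * d[2], d[3])
  s1 <- rowSums(m)
  s2 <- rowSums(m^2)
  v <- (s2 - s1^2 / d[3]) / (d[3] - 1)
  v[v < 0] <- 0
  matrix(sqrt(v), d[1], d[2])
}

#' Detect stationary soft-tissue pixels
#'
#' A pixel is stationary when its temporal standard deviation is below
#' `threshold` (default 5 mm/s) in all three velocity components, intersected
#' with the soft-tissue mask.
#'
#' @param series a [tpm_series()].
#' @param soft_mask logical matrix from [classify_soft_tissue()].
#' @param threshold SD threshold in mm/s (default 5).
#' @return An object of class `stationary_mask`: list with `mask` (logical
#'   matrix), `sd_threshold_mm_s` and `n_pixels`.
#' @export
detect_stationary <- function(series, soft_mask, threshold = 5) {
  stopifnot(inherits(series, "tpm_series"))
  if (!any(soft_mask)) stop("soft-tissue mask is empty")
  ok <- soft_mask
  for (k in 1:3) {
    sds <- .temporal_sd(series$velocity[, , , k, drop = FALSE][, , , 1])
    ok <- ok & (sds < threshold)
  }
  n <- sum(ok)
  if (n < 10) {
    stop("only ", n, " stationary pixels found; eddy-current plane fit is ill-posed")
  }
  if (n < 50) {
    warning("only ", n, " stationary pixels found; eddy-current plane fit may be unstable")
  }
  structure(list(mask = ok, sd_threshold_mm_s = threshold, n_pixels = n),
            class = "stationary_mask")
}

#' Fit first-order eddy-current offset planes
#'
#' For each velocity component, fits an ordinary-least-squares plane
#' `v(row, col) = a + b*col + c*row` (mm/s, per-pixel slopes) to the
#' time-averaged velocity of the stationary pixels. Eddy-current offsets are
#' temporally static, so one plane per component covers the whole series.
#'
#' @param series a [tpm_series()].
#' @param stationary a `stationary_mask` from [detect_stationary()].
#' @return An object of class `eddy_plane`: 3 x 3 numeric matrix, rows =
#'   components (x, y, z), columns = (a, b, c).
#' @export
fit_eddy_plane <- function(series, stationary) {
  mask <- if (inherits(stationary, "stationary_mask")) stationary$mask else stationary
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 10) stop("need at least 10 stationary pixels; got ", nrow(idx))
  rowc <- idx[, 1] - 1 # 0-based
  colc <- idx[, 2] - 1
  X <- cbind(1, colc, rowc)
  if (qr(X)$rank < 3) stop("stationary pixels are collinear; plane fit is singular")
  coefs <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("a", "b", "c")))
  for (k in 1:3) {
    vbar <- apply(series$velocity[, , , k, drop = FALSE][, , , 1], c(1, 2), mean)
    fit <- lm.fit(X, vbar[mask])
    coefs[k, ] <- fit$coefficients
  }
  structure(coefs, class = c("eddy_plane", "matrix"))
}

#' Subtract an eddy-current plane from a velocity series
#'
#' @param series a [tpm_series()].
#' @param plane an `eddy_plane` from [fit_eddy_plane()].
#' @return corrected [tpm_series()] (metadata unchanged).
#' @export
correct_eddy <- function(series, plane) {
  stopifnot(inherits(series, "tpm_series"), inherits(plane, "eddy_plane"))
  d <- dim(series$magnitude)
  colc <- matrix(rep(seq_len(d[2]) - 1, each = d[1]), d[1], d[2])
  rowc <- matrix(rep(seq_len(d[1]) - 1, times = d[2]), d[1], d[2])
  vel <- series$velocity
  for (k in 1:3) {
    offset <- plane[k, 1] + plane[k, 2] * colc + plane[k, 3] * rowc
    vel[, , , k] <- vel[, , , k, drop = FALSE][, , , 1] -
      array(offset, c(d[1], d[2], d[3]))
  }
  .with_velocity(series, vel)
}

#' Low-pass filter the velocity field
#'
#' Applies a 3x3 spatial filter to every velocity component of every frame to
#' reduce noise. The default is a 3x3 mean (the standard low-pass kernel);
#' a 3x3 median is available as an alternative. Edges are handled by
#' reflection.
#'
#' @param series a [tpm_series()].
#' @param method `"mean"` (default), `"median"` or `"none"`.
#' @return filtered [tpm_series()].
#' @export
smooth_velocity <- function(series, method = c("mean", "median", "none")) {
  method <- match.arg(method)
  if (method == "none") return(series)
  vel <- series$velocity
  d <- dim(series$magnitude)
  for (k in 1:3) for (t in seq_len(d[3])) {
    m <- vel[, , t, k]
    vel[, , t, k] <- if (method == "mean") mean_filter_3x3(m) else .median_filter_3x3(m)
  }
  .with_velocity(series, vel)
}

.median_filter_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  stack <- matrix(0, nr * nc, 9)
  i <- 0
  for (dr in -1:1) for (dc in -1:1) {
    i <- i + 1
    stack[, i] <- as.vector(p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  matrix(apply(stack, 1, median), nr, nc)
}

#' Run the full preprocessing chain
#'
#' Soft-tissue classification on the first magnitude frame, stationary-pixel
#' detection, eddy-current plane fit and subtraction, then 3x3 low-pass
#' filtering.
#'
#' @param series a [tpm_series()].
#' @param roi heart rectangle `c(row0, col0, row1, col1)` (0-based).
#' @param sd_threshold stationary SD threshold, mm/s (default 5).
#' @param filter `"mean"`, `"median"` or `"none"`.
#' @return list with `series` (corrected + filtered), `stationary`
#'   (`stationary_mask`), and `plane` (`eddy_plane`).
#' @export
preprocess_series <- function(series, roi, sd_threshold = 5,
                              filter = c("mean", "median", "none")) {
  filter <- match.arg(filter)
  soft <- classify_soft_tissue(series$magnitude[, , 1], roi)
  stationary <- detect_stationary(series, soft, sd_threshold)
  plane <- fit_eddy_plane(series, stationary)
  corrected <- correct_eddy(series, plane)
  list(series = smooth_velocity(corrected, filter),
       stationary = stationary, plane = plane)
}
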