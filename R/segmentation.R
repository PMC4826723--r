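# Myocardial segmentation: contour refinement (active contour driven by the
# in-plane velocity field), velocity-field contour propagation (RK4), mask
# rasterization with morphological closing, centerline thinning and
# endocardial/epicardial layer labelling.

# separable Gaussian smoothing with edge replication (used only to widen the
# capture range of the snake's external force)
gauss_smooth <- function(m, sigma = 1.5) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2 * half) - half, 1), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * half) - half, 1), nc)
  p <- m[ri, ci]
  # convolve rows then columns
  out <- matrix(0, nr + 2 * half, nc)
  for (i in seq_along(k)) out <- out + k[i] * p[, (i):(i + nc - 1)]
  res <- matrix(0, nr, nc)
  for (i in seq_along(k)) res <- res + k[i] * out[(i):(i + nr - 1), ]
  res
}

# in-plane speed image (mm/s) at one frame
.inplane_speed <- function(series, frame) {
  vx <- series$velocity[, , frame, 1]
  vy <- series$velocity[, , frame, 2]
  sqrt(vx^2 + vy^2)
}

.gradient <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  list(gr = (s[c(2:nr, nr), ] - s[c(1, 1:(nr - 1)), ]) / 2,
       gc = (s[, c(2:nc, nc)] - s[, c(1, 1:(nc - 1))]) / 2)
}

# normalized external force: gradient of the smoothed edge map of the
# in-plane speed image, so contours are attracted to velocity edges (the
# moving/static boundaries at endo- and epicardium); returns list(fr, fc)
.snake_force <- function(series, frame, sigma = 1.5) {
  s <- gauss_smooth(.inplane_speed(series, frame), sigma)
  g <- .gradient(s)
  edge <- gauss_smooth(sqrt(g$gr^2 + g$gc^2), sigma)
  f <- .gradient(edge)
  mx <- max(sqrt(f$gr^2 + f$gc^2))
  if (mx > 0) { f$gr <- f$gr / mx; f$gc <- f$gc / mx }
  list(fr = f$gr, fc = f$gc)
}

# implicit snake system matrix inverse for n vertices
.snake_matrix <- function(n, tension, rigidity, step) {
  d2 <- matrix(0, n, n)
  idx <- seq_len(n)
  d2[cbind(idx, idx)] <- 2
  d2[cbind(idx, idx %% n + 1)] <- -1
  d2[cbind(idx %% n + 1, idx)] <- -1
  d4 <- d2 %*% d2
  solve(diag(n) + step * (tension * d2 + rigidity * d4))
}

.evolve_snake <- function(poly, force, tension, rigidity, external, step,
                          tol_px, max_iter, shape) {
  n <- nrow(poly)
  inv <- .snake_matrix(n, tension, rigidity, step)
  p <- poly
  for (it in seq_len(max_iter)) {
    fr <- bilinear_interp(force$fr, p[, 1], p[, 2])
    fc <- bilinear_interp(force$fc, p[, 1], p[, 2])
    newp <- inv %*% (p + step * external * cbind(fr, fc))
    newp[, 1] <- pmin(pmax(newp[, 1], 0), shape[1] - 1)
    newp[, 2] <- pmin(pmax(newp[, 2], 0), shape[2] - 1)
    disp <- max(sqrt(rowSums((newp - p)^2)))
    if (polygon_area(newp) < 10) {
      stop("contour collapsed during refinement (area < 10 px^2); ",
           "last valid state retained at iteration ", it - 1)
    }
    p <- newp
    if (disp < tol_px) break
  }
  p
}

#' Refine manual contours with a velocity-driven active contour
#'
#' Evolves each contour as a closed snake with internal tension and rigidity
#' terms plus an external force given by the (normalized) spatial gradient of
#' the smoothed in-plane speed image at the contour's frame, so contours are
#' attracted to the edges of the moving myocardium. Iterates until the
#' maximum vertex displacement drops below `tol_px` or `max_iter` iterations.
#'
#' All weights are package defaults, not values from any acquisition
#' protocol; refinement is optional — trusted manual contours may be used
#' directly.
#'
#' @param initial a [contour_pair()] valid at its frame.
#' @param series the (preprocessed) [tpm_series()].
#' @param tension,rigidity,external snake weights (defaults 0.1, 0.1, 1.0).
#' @param step implicit evolution step size (default 0.5).
#' @param tol_px convergence threshold on vertex displacement (default 0.1 px).
#' @param max_iter iteration cap (default 300).
#' @param n_vertices contours are resampled to this many equally spaced
#'   vertices before evolution.
#' @param sigma Gaussian smoothing (px) of the speed image.
#' @return a refined [contour_pair()].
#' @export
refine_contours <- function(initial, series, tension = 0.1, rigidity = 0.1,
                            external = 1.0, step = 0.5, tol_px = 0.1,
                            max_iter = 300L, n_vertices = 100L, sigma = 1.5) {
  stopifnot(inherits(initial, "contour_pair"), inherits(series, "tpm_series"))
  if (initial$frame_index < 1 || initial$frame_index > series$n_frames) {
    stop("contour frame_index ", initial$frame_index, " outside series")
  }
  force <- .snake_force(series, initial$frame_index, sigma)
  shape <- dim(series$magnitude)[1:2]
  epi <- .evolve_snake(resample_polygon(initial$epi, n_vertices), force,
                       tension, rigidity, external, step, tol_px, max_iter, shape)
  endo <- .evolve_snake(resample_polygon(initial$endo, n_vertices), force,
                        tension, rigidity, external, step, tol_px, max_iter, shape)
  if (any(!point_in_polygon(endo[, 1], endo[, 2], epi))) {
    stop("refinement made the endo and epi contours cross; ",
         "last valid state is the initial contour pair")
  }
  contour_pair(epi, endo, initial$frame_index)
}

# velocity (row, col) in px/frame at continuous position and fractional frame
.velocity_px_per_frame <- function(series, pos, tf) {
  n <- series$n_frames
  tf <- min(max(tf, 1), n)
  f0 <- floor(tf); f1 <- min(f0 + 1, n)
  w <- tf - f0
  sample_comp <- function(k) {
    v0 <- bilinear_interp(series$velocity[, , f0, k], pos[, 1], pos[, 2])
    if (w > 0) {
      v1 <- bilinear_interp(series$velocity[, , f1, k], pos[, 1], pos[, 2])
      v0 <- (1 - w) * v0 + w * v1
    }
    v0
  }
  scale <- series$dt_ms / 1000 # mm per frame given mm/s
  cbind(sample_comp(2) * scale / series$pixel_spacing[1],   # v_y -> rows
        sample_comp(1) * scale / series$pixel_spacing[2])   # v_x -> cols
}

.rk4_step <- function(series, pos, t_frame, h_frames) {
  f <- function(p, tf) .velocity_px_per_frame(series, p, tf)
  k1 <- f(pos, t_frame)
  k2 <- f(pos + h_frames / 2 * k1, t_frame + h_frames / 2)
  k3 <- f(pos + h_frames / 2 * k2, t_frame + h_frames / 2)
  k4 <- f(pos + h_frames * k3, t_frame + h_frames)
  pos + h_frames / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

.rk2_step <- function(series, pos, t_frame, h_frames) {
  f <- function(p, tf) .velocity_px_per_frame(series, p, tf)
  k1 <- f(pos, t_frame)
  k2 <- f(pos + h_frames / 2 * k1, t_frame + h_frames / 2)
  pos + h_frames * k2
}

.advect_polygon <- function(series, poly, from_frame, to_frame, order,
                            n_vertices, shape) {
  stepper <- if (order == 4) .rk4_step else .rk2_step
  h <- sign(to_frame - from_frame)
  p <- poly
  for (k in seq(from_frame, to_frame - h, by = h)) {
    p <- stepper(series, p, k, h)
    out_of_image <- p[, 1] < 0 | p[, 1] > shape[1] - 1 |
      p[, 2] < 0 | p[, 2] > shape[2] - 1
    if (any(out_of_image)) {
      warning(sum(out_of_image), " vertex/vertices left the image at frame ",
              k + h, "; clamped")
      p[, 1] <- pmin(pmax(p[, 1], 0), shape[1] - 1)
      p[, 2] <- pmin(pmax(p[, 2], 0), shape[2] - 1)
    }
    if (!is_simple_polygon(p)) {
      warning("contour self-intersected at frame ", k + h,
              "; repaired by equal-arc-length resampling")
    }
    p <- resample_polygon(p, n_vertices)
  }
  p
}

#' Propagate contours through the velocity field
#'
#' Advects every contour vertex forward and backward from the start frame
#' through the in-plane velocity field using Runge-Kutta integration with
#' bilinear spatial and linear temporal interpolation (displacement in px =
#' v mm/s x dt s / pixel spacing mm; step = one frame interval). After each
#' step the contour is resampled to `n_vertices` equally spaced vertices.
#'
#' @param start a [contour_pair()] with a valid `frame_index`.
#' @param series the (preprocessed) [tpm_series()].
#' @param order Runge-Kutta order, 4 (default) or 2.
#' @param n_vertices resampling count after each step.
#' @return a list of [contour_pair()], one per frame.
#' @export
propagate_contours <- function(start, series, order = c(4, 2),
                               n_vertices = 100L) {
  order <- match.arg(as.character(order[1]), c("4", "2"))
  order <- as.integer(order)
  stopifnot(inherits(start, "contour_pair"), inherits(series, "tpm_series"))
  n <- series$n_frames
  k0 <- start$frame_index
  if (k0 < 1 || k0 > n) stop("start frame ", k0, " outside series")
  shape <- dim(series$magnitude)[1:2]
  out <- vector("list", n)
  base_epi <- resample_polygon(start$epi, n_vertices)
  base_endo <- resample_polygon(start$endo, n_vertices)
  out[[k0]] <- contour_pair(base_epi, base_endo, k0, check = FALSE)
  if (k0 < n) {
    for (k in (k0 + 1):n) {
      prev <- out[[k - 1]]
      out[[k]] <- contour_pair(
        .advect_polygon(series, prev$epi, k - 1, k, order, n_vertices, shape),
        .advect_polygon(series, prev$endo, k - 1, k, order, n_vertices, shape),
        k, check = FALSE
      )
    }
  }
  if (k0 > 1) {
    for (k in (k0 - 1):1) {
      nxt <- out[[k + 1]]
      out[[k]] <- contour_pair(
        .advect_polygon(series, nxt$epi, k + 1, k, order, n_vertices, shape),
        .advect_polygon(series, nxt$endo, k + 1, k, order, n_vertices, shape),
        k, check = FALSE
      )
    }
  }
  out
}

#' Rasterize a contour pair into a myocardial mask
#'
#' Pixels whose centres fall inside the epicardial and outside the
#' endocardial contour (even-odd rule) form the myocardial annulus, which is
#' then smoothed by binary morphological closing with a 3x3 structuring
#' element.
#'
#' @param contours a [contour_pair()].
#' @param shape integer (rows, cols).
#' @param closing apply 3x3 closing (default `TRUE`).
#' @return logical matrix, `TRUE` on myocardium.
#' @export
rasterize_and_close <- function(contours, shape, closing = TRUE) {
  stopifnot(inherits(contours, "contour_pair"))
  if (polygon_area(contours$epi) <= 0 || polygon_area(contours$endo) <= 0) {
    stop("degenerate zero-area contour; mask would be empty")
  }
  nr <- shape[1]; nc <- shape[2]
  py <- rep(seq_len(nr) - 1, times = nc)
  px <- rep(seq_len(nc) - 1, each = nr)
  mask <- matrix(
    point_in_polygon(py, px, contours$epi) &
      !point_in_polygon(py, px, contours$endo),
    nr, nc
  )
  if (closing) mask <- close_3x3(mask)
  mask
}

#' Extract the myocardial centerline by topology-preserving thinning
#'
#' Sequentially deletes simple (topology-preserving) border pixels in
#' directional subpasses until the annular mask is reduced to a one-pixel-wide
#' skeleton; spurs are pruned so that an annulus yields a single closed loop.
#'
#' @param mask logical matrix; must be a single 8-connected annular component
#'   (exactly one hole).
#' @return logical matrix of centerline pixels.
#' @export
extract_centerline <- function(mask) {
  comp <- max(label_components(mask, 8))
  if (comp != 1) {
    stop("mask must be a single 8-connected component; found ", comp)
  }
  holes <- count_holes(mask)
  if (holes != 1) {
    stop("mask is not annular: expected exactly 1 hole, found ", holes)
  }
  prune_spurs(thin_mask(mask))
}

#' Split the myocardial mask into endocardial and epicardial layers
#'
#' Mask pixels strictly inside the centerline loop are labelled endocardial,
#' pixels outside epicardial; centerline pixels themselves are assigned to the
#' epicardial layer (declared tie-break).
#'
#' @param mask logical myocardium matrix.
#' @param centerline logical centerline matrix (a closed loop within `mask`).
#' @return integer matrix: 0 background, 1 endocardial, 2 epicardial.
#' @export
label_layers <- function(mask, centerline) {
  if (count_holes(centerline) != 1) {
    stop("centerline is not a single closed loop; cannot split layers")
  }
  border <- matrix(FALSE, nrow(mask), ncol(mask))
  border[1, ] <- TRUE; border[nrow(mask), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(mask)] <- TRUE
  outside <- flood_fill(!centerline, border & !centerline, 4)
  layer <- matrix(0L, nrow(mask), ncol(mask))
  layer[mask & !centerline & !outside] <- 1L # inside the loop: endocardial
  layer[mask & !centerline & outside] <- 2L  # outside the loop: epicardial
  layer[mask & centerline] <- 2L             # tie-break: centerline -> epi
  layer
}

#' Segment a full series from one contour pair
#'
#' Runs (optional) refinement, contour propagation over all frames,
#' rasterization with closing and, when `layers = TRUE`, per-frame centerline
#' extraction and layer labelling.
#'
#' @param series a (preprocessed) [tpm_series()].
#' @param initial a [contour_pair()] drawn at one frame (typically
#'   mid-systole).
#' @param refine run [refine_contours()] first (default `FALSE`: manual
#'   contours trusted).
#' @param layers also compute centerline and layer maps (default `TRUE`).
#' @param order Runge-Kutta order for propagation.
#' @return An object of class `myo_segmentation`: list with `contours`
#'   (per-frame [contour_pair()]), `mask` (rows x cols x frames logical),
#'   and, if requested, `centerline` and `layer_map` arrays.
#' @export
segment_series <- function(series, initial, refine = FALSE, layers = TRUE,
                           order = 4) {
  if (refine) initial <- refine_contours(initial, series)
  contours <- propagate_contours(initial, series, order = order)
  shape <- dim(series$magnitude)[1:2]
  n <- series$n_frames
  mask <- array(FALSE, c(shape, n))
  centerline <- if (layers) array(FALSE, c(shape, n)) else NULL
  layer_map <- if (layers) array(0L, c(shape, n)) else NULL
  for (k in seq_len(n)) {
    m <- rasterize_and_close(contours[[k]], shape)
    mask[, , k] <- m
    if (layers) {
      cl <- extract_centerline(m)
      centerline[, , k] <- cl
      layer_map[, , k] <- label_layers(m, cl)
    }
  }
  structure(list(contours = contours, mask = mask, centerline = centerline,
                 layer_map = layer_map),
            class = "myo_segmentation")
}

#' @export
print.myo_segmentation <- function(x, ...) {
  n <- dim(x$mask)[3]
  cat(sprintf("<myo_segmentation> %d frames, mask %d x %d, mean area %.0f px\n",
              n, dim(x$mask)[1], dim(x$mask)[2], mean(apply(x$mask, 3, sum))))
  invisible(x)
}
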