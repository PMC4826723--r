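#' A matched pair of epicardial and endocardial contours
#'
#' Contours are closed simple polygons in 0-based (row, col) pixel
#' coordinates; the endocardial contour must lie strictly inside the
#' epicardial one. `frame_index` is the (1-based) cine frame the contours
#' belong to.
#'
#' @param epi,endo numeric matrices, one vertex per row, columns (row, col).
#' @param frame_index integer frame index (1-based).
#' @param check if `TRUE` (default), validate simplicity and nesting.
#' @return An object of class `contour_pair`.
#' @export
contour_pair <- function(epi, endo, frame_index = 1L, check = TRUE) {
  epi <- as.matrix(epi); endo <- as.matrix(endo)
  storage.mode(epi) <- "double"; storage.mode(endo) <- "double"
  if (ncol(epi) != 2 || ncol(endo) != 2) stop("contours must be n x 2 (row, col)")
  if (nrow(epi) < 3 || nrow(endo) < 3) stop("contours need at least 3 vertices")
  if (check) {
    if (!is_simple_polygon(epi)) stop("epicardial contour is self-intersecting")
    if (!is_simple_polygon(endo)) stop("endocardial contour is self-intersecting")
    inside <- point_in_polygon(endo[, 1], endo[, 2], epi)
    if (!all(inside)) {
      stop("endocardial contour must lie strictly inside the epicardial contour (",
           sum(!inside), " vertex/vertices outside)")
    }
    if (any(point_in_polygon(epi[, 1], epi[, 2], endo))) {
      stop("epicardial contour crosses into the endocardial region")
    }
  }
  structure(list(epi = epi, endo = endo, frame_index = as.integer(frame_index)),
            class = "contour_pair")
}

#' @export
print.contour_pair <- function(x, ...) {
  cat(sprintf("<contour_pair> frame %d: epi %d vertices (area %.1f px^2), endo %d vertices (area %.1f px^2)\n",
              x$frame_index, nrow(x$epi), polygon_area(x$epi),
              nrow(x$endo), polygon_area(x$endo)))
  invisible(x)
}

# proper-intersection test between all non-adjacent edge pairs
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  orient <- function(p, q, r1, r2) {
    (q[, 1] - p[, 1]) * (r2 - p[, 2]) - (q[, 2] - p[, 2]) * (r1 - p[, 1])
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    if (length(js) == 0) next
    p1 <- a[rep(i, length(js)), , drop = FALSE]
    p2 <- b[rep(i, length(js)), , drop = FALSE]
    q1 <- a[js, , drop = FALSE]
    q2 <- b[js, , drop = FALSE]
    d1 <- orient(p1, p2, q1[, 1], q1[, 2])
    d2 <- orient(p1, p2, q2[, 1], q2[, 2])
    d3 <- orient(q1, q2, p1[, 1], p1[, 2])
    d4 <- orient(q1, q2, p2[, 1], p2[, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Generate a circular contour
#'
#' Convenience constructor for circles in pixel coordinates, used for phantom
#' initialization and tests.
#'
#' @param center (row, col), 0-based pixels.
#' @param radius_px radius in pixels.
#' @param n number of vertices.
#' @return n x 2 matrix of (row, col) vertices.
#' @export
circle_contour <- function(center, radius_px, n = 100L) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(center[1] + radius_px * sin(ang), center[2] + radius_px * cos(ang))
}
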