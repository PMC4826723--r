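# Internal raster utilities: fixed 3x3 morphology, topology-preserving
# thinning, flood fill / labelling, polygon rasterization, interpolation.
# All matrices are (rows x cols); continuous coordinates are 0-based pixel
# centres in (row, col) order.

# value of the neighbour at offset (dr, dc) for every pixel; `fill` outside
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_src <- max(1, 1 + dr):min(nr, nr + dr)
  c_src <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(r_src) == 0 || length(c_src) == 0) return(out)
  out[r_src - dr, c_src - dc] <- m[r_src, c_src]
  out
}

.n8_offsets <- cbind(
  dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
  dc = c(0, 1, 1, 1, 0, -1, -1, -1)
) # N, NE, E, SE, S, SW, W, NW

# 3x3 mean filter; edges handled by (symmetric) reflection
mean_filter_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    acc <- acc + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  acc / 9
}

dilate_3x3 <- function(m) {
  out <- m
  for (k in seq_len(8)) {
    out <- out | shift_mat(m, .n8_offsets[k, 1], .n8_offsets[k, 2], FALSE)
  }
  out
}

erode_3x3 <- function(m) {
  out <- m
  for (k in seq_len(8)) {
    out <- out & shift_mat(m, .n8_offsets[k, 1], .n8_offsets[k, 2], FALSE)
  }
  out
}

close_3x3 <- function(m) erode_3x3(dilate_3x3(m))

# flood fill by iterative constrained dilation
flood_fill <- function(region, seeds, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  offs <- if (connectivity == 4) .n8_offsets[c(1, 3, 5, 7), , drop = FALSE] else .n8_offsets
  grow <- seeds & region
  repeat {
    nxt <- grow
    for (k in seq_len(nrow(offs))) {
      nxt <- nxt | shift_mat(grow, offs[k, 1], offs[k, 2], FALSE)
    }
    nxt <- nxt & region
    if (!any(nxt & !grow)) return(grow)
    grow <- nxt
  }
}

# integer label map of connected components (0 = background)
label_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- flood_fill(remaining, seed, connectivity)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

# background components of !mask not reachable from the image border (4-conn)
count_holes <- function(mask) {
  bg <- !mask
  border <- matrix(FALSE, nrow(mask), ncol(mask))
  border[1, ] <- TRUE; border[nrow(mask), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(mask)] <- TRUE
  outside <- flood_fill(bg, border & bg, 4)
  holes <- bg & !outside
  max(label_components(holes, 4))
}

# ---- topology-preserving thinning -----------------------------------------

# Simple-point lookup over the 256 possible 8-neighbourhood configurations.
# A foreground pixel is simple (deletable without changing topology, with
# 8-connected foreground / 4-connected background) iff its neighbourhood has
# exactly one 8-connected foreground component and exactly one 4-connected
# background component touching a 4-neighbour.
.simple_lut_env <- new.env(parent = emptyenv())

simple_point_lut <- function() {
  if (!is.null(.simple_lut_env$lut)) return(.simple_lut_env$lut)
  lut <- logical(256)
  # ring positions in a 3x3 patch, (row, col) with centre (2, 2)
  ring <- .n8_offsets + 2
  for (code in 0:255) {
    patch <- matrix(FALSE, 3, 3)
    bits <- as.logical(bitwAnd(code, 2^(0:7)))
    patch[ring] <- bits
    fg_idx <- which(patch & !(row(patch) == 2 & col(patch) == 2))
    # foreground components, 8-connectivity within the ring
    n_fg <- if (length(fg_idx) == 0) 0L else {
      pf <- patch; pf[2, 2] <- FALSE
      max(label_components(pf, 8))
    }
    # background components, 4-connectivity, touching a 4-neighbour of centre
    pb <- !patch; pb[2, 2] <- FALSE
    labs <- label_components(pb, 4)
    four_nb <- labs[cbind(c(1, 2, 3, 2), c(2, 3, 2, 1))]
    n_bg <- length(unique(four_nb[four_nb > 0]))
    lut[code + 1] <- (n_fg == 1L) && (n_bg == 1L)
  }
  .simple_lut_env$lut <- lut
  lut
}

neighbour_code_at <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  code <- 0L
  for (k in seq_len(8)) {
    rr <- r + .n8_offsets[k, 1]; cc <- c + .n8_offsets[k, 2]
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc]) {
      code <- code + 2L^(k - 1L)
    }
  }
  code
}

# Sequential morphological thinning with directional subpasses: deletes
# simple, non-endpoint border pixels until stable. Preserves topology; an
# annular mask reduces to a one-pixel-wide closed loop near its centerline.
thin_mask <- function(mask) {
  lut <- simple_point_lut()
  m <- mask
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)) # N, S, W, E borders
  repeat {
    changed <- FALSE
    for (d in dirs) {
      cand <- m & !shift_mat(m, d[1], d[2], FALSE)
      idx <- which(cand, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      for (i in seq_len(nrow(idx))) {
        r <- idx[i, 1]; c <- idx[i, 2]
        if (!m[r, c]) next
        code <- neighbour_code_at(m, r, c)
        nnb <- sum(as.logical(bitwAnd(code, 2^(0:7))))
        if (nnb >= 2 && lut[code + 1]) {
          m[r, c] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m
}

# remove skeleton spurs: iteratively delete pixels with <= 1 neighbour
prune_spurs <- function(sk, max_iter = 100L) {
  for (i in seq_len(max_iter)) {
    nb <- matrix(0, nrow(sk), ncol(sk))
    for (k in seq_len(8)) {
      nb <- nb + shift_mat(sk, .n8_offsets[k, 1], .n8_offsets[k, 2], FALSE)
    }
    ends <- sk & nb <= 1
    if (!any(ends)) return(sk)
    sk <- sk & !ends
  }
  sk
}

# ---- polygon geometry ------------------------------------------------------

# even-odd point-in-polygon test; points (py, px) and poly in (row, col)
point_in_polygon <- function(py, px, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- (xj - xi) * (py[crosses] - yi) / (yj - yi) + xi
      flip <- px[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  y <- poly[, 1]; x <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(poly) c(mean(poly[, 1]), mean(poly[, 2]))

# resample a closed polygon to n vertices equally spaced in arc length
resample_polygon <- function(poly, n = 100L) {
  closed <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polygon: zero perimeter")
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(
    approx(s, closed[, 1], xout = target, rule = 2)$y,
    approx(s, closed[, 2], xout = target, rule = 2)$y
  )
}

# ---- interpolation ---------------------------------------------------------

# bilinear interpolation of matrix `m` at 0-based (rr, cc); clamped at edges
bilinear_interp <- function(m, rr, cc) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- pmin(pmax(rr, 0), nr - 1)
  cc <- pmin(pmax(cc, 0), nc - 1)
  r0 <- pmin(floor(rr), nr - 2); c0 <- pmin(floor(cc), nc - 2)
  fr <- rr - r0; fc <- cc - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2)
  i11 <- cbind(r0 + 2, c0 + 2)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}
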