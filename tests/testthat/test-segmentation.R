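# Segmentation: contour validation, snake refinement, RK propagation,
# rasterization, centerline thinning, layer labelling.

test_that("contour pairs validate simplicity and nesting", {
  c20 <- c(20, 20)
  expect_s3_class(contour_pair(circle_contour(c20, 10), circle_contour(c20, 5)),
                  "contour_pair")
  bowtie <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  expect_error(contour_pair(bowtie, circle_contour(c(2, 2), 0.5)),
               "self-intersecting")
  expect_error(contour_pair(circle_contour(c20, 5), circle_contour(c20, 10)),
               "inside")
  expect_error(contour_pair(circle_contour(c20, 10), circle_contour(c(40, 40), 2)),
               "inside")
  expect_error(contour_pair(rbind(c(0, 0), c(1, 1)), circle_contour(c20, 5)),
               "3 vertices")
})

test_that("rasterization reproduces the analytic annulus area and shape", {
  shape <- c(64, 64)
  center <- c(31.5, 31.5)
  pair <- contour_pair(circle_contour(center, 14, 100),
                       circle_contour(center, 8, 100))
  mask <- rasterize_and_close(pair, shape)
  expect_equal(sum(mask), pi * (14^2 - 8^2), tolerance = 0.05)
  idx <- which(mask, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - 1 - center[1])^2 + (idx[, 2] - 1 - center[2])^2)
  expect_true(all(r > 8 - 1.1 & r < 14 + 1.1))
  expect_error(
    rasterize_and_close(contour_pair(matrix(1, 3, 2), matrix(1, 3, 2),
                                     check = FALSE), shape),
    "degenerate")
})

test_that("RK4 integration tracks a rigid rotation almost exactly", {
  # bare integrator steps (no resampling) isolate the truncation error:
  # per step it is O((w dt)^5) for RK4 and O((w dt)^3) for RK2, i.e. about
  # 1e-11 px and 3e-6 px here, far below the tolerances checked
  s <- rigid_rotation_series(omega_dps = 30, n_frames = 11, dt_ms = 20)
  center <- c(31.5, 31.5)
  pts <- circle_contour(center, 14, 60)
  p4 <- pts; p2 <- pts
  for (k in 1:(s$n_frames - 1)) {
    p4 <- tpmtorsion:::.rk4_step(s, p4, k, 1)
    p2 <- tpmtorsion:::.rk2_step(s, p2, k, 1)
  }
  t_last <- (s$n_frames - 1) * s$dt_ms / 1000
  expected <- rotate_points(pts, center, 30 * t_last)
  err4 <- sqrt(rowSums((p4 - expected)^2))
  err2 <- sqrt(rowSums((p2 - expected)^2))
  expect_lt(max(err4), 1e-6)
  expect_lt(max(err2), 0.05)
  expect_gt(max(err2), max(err4)) # RK2 is less accurate on the same problem
})

test_that("full propagation with per-step resampling stays on the rotated circle", {
  s <- rigid_rotation_series(omega_dps = 30, n_frames = 11, dt_ms = 20)
  center <- c(31.5, 31.5)
  start <- contour_pair(circle_contour(center, 14, 60),
                        circle_contour(center, 8, 60), frame_index = 1L)
  out <- propagate_contours(start, s, order = 4)
  t_last <- (s$n_frames - 1) * s$dt_ms / 1000
  expected <- rotate_points(out[[1]]$epi, center, 30 * t_last)
  # each step resamples along polygon chords, pulling vertices slightly
  # inward (up to one chord sagitta, ~0.007 px for a 100-gon of radius 14,
  # per step); over 10 steps the cumulative drift is bounded by ~0.07 px,
  # still well under a pixel
  err <- sqrt(rowSums((out[[s$n_frames]]$epi - expected)^2))
  expect_lt(max(err), 0.07)
  r_obs <- sqrt(rowSums(sweep(out[[s$n_frames]]$epi, 2, center)^2))
  expect_lt(max(abs(r_obs - 14)), 0.07)
  expect_lte(max(r_obs), 14 + 1e-6) # the drift is inward only
})

test_that("propagated contours stay on the analytic phantom wall", {
  ph <- generate_phantom(two_slice_spec(seed = 2), slices = "base")
  s <- ph$slices$series$base
  k0 <- 8L
  start <- analytic_contours(ph$spec, "base", k0)
  out <- propagate_contours(start, s, order = 4)
  expect_length(out, s$n_frames)
  expect_equal(out[[k0]]$epi, tpmtorsion:::resample_polygon(start$epi, 100))
  # vertices slide tangentially with the wall, so compare radii: the contour
  # must stay on the (contracted) epicardial circle at every checked frame
  center <- c((ph$spec$rows - 1) / 2, (ph$spec$cols - 1) / 2)
  for (k in c(1, 5, 12, s$n_frames)) {
    sc <- tpmtorsion:::.radial_scale(frame_times(s)[k], ph$spec$radial_contraction,
                                     ph$spec$t_sys_ms, ph$spec$t_dia_ms)
    r_truth <- ph$spec$slices$base$r_epi_mm * sc / ph$spec$pixel_mm
    r_obs <- sqrt(rowSums(sweep(out[[k]]$epi, 2, center)^2))
    expect_lt(mean(abs(r_obs - r_truth)), 0.25)
  }
})

test_that("snake refinement pulls perturbed contours back to the wall", {
  spec <- phantom_spec(gamma = 0, radial_contraction = 0, vz_amp_mm_s = 0,
                       margin_mm = 0, n_frames = 8)
  ph <- generate_phantom(spec, slices = "base")
  s <- ph$slices$series$base
  center <- c((spec$rows - 1) / 2, (spec$cols - 1) / 2)
  r_epi <- spec$slices$base$r_epi_mm / spec$pixel_mm
  r_endo <- spec$slices$base$r_endo_mm / spec$pixel_mm
  k0 <- which.min(abs(frame_times(s) - spec$t_sys_ms / 2))
  init <- contour_pair(circle_contour(center, r_epi * 1.12, 100),
                       circle_contour(center, r_endo * 0.88, 100),
                       frame_index = k0)
  ref <- refine_contours(init, s)
  err_epi <- abs(sqrt(rowSums(sweep(ref$epi, 2, center)^2)) - r_epi)
  err_endo <- abs(sqrt(rowSums(sweep(ref$endo, 2, center)^2)) - r_endo)
  expect_lt(mean(err_epi), 1)
  expect_lt(mean(err_endo), 1)
  expect_error(refine_contours(contour_pair(init$epi, init$endo, 99L), s),
               "outside series")
})

test_that("centerline extraction yields a single closed loop at mid-wall", {
  shape <- c(64, 64)
  center <- c(31.5, 31.5)
  pair <- contour_pair(circle_contour(center, 14, 100),
                       circle_contour(center, 8, 100))
  mask <- rasterize_and_close(pair, shape)
  cl <- extract_centerline(mask)
  expect_equal(max(tpmtorsion:::label_components(cl, 8)), 1)
  expect_equal(tpmtorsion:::count_holes(cl), 1)
  idx <- which(cl, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - 1 - center[1])^2 + (idx[, 2] - 1 - center[2])^2)
  expect_lt(abs(mean(r) - 11), 1) # near the mid radius (8+14)/2

  expect_error(extract_centerline(matrix(TRUE, 5, 5)), "1 hole")
  two <- matrix(FALSE, 10, 10)
  two[2, 2] <- TRUE
  two[8, 8] <- TRUE
  expect_error(extract_centerline(two), "single 8-connected")
})

test_that("layer labelling partitions the mask with the declared tie-break", {
  shape <- c(64, 64)
  center <- c(31.5, 31.5)
  mask <- rasterize_and_close(
    contour_pair(circle_contour(center, 14, 100), circle_contour(center, 8, 100)),
    shape)
  cl <- extract_centerline(mask)
  lm <- label_layers(mask, cl)
  expect_true(all(lm[!mask] == 0))
  expect_true(all(lm[mask] %in% 1:2))
  expect_true(all(lm[cl] == 2)) # centerline pixels belong to the epi layer
  idx1 <- which(lm == 1, arr.ind = TRUE)
  idx2 <- which(lm == 2 & !cl, arr.ind = TRUE)
  r1 <- sqrt((idx1[, 1] - 1 - center[1])^2 + (idx1[, 2] - 1 - center[2])^2)
  r2 <- sqrt((idx2[, 1] - 1 - center[1])^2 + (idx2[, 2] - 1 - center[2])^2)
  expect_lt(mean(r1), mean(r2)) # endo band lies inside the epi band
  expect_error(label_layers(mask, matrix(FALSE, 64, 64)), "closed loop")
})

test_that("segment_series assembles contours, masks and layer maps", {
  ph <- generate_phantom(two_slice_spec(n_frames = 10, seed = 4), slices = "base")
  s <- ph$slices$series$base
  seg <- segment_series(s, analytic_contours(ph$spec, "base", 5), layers = TRUE)
  expect_s3_class(seg, "myo_segmentation")
  expect_length(seg$contours, 10)
  expect_equal(dim(seg$mask), c(48, 48, 10))
  expect_equal(dim(seg$layer_map), c(48, 48, 10))
  for (k in c(1, 10)) {
    expect_identical(seg$layer_map[, , k] > 0, seg$mask[, , k])
  }
})
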