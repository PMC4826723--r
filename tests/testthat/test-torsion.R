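# Torsion quantification: cylindrical decomposition, angular velocity,
# rotation angle, torsion curves, transmural and cohort-average summaries.

make_trace <- function(t_ms, theta_deg, label = NULL, position = NULL,
                       layer = "full") {
  structure(
    tibble::tibble(t_ms = t_ms, theta_deg = theta_deg),
    class = c("rotation_trace", "tbl_df", "tbl", "data.frame"),
    slice_label = label, layer = layer, dt_ms = diff(t_ms[1:2]),
    slice_position_mm = position
  )
}

test_that("cylindrical decomposition separates rotation from contraction", {
  nr <- nc <- 21
  center <- c(10, 10)
  d_row <- matrix(rep(0:(nr - 1), nc), nr, nc) - center[1]
  d_col <- matrix(rep(0:(nc - 1), each = nr), nr, nc) - center[2]
  w <- 0.5 # rad/s, clockwise
  cyl <- to_cylindrical(-w * d_row, w * d_col, d_row * 0, center)
  r <- sqrt(d_row^2 + d_col^2)
  expect_equal(cyl$v_phi, w * r)
  expect_equal(max(abs(cyl$v_r)), 0)
  expect_equal(cyl$v_phi[center[1] + 1, center[2] + 1], 0)

  # pure contraction: velocity points toward the centre
  k <- 0.3
  cyl2 <- to_cylindrical(-k * d_col, -k * d_row, d_row * 0, center)
  expect_equal(cyl2$v_r, k * r)
  expect_equal(max(abs(cyl2$v_phi)), 0)

  # anisotropic pixel spacing is honoured
  cyl3 <- to_cylindrical(-w * d_row * 2, w * d_col * 1.5, d_row * 0, center,
                         pixel_spacing = c(2, 1.5))
  r3 <- sqrt((d_row * 2)^2 + (d_col * 1.5)^2)
  expect_equal(cyl3$v_phi, w * r3)
  expect_error(to_cylindrical(d_row, d_row, d_row, c(-3, 10)), "inside")
})

test_that("angular velocity of a rigid field equals its true rate", {
  nr <- nc <- 31
  center <- c(15, 15)
  d_row <- matrix(rep(0:(nr - 1), nc), nr, nc) - center[1]
  d_col <- matrix(rep(0:(nc - 1), each = nr), nr, nc) - center[2]
  w <- 0.4 # rad/s
  cyl <- to_cylindrical(-w * d_row, w * d_col, d_row * 0, center)
  r <- sqrt(d_row^2 + d_col^2)
  mask <- r >= 5 & r <= 12
  R <- mean_radius(mask, center)
  expect_equal(mean_radius(mask, center, c(2.2, 2.2)), R * 2.2)
  expect_equal(angular_velocity(cyl, mask, R), w * 180 / pi)
  expect_error(angular_velocity(cyl, mask & FALSE, R), "empty")
  expect_error(angular_velocity(cyl, mask, 0), "R_mm")
})

test_that("rotation angle integrates exactly for linear angular velocity", {
  dt <- 20
  omega <- seq(0, 90, by = 9) # deg/s, linear in time: trapezoid is exact
  th <- rotation_angle(omega, dt)
  t_s <- (seq_along(omega) - 1) * dt / 1000
  expect_equal(th, 45 * t_s^2 / 0.2) # integral of (90/0.2) * t
  expect_equal(th[1], 0)
  expect_error(rotation_angle(5, 20), "at least 2")
})

test_that("torsion normalizes the angle difference by slice distance", {
  tu <- make_trace(c(0, 100, 200), c(0, 2, 3), "base", 0)
  tl <- make_trace(c(0, 100, 200), c(0, 1, 0), "apex", -50)
  cv <- torsion_curve(tu, tl) # h from slice positions: 50 mm
  expect_s3_class(cv, "torsion_curve")
  expect_equal(attr(cv, "h_mm"), 50)
  expect_equal(cv$torsion_deg_per_mm, c(0, 0.02, 0.06))
  expect_equal(attr(cv, "T_max"), 0.06)
  expect_equal(attr(cv, "t_peak_ms"), 200)
  g <- glance(cv)
  expect_equal(g$slice_pair, "base-apex")
  expect_equal(g$T_max, 0.06)

  expect_error(torsion_curve(tu, tl, h_mm = 0), "h_mm")
  expect_error(torsion_curve(make_trace(c(0, 100), c(0, 1)),
                             make_trace(c(0, 100), c(0, 1))), "h_mm required")
  slow <- make_trace(c(0, 150, 300), c(0, 1, 0), "apex", -50)
  expect_error(torsion_curve(tu, slow), "more than 10%")
})

test_that("a signed negative peak is preserved (clockwise-dominant torsion)", {
  tu <- make_trace(c(0, 100, 200), c(0, -2, -4), "base", 0)
  tl <- make_trace(c(0, 100, 200), c(0, 0, 0), "apex", -40)
  cv <- torsion_curve(tu, tl)
  expect_equal(attr(cv, "T_max"), 0) # signed maximum, not |minimum|
  expect_lt(min(cv$torsion_deg_per_mm), 0)
})

test_that("transmural summary subtracts the layer peaks", {
  mk <- function(tm) {
    structure(tibble::tibble(t_ms = c(0, 100), torsion_deg_per_mm = c(0, tm)),
              class = c("torsion_curve", "tbl_df", "tbl", "data.frame"),
              slice_pair = c("base", "apex"), layer = "endo", h_mm = 50,
              T_max = tm, t_peak_ms = 100)
  }
  out <- transmural_summary(mk(0.46), mk(0.30))
  expect_equal(out$dT_max, 0.16)
  expect_equal(out$dPctT_max, 0.16 / 0.46 * 100)
  expect_warning(z <- transmural_summary(mk(0), mk(0.30)), "zero")
  expect_true(is.na(z$dPctT_max))
  other <- mk(0.3)
  attr(other, "slice_pair") <- c("base", "mid")
  expect_error(transmural_summary(mk(0.46), other), "different slice pairs")
})

test_that("translation correction removes an injected bulk drift", {
  ph <- generate_phantom(two_slice_spec(translation_mm_s = c(8, -6), seed = 9),
                         slices = "base")
  s <- ph$slices$series$base
  contours <- lapply(seq_len(s$n_frames), function(k) {
    analytic_contours(ph$spec, "base", k)
  })
  seg <- tpmtorsion:::seg_from_contour_list(contours, dim(s$magnitude)[1:2],
                                            layers = FALSE)
  cs <- correct_translation(s, seg$mask)
  for (k in c(1, 7, 15)) {
    m <- seg$mask[, , k]
    expect_lt(abs(mean(cs$velocity[, , k, 1][m])), 1e-10)
    expect_lt(abs(mean(cs$velocity[, , k, 2][m])), 1e-10)
  }
  expect_error(correct_translation(s, array(FALSE, dim(s$magnitude))), "empty")
})

test_that("slice rotation recovers the phantom's analytic angle", {
  ph <- generate_phantom(two_slice_spec(seed = 10), slices = "base")
  s <- smooth_velocity(ph$slices$series$base, "mean")
  contours <- lapply(seq_len(s$n_frames), function(k) {
    analytic_contours(ph$spec, "base", k)
  })
  seg <- tpmtorsion:::seg_from_contour_list(contours, dim(s$magnitude)[1:2],
                                            layers = FALSE)
  s <- correct_translation(s, seg$mask)
  tr <- slice_rotation(s, seg, "full")
  truth <- analytic_theta(ph$spec, "base", "full", tr$t_ms)
  expect_lt(max(abs(tr$theta_deg - truth)) / max(abs(truth)), 0.05)
  expect_equal(attr(tr, "slice_label"), "base")
  expect_equal(tr$t_ms, frame_times(s))
})

test_that("curve averaging keeps points covered by a strict majority", {
  mk <- function(t_end, val) {
    structure(tibble::tibble(t_ms = seq(0, t_end, by = 100),
                             torsion_deg_per_mm = rep(val, t_end / 100 + 1)),
              class = c("torsion_curve", "tbl_df", "tbl", "data.frame"))
  }
  out <- resample_and_average(list(mk(800, 1), mk(800, 2), mk(1000, 3)),
                              dt_out = 100)
  expect_equal(max(out$t_ms), 800) # 1/3 coverage beyond 800 ms is dropped
  expect_equal(out$mean_torsion, rep(2, 9))
  expect_equal(out$sd_torsion, rep(1, 9))
  expect_equal(out$n, rep(3, 9))
  one <- resample_and_average(mk(400, 5), dt_out = 200)
  expect_equal(one$mean_torsion, rep(5, 3))
  expect_error(resample_and_average(list()), "at least one")
})
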