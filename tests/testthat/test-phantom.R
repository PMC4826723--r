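# Phantom generator: waveform identities, determinism, field correctness,
# magnitude classes, and closed-loop parameter recovery at module scale.

test_that("spec validation catches impossible geometry and timing", {
  expect_error(two_slice_spec(slices = list(
    base = list(position_mm = 0, r_endo_mm = 20, r_epi_mm = 15, amp_dps = 10)
  )), "smaller than r_epi")
  expect_error(two_slice_spec(slices = list(
    base = list(position_mm = 0, r_endo_mm = 30, r_epi_mm = 51, amp_dps = 10)
  )), "exceeds the grid")
  expect_error(two_slice_spec(radial_contraction = 1.2))
  expect_error(two_slice_spec(n_frames = 1))
})

test_that("twist waveform integrates to zero over one cycle and peaks at end-systole", {
  spec <- two_slice_spec()
  t_cycle <- spec$t_sys_ms + spec$t_dia_ms
  expect_equal(analytic_theta(spec, "base", "full", t_cycle), 0)
  th_sys <- analytic_theta(spec, "base", "epi", spec$t_sys_ms)
  amp <- spec$slices$base$amp_dps
  expect_equal(th_sys, 2 * amp * (spec$t_sys_ms / 1000) / pi)
  # endo rotates (1 + gamma) times as far
  expect_equal(analytic_theta(spec, "base", "endo", spec$t_sys_ms),
               (1 + spec$gamma) * th_sys)
  # full-layer amplitude lies between the two
  th_full <- analytic_theta(spec, "base", "full", spec$t_sys_ms)
  expect_gt(th_full, th_sys)
  expect_lt(th_full, (1 + spec$gamma) * th_sys)
  expect_error(analytic_theta(spec, "nope", "full", 0), "unknown slice")
})

test_that("analytic torsion is the angle difference over slice distance", {
  spec <- two_slice_spec()
  t <- c(0, 150, 300, 500)
  expect_equal(
    analytic_torsion(spec, c("base", "apex"), "full", t),
    (analytic_theta(spec, "base", "full", t) -
       analytic_theta(spec, "apex", "full", t)) / 40
  )
  expect_error(analytic_torsion(spec, c("base", "mid")), "unknown slice pair")
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- two_slice_spec(noise_sd_mm_s = 5, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$slices$series$base$velocity, b$slices$series$base$velocity)
  expect_identical(a$slices$series$apex$magnitude, b$slices$series$apex$magnitude)
  c_ <- generate_phantom(two_slice_spec(noise_sd_mm_s = 5, seed = 43))
  expect_false(identical(a$slices$series$base$velocity,
                         c_$slices$series$base$velocity))
})

test_that("the sampled velocity field matches the kinematic model", {
  spec <- two_slice_spec(radial_contraction = 0, vz_amp_mm_s = 0, gamma = 0,
                         seed = 2)
  ph <- generate_phantom(spec, slices = "base")
  s <- ph$slices$series$base
  center <- c((spec$rows - 1) / 2, (spec$cols - 1) / 2)
  k <- 6
  t_ms <- frame_times(s)[k]
  w <- tpmtorsion:::.omega_wave(t_ms, spec$slices$base$amp_dps,
                                spec$t_sys_ms, spec$t_dia_ms) * pi / 180
  # probe a mid-wall pixel (integer 0-based coordinates; centre is at 23.5)
  px <- c(24, 32)
  d_row <- (px[1] - center[1]) * spec$pixel_mm
  d_col <- (px[2] - center[2]) * spec$pixel_mm
  expect_equal(s$velocity[px[1] + 1, px[2] + 1, k, 1], -w * d_row)
  expect_equal(s$velocity[px[1] + 1, px[2] + 1, k, 2], w * d_col)
  # outside the annulus plus margin: static
  far <- c(2, 2)
  expect_equal(max(abs(s$velocity[far[1], far[2], , ])), 0)
})

test_that("oversized amplitudes trip the venc guard", {
  spec <- two_slice_spec(slices = list(
    base = list(position_mm = 0, r_endo_mm = 14, r_epi_mm = 22, amp_dps = 700)
  ))
  expect_error(generate_phantom(spec), "exceed venc")
})

test_that("magnitude classes sit at their nominal levels", {
  ph <- generate_phantom(two_slice_spec(seed = 3), slices = "base")
  s <- ph$slices$series$base
  m <- s$magnitude[, , 1]
  expect_equal(mean(m[ph$soft_truth]), 100, tolerance = 0.05)
  spec <- ph$spec
  center <- c((spec$rows - 1) / 2, (spec$cols - 1) / 2)
  r <- sqrt((row(m) - 1 - center[1])^2 + (col(m) - 1 - center[2])^2) * spec$pixel_mm
  sc <- tpmtorsion:::.radial_scale(0, spec$radial_contraction, spec$t_sys_ms,
                                   spec$t_dia_ms)
  annulus <- r >= 14 * sc & r <= 22 * sc
  expect_equal(mean(m[annulus]), 200, tolerance = 0.05)
  cavity <- r < 10
  expect_lt(mean(m[cavity]), 15) # black-blood cavity
})

test_that("the phantom ROI contains the full annulus with margin", {
  spec <- two_slice_spec()
  roi <- phantom_roi(spec)
  center <- c((spec$rows - 1) / 2, (spec$cols - 1) / 2)
  rmax_px <- (22 + spec$margin_mm) / spec$pixel_mm
  expect_lte(roi[1], center[1] - rmax_px)
  expect_lte(roi[2], center[2] - rmax_px)
  expect_gte(roi[3], center[1] + rmax_px)
  expect_gte(roi[4], center[2] + rmax_px)
})

test_that("measured torsion closes the loop against the analytic truth", {
  spec <- two_slice_spec(seed = 8)
  curves <- measure_phantom_torsion(spec, pair = c("base", "apex"),
                                    layers = "full", preprocess = "full",
                                    segmentation = "analytic")
  truth <- analytic_torsion(spec, c("base", "apex"), "full", spec$t_sys_ms)
  expect_lt(abs(attr(curves$full, "T_max") - truth) / abs(truth), 0.05)

  # propagated segmentation agrees with the analytic one
  curves_p <- measure_phantom_torsion(spec, pair = c("base", "apex"),
                                      layers = "full", preprocess = "full",
                                      segmentation = "propagate")
  expect_lt(abs(attr(curves_p$full, "T_max") - truth) / abs(truth), 0.05)
})

test_that("layer torsion ordering matches the transmural gradient", {
  spec <- two_slice_spec(seed = 12)
  curves <- measure_phantom_torsion(spec, pair = c("base", "apex"),
                                    layers = c("full", "endo", "epi"),
                                    preprocess = "smooth",
                                    segmentation = "analytic")
  tm <- vapply(curves, function(cv) attr(cv, "T_max"), numeric(1))
  expect_gt(tm[["endo"]], tm[["epi"]]) # endocardial torsion dominates
  s <- transmural_summary(curves$endo, curves$epi)
  expect_equal(s$dT_max, tm[["endo"]] - tm[["epi"]])
  expect_gt(s$dPctT_max, 0)
})
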