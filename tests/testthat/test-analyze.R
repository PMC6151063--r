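test_that("SIA matches worked examples and the law-of-cosines closed form", {
  # full correction: SIA equals the preoperative vector
  expect_equal(compute_sia(2, 90, 0, 180), tibble::tibble(magnitude = 2, axis = 90))
  # no surgical change: zero magnitude
  expect_equal(compute_sia(1.5, 37, 1.5, 37)$magnitude, 0)
  # crossed cylinders one diopter apart: (-1,0) - (1,0) = (-2,0)
  expect_equal(compute_sia(1, 90, 1, 180), tibble::tibble(magnitude = 2, axis = 90))

  # independent closed form: |pre - post| = sqrt(M1^2 + M2^2 - 2 M1 M2 cos 2(dtheta))
  withr::with_seed(41, {
    pre <- random_polar(1e4)
    post <- random_polar(1e4)
  })
  sia <- compute_sia(pre$magnitude, pre$axis, post$magnitude, post$axis)
  oracle <- sqrt(pre$magnitude^2 + post$magnitude^2 -
                   2 * pre$magnitude * post$magnitude *
                   cospi((pre$axis - post$axis) / 90))
  expect_equal(sia$magnitude, oracle, tolerance = 1e-9)
})

test_that("DV is the vectorial TIA - SIA remainder", {
  expect_equal(compute_dv(1.25, 80, 1.25, 80)$magnitude, 0)  # perfect outcome
  expect_equal(compute_dv(1, 90, 1, 180), tibble::tibble(magnitude = 2, axis = 90))
})

test_that("CI is the SIA/TIA magnitude ratio, undefined at zero TIA", {
  expect_equal(compute_ci(2, 2), 1)
  expect_equal(compute_ci(1, 2), 0.5)
  expect_true(is.na(compute_ci(0.5, 0)))
  expect_equal(compute_ci(c(1, 3), c(2, 2)), c(0.5, 1.5))
})

test_that("per-eye pipeline reproduces hand-traced cases", {
  d <- tibble::tibble(
    eye = c("OD", "OS", "OD"),
    preop_mag = c(2, -2, 2), preop_axis = c(90, 90, 90),
    postop_mag = c(0, 0, 1), postop_axis = c(90, 90, 90)
  )
  r <- analyze_eyes(d)
  # OD +2.00 x 90 fully corrected: TIA = SIA, null DV, CI 1
  expect_equal(r$tia_mag[1], 2)
  expect_equal(r$tia_axis[1], 90)
  expect_equal(r$sia_mag[1], 2)
  expect_equal(r$dv_mag[1], 0)
  expect_equal(r$ci[1], 1)
  # OS -2.00 x 90 -> +2.00 x 180; mirror maps 180 to 180
  expect_equal(r$tia_mag[2], 2)
  expect_equal(r$tia_axis[2], 180)
  expect_equal(r$ci[2], 1)
  # collinear half correction
  expect_equal(r$ci[3], 0.5)
})

test_that("analysis invariants hold on random cohorts", {
  withr::with_seed(51, d <- random_dataset(400))
  r <- analyze_eyes(d)
  # TIA magnitude equals the preoperative magnitude (emmetropic target)
  expect_equal(r$tia_mag, abs(d$preop_mag))
  # DV equals the normalized, mirrored postoperative vector
  post <- to_positive_cylinder(d$postop_mag, d$postop_axis)
  post$axis <- mirror_os_axis(post$axis, d$eye)
  expect_equal(r$dv_mag, post$magnitude, tolerance = 1e-9)
  nz <- r$dv_mag > 1e-9
  expect_equal(r$dv_axis[nz], post$axis[nz], tolerance = 1e-6)
  # CI is defined exactly for nonzero-TIA eyes
  expect_equal(is.na(r$ci), r$tia_mag == 0)
})

test_that("swapping eye labels and mirroring axes leaves all magnitudes unchanged", {
  withr::with_seed(61, d <- random_dataset(200))
  m <- d
  m$eye <- ifelse(d$eye == "OD", "OS", "OD")
  m$preop_axis <- ifelse(180 - d$preop_axis == 0, 180, 180 - d$preop_axis)
  m$postop_axis <- ifelse(180 - d$postop_axis == 0, 180, 180 - d$postop_axis)
  r1 <- analyze_eyes(d)
  r2 <- analyze_eyes(m)
  expect_equal(r2$tia_mag, r1$tia_mag, tolerance = 1e-9)
  expect_equal(r2$sia_mag, r1$sia_mag, tolerance = 1e-9)
  expect_equal(r2$dv_mag, r1$dv_mag, tolerance = 1e-9)
  expect_equal(r2$ci, r1$ci, tolerance = 1e-9)
})

test_that("vector population summaries match a brute-force accumulation oracle", {
  # single vector: the vector mean is the vector itself, SDs are zero
  s1 <- summarize_vectors(1.5, 70)
  expect_equal(s1$vector_mean, tibble::tibble(magnitude = 1.5, axis = 70))
  expect_equal(c(s1$sd_x, s1$sd_y), c(0, 0))
  # antipodal pair in double-angle space cancels
  s2 <- summarize_vectors(c(1, 1), c(45, 135))
  expect_equal(s2$vector_mean$magnitude, 0)

  withr::with_seed(71, v <- random_polar(1000))
  s <- summarize_vectors(v$magnitude, v$axis)
  # independent accumulation: scalar loop over eyes
  sx <- 0; sy <- 0
  for (i in seq_len(1000)) {
    sx <- sx + v$magnitude[i] * cospi(v$axis[i] / 90)
    sy <- sy + v$magnitude[i] * sinpi(v$axis[i] / 90)
  }
  expect_equal(s$mean_x, sx / 1000, tolerance = 1e-9)
  expect_equal(s$mean_y, sy / 1000, tolerance = 1e-9)
  expect_equal(s$vector_mean$magnitude, sqrt(s$mean_x^2 + s$mean_y^2), tolerance = 1e-9)
  expect_equal(s$arith_mean_magnitude, mean(v$magnitude))
  expect_gt(s$sd_x, 0)
  expect_error(summarize_vectors(numeric(0), numeric(0)), "empty")
})

test_that("CI summaries use the geometric mean over defined positive values", {
  expect_equal(summarize_ci(c(1, 1, 1))$geometric_mean, 1)
  expect_equal(summarize_ci(c(0.5, 2))$geometric_mean, 1)
  expect_equal(summarize_ci(rep(0.9, 40))$geometric_mean, 0.9)
  s <- summarize_ci(c(0.8, 1.2, NA, 0))
  expect_equal(s$n_defined, 2)
  expect_equal(s$n_excluded, 2)
  expect_error(summarize_ci(c(NA_real_, 0)), "no positive")
})
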