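test_that("proportional TACs give an exact Logan line", {
  fx <- tt_cp_fixture()
  ct <- tac(fx$cp$time_min, 4 * fx$cp$activity, fx$cp$duration_min)
  fit <- logan_fit(ct, fx$cp)
  expect_equal(fit$slope, 4, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
})

test_that("Logan slope recovers compartmental DV from noise-free TACs", {
  fx <- tt_cp_fixture()
  # 1TC with DV = 4: the Logan relation is exact, only discretization remains
  ct1 <- tt_ct_frames(kinetic_params(0.2, 0.05), fx)
  expect_equal(logan_fit(ct1, fx$cp)$slope, 4, tolerance = 0.01)
  # slow 2TC with DV = 2: late-time convergence within 5% at t* = 50
  ct2 <- tt_ct_frames(kinetic_params(0.2, 0.2, 0.05, 0.05), fx)
  expect_equal(logan_fit(ct2, fx$cp)$slope, 2, tolerance = 0.05)
  # moving t* between 40 and 50 min (3 vs 2 late frames on this schedule)
  # moves the noise-free slope by < 2%
  s50 <- logan_fit(ct1, fx$cp, t_star = 50)$slope
  s40 <- logan_fit(ct1, fx$cp, t_star = 40)$slope
  expect_equal(s40 / s50, 1, tolerance = 0.02)
})

test_that("Logan slope obeys its scaling invariances", {
  fx <- tt_cp_fixture()
  ct <- tt_ct_frames(kinetic_params(0.3, 0.2, 0.1, 0.25), fx)
  base <- logan_fit(ct, fx$cp)$slope
  # common rescaling of both curves leaves the slope unchanged
  ct_s <- tac(ct$time_min, 3 * ct$activity, ct$duration_min)
  cp_s <- tac(fx$cp$time_min, 3 * fx$cp$activity, fx$cp$duration_min)
  expect_equal(logan_fit(ct_s, cp_s)$slope, base, tolerance = 1e-10)
  # rescaling the tissue curve alone scales the slope linearly
  expect_equal(logan_fit(ct_s, fx$cp)$slope, 3 * base, tolerance = 1e-10)
})

test_that("degenerate Logan inputs are rejected or masked", {
  fx <- tt_cp_fixture()
  ct <- tt_ct_frames(kinetic_params(0.3, 0.2), fx)
  expect_error(logan_fit(ct, fx$cp, t_star = 69), "fewer than 2")
  bad <- tac(fx$cp$time_min, rep(0, nrow(fx$cp)), fx$cp$duration_min)
  expect_error(logan_fit(bad, fx$cp), "usable|degenerate")
})

test_that("reference-tissue Logan estimates DVR", {
  fx <- tt_cp_fixture()
  cref <- tt_ct_frames(kinetic_params(0.3, 0.2), fx)
  # identical and proportional tissue curves
  expect_equal(coef(logan_fit(cref, cref)),
               c(slope = 1, intercept = 0), tolerance = 1e-8)
  ct2x <- tac(cref$time_min, 2 * cref$activity, cref$duration_min)
  expect_equal(logan_fit(ct2x, cref)$slope, 2, tolerance = 1e-10)
  # 2TC target with true DVR 2 against the 1TC reference
  ct <- tt_ct_frames(kinetic_params(0.3, 0.2, 0.25, 0.25), fx)
  dvr_r <- logan_fit(ct, cref)$slope
  expect_equal(dvr_r, 2, tolerance = 0.05)
  # plasma-input route for the same pair
  dvr_l <- logan_fit(ct, fx$cp)$slope / logan_fit(cref, fx$cp)$slope
  expect_equal(dvr_l, 2, tolerance = 0.05)
  # with a fast-equilibrating reference the two routes agree closely
  expect_lt(abs(dvr_r - dvr_l), 0.02)
  # supplying k2' keeps the reference estimate within the same tolerance
  dvr_k2 <- logan_fit(ct, cref, k2_ref = 0.2)$slope
  expect_equal(dvr_k2, 2, tolerance = 0.05)
})

test_that("voxel-wise Logan images recover truth and mask bad voxels", {
  dvr <- tt_three_level_dvr()
  ph <- build_phantom(phantom_spec(dvr = dvr, dim = c(16, 16, 12),
                                   noise_scale = 0))
  dv <- logan_image(ph$dyn, ph$input_truth$cp)
  ids <- pib_region_ids()
  for (r in c("cerebellum", "pcc", "frontal_l")) {
    truth <- ph$truth$DV[ph$truth$region == r]
    vox <- dv$values[ph$labels == ids[[r]]]
    expect_equal(median(vox), truth, tolerance = 0.02)
  }
  # background (all-zero) voxels are masked invalid with value 0
  expect_true(all(!dv$valid[ph$labels == 0]))
  expect_true(all(dv$values[ph$labels == 0] == 0))
  expect_error(logan_image(ph$dyn, tac(1:3, 1:3, rep(1, 3))), "grid")
})

test_that("reference normalization divides by the reference mean", {
  vals <- array(4, c(4, 4, 4))
  lab <- array(1L, c(4, 4, 4)); lab[1:2, , ] <- 2L
  vals[lab == 2L] <- 2
  m <- pibquant:::metric_image(vals, array(TRUE, dim(vals)), "DV")
  dvr <- normalize_to_reference(m, lab, 2L)
  expect_equal(dvr$reference_value, 2)
  expect_true(all(dvr$values[lab == 1L] == 2))   # 4 / 2
  expect_equal(mean(dvr$values[lab == 2L]), 1)   # self-normalization
  neg <- pibquant:::metric_image(-vals, array(TRUE, dim(vals)), "DV")
  expect_error(normalize_to_reference(neg, lab, 2L), "nonpositive")
})
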