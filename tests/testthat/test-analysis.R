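test_that("lateral_profile averages depth windows as specified", {
  g <- make_grid(matrix(2, 40, 10))
  p <- lateral_profile(g, 5)
  expect_true(all(p$dose == 2))
  g2 <- make_grid(cbind(matrix(1, 40, 1), matrix(3, 40, 1)), dz_mm = 1)
  p2 <- lateral_profile(g2, 1, averaging_window_mm = 2)
  expect_true(all(p2$dose == 2))          # mean of the two rows
  comb <- matrix(rep(c(0, 5), 20), 40, 6)
  expect_equal(lateral_profile(make_grid(comb), 3)$dose, comb[, 3])
  expect_error(lateral_profile(g, 99), "outside")
})

test_that("pvr matches closed forms on constructed profiles", {
  # printed surface doses: peaks 5.4 Gy, valleys 0.42 Gy
  expect_equal(5.4 / 0.42, 12.857, tolerance = 1e-3)
  # cosine profile sampled at beam centers and midpoints: 1.1 / 0.9
  p_mm <- 1
  dx <- 0.01
  nx <- 2000
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  dose <- matrix(rep(1 + 0.1 * cos(2 * pi * x / p_mm), 3), nx, 3)
  g <- make_grid(dose, dx_mm = dx)
  cfg <- beamline_config(source_model(1e-6),
                         multislit_collimator(0.06, p_mm, 9), scd_mm = 1e9)
  cv <- pvr_curve(g, cfg)
  expect_equal(cv$pvr, rep(1.1 / 0.9, 3), tolerance = 1e-3)
  expect_equal(cv$percent_diff, rep((1.1 - 0.9) / 1.1 * 100, 3),
               tolerance = 0.1)
  # uniform profile: pvr 1, percent difference 0
  gu <- make_grid(matrix(4, nx, 2), dx_mm = dx)
  cu <- pvr_curve(gu, cfg)
  expect_equal(cu$pvr, c(1, 1))
  expect_equal(cu$percent_diff, c(0, 0))
})

test_that("merge depth interpolates the threshold crossing", {
  cv <- structure(data.frame(depth_mm = c(10, 20), pvr = c(2, 1),
                             defined = TRUE),
                  class = c("PVRCurve", "data.frame"))
  # linear in valley/peak: 0.5 -> 1.0 crossing 1/1.2 at z = 16.67
  expect_equal(merge_depth(cv), 10 + (1 / 1.2 - 0.5) / 0.5 * 10,
               tolerance = 1e-9)
  cv2 <- structure(data.frame(depth_mm = 1:5, pvr = rep(1, 5), defined = TRUE),
                   class = c("PVRCurve", "data.frame"))
  expect_equal(merge_depth(cv2), 1)       # first sample already merged
  cv3 <- structure(data.frame(depth_mm = 1:50, pvr = seq(5, 1.3, length.out = 50),
                              defined = TRUE),
                   class = c("PVRCurve", "data.frame"))
  expect_true(is.na(merge_depth(cv3)))
  # monotone decreasing curve: crossing unique and consistent
  cv4 <- structure(data.frame(depth_mm = seq(0, 90, by = 10),
                              pvr = 10 * exp(-seq(0, 90, by = 10) / 25),
                              defined = TRUE),
                   class = c("PVRCurve", "data.frame"))
  md <- merge_depth(cv4)
  expect_equal(sum(cv4$pvr > 1.2 & cv4$depth_mm > md), 0)
})

test_that("sparing range reproduces the printed cross-section sequence", {
  # printed peak/valley doses at 0/2.5/5 cm: 5.4/0.42, 1.7/0.72, 0.5/0.5
  pvrs <- c(5.4 / 0.42, 1.7 / 0.72, 0.5 / 0.5)
  cv <- structure(data.frame(depth_mm = c(0, 25, 50), pvr = pvrs,
                             defined = TRUE),
                  class = c("PVRCurve", "data.frame"))
  sr <- sparing_depth_range(cv)
  expect_equal(sr[1], 0)
  expect_gt(sr[2], 0)
  expect_lt(sr[2], 25)                    # sparing ends before 2.5 cm
  cv_all <- structure(data.frame(depth_mm = 1:5, pvr = rep(8, 5),
                                 defined = TRUE),
                      class = c("PVRCurve", "data.frame"))
  expect_equal(sparing_depth_range(cv_all), c(1, 5))
  cv_none <- structure(data.frame(depth_mm = 1:5, pvr = rep(2, 5),
                                  defined = TRUE),
                       class = c("PVRCurve", "data.frame"))
  expect_true(all(is.na(sparing_depth_range(cv_none))))
})

test_that("biologic dose map equals the brute-force disk minimum", {
  set.seed(42)
  for (case in 1:3) {
    nx <- sample(30:60, 1)
    nz <- sample(10:20, 1)
    dose <- matrix(stats::runif(nx * nz), nx, nz)
    g <- make_grid(dose, dx_mm = 0.1, dz_mm = 0.2)
    r_um <- sample(c(250, 350, 500), 1)
    bio <- biologic_dose_map(g, r_um)
    oracle <- brute_disk_min(dose, 0.1, 0.2, r_um / 1000)
    expect_equal(bio$dose, oracle)
    expect_true(all(bio$dose <= dose))
  }
})

test_that("biologic dose of simple fields behaves as the model dictates", {
  g <- make_grid(matrix(2, 50, 5))
  expect_true(all(biologic_dose_map(g)$dose == 2))
  # a single 0.3-mm stripe on zero background vanishes entirely
  nx <- 200
  dose <- matrix(0, nx, 3)
  x <- (seq_len(nx) - (nx + 1) / 2) * 0.05
  dose[abs(x) <= 0.15, ] <- 5
  gs <- make_grid(dose, dx_mm = 0.05)
  expect_true(all(biologic_dose_map(gs, 350)$dose == 0))
  expect_error(biologic_dose_map(make_grid(matrix(1, 4, 4), dx_mm = 1), 350),
               "radius")
})

test_that("valley is empty before the geometric onset without scatter", {
  sp <- structure(list(energy_keV = 100, weights = 1, kvp = 320),
                  class = "Spectrum")
  cfg <- fx_fig6_config()
  ph <- phantom(lateral_mm = 40, depth_mm = 80, dx_mm = 0.05, dz_mm = 2)
  a <- analytic_primary_dose(cfg, sp, ph, n_src = 15, n_per_ap = 9,
                             n_groups = 1)
  cv <- pvr_curve(a, cfg)
  onset <- geometric_merge_onset(cfg)
  early <- cv$depth_mm < 0.6 * onset
  expect_true(all(cv$valley[early] < 0.02 * cv$peak[early]))
  # PVR decreases beyond the onset
  late <- cv$depth_mm > onset
  expect_true(all(diff(cv$pvr[late]) < 0.1))
})

test_that("penumbra metric matches its closed-form cases", {
  # ideal step edge
  x <- seq(-10, 10, by = 0.01)
  step <- data.frame(position_mm = x, dose = as.numeric(abs(x) <= 5))
  expect_lt(penumbra_80_20(step), 0.011)
  # linear ramp over 1 mm: (0.8 - 0.2) * 1
  ramp <- data.frame(position_mm = x,
                     dose = pmin(1, pmax(0, (5 - abs(x)) + 0.5)))
  expect_equal(penumbra_80_20(ramp), 0.6, tolerance = 0.02)
  # Gaussian-blurred edge, sigma 0.2 mm: 0.2 * (z0.8 - z0.2) = 0.337 mm
  blur <- data.frame(position_mm = x,
                     dose = stats::pnorm((5 - abs(x)) / 0.2))
  expect_equal(penumbra_80_20(blur),
               0.2 * (stats::qnorm(0.8) - stats::qnorm(0.2)),
               tolerance = 0.01)
})

test_that("fixture falloff profiles encode the measured 80-20 values", {
  expect_equal(penumbra_80_20(fixture_lateral_profile("220kVp")), 0.40,
               tolerance = 0.01)
  expect_equal(penumbra_80_20(fixture_lateral_profile("6MV")), 2.2,
               tolerance = 0.01)
})

test_that("depth-dose HVL fit matches closed forms and recovers noisy truth", {
  z <- 0:5
  expect_equal(as.numeric(hvl_from_depth_doses(z, 8 * 0.5^z)), 1.0)
  expect_equal(as.numeric(hvl_from_depth_doses(c(0, 3.2), c(4, 2))), 3.2)
  # log-linear least squares on the printed cross-section peak doses
  hv <- hvl_from_depth_doses(c(0, 2.5, 5), c(5.4, 1.7, 0.5))
  expect_equal(as.numeric(hv), 1.4565, tolerance = 1e-3)
  expect_length(attr(hv, "per_interval_cm"), 2)
  expect_error(hvl_from_depth_doses(c(0, 1), c(1, -1)), "positive")
  # 100-replicate recovery with 1% multiplicative noise
  set.seed(7)
  true_hvl <- 1.55
  mu <- log(2) / true_hvl
  zz <- seq(0, 6, by = 0.5)
  ests <- replicate(100, {
    d <- exp(-mu * zz) * (1 + stats::rnorm(length(zz), 0, 0.01))
    as.numeric(hvl_from_depth_doses(zz, d))
  })
  expect_lt(abs(mean(ests) - true_hvl) / true_hvl, 0.005)
})

test_that("dilution factor is pitch over width", {
  expect_equal(dilution_factor(0.3, 1.0), 10 / 3)
  expect_equal(dilution_factor(0.68, 1.36), 2.0)
  expect_equal(dilution_factor(1.0, 1.0), 1.0)
  expect_error(dilution_factor(2, 1), "width")
})

test_that("normalization at a depth rescales and is idempotent", {
  z <- seq(0, 100, by = 1)
  c1 <- structure(data.frame(depth_mm = z, dose = 10 * exp(-0.03 * z),
                             label = "a"),
                  class = c("DepthDoseCurve", "data.frame"))
  c2 <- structure(data.frame(depth_mm = z, dose = 3 * exp(-0.01 * z),
                             label = "b"),
                  class = c("DepthDoseCurve", "data.frame"))
  out <- normalize_at(list(c1, c2), 50)
  expect_equal(stats::approx(out[[1]]$depth_mm, out[[1]]$dose, 50)$y, 1)
  expect_equal(stats::approx(out[[2]]$depth_mm, out[[2]]$dose, 50)$y, 1)
  ratio <- out[[1]]$dose / out[[2]]$dose
  expect_equal(ratio, exp(-(0.03 - 0.01) * (z - 50)), tolerance = 1e-9)
  again <- normalize_at(out[[1]], 50)
  expect_equal(again$dose, out[[1]]$dose)
  expect_error(normalize_at(c1, 1e4), "undefined|outside")
})
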