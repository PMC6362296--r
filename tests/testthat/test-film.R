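test_that("zero dose with zero noise gives a uniform background image", {
  img <- dose_to_film(matrix(0, 20, 30), noise_sd = 0, seed = 1)
  expect_true(all(img$pixels == img$response$pixel_max))
})

test_that("large doses saturate at the OD_max pixel floor", {
  resp <- scanner_response(od_max = 2, d0_gy = 5)
  img <- dose_to_film(matrix(1000, 5, 5), resp, noise_sd = 0, seed = 1)
  floor_px <- round(resp$pixel_max * 10^(-resp$od_max))
  expect_true(all(img$pixels == floor_px))
  d <- film_to_dose(img)
  expect_true(all(attr(d, "saturated")))
  expect_true(all(is.na(d)))
})

test_that("noiseless round trip is exact to quantization", {
  resp <- scanner_response()
  dose <- matrix(seq(0.05, 6, length.out = 600), 30, 20)
  img <- dose_to_film(dose, resp, noise_sd = 0, seed = 1)
  back <- film_to_dose(img)
  od <- resp$od_max * (1 - exp(-dose / resp$d0_gy))
  px <- resp$pixel_max * 10^(-od)
  quant_gy <- resp$d0_gy / (resp$od_max - od) / (px * log(10)) * 1.01
  expect_true(all(abs(back - dose) <= quant_gy + 1e-9))
})

test_that("noisy round trip stays within quantization plus 3 x noise", {
  resp <- scanner_response()
  noise_sd <- 0.01
  d_sat <- saturation_dose(resp)
  dose <- matrix(seq(0.1, 0.8 * d_sat, length.out = 4000), 100, 40)
  img <- dose_to_film(dose, resp, noise_sd = noise_sd, seed = 42)
  back <- film_to_dose(img)
  od <- resp$od_max * (1 - exp(-dose / resp$d0_gy))
  px <- pmax(resp$pixel_max * 10^(-od), 1)
  # propagate OD-space tolerance (3 sigma noise + one pixel step) to dose
  dd_dod <- resp$d0_gy / (resp$od_max - od)
  tol <- dd_dod * (3 * noise_sd * od + 1 / (px * log(10))) + 1e-9
  ok <- abs(back - dose) <= tol
  expect_gt(mean(ok, na.rm = TRUE), 0.99)
})

test_that("linear-regime response is proportional to optical density", {
  resp <- scanner_response(od_max = 2, d0_gy = 50)   # D << D0 regime
  dose <- matrix(seq(0.01, 1, length.out = 400), 20, 20)
  img <- dose_to_film(dose, resp, noise_sd = 0, seed = 1)
  od <- -log10(img$pixels / resp$pixel_max)
  fit <- stats::lm(as.vector(dose) ~ as.vector(od))
  expect_gt(summary(fit)$r.squared, 0.9999)
  expect_lt(abs(stats::coef(fit)[[1]]), 0.01)       # near-zero intercept
})

test_that("film TIFF write/read round trip preserves pixels", {
  skip_if_not_installed("tiff")
  img <- dose_to_film(matrix(stats::runif(600, 0, 4), 20, 30), seed = 5)
  f <- tempfile(fileext = ".tiff")
  write_film_tiff(img, f)
  back <- read_film_tiff(f, response = img$response)
  expect_equal(back$pixels, img$pixels)
  cal <- utils::read.csv(sub("\\.tiff$", "_calibration.csv", f))
  expect_true(all(c("pixel_value", "dose_Gy") %in% names(cal)))
  expect_true(all(diff(cal$dose_Gy) * diff(cal$pixel_value) < 0))
  unlink(f)
})

test_that("cross-section film stacks attenuate and de-merge with depth", {
  sp <- fx_spectrum_320()
  col <- multislit_collimator(0.34, 1.12, 15)
  cfg <- beamline_config(source_model(6, "disk"), col, scd_mm = 295)
  ph <- phantom(lateral_mm = 40, depth_mm = 60, dx_mm = 0.05, dz_mm = 1)
  fx <- generate_film_fixture("cross_section_stack", cfg, sp, ph,
                              transport_settings(n_histories = 4e5, seed = 31),
                              depths_mm = c(0, 25, 50),
                              entrance_peak_gy = 5.4, seed = 8)
  mean_doses <- vapply(fx$truth, mean, 0)
  expect_true(all(diff(mean_doses) < 0))            # attenuation with depth
  pvrs <- vapply(fx$images, function(img) {
    d <- film_to_dose(img)
    prof <- data.frame(position_mm = seq_len(ncol(d)) * img$pixel_pitch_um / 1000,
                       dose = colMeans(d, na.rm = TRUE))
    profile_extrema_pvr(prof, min_sep_mm = 0.8)$pvr
  }, 0)
  expect_true(all(diff(pvrs) < 0))                  # gradual merging
  expect_gt(pvrs[1], 3)                             # separated at entrance
})

test_that("edge-on film recovers the merge depth of its ground truth", {
  sp <- fx_spectrum_320()
  cfg <- beamline_config(source_model(6.8, "disk"),
                         multislit_collimator(0.3, 1.0, 15), scd_mm = 295)
  ph <- phantom(lateral_mm = 40, depth_mm = 90, dx_mm = 0.05, dz_mm = 1)
  fx <- generate_film_fixture("edge_on", cfg, sp, ph,
                              transport_settings(n_histories = 8e5, seed = 13),
                              entrance_peak_gy = 4, noise_sd = 0.003, seed = 2)
  md_truth <- merge_depth(pvr_curve(fx$grid, cfg))
  g_film <- fx$grid
  g_film$dose <- film_to_dose(fx$images[[1]])
  g_film$dose[is.na(g_film$dose)] <- 0
  md_film <- merge_depth(pvr_curve(g_film, cfg))
  expect_lt(abs(md_film - md_truth) / md_truth, 0.10)
})

test_that("film fixtures are deterministic per seed", {
  dose <- matrix(stats::runif(200, 0, 3), 10, 20)
  i1 <- dose_to_film(dose, seed = 77)
  i2 <- dose_to_film(dose, seed = 77)
  i3 <- dose_to_film(dose, seed = 78)
  expect_identical(i1$pixels, i2$pixels)
  expect_false(identical(i1$pixels, i3$pixels))
})
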