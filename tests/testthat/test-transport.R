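mono_spectrum <- function(E) {
  structure(list(energy_keV = E, weights = 1, kvp = 320), class = "Spectrum")
}

pencil_config <- function() {
  # near-parallel, near-point source: plain exponential geometry
  beamline_config(source_model(1e-3), NULL, scd_mm = 1e6, field_mm = 0.2)
}

test_that("air phantom deposits nearly nothing compared to water", {
  sp <- mono_spectrum(100)
  cfg <- pencil_config()
  st <- transport_settings(n_histories = 2e4, seed = 3,
                           electron_spread = FALSE)
  g_air <- run_transport(cfg, sp, phantom(20, 100, dx_mm = 1, dz_mm = 5,
                                          material = "air"), st)
  g_wat <- run_transport(cfg, sp, phantom(20, 100, dx_mm = 1, dz_mm = 5,
                                          material = "water"), st)
  expect_lt(g_air$meta$edep_keV_per_hist, 0.01 * g_wat$meta$edep_keV_per_hist)
})

test_that("primary-only depth profile follows exp(-mu z) within 3 sigma", {
  sp <- mono_spectrum(100)
  ph <- phantom(lateral_mm = 20, depth_mm = 100, dx_mm = 0.5, dz_mm = 2)
  g <- run_transport(pencil_config(), sp, ph,
                     transport_settings(n_histories = 3e5, seed = 11,
                                        electron_spread = FALSE,
                                        primary_only = TRUE))
  dd <- colSums(g$dose)
  mu <- attenuation_coefficients("water", 100)$total / 10    # 1/mm
  z <- g$z_mm
  expected <- dd[1] * exp(-mu * (z - z[1]))
  # per-bin Poisson error from the collision counts
  n0 <- 3e5 * (1 - exp(-mu * g$dz_mm))                       # first-bin count
  n_exp <- n0 * exp(-mu * (z - z[1]))
  sigma <- expected / sqrt(n_exp)
  expect_true(all(abs(dd - expected) < 3.5 * sigma))
  fit <- stats::lm(log(dd) ~ z)
  expect_equal(-coef(fit)[[2]], mu, tolerance = 0.02)
})

test_that("identical seeds reproduce the grid bit-for-bit; seeds differ", {
  sp <- fx_spectrum_320()
  cfg <- fx_fig6_config()
  ph <- phantom(lateral_mm = 40, depth_mm = 50, dx_mm = 0.2, dz_mm = 2)
  st <- transport_settings(n_histories = 5e4, seed = 9)
  g1 <- run_transport(cfg, sp, ph, st)
  g2 <- run_transport(cfg, sp, ph, st)
  expect_identical(g1$dose, g2$dose)
  g3 <- run_transport(cfg, sp, ph,
                      transport_settings(n_histories = 5e4, seed = 10))
  expect_false(identical(g1$dose, g3$dose))
})

test_that("energy is conserved: deposited <= entering, equality when absorbing", {
  sp <- fx_spectrum_320()
  mean_E <- spectrum_mean_energy(sp)
  g <- fx_fig6_grid(n_hist = 1e6)
  expect_lt(g$meta$edep_keV_per_hist, mean_E)
  expect_gt(g$meta$edep_keV_per_hist, 0.2 * mean_E)
  expect_true(all(g$dose >= 0))
  expect_true(all(is.finite(g$dose)))
  # low-energy photons in a deep phantom: (almost) fully absorbed
  sp30 <- mono_spectrum(30)
  ph <- phantom(lateral_mm = 60, depth_mm = 150, dx_mm = 1, dz_mm = 5)
  g2 <- run_transport(pencil_config(), sp30, ph,
                      transport_settings(n_histories = 3e4, seed = 5,
                                         electron_spread = FALSE,
                                         primary_only = TRUE))
  expect_gt(g2$meta$edep_keV_per_hist, 0.95 * 30)
  expect_lte(g2$meta$edep_keV_per_hist, 30 + 1e-9)
})

test_that("primary-only Monte Carlo matches the analytic oracle within 3 sigma", {
  sp <- mono_spectrum(80)
  cfg <- beamline_config(source_model(6.8, "disk"),
                         multislit_collimator(0.3, 1.0, 11), scd_mm = 295)
  ph <- phantom(lateral_mm = 20, depth_mm = 60, dx_mm = 0.5, dz_mm = 5)
  n <- 4e5
  g <- run_transport(cfg, sp, ph,
                     transport_settings(n_histories = n, seed = 21,
                                        electron_spread = FALSE,
                                        primary_only = TRUE))
  a <- analytic_primary_dose(cfg, sp, ph, n_src = 21, n_per_ap = 15,
                             n_groups = 1)
  # convert doses back to expected collision counts for Poisson errors
  mass_g <- 0.05 * 0.5 * 1 * 1            # dx * dz cm3 * 1 cm * rho
  to_counts <- function(d) d * (mass_g * 1e-3) / 1.602176634e-16 / 80 * n
  cn_mc <- to_counts(g$dose)
  cn_an <- to_counts(a$dose)
  sel <- cn_an > 25
  zsc <- (cn_mc[sel] - cn_an[sel]) / sqrt(cn_an[sel])
  expect_lt(mean(abs(zsc) > 3), 0.01)
  expect_lt(abs(mean(zsc)), 0.5)
})

test_that("bone slab attenuates the primary under it by the expected factor", {
  sp <- mono_spectrum(80)
  cfg <- beamline_config(source_model(2, "disk"), NULL, scd_mm = 1e5,
                         field_mm = 30)
  ph <- phantom(lateral_mm = 40, depth_mm = 40, dx_mm = 0.5, dz_mm = 1,
                inserts = list(list(material = "bone", x_mm = c(0, Inf),
                                    z_mm = c(0, 5))))
  a <- analytic_primary_dose(cfg, sp, ph, n_src = 5, n_per_ap = 40,
                             n_groups = 1)
  prof <- lateral_profile(a, 20, averaging_window_mm = 10)
  open_half <- mean(prof$dose[prof$position_mm < -2])
  bone_half <- mean(prof$dose[prof$position_mm > 2])
  mu_b <- attenuation_coefficients("bone", 80)$total
  mu_w <- attenuation_coefficients("water", 80)$total
  expect_equal(bone_half / open_half, exp(-(mu_b - mu_w) * 0.5),
               tolerance = 0.02)
})

test_that("electron kernel width follows the range table and stays sub-beam", {
  expect_equal(csda_range_water(100), 0.143, tolerance = 0.01)
  sig100 <- 0.3 * csda_range_water(100)
  expect_equal(sig100, 0.043, tolerance = 0.01)
  s_lo <- electron_kernel_sigma(build_spectrum(150))
  s_hi <- electron_kernel_sigma(build_spectrum(320))
  expect_gt(s_hi, s_lo)
  expect_lt(s_hi, 0.3)      # well under the 0.3-mm beam width
})

test_that("valley dose rises to a unique interior maximum near the merge depth", {
  g <- fx_fig6_grid(n_hist = 1e6)
  cfg <- fx_fig6_config()
  vc <- valley_depth_curve(g, cfg)
  sm <- stats::filter(vc$dose, rep(1 / 7, 7))
  imax <- which.max(sm)
  expect_gt(vc$depth_mm[imax], geometric_merge_onset(cfg))
  expect_lt(vc$depth_mm[imax], 80)
  onset_i <- which(vc$depth_mm >= geometric_merge_onset(cfg))[1]
  expect_gt(vc$dose[onset_i], 0)   # valley already filled at the onset
  # monotone rise (smoothed) from the surface up to the maximum
  rise <- sm[seq(4, imax)]
  expect_true(all(diff(rise) > -0.05 * max(sm, na.rm = TRUE), na.rm = TRUE))
})
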