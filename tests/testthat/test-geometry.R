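test_that("collimator exit plane reproduces the aperture and pitch", {
  cfg <- beamline_config(source_model(6.8), multislit_collimator(0.3, 0.7, 23),
                         scd_mm = 295)
  g <- projected_geometry(cfg, 0)
  expect_equal(g$full_width_mm, 0.3)
  expect_equal(g$pitch_mm, 0.7)
})

test_that("a point source produces no penumbra", {
  cfg <- beamline_config(source_model(1e-9), multislit_collimator(0.3, 1, 9),
                         scd_mm = 300)
  g <- projected_geometry(cfg, c(0, 20, 80))
  expect_equal(g$umbra_width_mm, g$full_width_mm)
  expect_equal(g$full_width_mm, 0.3 * (300 + g$z_mm) / 300)
})

test_that("projected widths match an independent edge-ray trace", {
  a <- 0.3; p <- 1.0; s <- 6.0; L <- 315; z <- 50
  cfg <- beamline_config(source_model(s), multislit_collimator(a, p, 9),
                         scd_mm = L)
  xs <- seq(-s / 2, s / 2, length.out = 2001)
  proj <- function(xa) xa + (xa - xs) / L * z      # all source points -> depth
  lit_left <- min(proj(-a / 2)); lit_right <- max(proj(a / 2))
  umb_left <- max(proj(-a / 2)); umb_right <- min(proj(a / 2))
  g <- projected_geometry(cfg, z)
  expect_equal(g$full_width_mm, lit_right - lit_left, tolerance = 1e-9)
  expect_equal(g$umbra_width_mm, max(0, umb_right - umb_left),
               tolerance = 1e-9)
  expect_equal(g$pitch_mm, p * (L + z) / L, tolerance = 1e-12)
})

test_that("widths and pitch are non-decreasing in depth with penumbra bookkeeping", {
  cfg <- beamline_config(source_model(6.8), multislit_collimator(0.3, 1, 23),
                         scd_mm = 295)
  z <- seq(0, 100, by = 1)
  g <- projected_geometry(cfg, z)
  expect_true(all(diff(g$full_width_mm) >= 0))
  expect_true(all(diff(g$pitch_mm) >= 0))
  has_umbra <- g$umbra_width_mm > 0
  expect_equal((g$full_width_mm - g$umbra_width_mm)[has_umbra],
               (2 * 6.8 * z / 295)[has_umbra])
})

test_that("geometric merge onset matches its closed form and a width scan", {
  cfg <- beamline_config(source_model(6.8), multislit_collimator(0.3, 0.7, 23),
                         scd_mm = 295)
  onset <- geometric_merge_onset(cfg)
  expect_equal(onset, 0.4 * 295 / 6.4, tolerance = 1e-12)
  z <- seq(0, 60, by = 0.001)
  g <- projected_geometry(cfg, z)
  scan <- z[which(g$full_width_mm >= g$pitch_mm)[1]]
  expect_equal(onset, scan, tolerance = 1e-2)
})

test_that("merge onset boundary and scaling behave", {
  cfg <- beamline_config(source_model(0.7), multislit_collimator(0.3, 1.0, 9),
                         scd_mm = 300)
  expect_identical(geometric_merge_onset(cfg), Inf)   # s = p - a exactly
  cfg1 <- beamline_config(source_model(6.8), multislit_collimator(0.3, 1, 9),
                          scd_mm = 295)
  cfg2 <- beamline_config(source_model(6.8), multislit_collimator(0.3, 1, 9),
                          scd_mm = 590)
  expect_equal(geometric_merge_onset(cfg2), 2 * geometric_merge_onset(cfg1))
})

test_that("scd solver inverts the onset formula and agrees with bisection", {
  cfg <- beamline_config(source_model(6.8), multislit_collimator(0.3, 1.0, 23),
                         scd_mm = 295)
  for (target in c(10, 30, 55)) {
    L <- solve_scd_for_merge_depth(cfg, target)
    cfg2 <- beamline_config(cfg$source, cfg$collimator, scd_mm = L)
    expect_equal(geometric_merge_onset(cfg2), target, tolerance = 1e-6)
  }
  expect_gt(solve_scd_for_merge_depth(cfg, 50),
            solve_scd_for_merge_depth(cfg, 30))
  # bisection oracle
  target <- 30
  onset_at <- function(L) geometric_merge_onset(
    beamline_config(cfg$source, cfg$collimator, scd_mm = L))
  lo <- 1; hi <- 5000
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (onset_at(mid) < target) lo <- mid else hi <- mid
  }
  expect_equal(solve_scd_for_merge_depth(cfg, target), (lo + hi) / 2,
               tolerance = 1e-4)
})

test_that("pitch solver hits its degenerate case, ordering, and round trip", {
  cfg <- beamline_config(source_model(6.8), multislit_collimator(0.3, 1.0, 23),
                         scd_mm = 295)
  expect_equal(solve_pitch_for_merge_depth(cfg, 0), 0.3)
  targets <- c(20, 40, 60)
  pitches <- vapply(targets, function(t) solve_pitch_for_merge_depth(cfg, t), 0)
  expect_true(all(diff(pitches) > 0))
  for (i in seq_along(targets)) {
    col2 <- multislit_collimator(0.3, pitches[i], 23)
    cfg2 <- beamline_config(cfg$source, col2, scd_mm = 295)
    expect_equal(geometric_merge_onset(cfg2), targets[i], tolerance = 1e-6)
  }
})
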