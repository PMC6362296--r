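# Shared fixtures: spectra and simulation runs are cached per test session
# so several test files can reuse the same (seeded) grids.

.fx <- new.env()

fx_spectrum_320 <- function() {
  if (is.null(.fx$sp320)) .fx$sp320 <- spectrum_from_quality(320, 3.8)
  .fx$sp320
}

fx_fig6_config <- function() {
  beamline_config(source_model(6.8, "disk"),
                  multislit_collimator(0.3, 1.0, 23), scd_mm = 295)
}

fx_fig6_grid <- function(n_hist = 1e6) {
  key <- paste0("fig6_", n_hist)
  if (is.null(.fx[[key]])) {
    ph <- phantom(lateral_mm = 60, depth_mm = 100, dx_mm = 0.05, dz_mm = 1)
    .fx[[key]] <- run_transport(fx_fig6_config(), fx_spectrum_320(), ph,
                                transport_settings(n_histories = n_hist,
                                                   seed = 101))
  }
  .fx[[key]]
}

# hand-built dose grid wrapper for analysis-function tests
make_grid <- function(dose, dx_mm = 0.05, dz_mm = 1, gap_mm = 0) {
  nx <- nrow(dose); nz <- ncol(dose)
  structure(list(
    dose = dose,
    x_mm = (seq_len(nx) - (nx + 1) / 2) * dx_mm,
    z_mm = (seq_len(nz) - 0.5) * dz_mm + gap_mm,
    dx_mm = dx_mm, dz_mm = dz_mm, gap_mm = gap_mm,
    config = NULL, meta = list()), class = "DoseGrid")
}

# brute-force disk-minimum filter (oracle for biologic_dose_map)
brute_disk_min <- function(dose, dx_mm, dz_mm, r_mm) {
  nx <- nrow(dose); nz <- ncol(dose)
  out <- dose
  for (i in seq_len(nx)) {
    for (j in seq_len(nz)) {
      di <- floor(r_mm / dx_mm)
      lo_i <- max(1, i - di); hi_i <- min(nx, i + di)
      dj <- floor(r_mm / dz_mm)
      lo_j <- max(1, j - dj); hi_j <- min(nz, j + dj)
      best <- Inf
      for (ii in lo_i:hi_i) {
        for (jj in lo_j:hi_j) {
          d2 <- ((ii - i) * dx_mm)^2 + ((jj - j) * dz_mm)^2
          if (d2 <= r_mm^2 && dose[ii, jj] < best) best <- dose[ii, jj]
        }
      }
      out[i, j] <- best
    }
  }
  out
}

# Full-scale scenario runs for the acceptance checks (cached; each is used
# by several test blocks).
fx_fig6_run <- function() {
  if (is.null(.fx$fig6run)) {
    cfg <- fx_fig6_config()
    ph <- phantom(lateral_mm = 60, depth_mm = 100, dx_mm = 0.05, dz_mm = 1)
    g <- run_transport(cfg, fx_spectrum_320(), ph,
                       transport_settings(n_histories = 2e6, seed = 1))
    .fx$fig6run <- list(config = cfg, grid = g, report = merge_report(g, cfg))
  }
  .fx$fig6run
}

fx_fig10_run <- function() {
  if (is.null(.fx$fig10run)) {
    cfg <- beamline_config(source_model(6.8, "disk"),
                           multislit_collimator(0.3, 0.7, 23), scd_mm = 295)
    ph <- phantom(lateral_mm = 50, depth_mm = 100, dx_mm = 0.05, dz_mm = 1,
                  inserts = list(list(material = "bone_cortical",
                                      x_mm = c(0, Inf), z_mm = c(0, 5))))
    g <- run_transport(cfg, fx_spectrum_320(), ph,
                       transport_settings(n_histories = 6e6, seed = 1))
    .fx$fig10run <- list(config = cfg, grid = g, report = merge_report(g, cfg))
  }
  .fx$fig10run
}

fx_fig5_run <- function() {
  if (is.null(.fx$fig5run)) {
    cfg <- beamline_config(source_model(6.0, "disk"),
                           multislit_collimator(0.3, 1.0, 9), scd_mm = 315)
    ph <- phantom(lateral_mm = 40, depth_mm = 90, dx_mm = 0.05, dz_mm = 1,
                  material = "film_plastic")
    g <- run_transport(cfg, fx_spectrum_320(), ph,
                       transport_settings(n_histories = 2e6, seed = 1))
    .fx$fig5run <- list(config = cfg, grid = g, report = merge_report(g, cfg))
  }
  .fx$fig5run
}
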