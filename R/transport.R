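#' Transport settings
#'
#' @param n_histories photon histories (>= 1e4)
#' @param seed RNG seed recorded in the output grid; `run_transport()` calls
#'   `set.seed(seed)` so identical seeds give bit-identical grids
#' @param cutoff_keV energy transport cutoff (default 10 keV; photons falling
#'   below it deposit locally)
#' @param electron_spread logical; convolve each depth row with the Gaussian
#'   electron dose-spread kernel (sigma from [electron_kernel_sigma()])
#' @param blade_transmission `"opaque"` (default) or `"attenuated"` (rays
#'   through blades carried with weight exp(-mu_W t))
#' @param primary_only logical; deposit the full photon energy at the first
#'   collision and stop (collision-density mode, used as the analytic oracle's
#'   Monte Carlo counterpart)
#' @export
transport_settings <- function(n_histories = 1e6, seed = 1, cutoff_keV = 10,
                               electron_spread = TRUE,
                               blade_transmission = c("opaque", "attenuated"),
                               primary_only = FALSE) {
  blade_transmission <- match.arg(blade_transmission)
  stopifnot(n_histories >= 1e4)
  structure(list(n_histories = as.integer(n_histories), seed = as.integer(seed),
                 cutoff_keV = cutoff_keV, electron_spread = electron_spread,
                 blade_transmission = blade_transmission,
                 primary_only = primary_only), class = "TransportSettings")
}

.dose_grid <- function(dose, phantom, config, meta) {
  structure(list(
    dose = dose,                        # Gy per source photon (arb. fluence)
    x_mm = phantom$x_mm,
    z_mm = phantom$z_surface_mm + config$gap_mm,  # from collimator exit
    dx_mm = phantom$dx_mm, dz_mm = phantom$dz_mm,
    gap_mm = config$gap_mm,
    config = config, meta = meta), class = "DoseGrid")
}

#' @export
print.DoseGrid <- function(x, ...) {
  cat(sprintf(
    "<DoseGrid> %d x %d voxels (%g x %g mm), z %g-%g mm from collimator\n",
    nrow(x$dose), ncol(x$dose), x$dx_mm, x$dz_mm, min(x$z_mm), max(x$z_mm)))
  if (!is.null(x$meta$n_histories))
    cat(sprintf("  %s histories, seed %d%s\n",
                format(x$meta$n_histories, big.mark = ","), x$meta$seed,
                if (isTRUE(x$meta$analytic)) " (analytic)" else ""))
  invisible(x)
}

# Per-material transport tables on a 1-keV grid: linear mu (1/mm) and
# channel probabilities, plus the Woodcock majorant.
.transport_tables <- function(phantom, e_min, e_max) {
  E <- seq(e_min + 0.5, e_max - 0.5, by = 1)
  mats <- phantom$materials
  nm <- length(mats)
  mu_tot <- p_pe <- p_ray <- matrix(0, length(E), nm)
  ray_coef <- numeric(nm)
  for (j in seq_len(nm)) {
    ac <- attenuation_coefficients(mats[[j]], E)
    mu_tot[, j] <- ac$total / 10          # 1/cm -> 1/mm
    p_pe[, j] <- ac$pe / ac$total
    p_ray[, j] <- ac$rayleigh / ac$total
    ray_coef[j] <- 0.026 * mats[[j]]$z_eff^(1 / 3)
  }
  list(E = E, mu_tot = mu_tot, p_pe = p_pe, p_ray = p_ray,
       mu_max = apply(mu_tot, 1, max), ray_coef = ray_coef, e_min = e_min)
}

.voxel_mass_g <- function(phantom) {
  rho <- vapply(phantom$materials, function(m) m$density, 0)
  vol_cm3 <- (phantom$dx_mm / 10) * (phantom$dz_mm / 10) * 1  # 1-cm slab
  matrix(rho[phantom$material_id], phantom$nx, phantom$nz) * vol_cm3
}

#' Run the 2-D photon Monte Carlo
#'
#' Transports photons sampled from `spectrum` through the beamline of
#' `config` into `phantom`, scoring absorbed dose per source photon on the
#' phantom's (x, z) voxel grid. See the methods vignette for the physics
#' model (Klein-Nishina Compton, local electron deposit with optional
#' Gaussian spread, forward-peaked Rayleigh, Woodcock tracking).
#'
#' @param config a [beamline_config()]
#' @param spectrum a [build_spectrum()] / [spectrum_from_quality()] spectrum
#' @param phantom a [phantom()]
#' @param settings a [transport_settings()]
#' @return a `DoseGrid` (matrix `dose[x, z]` in Gy per source photon, with
#'   `z_mm` measured from the collimator exit face)
#' @export
run_transport <- function(config, spectrum, phantom,
                          settings = transport_settings()) {
  col <- config$collimator
  if (is.null(col)) {
    ap_centers <- numeric(0)
    ap_half <- 0
    open_half <- config$field_mm / 2
  } else {
    ap_centers <- beam_centers_at(config, 0)
    ap_half <- col$aperture_mm / 2
    open_half <- 0
    span <- max(ap_centers) - min(ap_centers) + col$aperture_mm
    if (span > phantom$lateral_mm)
      stop("phantom narrower than the collimated array", call. = FALSE)
  }
  tt <- .transport_tables(phantom, e_min = 10, e_max = spectrum$kvp)
  blade_mu <- 0
  blade_frac <- 0
  if (!is.null(col) && settings$blade_transmission == "attenuated") {
    muW <- attenuation_coefficients("tungsten",
                                    spectrum_mean_energy(spectrum))$total / 10
    blade_mu <- muW * col$blade_mm
    blade_frac <- 1 - col$aperture_mm / col$pitch_mm
  }
  set.seed(settings$seed)
  edep <- mc_transport_cpp(
    n_hist = settings$n_histories,
    spec_E = spectrum$energy_keV, spec_cdf = cumsum(spectrum$weights),
    src_half_mm = config$source$spot_mm / 2,
    src_disk = as.integer(config$source$shape == "disk"),
    L_mm = config$scd_mm, gap_mm = config$gap_mm,
    ap_centers = ap_centers, ap_half_mm = ap_half, open_half_mm = open_half,
    x0_mm = -phantom$lateral_mm / 2, dx_mm = phantom$dx_mm, nx = phantom$nx,
    z0_mm = config$gap_mm, dz_mm = phantom$dz_mm, nz = phantom$nz,
    mat_map = as.integer(phantom$material_id) - 1L,
    mu_tot = tt$mu_tot, p_pe = tt$p_pe, p_ray = tt$p_ray, mu_max = tt$mu_max,
    ray_coef = tt$ray_coef, e_min_keV = tt$e_min,
    cutoff_keV = settings$cutoff_keV,
    primary_only = as.integer(settings$primary_only),
    blade_mu_mm = blade_mu, blade_frac = blade_frac)
  edep_total <- sum(edep)
  dose <- edep * 1.602176634e-16 / (.voxel_mass_g(phantom) * 1e-3) /
    settings$n_histories
  if (settings$electron_spread) {
    sig <- electron_kernel_sigma(spectrum)
    dose <- blur_lateral(dose, sig / phantom$dx_mm)
  }
  .dose_grid(dose, phantom, config,
             meta = list(n_histories = settings$n_histories,
                         seed = settings$seed,
                         cutoff_keV = settings$cutoff_keV,
                         electron_spread = settings$electron_spread,
                         blade_transmission = settings$blade_transmission,
                         primary_only = settings$primary_only,
                         edep_keV_per_hist = edep_total / settings$n_histories,
                         mean_E_keV = spectrum_mean_energy(spectrum)))
}

# Gaussian blur along x (rows) with sigma in voxel units; kernel truncated
# at 4 sigma, renormalized (edge-preserving total within the grid)
blur_lateral <- function(dose, sigma_vox) {
  if (!is.finite(sigma_vox) || sigma_vox < 0.25) return(dose)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k <- k / sum(k)
  nx <- nrow(dose)
  out <- matrix(0, nx, ncol(dose))
  pad <- rbind(matrix(0, half, ncol(dose)), dose, matrix(0, half, ncol(dose)))
  for (i in seq_along(k)) {
    out <- out + k[i] * pad[i:(i + nx - 1), , drop = FALSE]
  }
  out
}

#' Analytic primary-dose oracle
#'
#' Deterministic ray-traced primary collision dose: rays from a quadrature
#' over the source spot through each aperture, attenuated exponentially
#' per energy group along the voxelized material path, depositing the full
#' photon energy at the collision site (the same convention as
#' `primary_only` Monte Carlo). Includes the planar finite-source divergence
#' factor L/(L+z) through ray spreading. No scatter.
#'
#' @param config a [beamline_config()]
#' @param spectrum a `Spectrum` (internally condensed to `n_groups` groups)
#' @param phantom a [phantom()]
#' @param n_src source quadrature points (default 15)
#' @param n_per_ap rays per aperture (default 7)
#' @param n_groups condensed energy groups (default 25)
#' @return a `DoseGrid` (same units/axes as [run_transport()])
#' @export
analytic_primary_dose <- function(config, spectrum, phantom, n_src = 15,
                                  n_per_ap = 7, n_groups = 25) {
  sp <- rebin_spectrum(spectrum, n_groups)
  col <- config$collimator
  s2 <- config$source$spot_mm / 2
  # source quadrature: midpoint rule with the collapsed spot profile
  u <- (seq_len(n_src) - 0.5) / n_src
  xs <- (2 * u - 1) * s2
  ws <- if (config$source$shape == "disk" && s2 > 0)
    sqrt(pmax(0, 1 - (xs / s2)^2)) else rep(1, n_src)
  if (s2 == 0) { xs <- 0; ws <- 1 }
  ws <- ws / sum(ws)
  if (is.null(col)) {
    n_rays_per_src <- max(n_per_ap * 10, 50)
    v <- (seq_len(n_rays_per_src) - 0.5) / n_rays_per_src
    xa <- (2 * v - 1) * config$field_mm / 2
  } else {
    centers <- beam_centers_at(config, 0)
    v <- (seq_len(n_per_ap) - 0.5) / n_per_ap
    off <- (2 * v - 1) * col$aperture_mm / 2
    xa <- as.vector(outer(off, centers, `+`))
  }
  L <- config$scd_mm
  gap <- config$gap_mm
  nx <- phantom$nx; nz <- phantom$nz
  dz <- phantom$dz_mm; dx <- phantom$dx_mm
  x0 <- -phantom$lateral_mm / 2
  zmid <- phantom$z_surface_mm + gap          # from collimator
  mats <- phantom$materials
  mu <- vapply(mats, function(m)
    attenuation_coefficients(m, sp$energy_keV)$total / 10, sp$energy_keV) # 1/mm
  mu <- matrix(mu, nrow = length(sp$energy_keV))
  we <- sp$weights * sp$energy_keV            # weight x energy per group
  edep <- matrix(0, nx, nz)
  for (i in seq_along(xs)) {
    for (j in seq_along(xa)) {
      slope <- (xa[j] - xs[i]) / L
      xz <- xa[j] + slope * zmid              # lateral position per row
      ix <- floor((xz - x0) / dx) + 1
      ok <- ix >= 1 & ix <= nx
      if (!any(ok)) next
      mat_ids <- phantom$material_id[cbind(pmax(pmin(ix, nx), 1), seq_len(nz))]
      dl <- dz * sqrt(1 + slope^2)
      mu_ray <- mu[, mat_ids, drop = FALSE] * dl      # nE x nz
      cum <- cbind(0, t(apply(mu_ray, 1, cumsum)))    # nE x (nz+1)
      trans <- exp(-cum)
      dep_gr <- trans[, -ncol(trans), drop = FALSE] -
        trans[, -1, drop = FALSE]                     # collision prob / row
      dep <- as.numeric(we %*% dep_gr) * ws[i]
      dep[!ok] <- 0
      idx <- cbind(ix[ok], which(ok))
      edep[idx] <- edep[idx] + dep[ok]
    }
  }
  edep <- edep / length(xa)
  dose <- edep * 1.602176634e-16 / (.voxel_mass_g(phantom) * 1e-3)
  .dose_grid(dose, phantom, config,
             meta = list(analytic = TRUE, n_src = n_src, n_per_ap = n_per_ap,
                         n_groups = n_groups))
}

#' CSDA range of electrons in water
#' @param energy_keV electron kinetic energy (keV), 10--500
#' @return range in mm of water
#' @export
csda_range_water <- function(energy_keV) {
  tab <- utils::read.csv(file.path(.material_dir(),
                                   "electron_range_water.csv"))
  .loglog(tab$energy_keV, tab$csda_g_cm2, energy_keV) * 10  # g/cm2 -> mm
}

# mean fraction of the photon energy transferred to the Compton electron,
# averaged over the Klein-Nishina distribution (numeric quadrature)
.kn_mean_electron_fraction <- function(E_keV) {
  vapply(E_keV, function(E) {
    k <- E / 510.99895
    emin <- 1 / (1 + 2 * k)
    eps <- seq(emin, 1, length.out = 200)
    ct <- 1 - (1 - eps) / (k * eps)
    f <- eps + 1 / eps - (1 - ct^2)
    1 - sum(eps * f) / sum(f)
  }, 0)
}

#' Electron dose-spread kernel width
#'
#' The lateral Gaussian sigma standing in for secondary-electron transport:
#' sigma = k R_CSDA(mean secondary-electron energy) with k = 0.3. The mean
#' secondary energy averages photoelectron (full photon energy) and Compton
#' electron energies over the spectrum, weighted by interaction rates in the
#' reference material.
#'
#' @param spectrum a `Spectrum`
#' @param material reference material (default water)
#' @param k scale constant (default 0.3; a CSDA range is a hard upper bound
#'   on the electron's net displacement, most of the dose lands well inside)
#' @return sigma in mm
#' @export
electron_kernel_sigma <- function(spectrum, material = "water", k = 0.3) {
  if (is.character(material)) material <- material(material)
  E <- spectrum$energy_keV
  w <- spectrum$weights
  ac <- attenuation_coefficients(material, E)
  fe <- .kn_mean_electron_fraction(E)
  num <- sum(w * (ac$pe * E + ac$compton * fe * E))
  den <- sum(w * (ac$pe + ac$compton))
  t_mean <- num / den
  k * csda_range_water(max(t_mean, 10))
}
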