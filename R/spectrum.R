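#' Filtered orthovoltage x-ray spectra
#'
#' The tube spectrum is modeled as a Kramers-type bremsstrahlung fluence,
#' phi(E) proportional to (E_max - E)/E, on 1-keV bins, hardened by
#' exponential filtration through each filter layer. Characteristic tungsten
#' lines are omitted: downstream dosimetry depends on beam hardness, which is
#' pinned to a measured copper half-value layer with
#' [tune_filtration_to_hvl()] rather than on fine spectral structure.
#'
#' @name spectrum
NULL

#' A filtration layer
#' @param material material name or [material()] object
#' @param thickness_mm layer thickness in mm (>= 0)
#' @return a `FiltrationLayer`
#' @export
filtration_layer <- function(material, thickness_mm) {
  if (is.character(material)) material <- material(material)
  stopifnot(thickness_mm >= 0)
  structure(list(material = material, thickness_mm = thickness_mm),
            class = "FiltrationLayer")
}

#' Build a filtered bremsstrahlung spectrum
#'
#' @param kvp tube potential in kV (80--400)
#' @param filtration list of [filtration_layer()]s (may be empty)
#' @param cutoff_keV transport cutoff; bins below it are dropped (default 10)
#' @return a `Spectrum`: list with `energy_keV` (bin midpoints, 1-keV bins),
#'   `weights` (relative fluence, sums to 1), `kvp`
#' @export
build_spectrum <- function(kvp, filtration = list(), cutoff_keV = 10) {
  if (kvp < 80 || kvp > 400) stop("kvp out of range [80, 400]", call. = FALSE)
  if (inherits(filtration, "FiltrationLayer")) filtration <- list(filtration)
  edges <- seq(cutoff_keV, kvp, by = 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- (kvp - mid) / mid                      # Kramers fluence shape
  for (fl in filtration) {
    if (!inherits(fl, "FiltrationLayer"))
      stop("filtration must be a list of filtration_layer()s", call. = FALSE)
    mu <- attenuation_coefficients(fl$material, mid)$total   # 1/cm
    w <- w * exp(-mu * fl$thickness_mm / 10)
  }
  w <- w / sum(w)
  structure(list(energy_keV = mid, weights = w, kvp = kvp), class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum> %g kVp, %d bins %g-%g keV, mean %.1f keV\n",
              x$kvp, length(x$energy_keV), min(x$energy_keV),
              max(x$energy_keV), spectrum_mean_energy(x)))
  invisible(x)
}

#' Fluence-weighted mean energy of a spectrum (keV)
#' @param spectrum a `Spectrum`
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$energy_keV * spectrum$weights) / sum(spectrum$weights)
}

#' Rebin a spectrum to fewer energy groups
#'
#' Weight-preserving condensation onto `n_groups` equal-width groups; used by
#' the analytic dose oracle to keep its energy loop short.
#' @param spectrum a `Spectrum`
#' @param n_groups number of groups
#' @export
rebin_spectrum <- function(spectrum, n_groups = 30) {
  br <- seq(min(spectrum$energy_keV) - 0.5, max(spectrum$energy_keV) + 0.5,
            length.out = n_groups + 1)
  g <- cut(spectrum$energy_keV, br, labels = FALSE)
  w <- as.numeric(tapply(spectrum$weights, g, sum))
  ew <- as.numeric(tapply(spectrum$weights * spectrum$energy_keV, g, sum))
  keep <- w > 0
  structure(list(energy_keV = ew[keep] / w[keep], weights = w[keep] / sum(w),
                 kvp = spectrum$kvp), class = "Spectrum")
}

#' Half-value layer of a beam in a material
#'
#' Thickness t* at which the narrow-beam transmitted fluence
#' sum_i w_i exp(-mu_i t*) falls to one half, found by bracketing and
#' bisection to 1e-3 mm.
#'
#' @param spectrum a `Spectrum`
#' @param material material name or [material()] object
#' @return HVL in mm
#' @export
hvl_of_beam <- function(spectrum, material) {
  if (is.character(material)) material <- material(material)
  mu <- attenuation_coefficients(material, spectrum$energy_keV)$total # 1/cm
  w <- spectrum$weights / sum(spectrum$weights)
  trans <- function(t_mm) sum(w * exp(-mu * t_mm / 10))
  hi <- 1
  it <- 0
  while (trans(hi) > 0.5) {
    hi <- hi * 2
    it <- it + 1
    if (it > 60) stop("HVL bracketing failed", call. = FALSE)
  }
  lo <- 0
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (trans(mid) > 0.5) lo <- mid else hi <- mid
    if (hi - lo < 1e-3) return((lo + hi) / 2)
  }
  stop("HVL bisection did not converge in 200 iterations", call. = FALSE)
}

#' Solve the filter thickness that yields a target HVL
#'
#' Monotone bisection on a single filter layer's thickness so that the
#' filtered spectrum's half-value layer matches `target_hvl_mm` within 1%.
#' Used to emulate beam-quality specifications such as "320 kVp, 3.8-mm Cu
#' HVL" without a published spectrum.
#'
#' @param kvp tube potential (kV)
#' @param material filter material (also the HVL reference material)
#' @param target_hvl_mm target half-value layer in mm of that material
#' @param max_thickness_mm search ceiling (default 20 mm)
#' @param extra_filtration fixed additional layers applied before the tuned one
#' @return a [filtration_layer()] of the tuned material
#' @export
tune_filtration_to_hvl <- function(kvp, material, target_hvl_mm,
                                   max_thickness_mm = 20,
                                   extra_filtration = list()) {
  if (is.character(material)) material <- material(material)
  hvl_at <- function(t_mm) {
    sp <- build_spectrum(kvp, c(extra_filtration,
                                list(filtration_layer(material, t_mm))))
    hvl_of_beam(sp, material)
  }
  lo <- 0
  hi <- max_thickness_mm
  if (hvl_at(0) >= target_hvl_mm)
    return(filtration_layer(material, 0))
  if (hvl_at(hi) < target_hvl_mm)
    stop("target HVL unreachable below ", max_thickness_mm, " mm of ",
         material$name, call. = FALSE)
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    if (hvl_at(mid) < target_hvl_mm) lo <- mid else hi <- mid
    if ((hi - lo) / max(target_hvl_mm, 1) < 1e-4) break
  }
  t_mm <- (lo + hi) / 2
  got <- hvl_at(t_mm)
  if (abs(got - target_hvl_mm) / target_hvl_mm > 0.01)
    stop("HVL tuning failed to converge within 1%", call. = FALSE)
  filtration_layer(material, t_mm)
}

#' Beam-quality-matched spectrum
#'
#' Convenience wrapper: a `kvp` spectrum filtered so its HVL in
#' `hvl_material` equals `hvl_mm` (the way orthovoltage beams are specified).
#' @inheritParams tune_filtration_to_hvl
#' @param hvl_material material in which the HVL is specified
#' @param hvl_mm target HVL (mm)
#' @export
spectrum_from_quality <- function(kvp, hvl_mm, hvl_material = "copper") {
  fl <- tune_filtration_to_hvl(kvp, hvl_material, hvl_mm)
  build_spectrum(kvp, list(fl))
}
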