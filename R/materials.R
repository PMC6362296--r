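#' Material library for photon attenuation
#'
#' The package ships compact photon mass-attenuation tables (10--1000 keV)
#' for the materials used in orthovoltage minibeam work: water, air, cortical
#' bone (density 1.85 g/cm3), aluminium, copper, tin, tungsten, iodine and a
#' film-equivalent plastic. Each table partitions the mass attenuation
#' coefficient into photoelectric, Compton (incoherent) and Rayleigh
#' (coherent) channels; the total is the exact channel sum.
#'
#' @name materials
NULL

.ox_env <- new.env(parent = emptyenv())

.material_dir <- function() {
  system.file("extdata", "materials", package = "oxminibeam", mustWork = TRUE)
}

#' List bundled materials
#' @return character vector of material names accepted by [material()]
#' @export
list_materials <- function() {
  f <- list.files(.material_dir(), pattern = "\\.csv$")
  setdiff(sub("\\.csv$", "", f), c("densities", "electron_range_water"))
}

#' Load a bundled material
#'
#' @param name material name (see [list_materials()]); a few aliases are
#'   accepted (`"bone"`, `"Al"`, `"Cu"`, `"Sn"`, `"W"`, `"I"`, `"film"`)
#' @param density optional density override in g/cm3
#' @return a `Material` object: list with `name`, `density` (g/cm3) and
#'   `table` (data frame energy_keV, pe, compton, rayleigh, total; cm2/g)
#' @export
material <- function(name, density = NULL) {
  aliases <- c(bone = "bone_cortical", Al = "aluminium", Cu = "copper",
               Sn = "tin", W = "tungsten", I = "iodine", film = "film_plastic",
               plastic = "film_plastic")
  key <- if (name %in% names(aliases)) aliases[[name]] else name
  cache_key <- paste0(key, "@", if (is.null(density)) "def" else density)
  if (!is.null(.ox_env[[cache_key]])) return(.ox_env[[cache_key]])
  path <- file.path(.material_dir(), paste0(key, ".csv"))
  if (!file.exists(path)) {
    stop("material not found: '", name, "' (have: ",
         paste(list_materials(), collapse = ", "), ")", call. = FALSE)
  }
  tab <- utils::read.csv(path)
  dens <- utils::read.csv(file.path(.material_dir(), "densities.csv"))
  rho <- if (!is.null(density)) density else
    dens$density_g_cm3[dens$material == key]
  m <- structure(list(name = key, density = rho,
                      z_eff = dens$z_eff[dens$material == key], table = tab),
                 class = "Material")
  .ox_env[[cache_key]] <- m
  m
}

#' @export
print.Material <- function(x, ...) {
  cat(sprintf("<Material> %s  (density %.4g g/cm3, %d energies %g-%g keV)\n",
              x$name, x$density, nrow(x$table), min(x$table$energy_keV),
              max(x$table$energy_keV)))
  invisible(x)
}

.loglog <- function(E_tab, y_tab, E) {
  exp(stats::approx(log(E_tab), log(pmax(y_tab, 1e-300)), xout = log(E))$y)
}

#' Linear attenuation coefficients by interaction channel
#'
#' Log-log interpolates the material's mass-attenuation table and multiplies
#' by density, yielding linear coefficients in 1/cm per channel.
#'
#' @param material a [material()] object (or a name passed through it)
#' @param energy photon energy (keV), vectorized; must lie within the table
#' @return data frame with columns `energy_keV`, `pe`, `compton`, `rayleigh`,
#'   `total` (1/cm)
#' @export
attenuation_coefficients <- function(material, energy) {
  if (is.character(material)) material <- material(material)
  tab <- material$table
  if (any(energy < min(tab$energy_keV) | energy > max(tab$energy_keV))) {
    stop("energy outside tabulated range [", min(tab$energy_keV), ", ",
         max(tab$energy_keV), "] keV", call. = FALSE)
  }
  rho <- material$density
  data.frame(
    energy_keV = energy,
    pe = .loglog(tab$energy_keV, tab$pe, energy) * rho,
    compton = .loglog(tab$energy_keV, tab$compton, energy) * rho,
    rayleigh = .loglog(tab$energy_keV, tab$rayleigh, energy) * rho,
    total = .loglog(tab$energy_keV, tab$total, energy) * rho
  )
}

#' Mass attenuation coefficient (total) in cm2/g
#' @inheritParams attenuation_coefficients
#' @return numeric vector, cm2/g
#' @export
mass_attenuation <- function(material, energy) {
  if (is.character(material)) material <- material(material)
  attenuation_coefficients(material, energy)$total / material$density
}

# internal alias: lets functions with an argument named `material` still
# reach the constructor
.material_fn <- material
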