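#' Synthetic radiochromic-film dosimetry
#'
#' Forward model for film scans of minibeam dose planes and its inverse, so
#' film-based analyses (cross-section stacks through a phantom, edge-on
#' merging films) can be exercised without physical films. The scanner
#' response is a saturating exponential in net optical density,
#' OD(D) = OD_max (1 - exp(-D / D0)), a standard parametric shape for
#' radiochromic film; the true calibration curve of any given scanner/film
#' lot is not published, so the parameters live in the response object and
#' in fixture metadata.
#'
#' @name film_synth
NULL

#' Scanner response model
#'
#' @param od_max saturation net optical density (default 2)
#' @param d0_gy dose constant of the saturating exponential (Gy, default 5)
#' @param pixel_pitch_um scan pixel pitch; default 7.94 um (3200 dpi)
#' @param bit_depth pixel bit depth (default 16)
#' @return a `ScannerResponse`
#' @export
scanner_response <- function(od_max = 2, d0_gy = 5, pixel_pitch_um = 7.94,
                             bit_depth = 16) {
  stopifnot(od_max > 0, d0_gy > 0)
  structure(list(od_max = od_max, d0_gy = d0_gy,
                 pixel_pitch_um = pixel_pitch_um,
                 bit_depth = as.integer(bit_depth),
                 pixel_max = 2L^as.integer(bit_depth) - 1L),
            class = "ScannerResponse")
}

#' Dose corresponding to (near-)saturation of the film
#'
#' Dose at which the optical density reaches `frac` of OD_max; above it the
#' inverse response becomes ill-conditioned.
#' @param response a [scanner_response()]
#' @param frac OD fraction defining saturation (default 0.98)
#' @export
saturation_dose <- function(response, frac = 0.98) {
  -response$d0_gy * log(1 - frac)
}

#' Expose a synthetic film to a dose plane
#'
#' Applies the OD response, multiplicative Gaussian noise on the optical
#' density, converts to scanner transmission pixel values and quantizes to
#' the scanner bit depth. Seeded and reproducible.
#'
#' @param dose_plane matrix of dose values (Gy), >= 0
#' @param response a [scanner_response()]
#' @param noise_sd relative (multiplicative) OD noise, >= 0 (default 0.01)
#' @param seed RNG seed
#' @param pixel_pitch_um pixel pitch recorded in the image (defaults to the
#'   response's)
#' @param orientation `"cross_section"` or `"edge_on"` metadata tag
#' @return a `FilmImage`: integer pixel matrix plus calibration metadata
#' @export
dose_to_film <- function(dose_plane, response = scanner_response(),
                         noise_sd = 0.01, seed = 1,
                         pixel_pitch_um = response$pixel_pitch_um,
                         orientation = "cross_section") {
  stopifnot(all(dose_plane >= 0), noise_sd >= 0)
  set.seed(seed)
  od <- response$od_max * (1 - exp(-dose_plane / response$d0_gy))
  if (noise_sd > 0)
    od <- od * matrix(stats::rnorm(length(od), 1, noise_sd), nrow(od))
  od <- pmax(od, 0)
  px <- round(response$pixel_max * 10^(-od))
  px <- pmin(pmax(px, 0), response$pixel_max)
  structure(list(pixels = matrix(as.integer(px), nrow(dose_plane)),
                 pixel_pitch_um = pixel_pitch_um, response = response,
                 orientation = orientation, noise_sd = noise_sd, seed = seed),
            class = "FilmImage")
}

#' @export
print.FilmImage <- function(x, ...) {
  cat(sprintf("<FilmImage> %d x %d px at %.3g um (%s), OD_max %.2g, D0 %.2g Gy\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_um, x$orientation,
              x$response$od_max, x$response$d0_gy))
  invisible(x)
}

#' Convert a film image back to dose
#'
#' Inverts the scanner response pixel-wise. Pixels at or beyond `sat_frac`
#' of the saturation density are flagged (attribute `saturated`, a logical
#' matrix) and returned as `NA`.
#'
#' @param image a `FilmImage` (or integer pixel matrix, with `response` given)
#' @param response calibration; defaults to the image's own
#' @param sat_frac OD fraction treated as saturated (default 0.98)
#' @return dose matrix (Gy) with attribute `saturated`
#' @export
film_to_dose <- function(image, response = NULL, sat_frac = 0.98) {
  if (inherits(image, "FilmImage")) {
    px <- image$pixels
    if (is.null(response)) response <- image$response
  } else {
    px <- image
  }
  if (is.null(response)) stop("no calibration available", call. = FALSE)
  od <- -log10(pmax(px, 1) / response$pixel_max)
  sat <- od >= sat_frac * response$od_max
  od <- pmin(od, sat_frac * response$od_max)
  dose <- -response$d0_gy * log(1 - od / response$od_max)
  dose[sat] <- NA_real_
  attr(dose, "saturated") <- sat
  dose
}

#' Calibration table for export
#'
#' Pixel-value-to-dose lookup derived from a [scanner_response()], suitable
#' for writing alongside film TIFFs (columns `pixel_value`, `dose_Gy`).
#' @param response a [scanner_response()]
#' @param n number of table rows (default 512)
#' @export
calibration_table <- function(response, n = 512) {
  pmin_val <- ceiling(response$pixel_max * 10^(-0.98 * response$od_max))
  px <- unique(round(exp(seq(log(pmin_val), log(response$pixel_max),
                             length.out = n))))
  od <- -log10(px / response$pixel_max)
  data.frame(pixel_value = rev(px),
             dose_Gy = rev(-response$d0_gy * log(1 - od / response$od_max)))
}

#' Write a film image as 16-bit grayscale TIFF
#' @param image a `FilmImage`
#' @param path output file; a calibration CSV is written alongside when
#'   `calibration = TRUE`
#' @param calibration also write `<path>_calibration.csv`
#' @export
write_film_tiff <- function(image, path, calibration = TRUE) {
  tiff::writeTIFF(image$pixels / image$response$pixel_max, path,
                  bits.per.sample = 16L)
  if (calibration) {
    utils::write.csv(calibration_table(image$response),
                     sub("\\.tiff?$", "_calibration.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a film TIFF back as a pixel matrix
#' @param path TIFF path
#' @param response a [scanner_response()] to attach (optional)
#' @return a `FilmImage` (response may be `NULL` if not supplied)
#' @export
read_film_tiff <- function(path, response = NULL) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  pixel_max <- 65535L
  structure(list(pixels = matrix(as.integer(round(v * pixel_max)), nrow(v)),
                 pixel_pitch_um = NA_real_, response = response,
                 orientation = "unknown", noise_sd = NA_real_, seed = NA),
            class = "FilmImage")
}

#' Generate synthetic film fixtures for a minibeam scenario
#'
#' Runs the transport (or the analytic primary oracle) for the given
#' beamline and phantom, extracts dose planes at film positions, scales them
#' to a stated entrance peak dose, and converts each to a film image.
#' Ground-truth dose planes are returned alongside the images so analyses of
#' the films can be validated.
#'
#' @param scenario `"cross_section_stack"` (films normal to the beam at the
#'   given depths; the slit-length direction is replicated) or `"edge_on"`
#'   (a single film spanning the x-z plane)
#' @param config a [beamline_config()]
#' @param spectrum a `Spectrum`
#' @param phantom a [phantom()]
#' @param settings a [transport_settings()]
#' @param response a [scanner_response()]
#' @param depths_mm film depths from the collimator exit (cross-section mode;
#'   default 0/25.4/50.8 mm, one-inch slices)
#' @param entrance_peak_gy peak dose at the first film/entrance plane used to
#'   set the absolute scale (default 5.4)
#' @param noise_sd film noise (see [dose_to_film()])
#' @param seed seed for the film noise (transport uses `settings$seed`)
#' @param method `"transport"` (default) or `"analytic"` (primary only, no
#'   scatter: faster, no valley fill)
#' @param ny_px rows used to replicate cross-section films (default 64)
#' @return list with `images` (list of `FilmImage`), `truth` (dose planes,
#'   Gy), `grid` (the `DoseGrid`), `depths_mm`
#' @export
generate_film_fixture <- function(scenario = c("cross_section_stack", "edge_on"),
                                  config, spectrum, phantom,
                                  settings = transport_settings(),
                                  response = scanner_response(),
                                  depths_mm = c(0, 25.4, 50.8),
                                  entrance_peak_gy = 5.4, noise_sd = 0.005,
                                  seed = 1, method = c("transport", "analytic"),
                                  ny_px = 64) {
  scenario <- match.arg(scenario)
  method <- match.arg(method)
  grid <- if (method == "transport")
    run_transport(config, spectrum, phantom, settings)
  else analytic_primary_dose(config, spectrum, phantom)
  # absolute scale: entrance peak -> entrance_peak_gy
  p1 <- lateral_profile(grid, grid$z_mm[1])
  scale <- entrance_peak_gy / max(p1$dose)
  grid$dose <- grid$dose * scale
  grid$meta$dose_scale_gy_per_unit <- scale
  images <- list()
  truth <- list()
  if (scenario == "cross_section_stack") {
    pitch_mm <- response$pixel_pitch_um / 1000
    xpx <- seq(min(grid$x_mm), max(grid$x_mm), by = pitch_mm)
    for (i in seq_along(depths_mm)) {
      z <- max(depths_mm[i], grid$z_mm[1])
      prof <- lateral_profile(grid, z)
      row <- stats::approx(prof$position_mm, prof$dose, xout = xpx)$y
      plane <- matrix(rep(row, each = ny_px), nrow = ny_px)
      truth[[i]] <- plane
      images[[i]] <- dose_to_film(plane, response, noise_sd,
                                  seed = seed + i - 1,
                                  pixel_pitch_um = response$pixel_pitch_um,
                                  orientation = "cross_section")
    }
  } else {
    plane <- grid$dose
    truth[[1]] <- plane
    images[[1]] <- dose_to_film(plane, response, noise_sd, seed = seed,
                                pixel_pitch_um = grid$dx_mm * 1000,
                                orientation = "edge_on")
    depths_mm <- grid$z_mm
  }
  list(images = images, truth = truth, grid = grid, depths_mm = depths_mm)
}
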