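#' Finite-source multislit beam optics
#'
#' Closed-form similar-triangle optics for a planar minibeam array produced
#' by a finite source spot and a multislit collimator. With aperture width
#' `a`, on-center pitch `p`, source spot size `s` and source-to-collimator
#' distance `L`, the projected quantities at depth `z` beyond the collimator
#' exit are
#'   full width  = a (L+z)/L + s z / L
#'   umbra width = max(0, a (L+z)/L - s z / L)
#'   pitch       = p (L+z)/L
#' Penumbrae of adjacent beams first touch (the scatter-free merge onset) at
#'   z* = (p - a) L / (s - (p - a)),
#' provided s > p - a; otherwise the array never merges geometrically. The
#' onset is a lower bound for the dose-based merge depth (peak-to-valley
#' ratio threshold), since scatter only adds valley dose.
#'
#' @name beam_geometry
NULL

#' Source model
#' @param spot_mm source spot size (diameter) in mm, 0 < spot <= 12
#' @param shape `"disk"` (focal-spot disk; collapsed lateral profile is a
#'   semicircle) or `"strip"` (uniform)
#' @export
source_model <- function(spot_mm, shape = c("disk", "strip")) {
  shape <- match.arg(shape)
  stopifnot(spot_mm > 0, spot_mm <= 12)
  structure(list(spot_mm = spot_mm, shape = shape), class = "SourceModel")
}

#' Multislit collimator
#' @param aperture_mm slit width (mm)
#' @param pitch_mm on-center slit spacing (mm), > aperture
#' @param n_apertures number of slits (odd preferred; centered array)
#' @param blade_mm blade (collimator) thickness in mm, default 5 (tungsten)
#' @param focusing `"parallel"` or `"diverging"`; diverging collimators are
#'   focused at the source and are treated as parallel at first order (slit
#'   axes aim at the source, so projection formulas coincide)
#' @param focal_mm focal distance for diverging collimators (defaults to scd)
#' @export
multislit_collimator <- function(aperture_mm, pitch_mm, n_apertures,
                                 blade_mm = 5,
                                 focusing = c("parallel", "diverging"),
                                 focal_mm = NA_real_) {
  focusing <- match.arg(focusing)
  stopifnot(aperture_mm > 0, aperture_mm < pitch_mm, n_apertures >= 1)
  structure(list(aperture_mm = aperture_mm, pitch_mm = pitch_mm,
                 n_apertures = as.integer(n_apertures), blade_mm = blade_mm,
                 focusing = focusing, focal_mm = focal_mm),
            class = "MultislitCollimator")
}

#' Beamline configuration
#' @param source a [source_model()]
#' @param collimator a [multislit_collimator()]
#' @param scd_mm source-to-collimator distance (mm), > 0
#' @param gap_mm collimator-to-phantom-surface gap (mm), >= 0
#' @param field_mm open-field width (mm) when `collimator` is `NULL`
#'   (unsegmented beam; the "collimator plane" is then just the aperture
#'   plane at distance `scd_mm`)
#' @export
beamline_config <- function(source, collimator, scd_mm, gap_mm = 0,
                            field_mm = NA_real_) {
  stopifnot(inherits(source, "SourceModel"), scd_mm > 0, gap_mm >= 0)
  if (is.null(collimator)) {
    if (!is.finite(field_mm) || field_mm <= 0)
      stop("open-field config needs a positive field_mm", call. = FALSE)
  } else {
    stopifnot(inherits(collimator, "MultislitCollimator"))
  }
  structure(list(source = source, collimator = collimator,
                 scd_mm = scd_mm, gap_mm = gap_mm, field_mm = field_mm),
            class = "BeamlineConfig")
}

#' @export
print.BeamlineConfig <- function(x, ...) {
  cat(sprintf("<BeamlineConfig> spot %.1f mm (%s), scd %.0f mm, gap %.0f mm\n",
              x$source$spot_mm, x$source$shape, x$scd_mm, x$gap_mm))
  if (is.null(x$collimator)) {
    cat(sprintf("  open field, %.3g mm wide\n", x$field_mm))
  } else {
    cat(sprintf("  collimator: %d x %.2g-mm apertures at %.2g-mm pitch (%s)\n",
                x$collimator$n_apertures, x$collimator$aperture_mm,
                x$collimator$pitch_mm, x$collimator$focusing))
  }
  invisible(x)
}

#' Projected beam geometry at depth
#'
#' @param config a [beamline_config()]
#' @param z depth beyond the collimator exit face (mm), vectorized, >= 0
#' @return data frame with `z_mm`, `full_width_mm`, `umbra_width_mm`,
#'   `pitch_mm`
#' @export
projected_geometry <- function(config, z) {
  stopifnot(all(z >= 0))
  if (is.null(config$collimator))
    stop("projected_geometry needs a multislit collimator", call. = FALSE)
  a <- config$collimator$aperture_mm
  p <- config$collimator$pitch_mm
  s <- config$source$spot_mm
  L <- config$scd_mm
  data.frame(
    z_mm = z,
    full_width_mm = a * (L + z) / L + s * z / L,
    umbra_width_mm = pmax(0, a * (L + z) / L - s * z / L),
    pitch_mm = p * (L + z) / L
  )
}

#' Projected beam-center positions at depth
#' @inheritParams projected_geometry
#' @return numeric vector of lateral beam-center positions (mm) at depth z
#' @export
beam_centers_at <- function(config, z) {
  n <- config$collimator$n_apertures
  p <- config$collimator$pitch_mm
  k <- seq_len(n) - (n + 1) / 2
  k * p * (config$scd_mm + z) / config$scd_mm
}

#' Scatter-free geometric merge onset
#'
#' Smallest depth at which the projected full width reaches the projected
#' pitch: z* = (p - a) L / (s - (p - a)). Returns `Inf` ("never merges")
#' when s <= p - a.
#'
#' @param config a [beamline_config()]
#' @return onset depth from the collimator exit, mm (possibly `Inf`)
#' @export
geometric_merge_onset <- function(config) {
  if (is.null(config$collimator))
    stop("geometric_merge_onset needs a multislit collimator", call. = FALSE)
  a <- config$collimator$aperture_mm
  p <- config$collimator$pitch_mm
  s <- config$source$spot_mm
  L <- config$scd_mm
  if (s <= p - a) return(Inf)
  (p - a) * L / (s - (p - a))
}

#' Source-to-collimator distance for a requested merge onset
#'
#' Inverts the merge-onset formula: L = z* (s - (p - a)) / (p - a).
#' @param config a [beamline_config()] (its scd is ignored)
#' @param target_onset_mm requested geometric onset depth (mm)
#' @return scd in mm
#' @export
solve_scd_for_merge_depth <- function(config, target_onset_mm) {
  a <- config$collimator$aperture_mm
  p <- config$collimator$pitch_mm
  s <- config$source$spot_mm
  if (s <= p - a)
    stop("beams never merge for this spot/pitch (s <= p - a)", call. = FALSE)
  L <- target_onset_mm * (s - (p - a)) / (p - a)
  if (L <= 0) stop("requested onset yields non-positive scd", call. = FALSE)
  L
}

#' Collimator pitch for a requested merge onset
#'
#' p = a + s z* / (L + z*); larger pitch pushes the merge deeper.
#' @param config a [beamline_config()] (its pitch is ignored)
#' @param target_onset_mm requested geometric onset depth (mm)
#' @return pitch in mm
#' @export
solve_pitch_for_merge_depth <- function(config, target_onset_mm) {
  a <- config$collimator$aperture_mm
  s <- config$source$spot_mm
  L <- config$scd_mm
  p <- a + s * target_onset_mm / (L + target_onset_mm)
  if (p <= a && target_onset_mm > 0)
    stop("infeasible: resulting pitch <= aperture width", call. = FALSE)
  p
}
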