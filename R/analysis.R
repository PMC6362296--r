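#' Dosimetric analysis of minibeam dose grids
#'
#' Peak/valley extraction is geometry-anchored: peak windows are centered on
#' the projected beam centers and valley windows midway between them, with a
#' window width of one third of the projected beam width (capped at one
#' third of the projected pitch so the two window families never overlap).
#' This is robust to Monte Carlo noise; a windowed-extrema fallback
#' ([profile_extrema_pvr()]) covers film images with unknown geometry.
#'
#' @name dose_analysis
NULL

.depth_index <- function(grid, depth_mm) {
  if (depth_mm < min(grid$z_mm) - grid$dz_mm / 2 ||
      depth_mm > max(grid$z_mm) + grid$dz_mm / 2)
    stop("depth ", depth_mm, " mm outside grid range", call. = FALSE)
  which.min(abs(grid$z_mm - depth_mm))
}

#' Lateral dose profile at a depth
#'
#' @param grid a `DoseGrid`
#' @param depth_mm depth from the collimator exit (mm)
#' @param averaging_window_mm depth window to average over (>= one voxel)
#' @return a `LateralProfile` data frame (`position_mm`, `dose`) with depth
#'   attributes
#' @export
lateral_profile <- function(grid, depth_mm, averaging_window_mm = NULL) {
  if (is.null(averaging_window_mm)) averaging_window_mm <- grid$dz_mm
  sel <- abs(grid$z_mm - depth_mm) <= averaging_window_mm / 2
  if (!any(sel)) sel <- seq_along(grid$z_mm) == .depth_index(grid, depth_mm)
  prof <- rowMeans(grid$dose[, sel, drop = FALSE])
  structure(data.frame(position_mm = grid$x_mm, dose = prof),
            depth_mm = depth_mm, window_mm = averaging_window_mm,
            class = c("LateralProfile", "data.frame"))
}

.pv_windows <- function(config, z, interior_margin = 2) {
  geo <- projected_geometry(config, z)
  centers <- beam_centers_at(config, z)
  n <- length(centers)
  keep <- seq_len(n)
  if (n > 2 * interior_margin + 1)
    keep <- keep[(interior_margin + 1):(n - interior_margin)]
  centers <- centers[keep]
  valleys <- (centers[-1] + centers[-length(centers)]) / 2
  halfw <- min(geo$full_width_mm, geo$pitch_mm) / 6
  list(centers = centers, valleys = valleys, halfw = halfw)
}

.window_mean <- function(x_mm, prof, centers, halfw) {
  sel <- rep(FALSE, length(x_mm))
  for (c0 in centers) sel <- sel | abs(x_mm - c0) <= halfw
  if (!any(sel)) return(NA_real_)
  mean(prof[sel])
}

#' Peak-to-valley dose-ratio curve
#'
#' At each depth, the peak dose is the mean over windows centered on the
#' projected beam centers and the valley dose the mean over windows midway
#' between them (interior beams only; the outermost `interior_margin` beams
#' on each side are excluded since they lack a full complement of
#' neighbors). Also reports the percent difference (peak - valley)/peak.
#'
#' @param grid a `DoseGrid`
#' @param config the [beamline_config()] that produced it
#' @param interior_margin beams dropped at each array edge (default 2)
#' @return a `PVRCurve` data frame: `depth_mm` (from collimator exit),
#'   `peak`, `valley`, `pvr`, `percent_diff`, `defined`
#' @export
pvr_curve <- function(grid, config, interior_margin = 2) {
  depths <- grid$z_mm
  out <- data.frame(depth_mm = depths, peak = NA_real_, valley = NA_real_)
  for (i in seq_along(depths)) {
    w <- .pv_windows(config, depths[i], interior_margin)
    prof <- grid$dose[, i]
    out$peak[i] <- .window_mean(grid$x_mm, prof, w$centers, w$halfw)
    out$valley[i] <- .window_mean(grid$x_mm, prof, w$valleys, w$halfw)
  }
  out$pvr <- ifelse(out$valley > 0, out$peak / out$valley, Inf)
  out$percent_diff <- ifelse(out$peak > 0,
                             (out$peak - out$valley) / out$peak * 100,
                             NA_real_)
  out$defined <- is.finite(out$pvr)
  class(out) <- c("PVRCurve", "data.frame")
  out
}

#' Peak/valley ratio of a single profile by windowed extrema
#'
#' Geometry-free fallback for film images: peaks are local maxima above half
#' the profile maximum, valleys the minima between consecutive peaks.
#' @param profile a [lateral_profile()] (or data frame position_mm/dose)
#' @param min_sep_mm minimum peak separation (default 0.5)
#' @return list with `peak`, `valley`, `pvr`
#' @export
profile_extrema_pvr <- function(profile, min_sep_mm = 0.5) {
  x <- profile$position_mm
  d <- profile$dose
  thr <- max(d) / 2
  cand <- which(d > thr)
  peaks <- integer(0)
  last_x <- -Inf
  for (i in cand[order(-d[cand])]) {
    if (all(abs(x[i] - x[peaks]) >= min_sep_mm)) peaks <- c(peaks, i)
  }
  peaks <- sort(peaks)
  if (length(peaks) < 2)
    return(list(peak = max(d), valley = min(d), pvr = max(d) / max(min(d), 1e-12)))
  vall <- vapply(seq_len(length(peaks) - 1), function(j)
    min(d[peaks[j]:peaks[j + 1]]), 0)
  pk <- mean(d[peaks])
  vl <- mean(vall)
  list(peak = pk, valley = vl, pvr = pk / max(vl, 1e-12))
}

#' Merge depth from a PVR curve
#'
#' First depth at which the peak-to-valley ratio falls to `threshold` or
#' below. The crossing is linearly interpolated on the valley-to-peak ratio
#' (the inverse PVR), which is the bounded quantity that grows linearly as
#' scatter and penumbrae fill the valleys; it is also well behaved when the
#' shallow samples have empty valleys (inverse 0). Returns `NA` (with a
#' `reason` attribute) if the threshold is never reached.
#'
#' @param curve a [pvr_curve()]
#' @param threshold PVR threshold defining "merged" (default 1.2)
#' @return depth in mm from the collimator exit (NA if not reached)
#' @export
merge_depth <- function(curve, threshold = 1.2) {
  z <- curve$depth_mm
  v <- ifelse(curve$defined & is.finite(curve$pvr), 1 / curve$pvr, 0)
  thr <- 1 / threshold
  above <- which(v >= thr)
  if (!length(above)) return(structure(NA_real_, reason = "not reached"))
  i <- above[1]
  if (i == 1) return(z[1])
  z0 <- z[i - 1]; z1 <- z[i]
  v0 <- v[i - 1]; v1 <- v[i]
  z0 + (thr - v0) / (v1 - v0) * (z1 - z0)
}

#' Tissue-sparing depth range from a PVR curve
#'
#' Contiguous interval from the surface over which PVR stays at or above
#' `threshold` (default 3): the depth range where the array still acts as
#' separated minibeams.
#' @param curve a [pvr_curve()]
#' @param threshold sparing PVR threshold (default 3)
#' @return numeric length-2 vector (mm); `c(NA, NA)` if sparing never holds
#' @export
sparing_depth_range <- function(curve, threshold = 3) {
  z <- curve$depth_mm
  r <- ifelse(curve$defined, curve$pvr, Inf)
  if (r[1] < threshold) return(c(NA_real_, NA_real_))
  below <- which(r < threshold)
  if (!length(below)) return(c(z[1], z[length(z)]))
  i <- below[1]
  z0 <- z[i - 1]; z1 <- z[i]
  r0 <- r[i - 1]; r1 <- r[i]
  if (!is.finite(r0)) return(c(z[1], z0))
  c(z[1], z0 + (threshold - r0) / (r1 - r0) * (z1 - z0))
}

#' Merge report for a simulated scenario
#'
#' Bundles the PVR-threshold merge depth, the sparing range, and the
#' scatter-free geometric onset, in both reference frames ("from the
#' collimator" and "from the phantom surface" are both in common use).
#'
#' @param grid a `DoseGrid`
#' @param config its [beamline_config()]
#' @param merge_threshold PVR threshold for merging (default 1.2)
#' @param sparing_threshold PVR threshold for sparing (default 3)
#' @return a `MergeReport` list
#' @export
merge_report <- function(grid, config, merge_threshold = 1.2,
                         sparing_threshold = 3) {
  curve <- pvr_curve(grid, config)
  md <- merge_depth(curve, merge_threshold)
  sr <- sparing_depth_range(curve, sparing_threshold)
  structure(list(
    merge_depth_mm = as.numeric(md),
    merge_depth_from_surface_mm = as.numeric(md) - config$gap_mm,
    sparing_range_mm = sr,
    geometric_onset_mm = geometric_merge_onset(config),
    merge_threshold = merge_threshold,
    sparing_threshold = sparing_threshold,
    pvr_curve = curve), class = "MergeReport")
}

#' @export
print.MergeReport <- function(x, ...) {
  cat(sprintf("<MergeReport> merge (PVR<=%.2g) at %.1f mm from collimator",
              x$merge_threshold, x$merge_depth_mm))
  cat(sprintf(" (%.1f mm in tissue)\n", x$merge_depth_from_surface_mm))
  cat(sprintf("  sparing (PVR>=%.2g): %.1f-%.1f mm; geometric onset %.1f mm\n",
              x$sparing_threshold, x$sparing_range_mm[1], x$sparing_range_mm[2],
              x$geometric_onset_mm))
  invisible(x)
}

#' Valley-minimum biologic dose map
#'
#' For each voxel, the biologic dose is the minimum physical dose within a
#' disk of `radius_um` around it (the nearest-valley dose available for
#' repopulation); equivalently a morphological minimum filter. With the
#' default 1-mm depth voxels the 350-um disk reduces to a +/-350-um lateral
#' window within each depth row, since the collapsed slit-length direction
#' is dose-invariant.
#'
#' @param grid a `DoseGrid`
#' @param radius_um search radius in micrometres (default 350)
#' @return a `DoseGrid` with the filtered dose (biologic dose <= physical
#'   dose everywhere, equality for laterally uniform fields)
#' @export
biologic_dose_map <- function(grid, radius_um = 350) {
  r_mm <- radius_um / 1000
  if (r_mm < grid$dx_mm)
    stop("search radius smaller than one lateral voxel", call. = FALSE)
  di_max <- floor(r_mm / grid$dx_mm)
  dj_max <- floor(r_mm / grid$dz_mm)
  out <- grid$dose
  nx <- nrow(out); nz <- ncol(out)
  for (dj in -dj_max:dj_max) {
    max_di <- floor(sqrt(max(r_mm^2 - (dj * grid$dz_mm)^2, 0)) / grid$dx_mm)
    for (di in -max_di:max_di) {
      if (di == 0 && dj == 0) next
      src_i <- (1 + max(0, di)):(nx + min(0, di))
      dst_i <- src_i - di
      src_j <- (1 + max(0, dj)):(nz + min(0, dj))
      dst_j <- src_j - dj
      out[dst_i, dst_j] <- pmin(out[dst_i, dst_j],
                                grid$dose[src_i, src_j, drop = FALSE])
    }
  }
  g <- grid
  g$dose <- out
  g$meta$biologic_radius_um <- radius_um
  g
}

#' Valley-dose depth curve
#'
#' Valley dose versus depth; beyond the merge depth the valley is taken as
#' the mean dose over the array core (the beams have merged, so valley and
#' mean coincide by definition).
#' @param grid a `DoseGrid`
#' @param config its [beamline_config()]
#' @param interior_margin as in [pvr_curve()]
#' @return a `DepthDoseCurve` data frame (`depth_mm`, `dose`, `label`)
#' @export
valley_depth_curve <- function(grid, config, interior_margin = 2) {
  curve <- pvr_curve(grid, config, interior_margin)
  md <- merge_depth(curve)
  dose <- curve$valley
  if (!is.na(md)) {
    merged <- curve$depth_mm >= md
    for (i in which(merged)) {
      w <- .pv_windows(config, curve$depth_mm[i], interior_margin)
      core <- abs(grid$x_mm) <= max(abs(w$centers)) + w$halfw
      dose[i] <- mean(grid$dose[core, i])
    }
  }
  structure(data.frame(depth_mm = curve$depth_mm, dose = dose,
                       label = "valley"),
            class = c("DepthDoseCurve", "data.frame"))
}

#' Central-axis depth-dose curve of a grid
#' @param grid a `DoseGrid`
#' @param half_width_mm lateral half-width to average (default 2 mm)
#' @param label curve label
#' @export
depth_dose_curve <- function(grid, half_width_mm = 2, label = "open-beam") {
  sel <- abs(grid$x_mm) <= half_width_mm
  structure(data.frame(depth_mm = grid$z_mm,
                       dose = colMeans(grid$dose[sel, , drop = FALSE]),
                       label = label),
            class = c("DepthDoseCurve", "data.frame"))
}

#' 80-20 penumbra width of a lateral profile
#'
#' Plateau dose is the mean over the central half of the field (field =
#' region above 50% of the profile maximum). On each edge the lateral
#' distance between the 80% and 20% of-plateau crossings is found by linear
#' interpolation; the two edges are averaged.
#'
#' @param profile a [lateral_profile()]
#' @return penumbra width in mm
#' @export
penumbra_80_20 <- function(profile) {
  x <- profile$position_mm
  d <- profile$dose
  above <- which(d >= max(d) * 0.5)
  if (!length(above)) stop("no field edge found", call. = FALSE)
  lo <- x[above[1]]; hi <- x[above[length(above)]]
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2
  plateau <- mean(d[x >= mid - half / 2 & x <= mid + half / 2])
  cross <- function(xx, dd, level) {
    # first crossing of `level` walking outward from the plateau
    idx <- which(dd[-1] < level & dd[-length(dd)] >= level)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    xx[i] + (dd[i] - level) / (dd[i] - dd[i + 1]) * (xx[i + 1] - xx[i])
  }
  right <- x >= mid
  r80 <- cross(x[right], d[right], 0.8 * plateau)
  r20 <- cross(x[right], d[right], 0.2 * plateau)
  leftx <- rev(-x[x <= mid]); leftd <- rev(d[x <= mid])
  l80 <- cross(leftx, leftd, 0.8 * plateau)
  l20 <- cross(leftx, leftd, 0.2 * plateau)
  widths <- c(r20 - r80, l20 - l80)
  widths <- widths[is.finite(widths)]
  if (!length(widths)) stop("no 80/20 crossings found", call. = FALSE)
  mean(widths)
}

#' Half-value layer from measured depth doses
#'
#' Log-linear least-squares fit ln(D) = ln(D0) - mu z over all points;
#' HVL = ln 2 / mu. Per-interval HVLs between consecutive points are
#' attached as an attribute.
#'
#' @param depth_cm depths (cm)
#' @param dose doses (> 0, any consistent unit)
#' @return HVL in cm, with attribute `per_interval_cm`
#' @export
hvl_from_depth_doses <- function(depth_cm, dose) {
  if (length(depth_cm) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  fit <- stats::lm(log(dose) ~ depth_cm)
  mu <- -stats::coef(fit)[[2]]
  per <- diff(depth_cm) * log(2) / -diff(log(dose))
  structure(log(2) / mu, per_interval_cm = per)
}

#' Dose dilution factor of a minibeam array
#'
#' The factor by which segmenting a solid beam into minibeams reduces the
#' area-averaged entrance dose: pitch / width.
#' @param aperture_width_mm beam (aperture) width, mm
#' @param pitch_mm on-center spacing, mm (>= width)
#' @export
dilution_factor <- function(aperture_width_mm, pitch_mm) {
  if (aperture_width_mm <= 0 || aperture_width_mm > pitch_mm)
    stop("need 0 < width <= pitch", call. = FALSE)
  pitch_mm / aperture_width_mm
}

#' Normalize depth-dose curves to coincide at a depth
#'
#' Scales each curve so its (interpolated) value at `depth_mm` is 1, the
#' convention used to compare beams at the center of a target.
#' @param curves a `DepthDoseCurve` or list of them
#' @param depth_mm normalization depth (mm)
#' @return list of rescaled curves (or a single curve if one was given)
#' @export
normalize_at <- function(curves, depth_mm) {
  single <- inherits(curves, "DepthDoseCurve")
  if (single) curves <- list(curves)
  out <- lapply(curves, function(cv) {
    v <- stats::approx(cv$depth_mm, cv$dose, xout = depth_mm)$y
    if (!is.finite(v) || v <= 0)
      stop("curve undefined or zero at the normalization depth", call. = FALSE)
    cv$dose <- cv$dose / v
    cv
  })
  if (single) out[[1]] else out
}

#' Maximum deviation between the mean-normalized half-profiles of a grid
#'
#' Used for half-slab scenarios (e.g. a cortical-bone slab covering x > 0):
#' each half of the lateral profile at `depth_mm` is normalized to its own
#' mean, the x > 0 half is mirrored onto the x < 0 half, and the maximum
#' percent difference over the array core is returned.
#'
#' @param grid a `DoseGrid`
#' @param config its [beamline_config()]
#' @param depth_mm depth at which to compare (mm from collimator exit)
#' @param core_half_mm lateral half-extent compared (default: interior of the
#'   projected array)
#' @param bin_mm re-binning width; defaults to one projected pitch, since at
#'   and beyond the merge depth sub-pitch structure is the residual minibeam
#'   pattern itself, not the slab effect being measured
#' @return maximum percent difference between the normalized halves
#' @export
half_profile_deviation <- function(grid, config, depth_mm,
                                   core_half_mm = NULL, bin_mm = NULL) {
  if (is.null(bin_mm))
    bin_mm <- projected_geometry(config, depth_mm)$pitch_mm
  prof <- lateral_profile(grid, depth_mm)
  if (is.null(core_half_mm)) {
    centers <- beam_centers_at(config, depth_mm)
    n <- length(centers)
    core_half_mm <- abs(centers[max(1, n - 2)])
  }
  bins <- seq(0, core_half_mm, by = bin_mm)
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  bin_mean <- function(xx, dd) {
    g <- cut(xx, bins, labels = FALSE)
    as.numeric(tapply(dd, factor(g, levels = seq_along(mids)), mean))
  }
  left <- bin_mean(-prof$position_mm[prof$position_mm < 0],
                   prof$dose[prof$position_mm < 0])
  right <- bin_mean(prof$position_mm[prof$position_mm > 0],
                    prof$dose[prof$position_mm > 0])
  left <- left / mean(left, na.rm = TRUE)
  right <- right / mean(right, na.rm = TRUE)
  max(abs(left - right) / pmax((left + right) / 2, 1e-12) * 100, na.rm = TRUE)
}

#' Parametric 6-MV percentage-depth-dose fixture
#'
#' A packaged analytic stand-in for a measured 6-MV linac depth-dose curve
#' (10 x 10 cm2 field, 100-cm SSD): a quadratic build-up to d_max = 15 mm
#' followed by exponential attenuation at 4.7%/cm. Fixture, not simulated;
#' used only for comparison plots and ratios.
#'
#' @param depth_mm depths (mm), vectorized
#' @return a `DepthDoseCurve` labeled `"fixture-6MV"`
#' @export
pdd_6mv_fixture <- function(depth_mm = seq(0, 150, by = 1)) {
  zmax <- 15
  mu <- 0.00473                       # 1/mm
  d <- ifelse(depth_mm < zmax,
              1 - 0.45 * ((zmax - depth_mm) / zmax)^1.8,
              exp(-mu * (depth_mm - zmax)))
  structure(data.frame(depth_mm = depth_mm, dose = d, label = "fixture-6MV"),
            class = c("DepthDoseCurve", "data.frame"))
}

#' Parametric measured lateral-falloff fixtures
#'
#' Error-function-edged solid-beam profiles whose 80-20 falloffs reproduce
#' the film-measured values for a 220-kVp orthovoltage cone beam (0.40 mm)
#' and a 6-MV linac cone beam (2.2 mm). Fixtures, not simulated.
#'
#' @param beam `"220kVp"` or `"6MV"`
#' @param field_mm field diameter (default 15)
#' @param dx_mm sample spacing (default 0.02)
#' @return a `LateralProfile`
#' @export
fixture_lateral_profile <- function(beam = c("220kVp", "6MV"), field_mm = 15,
                                    dx_mm = 0.02) {
  beam <- match.arg(beam)
  falloff <- c("220kVp" = 0.40, "6MV" = 2.2)[[beam]]
  sigma <- falloff / (stats::qnorm(0.8) - stats::qnorm(0.2))
  x <- seq(-field_mm, field_mm, by = dx_mm)
  d <- stats::pnorm((field_mm / 2 - abs(x)) / sigma)
  structure(data.frame(position_mm = x, dose = d),
            depth_mm = NA_real_, window_mm = NA_real_, fixture = beam,
            class = c("LateralProfile", "data.frame"))
}
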