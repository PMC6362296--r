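#' Voxelized x-z phantom
#'
#' A rectangular phantom cross-section, laterally centered on the beam axis,
#' starting at the phantom surface (which sits `gap_mm` beyond the collimator
#' exit; see [beamline_config()]). A background material fills the phantom;
#' rectangular inserts (e.g. a cortical-bone half-slab) override it.
#'
#' @param lateral_mm total lateral extent (mm)
#' @param depth_mm total depth extent (mm)
#' @param dx_mm lateral voxel size (mm), default 0.05 (50 um)
#' @param dz_mm depth voxel size (mm), default 1 (1000 um)
#' @param material background material name
#' @param inserts list of inserts, each
#'   `list(material =, x_mm = c(lo, hi), z_mm = c(lo, hi))` with `z_mm`
#'   measured from the phantom surface; use `-Inf`/`Inf` for open bounds
#' @param density optional background density override (g/cm3)
#' @return a `Phantom` object
#' @export
phantom <- function(lateral_mm = 60, depth_mm = 100, dx_mm = 0.05,
                    dz_mm = 1, material = "water", inserts = list(),
                    density = NULL) {
  stopifnot(dx_mm > 0, dz_mm > 0, lateral_mm > 0, depth_mm > 0)
  nx <- round(lateral_mm / dx_mm)
  nz <- round(depth_mm / dz_mm)
  mats <- c(material, vapply(inserts, function(i) i$material, ""))
  mat_objs <- lapply(mats, .material_fn)  # resolve aliases, validate
  if (!is.null(density))
    mat_objs[[1]] <- .material_fn(material, density = density)
  names(mat_objs) <- vapply(mat_objs, function(m) m$name, "")
  mat_objs <- mat_objs[!duplicated(names(mat_objs))]
  x <- (seq_len(nx) - 0.5) * dx_mm - lateral_mm / 2
  z <- (seq_len(nz) - 0.5) * dz_mm
  id <- matrix(1L, nx, nz)
  for (ins in inserts) {
    nm <- .material_fn(ins$material)$name
    mid <- match(nm, names(mat_objs))
    xin <- x >= ins$x_mm[1] & x <= ins$x_mm[2]
    zin <- z >= ins$z_mm[1] & z <= ins$z_mm[2]
    id[xin, zin] <- mid
  }
  structure(list(nx = nx, nz = nz, dx_mm = dx_mm, dz_mm = dz_mm,
                 lateral_mm = lateral_mm, depth_mm = depth_mm,
                 x_mm = x, z_surface_mm = z, materials = mat_objs,
                 material_id = id), class = "Phantom")
}

#' @export
print.Phantom <- function(x, ...) {
  cat(sprintf("<Phantom> %g x %g mm (%d x %d voxels of %g x %g mm), %s",
              x$lateral_mm, x$depth_mm, x$nx, x$nz, x$dx_mm, x$dz_mm,
              names(x$materials)[1]))
  if (length(x$materials) > 1)
    cat(" + inserts:", paste(names(x$materials)[-1], collapse = ", "))
  cat("\n")
  invisible(x)
}
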