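# En-face reconstruction: mean-value fundus images, orientation
# normalisation, total-retina thickness and ETDRS sector means.

#' OCT volume container
#'
#' @param intensity 3-D numeric array indexed `[x, y, z]`: x runs
#'   temporal-to-nasal for right eyes, y superior-to-inferior, z is depth.
#' @param voxel_scale Micrometres per voxel along x, y, z.
#' @param laterality `"left"` or `"right"`.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, voxel_scale, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (length(dim(intensity)) != 3) stop("intensity must be a 3-D array")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  stopifnot(length(voxel_scale) == 3, all(voxel_scale > 0))
  structure(list(intensity = intensity,
                 voxel_scale = as.numeric(voxel_scale),
                 laterality = laterality),
            class = "oct_volume")
}

#' Layer boundary surfaces container
#'
#' @param depths 3-D numeric array `[x, y, boundary]` of boundary depths in
#'   µm; the boundary dimension must carry the eight [surface_names()] in
#'   order and boundaries must not cross.
#' @return An object of class `layer_surfaces`.
#' @export
layer_surfaces <- function(depths) {
  if (length(dim(depths)) != 3 || dim(depths)[3] != 8)
    stop("depths must be an [x, y, 8] array")
  dimnames(depths)[[3]] <- surface_names()
  for (i in 1:7) {
    if (any(depths[, , i + 1] < depths[, , i]))
      stop("boundary ordering violated between ", surface_names()[i],
           " and ", surface_names()[i + 1])
  }
  structure(list(depths = depths), class = "layer_surfaces")
}

#' Mean value fundus image container
#'
#' @param values 2-D numeric matrix over the `(x, y)` en-face grid.
#' @param layer Layer name.
#' @param laterality `"left"` or `"right"`.
#' @param normalised Logical; `TRUE` once the image is in right-eye
#'   orientation (see [normalise_orientation()]).
#' @return An object of class `mvf_image`.
#' @export
mvf_image <- function(values, layer, laterality = "right", normalised = FALSE) {
  stopifnot(is.matrix(values))
  structure(list(values = values, layer = layer,
                 laterality = laterality, normalised = isTRUE(normalised)),
            class = "mvf_image")
}

# Depth voxel index range for a half-open [upper, lower) µm segment:
# voxel k (1-based) starts at (k-1)*dz; it is included iff its start lies
# in [upper, lower), i.e. k-1 >= upper/dz and k-1 < lower/dz. A small
# epsilon guards against floating-point jitter on exact boundaries.
segment_voxels <- function(upper, lower, dz, nz) {
  eps <- 1e-9
  k_first <- pmax(ceiling(upper / dz - eps) + 1, 1)
  k_last <- pmin(ceiling(lower / dz - eps), nz)
  list(first = k_first, last = k_last)
}

# Cumulative intensity along depth, reusable across the six layers of one
# volume.
depth_cumsum <- function(volume) {
  v <- volume$intensity
  nz <- dim(v)[3]
  if (nz >= 2) for (k in 2:nz) v[, , k] <- v[, , k] + v[, , k - 1]
  v
}

#' Compute a mean value fundus image
#'
#' The value at each en-face position is the arithmetic mean of the A-scan
#' intensities between the layer's two boundary interfaces (half-open
#' `[upper, lower)` in depth). A layer of zero voxel extent at a position
#' yields the single voxel at the upper boundary.
#'
#' @param volume An [oct_volume()].
#' @param surfaces A [layer_surfaces()] covering the same grid.
#' @param layer One of [retinal_layers()].
#' @param .depth_cumsum Optional precomputed cumulative-intensity array
#'   (internal, lets callers share it across the six layers).
#' @return An [mvf_image()] in the eye's native orientation.
#' @export
compute_mvf <- function(volume, surfaces, layer, .depth_cumsum = NULL) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "layer_surfaces"))
  layer <- match.arg(layer, retinal_layers())
  li <- match(layer, retinal_layers())
  d <- surfaces$depths
  dims <- dim(volume$intensity)
  if (!all(dim(d)[1:2] == dims[1:2]))
    stop("surfaces do not cover the volume grid")
  upper <- matrix(d[, , li], dims[1], dims[2])
  lower <- matrix(d[, , li + 1L], dims[1], dims[2])
  bad <- which(lower < upper, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("crossing boundaries for layer %s at (x=%d, y=%d)",
                 layer, bad[1, 1], bad[1, 2]))
  dz <- volume$voxel_scale[3]; nz <- dims[3]
  nx <- dims[1]; ny <- dims[2]
  sv <- segment_voxels(upper, lower, dz, nz)
  k1 <- as.vector(sv$first); k2 <- as.vector(sv$last)
  cs <- if (is.null(.depth_cumsum)) depth_cumsum(volume) else .depth_cumsum
  xi <- rep(seq_len(nx), ny); yi <- rep(seq_len(ny), each = nx)
  has <- k2 >= k1
  vals <- numeric(nx * ny)
  if (any(has)) {
    s2 <- cs[cbind(xi[has], yi[has], k2[has])]
    s1 <- numeric(sum(has))
    pos <- k1[has] > 1
    if (any(pos))
      s1[pos] <- cs[cbind(xi[has][pos], yi[has][pos], k1[has][pos] - 1L)]
    vals[has] <- (s2 - s1) / (k2[has] - k1[has] + 1)
  }
  if (any(!has)) {
    # zero-extent layer: single voxel at the upper boundary
    kb <- pmin(pmax(floor(as.vector(upper) / dz + 1e-9) + 1, 1), nz)
    vals[!has] <- volume$intensity[cbind(xi, yi, kb)][!has]
  }
  mvf_image(matrix(vals, nx, ny), layer, volume$laterality, normalised = FALSE)
}

#' Normalise an MVF image to right-eye orientation
#'
#' Left-eye images are mirrored about the vertical (superior-inferior)
#' axis, i.e. the temporal-nasal x axis is reversed; right-eye images are
#' returned unchanged. Either way the image is flagged as normalised.
#'
#' @param image An [mvf_image()].
#' @return The normalised [mvf_image()].
#' @export
normalise_orientation <- function(image) {
  stopifnot(inherits(image, "mvf_image"))
  if (image$normalised)
    stop("image is already laterality-normalised")
  if (image$laterality == "left")
    image$values <- image$values[rev(seq_len(nrow(image$values))), , drop = FALSE]
  image$normalised <- TRUE
  image
}

#' Total retinal thickness map
#'
#' Pointwise depth difference from the inner limiting membrane to the top
#' of the RPE, in µm.
#'
#' @param surfaces A [layer_surfaces()].
#' @return A numeric `(x, y)` matrix of thicknesses (µm).
#' @export
compute_total_thickness <- function(surfaces) {
  stopifnot(inherits(surfaces, "layer_surfaces"))
  surfaces$depths[, , "RPE_top"] - surfaces$depths[, , "ILM"]
}

#' Single-layer thickness map
#'
#' @param surfaces A [layer_surfaces()].
#' @param layer One of [retinal_layers()].
#' @return A numeric `(x, y)` matrix of thicknesses (µm).
#' @export
layer_thickness <- function(surfaces, layer) {
  stopifnot(inherits(surfaces, "layer_surfaces"))
  li <- match(match.arg(layer, retinal_layers()), retinal_layers())
  surfaces$depths[, , li + 1L] - surfaces$depths[, , li]
}

# Sector label of each pixel: "" outside the grid radii. Right-eye
# orientation: temporal = low x, nasal = high x, superior = low y,
# inferior = high y. Quadrant boundaries on the +-45 degree diagonals
# (|dx| >= |dy| goes to the horizontal quadrants).
etdrs_sector_labels <- function(nx, ny, voxel_scale, fovea_centre) {
  dx <- (seq_len(nx) - fovea_centre[1]) * voxel_scale[1]
  dy <- (seq_len(ny) - fovea_centre[2]) * voxel_scale[2]
  DX <- matrix(dx, nx, ny); DY <- matrix(dy, nx, ny, byrow = TRUE)
  r <- sqrt(DX^2 + DY^2)
  horiz <- abs(DX) >= abs(DY)
  quad <- ifelse(horiz, ifelse(DX < 0, "temporal", "nasal"),
                 ifelse(DY < 0, "superior", "inferior"))
  ring <- ifelse(r <= 500, "central",
                 ifelse(r <= 1500, "inner", ifelse(r <= 3000, "outer", "")))
  out <- ifelse(ring == "central", "central",
                ifelse(ring == "", "", paste(quad, ring, sep = "_")))
  matrix(out, nx, ny)
}

#' ETDRS sector mean thickness
#'
#' Mean thickness in the nine ETDRS sectors: the central subfield is the
#' disc of radius 500 µm around the fovea, the inner sectors are the
#' 500-1500 µm annulus and the outer sectors the 1500-3000 µm annulus,
#' each annulus split into temporal/nasal/superior/inferior quadrants by
#' the +-45 degree diagonals. Temporal/nasal assignment assumes right-eye
#' orientation.
#'
#' @param thickness Numeric `(x, y)` thickness map (µm).
#' @param voxel_scale Micrometres per pixel along x and y (length >= 2).
#' @param fovea_centre `(x, y)` pixel coordinates of the fovea; defaults
#'   to the grid centre.
#' @return Named numeric vector of nine sector means (µm).
#' @export
etdrs_sectors <- function(thickness, voxel_scale, fovea_centre = NULL) {
  stopifnot(is.matrix(thickness))
  nx <- nrow(thickness); ny <- ncol(thickness)
  if (is.null(fovea_centre)) fovea_centre <- c((nx + 1) / 2, (ny + 1) / 2)
  if (nx * voxel_scale[1] < 6000 - voxel_scale[1] ||
      ny * voxel_scale[2] < 6000 - voxel_scale[2])
    stop("grid does not cover a 3000 µm radius around the fovea")
  lab <- etdrs_sector_labels(nx, ny, voxel_scale, fovea_centre)
  sectors <- c("central",
               paste(rep(c("nasal", "temporal", "superior", "inferior"), 2),
                     rep(c("inner", "outer"), each = 4), sep = "_"))
  vapply(sectors, function(s) mean(thickness[lab == s]), 0)
}

#' Per-eye ETDRS thickness sectors
#'
#' Convenience wrapper computing [compute_total_thickness()] then
#' [etdrs_sectors()] for one eye record, after mirroring left-eye maps to
#' right-eye orientation so that temporal/nasal labels are consistent.
#'
#' @param eye An `eye_record` from [generate_cohort()].
#' @return Named numeric vector of nine sector means (µm).
#' @export
eye_thickness_sectors <- function(eye) {
  tk <- compute_total_thickness(eye$surfaces)
  if (eye$laterality == "left") tk <- tk[rev(seq_len(nrow(tk))), , drop = FALSE]
  etdrs_sectors(tk, eye$volume$voxel_scale)
}
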