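#' Pair an intensity raster with its segmentation labels
#'
#' Bundles a 2D or 3D intensity array with a co-registered integer label
#' array. Label 0 is background; objects carry labels >= 1. For 3D data the
#' third array dimension is treated as the polar (z) axis of the spherical
#' projection; for 2D data angles are measured from the first axis towards
#' the second.
#'
#' @param intensity Numeric array (2D matrix or 3D array).
#' @param labels Integer-valued array of the same shape; 0 = background.
#' @return A `labeled_image` object.
#' @examples
#' img <- labeled_image(array(runif(8^3), c(8, 8, 8)),
#'                      array(1L, c(8, 8, 8)))
#' img
#' @export
labeled_image <- function(intensity, labels) {
  if (is.null(dim(intensity))) abort("`intensity` must be a 2D or 3D array")
  if (!identical(dim(intensity), dim(labels))) {
    abort("`intensity` and `labels` must have identical dimensions")
  }
  nd <- length(dim(intensity))
  if (!nd %in% c(2L, 3L)) abort("only 2D and 3D rasters are supported")
  if (any(labels < 0) || any(labels != round(labels))) {
    abort("`labels` must contain non-negative integers")
  }
  structure(
    list(intensity = intensity, labels = labels, ndim = nd),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  labs <- setdiff(unique(as.vector(x$labels)), 0)
  cat(sprintf(
    "<labeled_image> %dD, dims %s, %d object label(s)\n",
    x$ndim, paste(dim(x$intensity), collapse = "x"), length(labs)
  ))
  invisible(x)
}

#' Crop one labeled object to its bounding box
#'
#' Returns the tight bounding box of `label` in the label raster, together
#' with the binary mask of that label inside the crop. Intensity outside the
#' mask is retained in the crop; masking happens after resampling in
#' [rescale_to_cube()].
#'
#' @param image A [labeled_image()].
#' @param label Positive integer label to extract.
#' @return A list with `intensity` (numeric array), `mask` (integer array of
#'   0/1), `label`, and `size_pixels` (voxel count of the label at original
#'   resolution).
#' @export
extract_object <- function(image, label) {
  stopifnot(inherits(image, "labeled_image"))
  label <- as.integer(label)
  hit <- image$labels == label
  if (!any(hit)) {
    abort(sprintf("label %s not found in label image", format(label)),
          class = "sphtex_label_not_found")
  }
  idx <- which(hit, arr.ind = TRUE)
  ranges <- lapply(seq_len(ncol(idx)), function(a) {
    range(idx[, a])
  })
  slices <- lapply(ranges, function(r) r[1]:r[2])
  crop_int <- do.call(`[`, c(list(image$intensity), slices, list(drop = FALSE)))
  crop_hit <- do.call(`[`, c(list(hit), slices, list(drop = FALSE)))
  mask <- array(0L, dim(crop_hit))
  mask[crop_hit] <- 1L
  list(
    intensity = array(as.numeric(crop_int), dim(crop_int)),
    mask = mask,
    label = label,
    size_pixels = sum(hit)
  )
}

#' Resample an object crop to a standard cube
#'
#' Stretches each axis of the crop independently to `side` samples: intensity
#' with multilinear (bilinear/trilinear) interpolation, the mask with
#' nearest-neighbor lookup so it stays binary. Intensity outside the
#' resampled mask is set to 0. The per-axis stretch is what makes downstream
#' descriptors tolerant of anisotropic voxel sizes.
#'
#' @param object A list with `intensity` and `mask` arrays (as returned by
#'   [extract_object()]), or the two arrays given separately via `mask`.
#' @param mask Optional binary array when `object` is a bare intensity array.
#' @param side Cube side length (default 80).
#' @return An `object_cube`: list with `values` (masked intensity, all axes of
#'   length `side`), `mask` (integer 0/1), `ndim`, `label`, `size_pixels`.
#' @export
rescale_to_cube <- function(object, mask = NULL, side = 80) {
  if (is.null(mask)) {
    intensity <- object$intensity
    mask <- object$mask
    label <- object$label %||% NA_integer_
    size_pixels <- object$size_pixels %||% sum(mask != 0)
  } else {
    intensity <- object
    label <- NA_integer_
    size_pixels <- sum(mask != 0)
  }
  stopifnot(side >= 2, identical(dim(intensity), dim(mask)))
  nd <- length(dim(intensity))
  if (!nd %in% c(2L, 3L)) abort("crop must be 2D or 3D")
  d_in <- dim(intensity)
  pad <- function(a) array(as.numeric(a), c(dim(a), rep(1L, 3 - nd)))
  odim <- as.integer(c(rep(side, nd), rep(1L, 3 - nd)))
  vals <- cpp_resample(pad(intensity), odim, nearest = FALSE)
  msk <- cpp_resample(pad(mask), odim, nearest = TRUE)
  msk <- array(as.integer(msk != 0), odim)
  if (sum(msk) == 0) {
    abort("degenerate object: mask is empty after resampling",
          class = "sphtex_degenerate_object")
  }
  vals[msk == 0] <- 0
  final_dim <- rep(as.integer(side), nd)
  structure(
    list(
      values = array(vals, final_dim),
      mask = array(msk, final_dim),
      ndim = nd, side = as.integer(side),
      label = label, size_pixels = size_pixels
    ),
    class = "object_cube"
  )
}

#' @export
print.object_cube <- function(x, ...) {
  cat(sprintf(
    "<object_cube> %dD side %d, %d mask voxel(s), label %s\n",
    x$ndim, x$side, sum(x$mask), format(x$label)
  ))
  invisible(x)
}

# cube center in 0-based coordinates, (S - 1) / 2 per axis
cube_center <- function(cube) (dim(cube$values) - 1) / 2

check_center_in_mask <- function(cube) {
  ci <- round(cube_center(cube)) + 1
  inside <- do.call(`[`, c(list(cube$mask), as.list(ci))) != 0
  if (!inside) {
    abort("centroid outside mask: the cube-center sample is background",
          class = "sphtex_centroid_outside")
  }
  invisible(TRUE)
}

new_sph_projection <- function(values, grid, normalized = FALSE) {
  structure(
    list(
      values = values,
      nlat = grid$nlat, nlon = grid$nlon,
      x = grid$x, w = grid$w, colat = grid$colat, lon = grid$lon,
      normalized = normalized
    ),
    class = "sph_projection"
  )
}

new_circ_projection <- function(values, angles, normalized = FALSE) {
  structure(
    list(values = values, n = length(values), angles = angles,
         normalized = normalized),
    class = "circ_projection"
  )
}

#' @export
print.sph_projection <- function(x, ...) {
  cat(sprintf(
    "<sph_projection> %d x %d (colat x lon)%s, range [%.3g, %.3g]\n",
    x$nlat, x$nlon, if (x$normalized) ", normalized" else "",
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.circ_projection <- function(x, ...) {
  cat(sprintf(
    "<circ_projection> %d angles%s, range [%.3g, %.3g]\n",
    x$n, if (x$normalized) ", normalized" else "",
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Spherical mean-intensity projection of a 3D object cube
#'
#' Casts one ray per grid direction from the geometric center of the cube and
#' averages the interpolated intensity along the ray until it first leaves
#' the mask or the cube (first-exit rule; concave re-entries beyond the first
#' exit are ignored). Intensity is interpolated multilinearly over in-mask
#' voxels only (weights renormalized at the mask boundary), so constant
#' objects project to exactly constant maps and the projection is exactly
#' affine in the intensity. Directions follow a Gauss-Legendre quadrature grid in
#' colatitude and a uniform grid in longitude, so the projection can be
#' analyzed with exact band-limited spherical-harmonic quadrature.
#'
#' @param cube A 3D `object_cube` whose center sample lies inside the mask.
#' @param nlat,nlon Grid size (default 251 x 512).
#' @param step Ray sampling step in voxel units (default 0.5).
#' @return A `sph_projection` with the `nlat` x `nlon` value matrix and the
#'   grid geometry (colatitudes, quadrature weights, longitudes).
#' @export
spherical_project <- function(cube, nlat = 251, nlon = 512, step = 0.5) {
  stopifnot(inherits(cube, "object_cube"))
  if (cube$ndim != 3) {
    abort("spherical_project needs a 3D cube; use circular_project for 2D data")
  }
  check_center_in_mask(cube)
  g <- sht_grid(nlat, nlon)
  st <- sin(g$colat)
  d1 <- outer(st, cos(g$lon))
  d2 <- outer(st, sin(g$lon))
  d3 <- matrix(g$x, g$nlat, g$nlon)
  dirs <- cbind(as.vector(d1), as.vector(d2), as.vector(d3))
  v <- cpp_raycast(cube$values, cube$mask, dirs, cube_center(cube), step)
  new_sph_projection(matrix(v, g$nlat, g$nlon), g)
}

#' Circular mean-intensity projection of a 2D object cube
#'
#' The 2D analogue of [spherical_project()]: rays are cast only in the plane,
#' at `n` uniformly spaced angles starting from 0, and averaged with the same
#' first-exit rule.
#'
#' @param cube A 2D `object_cube` whose center sample lies inside the mask.
#' @param n Number of angles (default 251).
#' @param step Ray sampling step in voxel units (default 0.5).
#' @return A `circ_projection` with `n` values and their angles.
#' @export
circular_project <- function(cube, n = 251, step = 0.5) {
  stopifnot(inherits(cube, "object_cube"))
  if (cube$ndim != 2) {
    abort("circular_project needs a 2D cube; use spherical_project for 3D data")
  }
  check_center_in_mask(cube)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  dirs <- cbind(cos(ang), sin(ang), 0)
  d2 <- dim(cube$values)
  vals3 <- array(cube$values, c(d2, 1L))
  mask3 <- array(cube$mask, c(d2, 1L))
  ctr <- c((d2 - 1) / 2, 0)
  v <- cpp_raycast(vals3, mask3, dirs, ctr, step)
  new_circ_projection(v, ang)
}

# area-weighted mean and variance of a projection; spherical projections use
# quadrature weights (so total spectral power equals the variance exactly for
# band-limited maps), circular projections use plain sample statistics
projection_stats <- function(proj, weighting = c("quadrature", "plain")) {
  weighting <- match.arg(weighting)
  if (inherits(proj, "sph_projection")) {
    f <- proj$values
    if (weighting == "quadrature") {
      wt <- proj$w / (2 * proj$nlon) # sums to 1 over the grid
      mu <- sum(wt * rowSums(f))
      v <- sum(wt * rowSums((f - mu)^2))
    } else {
      mu <- mean(f)
      v <- mean((f - mu)^2)
    }
  } else if (inherits(proj, "circ_projection")) {
    mu <- mean(proj$values)
    v <- mean((proj$values - mu)^2)
  } else {
    abort("not a projection object")
  }
  list(mean = mu, var = v)
}

#' Normalize a projection to zero mean and unit variance
#'
#' Standardizes a projection as `(F - mean(F)) / sqrt(var(F))`. For spherical
#' projections the mean and variance are area-weighted with the quadrature
#' weights by default, so Parseval's identity links the unit variance exactly
#' to the total spectral power of band-limited maps; `weighting = "plain"`
#' uses unweighted sample statistics instead. Circular projections always use
#' plain statistics (their angular grid is uniform).
#'
#' @param proj A `sph_projection` or `circ_projection`, not yet normalized.
#' @param weighting `"quadrature"` (default, spherical only) or `"plain"`.
#' @return The projection with standardized values and `normalized = TRUE`.
#' @export
normalize_projection <- function(proj, weighting = c("quadrature", "plain")) {
  weighting <- match.arg(weighting)
  if (isTRUE(proj$normalized)) abort("projection is already normalized")
  st <- projection_stats(proj, weighting)
  # constant up to rounding: spread below ~1e-8 of the value scale
  scale_ref <- max(abs(proj$values))
  if (sqrt(st$var) <= 1e-8 * scale_ref + 1e-300) {
    abort(paste0(
      "zero-variance projection: the texture descriptor is undefined for a ",
      "constant projection (batch callers may map this to an all-zero ",
      "descriptor via the zero-variance policy)"
    ), class = "sphtex_zero_variance")
  }
  proj$values <- (proj$values - st$mean) / sqrt(st$var)
  proj$normalized <- TRUE
  proj
}
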