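#' Seeded 3D Perlin gradient noise
#'
#' Classic gradient-lattice (Perlin) noise on a cubic grid: random unit
#' gradients on a lattice of `periods + 1` nodes per axis, quintic fade
#' interpolation of the corner dot products. `periods` controls the pattern
#' scale: fewer periods give coarser noise. Values are zero at lattice nodes
#' and bounded by \[-1, 1\].
#'
#' @param side Grid side (default 128); must be divisible by `periods`.
#' @param periods Periods of noise along each axis.
#' @param seed Integer seed; the output is a deterministic function of
#'   `(side, periods, seed)`.
#' @return A `side^3` numeric array.
#' @examples
#' v <- perlin_volume(side = 32, periods = 4, seed = 1)
#' range(v)
#' @export
perlin_volume <- function(side = 128, periods = 8, seed = 1L) {
  if (side %% periods != 0) {
    abort("`side` must be divisible by `periods` (gradient-lattice constraint)")
  }
  np <- periods + 1
  G <- withr::with_seed(seed, {
    g <- matrix(rnorm(3 * np^3), ncol = 3)
    g / sqrt(rowSums(g^2))
  })
  co <- (seq_len(side) - 1) * periods / side
  i0 <- floor(co)
  fr <- co - i0
  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  u <- fade(fr)
  n <- side
  I1 <- rep(i0, times = n * n); F1 <- rep(fr, times = n * n); U1 <- rep(u, times = n * n)
  I2 <- rep(rep(i0, each = n), times = n)
  F2 <- rep(rep(fr, each = n), times = n)
  U2 <- rep(rep(u, each = n), times = n)
  I3 <- rep(i0, each = n * n); F3 <- rep(fr, each = n * n); U3 <- rep(u, each = n * n)
  acc <- numeric(n^3)
  for (c3 in 0:1) {
    w3 <- if (c3 == 1) U3 else 1 - U3
    for (c2 in 0:1) {
      w23 <- w3 * (if (c2 == 1) U2 else 1 - U2)
      for (c1 in 0:1) {
        gi <- (I1 + c1) + np * ((I2 + c2) + np * (I3 + c3)) + 1
        dot <- G[gi, 1] * (F1 - c1) + G[gi, 2] * (F2 - c2) + G[gi, 3] * (F3 - c3)
        acc <- acc + w23 * (if (c1 == 1) U1 else 1 - U1) * dot
      }
    }
  }
  array(acc, c(n, n, n))
}

#' Middle slice of a Perlin volume
#'
#' 2D synthetic data is defined as the middle plane of the corresponding 3D
#' Perlin field, so 2D and 3D validation use the same underlying patterns.
#'
#' @inheritParams perlin_volume
#' @return A `side x side` matrix.
#' @export
perlin_slice <- function(side = 128, periods = 8, seed = 1L) {
  perlin_volume(side, periods, seed)[, , side %/% 2]
}

#' Binary test-shape masks
#'
#' Shapes used to probe robustness of the descriptor to object geometry:
#' a centered sphere (diameter `side`), an axis-aligned cone (base diameter
#' and height `side`, axis along the third dimension), and a star-like
#' pointed shape with concave creases: a central sphere of half radius whose
#' eight octant caps are displaced outward along the cube diagonals, leaving
#' eight pointed lobes that reach the full radius. The star is deliberately
#' not star-convex about its center: rays cast from the center towards the
#' gaps between the core and a lobe leave the mask and re-enter it, which is
#' exactly the geometry that is hard to map into a spherical space.
#'
#' @param kind `"sphere"`, `"cone"`, or `"star"`.
#' @param side Cube side (even, default 80).
#' @return A `side^3` integer 0/1 array containing the center voxel.
#' @export
shape_mask <- function(kind = c("sphere", "cone", "star"), side = 80) {
  kind <- match.arg(kind)
  stopifnot(side %% 2 == 0)
  r <- side / 2
  off <- seq_len(side) - (side + 1) / 2 # voxel-center offsets, +-0.5 .. +-(r-0.5)
  o1 <- array(rep(off, times = side * side), rep(side, 3))
  o2 <- array(rep(rep(off, each = side), times = side), rep(side, 3))
  o3 <- array(rep(off, each = side * side), rep(side, 3))
  m <- switch(kind,
    sphere = o1^2 + o2^2 + o3^2 <= r^2,
    cone = {
      t3 <- (slice.index(o3, 3) - 1) / (side - 1)
      o1^2 + o2^2 <= (r * (1 - t3))^2
    },
    star = {
      core <- o1^2 + o2^2 + o3^2 <= (r / 2)^2
      s <- 3 * r / (4 * sqrt(3)) # lobe centers on the cube diagonals
      lobes <- (abs(o1) - s)^2 + (abs(o2) - s)^2 + (abs(o3) - s)^2 <= (r / 4)^2
      core | lobes
    }
  )
  array(as.integer(m), rep(side, 3))
}

#' Volumetric pure-harmonic test pattern
#'
#' An `object_cube` with a spherical mask painted with one real
#' 4pi-normalized spherical-harmonic basis function, evaluated at each
#' voxel's direction from the cube center (radially constant). Projecting
#' such a cube and expanding it should concentrate all power at degree `l`.
#'
#' @param l Harmonic degree (>= 0).
#' @param m Harmonic order, `|m| <= l`; `m >= 0` pairs with `cos(m phi)`,
#'   `m < 0` with `sin(|m| phi)`.
#' @param side Cube side (default 80).
#' @return An `object_cube`.
#' @export
harmonic_pattern <- function(l, m, side = 80) {
  if (l < 0 || abs(m) > l || l != round(l) || m != round(m)) {
    abort("need integer degree l >= 0 and order |m| <= l")
  }
  mask <- shape_mask("sphere", side)
  off <- seq_len(side) - (side + 1) / 2
  o1 <- array(rep(off, times = side * side), rep(side, 3))
  o2 <- array(rep(rep(off, each = side), times = side), rep(side, 3))
  o3 <- array(rep(off, each = side * side), rep(side, 3))
  rho <- sqrt(o1^2 + o2^2 + o3^2)
  colat <- acos(pmin(1, pmax(-1, as.vector(o3 / rho))))
  lon <- atan2(as.vector(o2), as.vector(o1)) %% (2 * pi)
  vals <- array(eval_harmonic(l, m, colat, lon), rep(side, 3))
  vals[mask == 0] <- 0
  structure(
    list(values = vals, mask = mask, ndim = 3L, side = as.integer(side),
         label = NA_integer_, size_pixels = sum(mask)),
    class = "object_cube"
  )
}

#' Clip a cube's intensity to a radial shell
#'
#' Zeroes intensity outside the spherical shell `[r_lo, r_hi]` around the
#' cube center, leaving the mask unchanged. Used to probe how the apparent
#' coarseness of a pattern depends on its distance from the object center:
#' the same pattern looks coarser (longer wavelengths) when confined near
#' the center, because it subtends wider angles there.
#'
#' @param cube An `object_cube`.
#' @param r_lo,r_hi Shell radii in voxels, `0 <= r_lo < r_hi <= side/2`.
#' @return The clipped `object_cube`.
#' @export
clip_to_radius <- function(cube, r_lo, r_hi) {
  stopifnot(inherits(cube, "object_cube"), cube$ndim == 3)
  side <- cube$side
  if (!(r_lo >= 0 && r_lo < r_hi && r_hi <= side / 2)) {
    abort("need 0 <= r_lo < r_hi <= side / 2")
  }
  off <- seq_len(side) - (side + 1) / 2
  o1 <- array(rep(off, times = side * side), rep(side, 3))
  o2 <- array(rep(rep(off, each = side), times = side), rep(side, 3))
  o3 <- array(rep(off, each = side * side), rep(side, 3))
  rho <- sqrt(o1^2 + o2^2 + o3^2)
  shell <- rho >= r_lo & rho <= r_hi
  if (!any(shell & cube$mask != 0)) {
    abort("empty shell: no mask voxels between r_lo and r_hi")
  }
  cube$values[!shell] <- 0
  cube
}

#' Labeled Perlin-noise test object
#'
#' Builds a [labeled_image()] holding one synthetic object: a Perlin-noise
#' field on a `grid_side` cube, labeled by a centered shape mask of side
#' `mask_side`. This reproduces the validation inputs used to characterize
#' the descriptor (noise of a known scale inside a sphere, cone, or star).
#'
#' @param periods Perlin periods across the `grid_side` grid (coarseness:
#'   fewer periods = coarser pattern).
#' @param seed Integer seed.
#' @param kind Shape of the mask (see [shape_mask()]).
#' @param grid_side Side of the noise grid (default 128).
#' @param mask_side Side/diameter of the mask (default 80).
#' @param ndim 3 (default) for a volume, 2 for the middle slice.
#' @return A `labeled_image` with a single object labeled 1.
#' @export
perlin_object <- function(periods = 8, seed = 1L,
                          kind = c("sphere", "cone", "star"),
                          grid_side = 128, mask_side = 80, ndim = 3) {
  kind <- match.arg(kind)
  stopifnot(grid_side >= mask_side)
  vol <- perlin_volume(grid_side, periods, seed)
  msk_small <- shape_mask(kind, mask_side)
  lab <- array(0L, rep(grid_side, 3))
  lo <- (grid_side - mask_side) %/% 2 + 1
  sel <- lo:(lo + mask_side - 1)
  lab[sel, sel, sel] <- msk_small
  if (ndim == 3) {
    labeled_image(vol, lab)
  } else {
    mid <- grid_side %/% 2
    labeled_image(vol[, , mid], lab[, , mid])
  }
}

#' Random band-limited spherical projection
#'
#' Synthesizes a smooth random projection from seeded Gaussian harmonic
#' coefficients with power decaying as `(1 + l)^(-decay)`, band-limited to
#' `lmax`. Band-limited maps make Parseval's identity exact on the
#' quadrature grid, which is what the spectral tests rely on.
#'
#' @param nlat,nlon Grid size.
#' @param lmax Bandlimit (default `nlat - 1`).
#' @param seed Integer seed.
#' @param decay Spectral decay exponent (default 2).
#' @return A `sph_projection` (not normalized).
#' @export
random_projection <- function(nlat = 251, nlon = 512, lmax = nlat - 1,
                              seed = 1L, decay = 2) {
  stopifnot(lmax <= nlat - 1, nlon >= 2 * lmax + 1)
  cf <- withr::with_seed(seed, {
    amp <- matrix(0, lmax + 1, lmax + 1)
    for (l in 0:lmax) amp[l + 1, 1:(l + 1)] <- (1 + l)^(-decay)
    Cm <- matrix(rnorm((lmax + 1)^2), lmax + 1) * amp
    Sm <- matrix(rnorm((lmax + 1)^2), lmax + 1) * amp
    Sm[, 1] <- 0 # sin(0 * phi) terms do not exist
    list(C = Cm, S = Sm, lmax = lmax)
  })
  sh_synthesize(cf, sht_grid(nlat, nlon))
}
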