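#' Spherical-harmonic analysis of a spherical projection
#'
#' Expands a projection sampled on the Gauss-Legendre grid into real
#' 4pi-normalized (geodesy convention) spherical-harmonic coefficients up to
#' bandlimit `L = nlat - 1`. Longitude is reduced by FFT; colatitude by exact
#' Gauss-Legendre quadrature. Under the 4pi convention each basis function
#' has unit mean-square over the sphere, so summed squared coefficients are
#' directly contributions to variance.
#'
#' @param proj A `sph_projection`.
#' @param lmax Bandlimit; defaults to `nlat - 1`. Requires
#'   `nlon >= 2 * lmax + 1`.
#' @return List with matrices `C` and `S` (`(lmax+1) x (lmax+1)`, rows =
#'   degree l, cols = order m; `C` pairs with `cos(m lon)`, `S` with
#'   `sin(m lon)`) and `lmax`.
#' @export
sh_expand <- function(proj, lmax = proj$nlat - 1) {
  stopifnot(inherits(proj, "sph_projection"))
  if (proj$nlon < 2 * lmax + 1) {
    abort(sprintf(
      "nlon = %d is too small for bandlimit %d (need >= %d longitudes)",
      proj$nlon, lmax, 2 * lmax + 1
    ))
  }
  if (lmax > proj$nlat - 1) {
    abort(sprintf("bandlimit %d exceeds nlat - 1 = %d", lmax, proj$nlat - 1))
  }
  G <- mvfft(t(proj$values)) # nlon x nlat; row m+1 = sum_j f exp(-i m lon_j)
  Cm <- matrix(0, lmax + 1, lmax + 1)
  Sm <- matrix(0, lmax + 1, lmax + 1)
  wf <- proj$w / (2 * proj$nlon)
  for (m in 0:lmax) {
    P <- plmbar_m(proj$x, lmax, m)
    gm <- G[m + 1, ]
    Cm[(m:lmax) + 1, m + 1] <- crossprod(P, wf * Re(gm))
    if (m > 0) Sm[(m:lmax) + 1, m + 1] <- crossprod(P, wf * (-Im(gm)))
  }
  list(C = Cm, S = Sm, lmax = lmax)
}

#' Synthesize a spherical projection from harmonic coefficients
#'
#' Inverse of [sh_expand()]: evaluates the real 4pi-normalized harmonic sum
#' on a Gauss-Legendre grid.
#'
#' @param coef List with `C`, `S`, `lmax` as returned by [sh_expand()].
#' @param grid A grid from [sht_grid()]; defaults to
#'   `sht_grid(lmax + 1, 2 * lmax + 2)`.
#' @return A `sph_projection` (not normalized).
#' @export
sh_synthesize <- function(coef, grid = NULL) {
  L <- coef$lmax
  if (is.null(grid)) grid <- sht_grid(L + 1, 2 * L + 2)
  BC <- matrix(0, grid$nlat, L + 1)
  BS <- matrix(0, grid$nlat, L + 1)
  for (m in 0:L) {
    P <- plmbar_m(grid$x, L, m)
    BC[, m + 1] <- P %*% coef$C[(m:L) + 1, m + 1]
    if (m > 0) BS[, m + 1] <- P %*% coef$S[(m:L) + 1, m + 1]
  }
  mm <- outer(grid$lon, 0:L)
  vals <- BC %*% t(cos(mm)) + BS %*% t(sin(mm))
  new_sph_projection(vals, grid)
}

new_degree_spectrum <- function(degree, power, ndim) {
  wl <- rep(NA_real_, length(degree))
  pos <- degree >= 1
  wl[pos] <- degree_to_wavelength(degree[pos], ndim)
  out <- tibble::tibble(degree = as.integer(degree), wavelength = wl,
                        power = power)
  class(out) <- c("degree_spectrum", class(out))
  attr(out, "ndim") <- ndim
  out
}

#' @export
print.degree_spectrum <- function(x, ...) {
  cat(sprintf(
    "<degree_spectrum> %dD, degrees %d..%d, total power (degree >= 1) %.6g\n",
    attr(x, "ndim"), min(x$degree), max(x$degree), sum(x$power[x$degree >= 1])
  ))
  NextMethod()
}

#' Rotationally invariant spherical-harmonic power spectrum
#'
#' Per-degree power `S(l) = sum_m (c_lm^2 + s_lm^2)` of a normalized
#' spherical projection. Summing over orders removes all orientation
#' information, so the spectrum is invariant under rotations of the object.
#' With the 4pi normalization and a zero-mean, unit-variance projection,
#' Parseval's identity makes the total power over degrees >= 1 equal to the
#' variance (1) up to the part of the signal beyond the grid bandlimit.
#'
#' @param proj A normalized `sph_projection`.
#' @param lmax Bandlimit (default `nlat - 1`).
#' @return A `degree_spectrum` tibble with columns `degree`, `wavelength`
#'   (approximate angular wavelength, rad/2pi; `NA` for degree 0), `power`.
#' @export
sh_power_spectrum <- function(proj, lmax = proj$nlat - 1) {
  if (!isTRUE(proj$normalized)) {
    abort("projection must be normalized before spectral analysis")
  }
  cf <- sh_expand(proj, lmax)
  pw <- rowSums(cf$C^2) + rowSums(cf$S^2)
  new_degree_spectrum(0:lmax, pw, ndim = 3L)
}

#' Fourier power spectrum of a circular projection
#'
#' Per-frequency power of a normalized circular projection, scaled so that
#' the total over frequencies k >= 1 equals the sample variance (1 after
#' normalization): `P(k) = 2 |F_k|^2 / n^2` for `0 < k < n/2` (the factor 2
#' merges conjugate frequencies; it is dropped at k = 0 and, for even n, at
#' the Nyquist frequency).
#'
#' @param proj A normalized `circ_projection`.
#' @return A `degree_spectrum` tibble with columns `degree` (frequency k),
#'   `wavelength` (`1/k` rad/2pi), `power`.
#' @export
fourier_power_spectrum <- function(proj) {
  if (!isTRUE(proj$normalized)) {
    abort("projection must be normalized before spectral analysis")
  }
  n <- proj$n
  Fk <- fft(proj$values)
  kmax <- floor(n / 2)
  k <- 0:kmax
  fac <- ifelse(k == 0 | (n %% 2 == 0 & k == n / 2), 1, 2)
  pw <- fac * Mod(Fk[k + 1])^2 / n^2
  new_degree_spectrum(k, pw, ndim = 2L)
}

#' Map harmonic degree to approximate angular wavelength
#'
#' Uses the Jeans relation `lambda = 2 pi R / sqrt(l (l + 1))` on the unit
#' sphere (R = 1), expressed as a fraction of the full circle (rad/2pi), so
#' `lambda(l) = 1 / sqrt(l (l + 1))`. The relation breaks down at the lowest
#' degrees, so the wavelength is pinned to 1 at `l = 1`, where the basis
#' functions have exactly one peak and one valley across the sphere. For 2D
#' (Fourier) spectra the wavelength of frequency k is `1 / k`, sharing the
#' same anchor at k = 1.
#'
#' @param l Harmonic degree(s) (3D) or frequency(ies) (2D); must be >= 1.
#'   Degree 0 is the mean term and has no wavelength.
#' @param ndim 3 (spherical-harmonic degrees, default) or 2 (frequencies).
#' @return Wavelength(s) in rad/2pi units.
#' @examples
#' degree_to_wavelength(c(1, 10, 22))
#' @export
degree_to_wavelength <- function(l, ndim = 3) {
  if (any(l < 1) || any(l != round(l))) {
    abort("degree must be a positive integer: the mean term (l = 0) has no wavelength")
  }
  if (ndim == 3) {
    ifelse(l == 1, 1, 1 / sqrt(l * (l + 1)))
  } else if (ndim == 2) {
    1 / l
  } else {
    abort("ndim must be 2 or 3")
  }
}

# bin index of each log2-wavelength given bin edges decreasing in log2(lambda);
# ties at an interior edge go to the longer-wavelength bin
assign_bins <- function(log2_wl, edges_log2) {
  nbins <- length(edges_log2) - 1
  interior <- edges_log2[2:nbins]
  vapply(log2_wl, function(t) 1L + sum(interior > t), integer(1))
}

#' Bin a power spectrum into log2-spaced wavelength bins
#'
#' Reduces a per-degree (or per-frequency) spectrum to `nbins` values on 21
#' bin edges uniformly spaced in `log2(wavelength)` from the degree-1
#' wavelength (1 rad/2pi) down to the wavelength of the highest degree.
#' Binning is local integration: each degree's power is assigned wholly to
#' the bin containing its wavelength (ties on an edge go to the
#' longer-wavelength bin), so the area under the spectrum is conserved
#' exactly. Degree 0 carries no power after normalization and is excluded.
#'
#' @param spec A `degree_spectrum`.
#' @param nbins Number of bins (default 20).
#' @return A `binned_spectrum` tibble with columns `bin`, `wavelength_hi`,
#'   `wavelength_lo` (bin edges in rad/2pi, decreasing), `value`; attributes
#'   `edges` (21 wavelengths), `ndim`, `label`, `size_pixels`.
#' @export
bin_log2 <- function(spec, nbins = 20) {
  stopifnot(inherits(spec, "degree_spectrum"))
  pos <- spec$degree >= 1
  if (sum(pos) < nbins) {
    abort(sprintf(
      "too few degrees: need at least %d degrees >= 1, got %d",
      nbins, sum(pos)
    ))
  }
  wl <- spec$wavelength[pos]
  pw <- spec$power[pos]
  edges_log2 <- seq(0, log2(min(wl)), length.out = nbins + 1)
  bins <- assign_bins(log2(wl), edges_log2)
  values <- vapply(seq_len(nbins), function(b) sum(pw[bins == b]), numeric(1))
  new_binned_spectrum(values, 2^edges_log2, ndim = attr(spec, "ndim"))
}

new_binned_spectrum <- function(values, edges, ndim,
                                label = NA_integer_, size_pixels = NA_real_) {
  nbins <- length(values)
  out <- tibble::tibble(
    bin = seq_len(nbins),
    wavelength_hi = edges[seq_len(nbins)],
    wavelength_lo = edges[seq_len(nbins) + 1],
    value = values
  )
  class(out) <- c("binned_spectrum", class(out))
  attr(out, "edges") <- edges
  attr(out, "ndim") <- ndim
  attr(out, "label") <- label
  attr(out, "size_pixels") <- size_pixels
  out
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf(
    "<binned_spectrum> %d bins, %dD, label %s, size %s px, sum %.6g\n",
    nrow(x), attr(x, "ndim"), format(attr(x, "label")),
    format(attr(x, "size_pixels")), sum(x$value)
  ))
  NextMethod()
}

#' Spherical Texture descriptor of one labeled object
#'
#' Runs the full pipeline for a single object: bounding-box crop, resampling
#' to a standard cube, spherical (3D) or circular (2D) mean-intensity
#' projection, normalization to zero mean and unit variance, harmonic or
#' Fourier power spectrum, and log2-wavelength binning. The descriptor is
#' reported as the fraction of resolved variance per wavelength bin, so its
#' 20 values sum to 1; this absorbs the negligible part of the projection
#' variance that lies beyond the grid bandlimit.
#'
#' @param image A [labeled_image()].
#' @param label Positive integer label of the object.
#' @param side Cube side for resampling (default 80).
#' @param nlat,nlon Spherical grid (default 251 x 512; 3D only).
#' @param n_circ Number of circular angles (default 251; 2D only).
#' @param nbins Number of wavelength bins (default 20).
#' @param step Ray sampling step in voxels (default 0.5).
#' @param zero_variance `"error"` (default) raises on constant projections;
#'   `"zero"` returns an all-zero descriptor with a warning, for batch runs.
#' @param keep_spectrum If `TRUE`, attach the unbinned `degree_spectrum` as
#'   attribute `"spectrum"`.
#' @return A `binned_spectrum` carrying the object's label and original size
#'   in pixels as attributes.
#' @examples
#' img <- perlin_object(periods = 8, seed = 1)
#' tex <- spherical_texture(img, 1)
#' sum(tex$value)
#' @export
spherical_texture <- function(image, label, side = 80, nlat = 251, nlon = 512,
                              n_circ = 251, nbins = 20, step = 0.5,
                              zero_variance = c("error", "zero"),
                              keep_spectrum = FALSE) {
  zero_variance <- match.arg(zero_variance)
  obj <- extract_object(image, label)
  cube <- rescale_to_cube(obj, side = side)
  res <- tryCatch(
    {
      if (cube$ndim == 3) {
        proj <- spherical_project(cube, nlat = nlat, nlon = nlon, step = step)
        spec <- sh_power_spectrum(normalize_projection(proj))
      } else {
        proj <- circular_project(cube, n = n_circ, step = step)
        spec <- fourier_power_spectrum(normalize_projection(proj))
      }
      binned <- bin_log2(spec, nbins = nbins)
      binned$value <- binned$value / sum(binned$value)
      if (keep_spectrum) attr(binned, "spectrum") <- spec
      binned
    },
    sphtex_zero_variance = function(cnd) {
      if (zero_variance == "error") {
        rlang::cnd_signal(cnd)
      }
      warn(sprintf(
        "label %s has a constant projection; returning an all-zero descriptor",
        format(obj$label)
      ))
      L <- if (cube$ndim == 3) nlat - 1 else floor(n_circ / 2)
      edges <- 2^seq(0, log2(degree_to_wavelength(L, cube$ndim)),
                     length.out = nbins + 1)
      new_binned_spectrum(rep(0, nbins), edges, ndim = cube$ndim)
    }
  )
  attr(res, "label") <- obj$label
  attr(res, "size_pixels") <- obj$size_pixels
  res
}

#' Spectral-centroid wavelength
#'
#' Power-weighted mean wavelength of a spectrum: a one-number summary of
#' coarseness (larger = coarser). For binned spectra the geometric center of
#' each bin is used.
#'
#' @param x A `degree_spectrum` or `binned_spectrum`.
#' @return Centroid wavelength in rad/2pi.
#' @export
spectral_centroid <- function(x) {
  if (inherits(x, "binned_spectrum")) {
    ctr <- sqrt(x$wavelength_hi * x$wavelength_lo)
    weighted.mean(ctr, x$value)
  } else if (inherits(x, "degree_spectrum")) {
    pos <- x$degree >= 1
    weighted.mean(x$wavelength[pos], x$power[pos])
  } else {
    abort("spectral_centroid needs a degree_spectrum or binned_spectrum")
  }
}
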