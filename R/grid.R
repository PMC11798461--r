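#' Gauss-Legendre quadrature grid on the sphere
#'
#' Builds the sampling grid used for spherical projections and their harmonic
#' analysis: `nlat` colatitude nodes at the roots of the degree-`nlat`
#' Legendre polynomial (so band-limited integrals over the sphere are exact)
#' and `nlon` uniformly spaced longitudes starting at 0.
#'
#' Quadrature convention: for grid samples `f[i, j]`,
#' `sum_i w[i] * sum_j f[i, j] * (2 * pi / nlon)` approximates the integral of
#' `f` over the sphere; the weights `w` sum to 2, so the unit function
#' integrates to `4 * pi`.
#'
#' @param nlat Number of colatitude (quadrature) nodes; the attainable
#'   spherical-harmonic bandlimit is `nlat - 1`.
#' @param nlon Number of longitudes; must be at least `2 * (nlat - 1) + 1`
#'   for alias-free harmonic analysis at full bandlimit.
#' @return A list with `nlat`, `nlon`, `x` (node cosines, decreasing),
#'   `w` (positive weights), `colat` (strictly increasing colatitudes in
#'   (0, pi)), and `lon` (longitudes on \[0, 2pi)).
#' @examples
#' g <- sht_grid(25, 64)
#' sum(g$w) * g$nlon * (2 * pi / g$nlon)  # area of the unit sphere
#' @export
sht_grid <- function(nlat = 251, nlon = 512) {
  stopifnot(nlat >= 2, nlon >= 4)
  gl <- pracma::gaussLegendre(nlat, -1, 1)
  ord <- order(gl$x, decreasing = TRUE) # colatitude = acos(x) increasing
  x <- gl$x[ord]
  w <- gl$w[ord]
  list(
    nlat = as.integer(nlat), nlon = as.integer(nlon),
    x = x, w = w,
    colat = acos(x),
    lon = 2 * pi * (seq_len(nlon) - 1) / nlon
  )
}

# 4pi (geodesy) normalized associated Legendre functions for a fixed order m:
# values of Pbar_{l,m}(x) for l = m..lmax as a length(x) x (lmax - m + 1)
# matrix. Normalization: (1/4pi) * Int (Pbar_{lm}(cos th) * cos(m phi))^2 dOmega
# = 1 (Condon-Shortley phase omitted, as in geodesy). Uses the standard
# stable normalized three-term recursion; sectoral values below the double
# underflow threshold flush to zero, which is harmless at these bandlimits.
plmbar_m <- function(x, lmax, m) {
  stopifnot(m >= 0, lmax >= m)
  u <- sqrt(pmax(0, 1 - x^2))
  n <- length(x)
  out <- matrix(0, n, lmax - m + 1)
  pmm <- rep(1, n)
  if (m >= 1) {
    pmm <- sqrt(3) * u
    if (m >= 2) {
      for (k in 2:m) pmm <- pmm * u * sqrt((2 * k + 1) / (2 * k))
    }
  }
  out[, 1] <- pmm
  if (lmax > m) {
    out[, 2] <- sqrt(2 * m + 3) * x * pmm
    if (lmax > m + 1) {
      for (l in (m + 2):lmax) {
        a <- sqrt((2 * l - 1) * (2 * l + 1) / ((l - m) * (l + m)))
        b <- sqrt((2 * l + 1) * (l + m - 1) * (l - m - 1) /
                    ((l - m) * (l + m) * (2 * l - 3)))
        out[, l - m + 1] <- a * x * out[, l - m] - b * out[, l - m - 1]
      }
    }
  }
  out
}

# Evaluate one real 4pi-normalized spherical harmonic basis function at
# arbitrary directions (colat, lon vectors). m >= 0 pairs with cos(m lon),
# m < 0 with sin(|m| lon).
eval_harmonic <- function(l, m, colat, lon) {
  stopifnot(l >= 0, abs(m) <= l)
  am <- abs(m)
  p <- plmbar_m(cos(colat), l, am)[, l - am + 1]
  if (m >= 0) p * cos(am * lon) else p * sin(am * lon)
}
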