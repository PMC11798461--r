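#' Band-pass filter a projection by harmonic degree
#'
#' Reconstructs a projection keeping only degrees (3D) or frequencies (2D)
#' in `[lo, hi]`. The operation is linear and idempotent for signals already
#' limited to the band. Useful before [peak_direction()] to isolate the
#' angular scale of interest.
#'
#' @param proj A `sph_projection` or `circ_projection`.
#' @param lo,hi Band limits, `1 <= lo <= hi <= L`.
#' @return A projection of the same type containing only the selected band
#'   (its `normalized` flag is cleared: a band-passed signal no longer has
#'   unit variance).
#' @export
bandpass <- function(proj, lo, hi) {
  UseMethod("bandpass")
}

check_band <- function(lo, hi, L) {
  if (lo < 1 || hi < lo || hi > L) {
    abort(sprintf("invalid band [%s, %s]: need 1 <= lo <= hi <= %d",
                  format(lo), format(hi), L))
  }
}

#' @export
bandpass.sph_projection <- function(proj, lo, hi) {
  L <- proj$nlat - 1
  check_band(lo, hi, L)
  cf <- sh_expand(proj)
  keep <- (0:L) >= lo & (0:L) <= hi
  cf$C[!keep, ] <- 0
  cf$S[!keep, ] <- 0
  g <- list(nlat = proj$nlat, nlon = proj$nlon, x = proj$x, w = proj$w,
            colat = proj$colat, lon = proj$lon)
  out <- sh_synthesize(cf, g)
  out$normalized <- FALSE
  out
}

#' @export
bandpass.circ_projection <- function(proj, lo, hi) {
  n <- proj$n
  L <- floor(n / 2)
  check_band(lo, hi, L)
  Fk <- fft(proj$values)
  k <- c(0:(n - 1))
  kfold <- pmin(k, n - k) # frequency magnitude of each FFT slot
  Fk[kfold < lo | kfold > hi] <- 0
  out <- proj
  out$values <- Re(fft(Fk, inverse = TRUE)) / n
  out$normalized <- FALSE
  out
}

#' Peak direction of a projection
#'
#' The grid direction of the maximum projection value, a proxy for the
#' polarization direction of the object (e.g. the actin leading edge of a
#' migrating cell). Optionally band-pass the projection first to suppress
#' scales that should not drive the peak. The peak is reported at grid
#' resolution; ties are broken towards the smallest colatitude, then the
#' smallest longitude (2D: the smallest angle).
#'
#' @param proj A `sph_projection` or `circ_projection` (raw or normalized).
#' @param band Optional `c(lo, hi)` degree band applied via [bandpass()].
#' @return A `peak_direction`: list with `ndim`, `value` (the maximum), and
#'   either `angle` (2D) or `colat` + `lon` (3D).
#' @export
peak_direction <- function(proj, band = NULL) {
  if (!is.null(band)) proj <- bandpass(proj, band[1], band[2])
  v <- proj$values
  if (max(v) - min(v) <= 1e-12 * max(1, abs(max(v)))) {
    warn("no unique peak: projection is constant; returning the first grid point")
    ties <- 1L
  } else {
    mx <- max(v)
    ties <- which(v == mx)
  }
  if (inherits(proj, "sph_projection")) {
    ti <- (ties - 1) %% proj$nlat + 1 # row = colatitude index
    tj <- (ties - 1) %/% proj$nlat + 1
    pick <- order(ti, tj)[1]
    structure(
      list(ndim = 3L, colat = proj$colat[ti[pick]], lon = proj$lon[tj[pick]],
           value = v[ties[pick]]),
      class = "peak_direction"
    )
  } else {
    pick <- ties[1] # angles increase with index
    structure(
      list(ndim = 2L, angle = proj$angles[pick], value = v[pick]),
      class = "peak_direction"
    )
  }
}

#' @export
print.peak_direction <- function(x, ...) {
  if (x$ndim == 2) {
    cat(sprintf("<peak_direction> 2D angle %.4f rad, value %.4g\n",
                x$angle, x$value))
  } else {
    cat(sprintf("<peak_direction> 3D colat %.4f, lon %.4f rad, value %.4g\n",
                x$colat, x$lon, x$value))
  }
  invisible(x)
}

as_direction <- function(d) {
  if (inherits(d, "peak_direction")) {
    if (d$ndim == 2) c(d$angle) else c(d$colat, d$lon)
  } else {
    as.numeric(d)
  }
}

#' Shortest angle between two directions
#'
#' For 2D directions (scalar angles) the wrap-around angular distance
#' `min(|a - b|, 2 pi - |a - b|)`; for 3D directions (`c(colat, lon)`) the
#' great-circle angle from the spherical law of cosines. Either way the
#' result lies in `[0, pi]`, so a direction exactly opposite a reference
#' (e.g. an illumination site) scores pi.
#'
#' @param a,b Directions: numbers (2D), length-2 vectors `c(colat, lon)`
#'   (3D), or `peak_direction` objects.
#' @return Angle in `[0, pi]`.
#' @examples
#' angle_between(0, pi)            # maximum misalignment
#' angle_between(0.1, 2 * pi - 0.1)
#' @export
angle_between <- function(a, b) {
  a <- as_direction(a)
  b <- as_direction(b)
  if (length(a) != length(b)) abort("directions must have the same dimensionality")
  if (length(a) == 1) {
    d <- abs(a - b) %% (2 * pi)
    min(d, 2 * pi - d)
  } else if (length(a) == 2) {
    cg <- cos(a[1]) * cos(b[1]) + sin(a[1]) * sin(b[1]) * cos(a[2] - b[2])
    acos(pmin(1, pmax(-1, cg)))
  } else {
    abort("a direction is a scalar angle (2D) or c(colat, lon) (3D)")
  }
}
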