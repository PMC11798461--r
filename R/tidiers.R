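#' Tidy a binned Spherical Texture descriptor
#'
#' @param x A `binned_spectrum`.
#' @param ... Unused.
#' @return A plain tibble with `bin`, `wavelength_hi`, `wavelength_lo`,
#'   `value`, plus `label` and `size_pixels` columns.
#' @method tidy binned_spectrum
#' @export
tidy.binned_spectrum <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"),
    size_pixels = attr(x, "size_pixels"),
    bin = x$bin,
    wavelength_hi = x$wavelength_hi,
    wavelength_lo = x$wavelength_lo,
    value = x$value
  )
}

#' One-row summary of a binned descriptor
#'
#' @param x A `binned_spectrum`.
#' @param ... Unused.
#' @return A one-row tibble with `label`, `size_pixels`, `ndim`, `n_bins`,
#'   `total`, and `centroid_wavelength`.
#' @method glance binned_spectrum
#' @export
glance.binned_spectrum <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"),
    size_pixels = attr(x, "size_pixels"),
    ndim = attr(x, "ndim"),
    n_bins = nrow(x),
    total = sum(x$value),
    centroid_wavelength = if (sum(x$value) > 0) spectral_centroid(x) else NA_real_
  )
}

#' Tidy a degree spectrum
#'
#' @param x A `degree_spectrum`.
#' @param ... Unused.
#' @return A plain tibble with `degree`, `wavelength`, `power`.
#' @method tidy degree_spectrum
#' @export
tidy.degree_spectrum <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("degree", "wavelength", "power")])
}

#' Plot a binned descriptor as variance per wavelength band
#'
#' @param object A `binned_spectrum`.
#' @param ... Unused.
#' @return A ggplot: bin value against wavelength on a log2 axis.
#' @method autoplot binned_spectrum
#' @export
autoplot.binned_spectrum <- function(object, ...) {
  df <- tidy(object)
  df$wavelength_mid <- sqrt(df$wavelength_hi * df$wavelength_lo)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_mid, y = .data$value)) +
    ggplot2::geom_col(width = 0.08, fill = "grey30") +
    ggplot2::scale_x_continuous(
      trans = "log2",
      name = "approximate wavelength (rad/2π)"
    ) +
    ggplot2::labs(y = "fraction of variance",
                  title = "Spherical Texture descriptor") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum against wavelength
#'
#' @param object A `degree_spectrum`.
#' @param ... Unused.
#' @return A ggplot of per-degree power on a log2 wavelength axis.
#' @method autoplot degree_spectrum
#' @export
autoplot.degree_spectrum <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$degree >= 1, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$power)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::scale_x_continuous(
      trans = "log2",
      name = "approximate wavelength (rad/2π)"
    ) +
    ggplot2::labs(y = "power (contribution to variance)") +
    ggplot2::theme_minimal()
}

#' Plot a spherical projection as a planar map
#'
#' @param object A `sph_projection`.
#' @param ... Unused.
#' @return A ggplot raster of the projection in (longitude, colatitude).
#' @method autoplot sph_projection
#' @export
autoplot.sph_projection <- function(object, ...) {
  df <- expand.grid(colat = object$colat, lon = object$lon)
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$colat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(name = "colatitude (rad)") +
    ggplot2::scale_fill_viridis_c(name = "mean\nintensity") +
    ggplot2::labs(x = "longitude (rad)") +
    ggplot2::theme_minimal()
}

#' Plot a circular projection
#'
#' @param object A `circ_projection`.
#' @param ... Unused.
#' @return A ggplot of projection value against angle.
#' @method autoplot circ_projection
#' @export
autoplot.circ_projection <- function(object, ...) {
  df <- tibble::tibble(angle = object$angles, value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$value)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::labs(x = "angle (rad)", y = "mean intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
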