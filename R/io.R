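#' Read an intensity/label image pair from TIFF
#'
#' Reads single- or multi-page TIFF rasters. Multi-page files are stacked
#' along the third dimension (z). Sample values are read as stored
#' (`as.is = TRUE`), so integer label images round-trip exactly; intensity
#' scaling is irrelevant downstream because the descriptor is invariant to
#' affine intensity transforms.
#'
#' @param image_path Path to the intensity TIFF.
#' @param labels_path Path to the label TIFF (integer labels, 0 background).
#' @return A [labeled_image()].
#' @export
read_labeled_image <- function(image_path, labels_path) {
  rd <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 1) pages[[1]] else simplify2array(pages)
  }
  intensity <- rd(image_path)
  labels <- round(rd(labels_path))
  storage.mode(labels) <- "integer"
  labeled_image(intensity, labels)
}

#' Write an intensity/label pair as TIFF fixtures
#'
#' Writes 2D or 3D rasters as (multi-page) TIFF: intensity rescaled to 16-bit
#' (an affine transform the descriptor is invariant to), labels as 8- or
#' 16-bit integers. Intended for generating self-contained test inputs for
#' the command-line interface.
#'
#' @param image A [labeled_image()].
#' @param image_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_labeled_image <- function(image, image_path, labels_path) {
  stopifnot(inherits(image, "labeled_image"))
  as_pages <- function(a) {
    if (length(dim(a)) == 2) list(a) else {
      lapply(seq_len(dim(a)[3]), function(k) a[, , k])
    }
  }
  v <- image$intensity
  rng <- range(v)
  v01 <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  v16 <- round(v01 * 65535) / 65535
  tiff::writeTIFF(as_pages(v16), image_path, bits.per.sample = 16)
  mx <- max(image$labels)
  bits <- if (mx < 256) 8 else 16
  denom <- 2^bits - 1
  tiff::writeTIFF(as_pages(image$labels / denom), labels_path,
                  bits.per.sample = bits)
  invisible(c(image_path, labels_path))
}

#' Spherical Texture descriptors for every object in a labeled image
#'
#' Runs [spherical_texture()] for each label present in the image (in
#' increasing label order, so the output ordering is deterministic and
#' independent of any processing order) and returns one row per object.
#' Optionally extracts the projection peak direction per object.
#'
#' @param image A [labeled_image()], or the path to an intensity TIFF when
#'   `labels` is the path to a label TIFF.
#' @param labels Optional label TIFF path (when `image` is a path).
#' @param peaks If `TRUE`, add peak-direction columns (2D: `peak_angle`;
#'   3D: `peak_colat`, `peak_lon`; both: `peak_value`, and
#'   `angle_to_reference` when `reference` is given).
#' @param band Optional `c(lo, hi)` band-pass applied before peak finding.
#' @param reference Optional reference direction (2D angle or
#'   `c(colat, lon)`) to compare peaks against.
#' @param zero_variance `"error"` aborts on constant-projection objects;
#'   `"zero"` (default here) records an all-zero descriptor and continues.
#' @inheritParams spherical_texture
#' @return A tibble with columns `label`, `size_pixels`, `bin_01` ..
#'   `bin_<nbins>` (and peak columns if requested); attribute `edges` holds
#'   the 21 bin-edge wavelengths.
#' @examples
#' img <- perlin_object(periods = 8, seed = 1)
#' run_batch(img)
#' @export
run_batch <- function(image, labels = NULL, side = 80, nlat = 251, nlon = 512,
                      n_circ = 251, nbins = 20, step = 0.5,
                      peaks = FALSE, band = NULL, reference = NULL,
                      zero_variance = c("zero", "error")) {
  zero_variance <- match.arg(zero_variance)
  if (is.character(image)) {
    image <- read_labeled_image(image, labels)
  }
  stopifnot(inherits(image, "labeled_image"))
  ids <- sort(setdiff(unique(as.vector(image$labels)), 0))
  if (length(ids) == 0) abort("no labels: the label image is all background")
  rows <- purrr::map(ids, function(lb) {
    tex <- spherical_texture(
      image, lb, side = side, nlat = nlat, nlon = nlon, n_circ = n_circ,
      nbins = nbins, step = step, zero_variance = zero_variance
    )
    vals <- as.list(tex$value)
    names(vals) <- sprintf("bin_%02d", seq_len(nbins))
    row <- tibble::tibble(
      label = as.integer(lb),
      size_pixels = as.numeric(attr(tex, "size_pixels")),
      !!!vals
    )
    if (peaks) {
      obj <- extract_object(image, lb)
      cube <- rescale_to_cube(obj, side = side)
      proj <- if (cube$ndim == 3) {
        spherical_project(cube, nlat, nlon, step)
      } else {
        circular_project(cube, n_circ, step)
      }
      pk <- peak_direction(proj, band = band)
      if (pk$ndim == 2) {
        row$peak_angle <- pk$angle
      } else {
        row$peak_colat <- pk$colat
        row$peak_lon <- pk$lon
      }
      row$peak_value <- pk$value
      if (!is.null(reference)) {
        row$angle_to_reference <- angle_between(pk, reference)
      }
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  L <- if (image$ndim == 3) nlat - 1 else floor(n_circ / 2)
  attr(out, "edges") <- 2^seq(0, log2(degree_to_wavelength(L, image$ndim)),
                              length.out = nbins + 1)
  out
}

#' Write a descriptor table to CSV with a JSON sidecar
#'
#' The CSV holds one row per object (`label`, `size_pixels`,
#' `bin_01..bin_NN`, any peak columns); the sidecar JSON records the bin-edge
#' wavelengths and the run configuration, so the CSV is self-describing.
#'
#' @param descriptors Tibble from [run_batch()].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param config Optional named list recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_descriptors <- function(descriptors, path, config = list()) {
  readr::write_csv(descriptors, path)
  sidecar <- list(
    bin_edges_wavelength = attr(descriptors, "edges"),
    n_objects = nrow(descriptors),
    config = config
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a descriptor table written by [write_descriptors()]
#'
#' @param path CSV path; bin edges are restored from `<path>.json` when
#'   present.
#' @return A tibble with the `edges` attribute when the sidecar exists.
#' @export
read_descriptors <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "edges") <- meta$bin_edges_wavelength
  }
  out
}
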