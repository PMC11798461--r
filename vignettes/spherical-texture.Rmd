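---
title: "Spherical texture descriptors: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical texture descriptors: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphtex)
```

## The model

`sphtex` treats the texture of a segmented object as a function on the
sphere (circle in 2D): the mean intensity seen along each ray from the
object's center. This throws away radial detail on purpose — for many
biological objects (nuclei with peripheral chromatin, embryos with surface
expression stripes, cells with polarized cortical markers) the *angular*
organization of signal carries the phenotype, and a function on the sphere
can be decomposed into scales in a rotation-invariant way.

Given an intensity raster and a co-registered label raster, the pipeline
for one object is

```
extract_object %>% rescale_to_cube %>% spherical_project %>%
  normalize_projection %>% sh_power_spectrum %>% bin_log2
```

(`circular_project` / `fourier_power_spectrum` in 2D), composed by
`spherical_texture()` and batched by `run_batch()`.

The spherical-harmonic machinery uses the geodesy 4π normalization, in
which every real basis function has unit mean-square over the sphere.
Consequently, for a projection normalized to mean 0 and variance 1, the
per-degree power $S(\ell) = \sum_m (c_{\ell m}^2 + s_{\ell m}^2)$ is
directly the fraction of variance living at angular scale $\ell$, and the
whole spectrum integrates to 1 (Parseval). Degrees map to approximate
angular wavelengths through the Jeans relation
$\lambda = 2\pi R/\sqrt{\ell(\ell+1)}$ with $R = 1$, expressed as a
fraction of the full circle; the relation is poor at the lowest degrees, so
$\lambda$ is pinned to exactly 1 at $\ell = 1$, where a basis function has
one peak and one valley. In 2D the frequency-$k$ wavelength is $1/k$,
sharing the anchor. All assumptions inherit from the projection: objects
are treated as star-shaped about their center (rays stop at the first mask
exit, so concave pockets beyond the first boundary crossing are invisible),
and radial structure is deliberately averaged out.

## Parameters that matter

* **Cube side (`side = 80`)** — the common resolution every object is
  stretched to, one axis at a time. This is what makes the descriptor
  independent of object size and voxel anisotropy, and it caps the finest
  resolvable angular detail; patterns much finer than ~1/80 of the object
  are lost. Adjustable per call for unusually detailed data.
* **Grid (`nlat = 251`, `nlon = 512`)** — colatitudes sit at Gauss–Legendre
  quadrature nodes so band-limited spherical integrals are exact; 251
  latitudes support degrees up to $L = 250$, and 512 longitudes exceed the
  $2L + 1$ needed for alias-free analysis in longitude. The 2D circle uses
  251 angles (frequencies to 125).
* **Ray step (`step = 0.5` voxels)** — rays are sampled every half voxel
  with mask-aware multilinear interpolation; the first sample (the center)
  always contributes, so no ray is empty.
* **Bins (`nbins = 20`)** — edges uniform in $\log_2 \lambda$ from
  $\lambda(1) = 1$ down to $\lambda(250) \approx 0.004$. Each degree's
  power is assigned wholly to the bin containing its wavelength, so binning
  conserves the area under the spectrum exactly; a wavelength exactly on an
  edge goes to the longer-wavelength bin (deterministic, left-closed
  edges).
* **Zero-variance policy** — a constant projection has no texture; the
  descriptor is undefined. Interactive use gets an error
  (`zero_variance = "error"`); batch runs can map such objects to an
  all-zero row with a warning (`"zero"`, the `run_batch()` default) so one
  degenerate object does not abort a screen.

## Numerical choices

**Normalization weights.** The projection mean and variance are
area-weighted with the quadrature weights (a plain-statistics variant is
available via `weighting = "plain"`). Weighted statistics make the unit
variance exactly the quantity Parseval ties to the total spectral power of
a band-limited map, rather than agreeing with it only up to the grid's
latitude anisotropy.

**Descriptor unit sum.** The 251×512 grid holds more samples (≈129k) than
harmonics up to degree 250 (63k coefficients), so a measured projection has
a sliver of energy above the bandlimit; for Perlin-sphere objects the
resolved spectrum captures the unit variance to within about $10^{-5}$.
`spherical_texture()` therefore reports the binned values as fractions of
the *resolved* variance — dividing by their total — so the descriptor sums
to 1 exactly and objects remain comparable regardless of how much
unresolvable high-frequency energy they carry. `sh_power_spectrum()` itself
returns raw, unrescaled power: on band-limited inputs it satisfies Parseval
to machine precision, which is what the spectral unit tests check.

**Mask-aware ray interpolation.** Intensity outside the mask is zeroed
after resampling. A plain multilinear sample taken near the mask boundary
would mix those zeros in and drag every boundary ray towards zero, making
even a constant object appear textured; ray samples therefore interpolate
over in-mask voxels only, renormalizing the corner weights. This keeps two
exact invariants the tests rely on: constant objects project to exactly
constant maps, and the projection is exactly affine in the intensity (so
descriptors are invariant to gain/offset changes, e.g. detector settings).

**Stability.** Associated Legendre functions are evaluated with the
standard fully normalized three-term recursion, which is stable to degree
250 and far beyond; sectoral values that underflow double precision near
the poles flush to zero harmlessly. The transform is an FFT across
longitude followed by exact quadrature across latitude ($O(L^3)$ overall,
~0.3 s at full resolution).

**Ties and degeneracies.** Peak directions are reported at grid resolution
("the angle of the maximum value"), with ties broken towards the smallest
colatitude, then the smallest longitude; a constant projection warns and
returns the first grid point. Empty masks after resampling, absent labels,
and a cube center outside the mask raise typed errors
(`sphtex_degenerate_object`, `sphtex_label_not_found`,
`sphtex_centroid_outside`).

## The synthetic-data module

The generators reproduce the study conditions under which the descriptor's
behavior is characterized, so the whole pipeline is testable without any
microscopy data:

* `perlin_volume()` — classic gradient-lattice noise on a 128³ grid with a
  chosen number of periods per axis (the coarseness dial) and a seed; the
  middle slice (`perlin_slice()`) is the 2D variant, so 2D and 3D tests
  share patterns. Gradients sit on a lattice of `periods + 1` nodes, hence
  the side-divisible-by-periods constraint.
* `shape_mask()` — sphere (diameter 80), cone (base diameter = height =
  80), and a star. The star deserves a note: the obvious "flip each octant
  of a ball so its curved face points inward" construction turns out to be
  star-shaped about its center — no center-to-surface ray ever leaves and
  re-enters it — which defeats its purpose as a concavity probe. The
  construction used instead (a half-radius core plus eight quarter-radius
  lobes displaced 3R/4 along the cube diagonals) is provably non-convex
  from the center: about a fifth of random center rays exit and re-enter.
  Only this concavity and center coverage are relied upon.
* `harmonic_pattern()` — a sphere painted with a single 4π-normalized
  basis function, radially constant: the canonical fixture for checking
  that power lands at the right degree end-to-end.
* `clip_to_radius()` — zeroes intensity outside a radial shell, probing how
  a pattern's apparent angular scale depends on its distance from the
  center (the same pattern subtends wider angles near the center, so it
  reads coarser).
* `random_projection()` — band-limited random maps synthesized from seeded
  Gaussian coefficients with polynomial spectral decay; on these, Parseval
  holds exactly, which is what makes them the right fixture for spectral
  bookkeeping tests.

What passing these tests does *not* show: Perlin spheres are stationary,
isotropic, mid-frequency textures with no imaging noise, no intensity
gradients, no touching objects, and no segmentation errors. Real microscopy
adds all of these; the synthetic results validate the machinery
(projection, transform, binning, invariances), not robustness to
acquisition artifacts. Shot noise, for instance, mostly inflates the
short-wavelength bins.

## Test and validation scale

The unit tests run the oracle comparisons on reduced grids (bandlimit 8
against brute-force quadrature with an independently computed Legendre
basis; dense-step ray oracles at 10× finer steps on side-32 cubes with
~25-node grids), and the property suites at full default resolution:
descriptor sums, grid constants, rotational invariance under longitude
shifts, and the coarseness ordering across Perlin periods {16, 8, 4, 2} ×
5 seeds in both 2D and 3D. The brute-force Legendre oracle is deliberately
capped at low degree — the textbook unnormalized recursion it uses loses
all precision around degree 50, which is precisely why the package uses
the normalized recursion internally.

## Known limitations

* **Shape sensitivity.** The descriptor is less shape-independent than one
  might hope: mask geometry modulates ray lengths, and short rays average
  fewer pattern periods, shifting variance towards longer wavelengths. For
  identical noise fields under sphere versus cone masks the descriptor
  distance is of the same order as the seed-to-seed variability of a single
  shape, not negligibly small; the acceptance suite quantifies this
  honestly. Comparisons are safest between objects of broadly similar
  geometry.
* **Ray-mean shrinkage.** Samples near the center have poorly resolved
  directions, so a projected pattern is shrunk a few percent towards its
  mean relative to the ideal angular profile (measured ~4.5% for a painted
  degree-2 harmonic at default settings). This is a shared, systematic
  factor and cancels in comparisons at equal settings.
* **First-exit rule.** Structure hidden behind a concave boundary pocket is
  invisible; strongly non-convex objects (the star fixture is the extreme)
  are quantified only over their convex-from-center portion.
* **No physical units.** Wavelengths are angular fractions of the object's
  own circumference; mapping to micrometers requires the object's size,
  which is deliberately carried separately (`size_pixels`).
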