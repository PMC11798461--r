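# sphtex

Rotationally invariant texture descriptors for segmented objects in 2D and
3D microscopy images.

Many biological phenotypes are differences in how intensity is distributed
*within* an object — striped gene-expression patterns in an embryo,
clustered versus dispersed chromatin in a nucleus, a polarized actin edge in
a migrating cell. `sphtex` quantifies this as the variance of an object's
angular mean-intensity profile per angular wavelength, producing a compact
20-value spectrum that is independent of the object's orientation and
absolute size, and that can be fed directly into ordinary classifiers
(random forests and the like) or compared across conditions.

## Method

For each labeled object:

1. **Crop and standardize.** The object's bounding box is resampled to an
   80×80×80 cube (80×80 in 2D) — intensity with multilinear interpolation,
   the segmentation mask with nearest-neighbor lookup — and the intensity is
   masked. Per-axis stretching makes the result robust to anisotropic
   voxels.
2. **Project.** Rays are cast from the cube center in directions following a
   Gauss–Legendre quadrature grid (251 colatitudes × 512 longitudes; 251
   uniform angles in 2D). Intensity is averaged along each ray until the ray
   first leaves the mask, giving a spherical (circular) mean-intensity
   projection *F*.
3. **Normalize.** *F*<sub>norm</sub> = (*F* − ⟨*F*⟩) / √Var(*F*), with
   area-weighted (quadrature) statistics, so every object contributes mean 0
   and variance 1.
4. **Decompose.** The normalized projection is expanded in 4π-normalized
   (geodesy) real spherical harmonics up to degree ℓ = 250 (discrete Fourier
   transform in 2D), and squared coefficients are summed over orders *m*:
   *S*(ℓ) = Σ<sub>m</sub> (c²<sub>ℓm</sub> + s²<sub>ℓm</sub>). Summing over
   orders removes all orientation information, so *S* is rotation invariant,
   and under the 4π convention *S*(ℓ) is the contribution of scale ℓ to the
   variance.
5. **Bin by wavelength.** Degrees map to approximate angular wavelengths via
   the Jeans relation λ(ℓ) = 1/√(ℓ(ℓ+1)) (in rad/2π, i.e. fractions of the
   full circle), pinned to λ = 1 at ℓ = 1 where the relation degrades; in 2D,
   λ(k) = 1/k. Power is integrated into 20 bins spaced uniformly in
   log₂ λ and reported as the fraction of resolved variance per bin, so the
   descriptor always sums to 1.

The package also extracts **polarization directions** (the grid direction of
the projection maximum, optionally after band-passing the projection to the
scale of interest) and the shortest angle between a peak and a reference
direction (in [0, π]), and ships a **synthetic-data module** (seeded Perlin
noise volumes, sphere/cone/star masks, painted pure-harmonic patterns,
radial shells) with which the entire pipeline is validated — no external
data needed.

## Worked example

```r
library(sphtex)

img <- perlin_object(periods = 8, seed = 42)   # synthetic 3D test object
img
#> <labeled_image> 3D, dims 128x128x128, 1 object label(s)

tex <- spherical_texture(img, label = 1)
glance(tex)
#> # A tibble: 1 × 6
#>   label size_pixels  ndim n_bins total centroid_wavelength
#>   <int>       <int> <int>  <int> <dbl>               <dbl>
#> 1     1      268096     3     20     1               0.299

tidy(tex)[6:8, c("bin", "wavelength_hi", "wavelength_lo", "value")]
#>     bin wavelength_hi wavelength_lo value
#> 6     6         0.251         0.191 0.272
#> 7     7         0.191         0.145 0.229
#> 8     8         0.145         0.110 0.0840
```

The object is a sphere of Perlin noise with 8 periods across the grid. Its
descriptor sums to 1 and peaks in bins 6–7 (wavelengths ≈ 0.15–0.25 of the
circle), i.e. most intensity variance lives at patterns about one sixth the
object's circumference — exactly the noise scale that was generated.
Coarser noise shifts the mass to longer wavelengths (larger
`centroid_wavelength`); finer noise shifts it down. `autoplot(tex)` draws
the spectrum.

Batch extraction over every label in an image (in memory or from TIFF
files) returns a tibble, one row per object:

```r
run_batch(perlin_object(periods = 4, seed = 7, ndim = 2))[, 1:6]
#> # A tibble: 1 × 6
#>   label size_pixels bin_01 bin_02 bin_03 bin_04
#>   <int>       <dbl>  <dbl>  <dbl>  <dbl>  <dbl>
#> 1     1        5024  0.514      0  0.195      0
```

and `write_descriptors()` exports it as CSV with a JSON sidecar of bin
edges. A command-line wrapper is included for shell pipelines:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "sphtex.R", package = "sphtex"))') \
  run --image cells.tif --labels masks.tif --out textures.csv
```

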