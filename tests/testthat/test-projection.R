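test_that("extract_object returns tight bounding boxes and exact masks", {
  lab <- array(0L, c(16, 16, 16))
  lab[3, 3, 3] <- 1L                       # single voxel
  lab[5:14, 2:11, 4:9] <- 2L               # solid box
  lab[2, 15, 2] <- 3L; lab[15, 2, 15] <- 3L # two disjoint components
  img <- labeled_image(array(runif(16^3), c(16, 16, 16)), lab)

  o1 <- extract_object(img, 1)
  expect_identical(dim(o1$intensity), c(1L, 1L, 1L))
  expect_identical(as.vector(o1$mask), 1L)
  expect_identical(o1$size_pixels, 1L)

  o2 <- extract_object(img, 2)
  expect_identical(dim(o2$intensity), c(10L, 10L, 6L))
  expect_true(all(o2$mask == 1L))

  # oracle: exhaustive scan of every voxel carrying label 3
  o3 <- extract_object(img, 3)
  coords <- which(lab == 3L, arr.ind = TRUE)
  expect_identical(dim(o3$mask), unname(apply(coords, 2, function(v) {
    as.integer(diff(range(v)) + 1)
  })))
  expect_identical(sum(o3$mask), 2L)
  inside <- o3$mask[cbind(coords[, 1] - min(coords[, 1]) + 1,
                          coords[, 2] - min(coords[, 2]) + 1,
                          coords[, 3] - min(coords[, 3]) + 1)]
  expect_true(all(inside == 1L))

  expect_error(extract_object(img, 7), class = "sphtex_label_not_found")
})

test_that("rescale_to_cube is identity at matching size and preserves constants", {
  side <- 12
  vals <- array(rnorm(side^3), rep(side, 3))
  msk <- shape_mask("sphere", side)
  cube <- rescale_to_cube(vals, msk, side = side)
  expect_equal(cube$values[msk == 1], vals[msk == 1])
  expect_identical(cube$mask, msk)
  expect_true(all(cube$values[msk == 0] == 0))

  const <- rescale_to_cube(array(3.7, c(5, 9, 7)), array(1L, c(5, 9, 7)), side = 16)
  expect_equal(unique(as.vector(const$values)), 3.7)
})

test_that("multilinear upsampling of a ramp matches the analytic interpolant", {
  n <- 20; side <- 40
  ramp <- array(rep(0:(n - 1), times = n * n), rep(n, 3))
  cube <- rescale_to_cube(ramp, array(1L, rep(n, 3)), side = side)
  # oracle: evaluate the interpolant analytically at output coordinates
  cexp <- pmin(pmax((seq_len(side) - 0.5) * n / side - 0.5, 0), n - 1)
  expect_equal(cube$values[, 1, 1], cexp, tolerance = 1e-12)
  # interior increments are half the per-voxel increment of the input
  expect_equal(unique(round(diff(cube$values[5:35, 1, 1]), 12)), 0.5)
})

test_that("degenerate objects are rejected", {
  expect_error(
    rescale_to_cube(array(1, c(4, 4, 4)), array(0L, c(4, 4, 4)), side = 8),
    class = "sphtex_degenerate_object"
  )
})

test_that("spherical grid contract: shape, increasing colatitudes, 4pi area", {
  g <- sht_grid(251, 512)
  expect_length(g$colat, 251)
  expect_length(g$lon, 512)
  expect_true(all(diff(g$colat) > 0))
  expect_true(all(g$colat > 0 & g$colat < pi))
  expect_true(all(g$w > 0))
  expect_lt(abs(sum(g$w) * g$nlon * (2 * pi / g$nlon) - 4 * pi), 1e-9)

  cube <- smooth_cube(32, seed = 1)
  proj <- spherical_project(cube, nlat = 25, nlon = 64)
  expect_identical(dim(proj$values), c(25L, 64L))
})

test_that("constant objects project to constant maps (3D and 2D)", {
  msk <- shape_mask("sphere", 24)
  vals <- array(0, rep(24, 3)); vals[msk == 1] <- 1
  cube <- rescale_to_cube(vals, msk, side = 24)
  proj <- spherical_project(cube, nlat = 25, nlon = 64)
  expect_identical(unique(as.vector(proj$values)), 1)

  msk2 <- msk[, , 12]
  vals2 <- array(as.numeric(msk2), dim(msk2))
  cube2 <- rescale_to_cube(vals2, msk2, side = 24)
  cp <- circular_project(cube2, n = 64)
  expect_identical(unique(cp$values), 1)
})

test_that("half-bright sphere projects to a colatitude step (dense-step oracle)", {
  side <- 32
  msk <- shape_mask("sphere", side)
  k <- slice.index(msk, 3)
  vals <- array(as.numeric(k > side / 2), rep(side, 3))
  vals[msk == 0] <- 0
  cube <- rescale_to_cube(vals, msk, side = side)
  proj <- spherical_project(cube, nlat = 19, nlon = 48)
  # step in colatitude: bright for colat well below pi/2, dark well above
  expect_true(all(proj$values[proj$colat < pi / 3, ] > 0.9))
  expect_true(all(proj$values[proj$colat > 2 * pi / 3, ] < 0.1))
  # dense-step oracle at step/10 on the same cube
  g <- sht_grid(19, 48)
  st <- sin(g$colat)
  dirs <- cbind(as.vector(outer(st, cos(g$lon))),
                as.vector(outer(st, sin(g$lon))),
                as.vector(matrix(cos(g$colat), 19, 48)))
  ref <- raycast_oracle(cube$values, cube$mask, dirs, rep((side - 1) / 2, 3), 0.05)
  expect_lt(max(abs(as.vector(proj$values) - ref)), 0.05)
})

test_that("a painted zonal harmonic is recovered by the projection", {
  cube <- harmonic_pattern(2, 0, side = 80)
  proj <- spherical_project(cube, nlat = 25, nlon = 64)
  ref <- outer(seq_len(25), seq_len(64), function(i, j) {
    brute_harmonic(2, 0, proj$colat[i], proj$lon[j])
  })
  # the ray mean shrinks the pattern ~4.5% towards its mean (near-center
  # samples blur directions), so the frozen tolerance is 0.12 on a pattern
  # of amplitude sqrt(5)
  expect_lt(max(abs(proj$values - ref)), 0.12)
  expect_lt(median(abs(proj$values - ref)), 0.05)
})

test_that("projection matches a 10x-finer ray-step oracle on random smooth cubes", {
  g <- sht_grid(13, 32)
  st <- sin(g$colat)
  dirs <- cbind(as.vector(outer(st, cos(g$lon))),
                as.vector(outer(st, sin(g$lon))),
                as.vector(matrix(cos(g$colat), 13, 32)))
  for (seed in 1:10) {
    cube <- smooth_cube(32, seed = seed)
    proj <- spherical_project(cube, nlat = 13, nlon = 32)
    ref <- raycast_oracle(cube$values, cube$mask, dirs, rep(15.5, 3), 0.05)
    np <- normalize_projection(proj)
    # normalize the oracle with the same quadrature weighting
    wt <- g$w / (2 * g$nlon)
    refm <- matrix(ref, 13, 32)
    mu <- sum(wt * rowSums(refm))
    sdv <- sqrt(sum(wt * rowSums((refm - mu)^2)))
    expect_lt(max(abs(np$values - (refm - mu) / sdv)), 0.05)
  }
})

test_that("2D circular projection matches dense-step oracle on painted patterns", {
  side <- 48
  msk <- shape_mask("sphere", side)[, , side / 2]
  off <- seq_len(side) - (side + 1) / 2
  ang <- atan2(matrix(rep(off, each = side), side), matrix(rep(off, side * 1), side))
  vals <- cos(ang)
  vals[msk == 0] <- 0
  cube <- rescale_to_cube(vals, msk, side = side)
  cp <- circular_project(cube, n = 64)
  # radial cos(theta) paint projects to ~cos(angles)
  expect_lt(max(abs(cp$values - cos(cp$angles))), 0.06)
  # dense oracle agreement
  dirs <- cbind(cos(cp$angles), sin(cp$angles), 0)
  ref <- raycast_oracle(array(cube$values, c(side, side, 1)),
                        array(cube$mask, c(side, side, 1)),
                        dirs, c((side - 1) / 2, (side - 1) / 2, 0), 0.05)
  expect_lt(max(abs(cp$values - ref)), 0.05)

  # half-bright disk: bright near angle 0, dark near pi
  vals2 <- array(as.numeric(row(msk) > side / 2), dim(msk))
  vals2[msk == 0] <- 0
  cp2 <- circular_project(rescale_to_cube(vals2, msk, side = side), n = 64)
  expect_gt(mean(cp2$values[abs(cp2$angles) < 0.3]), 0.9)
  expect_lt(mean(cp2$values[abs(cp2$angles - pi) < 0.3]), 0.1)
})

test_that("rays shorten monotonically under radial shrinking; unit intensity stays unit", {
  # with intensity 1 everywhere, any star-convex mask containing the center
  # projects to exactly 1, whatever the ray lengths
  for (kind in c("sphere", "cone")) {
    msk <- shape_mask(kind, 24)
    vals <- array(0, rep(24, 3)); vals[msk == 1] <- 1
    proj <- spherical_project(rescale_to_cube(vals, msk, side = 24),
                              nlat = 13, nlon = 32)
    expect_identical(unique(as.vector(proj$values)), 1)
  }
})

test_that("normalization achieves exact weighted zero mean and unit variance", {
  # symmetric two-level circular case: {0, 2} -> {-1, +1}
  cp <- sphtex:::new_circ_projection(rep(c(0, 2), 32), 2 * pi * (0:63) / 64)
  ncp <- normalize_projection(cp)
  expect_equal(sort(unique(ncp$values)), c(-1, 1))

  cube <- smooth_cube(32, seed = 3)
  proj <- spherical_project(cube, nlat = 25, nlon = 64)
  np <- normalize_projection(proj)
  st <- sphtex:::projection_stats(np)
  expect_lt(abs(st$mean), 1e-9)
  expect_lt(abs(st$var - 1), 1e-9)
  expect_true(np$normalized)
  expect_error(normalize_projection(np), "already normalized")

  # constant projection has no texture
  const <- sphtex:::new_circ_projection(rep(2, 64), 2 * pi * (0:63) / 64)
  expect_error(normalize_projection(const), class = "sphtex_zero_variance")
})

test_that("dimensionality is enforced at the projection step", {
  msk2 <- shape_mask("sphere", 16)[, , 8]
  cube2 <- rescale_to_cube(array(runif(16 * 16), c(16, 16)), msk2, side = 16)
  expect_error(spherical_project(cube2), "3D")
  cube3 <- smooth_cube(16, seed = 1)
  expect_error(circular_project(cube3), "2D")
})

test_that("a center outside the mask is rejected", {
  msk <- array(0L, rep(16, 3))
  msk[1:4, 1:4, 1:4] <- 1L
  vals <- array(1, rep(16, 3))
  cube <- structure(
    list(values = vals, mask = msk, ndim = 3L, side = 16L,
         label = 1L, size_pixels = sum(msk)),
    class = "object_cube"
  )
  expect_error(spherical_project(cube, nlat = 9, nlon = 20),
               class = "sphtex_centroid_outside")
})
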