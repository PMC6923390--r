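test_that("Z-score normalization uses whole-brain population statistics", {
  im <- vol(c(2, 4, 6, 10, 10, 10, 10, 10), d = c(2, 2, 2))
  bm <- msk(c(1, 1, 1, 0, 0, 0, 0, 0), d = c(2, 2, 2))
  z <- zscoreNormalize(im, bm)
  expect_equal(z@values[1:3], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_identical(z@state, "zscored")
  # outside-brain voxels share the same affine map
  expect_equal(z@values[4], (10 - 4) / sqrt(8 / 3), tolerance = 1e-6)

  # post-hoc within-mask mean 0, population SD 1
  set.seed(5)
  im2 <- vol(rnorm(1000, 40, 7), d = c(10, 10, 10))
  bm2 <- msk(runif(1000) < 0.8, d = c(10, 10, 10))
  z2 <- zscoreNormalize(im2, bm2)
  v <- z2@values[bm2@values > 0]
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-10)

  # idempotence: a Z-scored image is a fixed point
  z3 <- zscoreNormalize(z2, bm2)
  expect_equal(z3@values, z2@values, tolerance = 1e-10)

  expect_error(zscoreNormalize(vol(rep(5, 8), d = c(2, 2, 2)), bm),
               class = "gliorad_degenerate_intensity")
})

test_that("isotropic image resampling reproduces grids, constants and ramps", {
  set.seed(6)
  a <- array(rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  same <- resampleImageIsotropic(vol(a), 1.0)
  expect_equal(same@values, a, tolerance = 1e-9)

  cst <- resampleImageIsotropic(vol(rep(4, 5 * 5 * 5), d = c(5, 5, 5),
                                    spacing = c(2, 1.5, 0.8)), 1.0)
  expect_equal(max(abs(cst@values - 4)), 0, tolerance = 1e-9)
  expect_equal(cst@spacing, c(1, 1, 1))

  # linear ramp f(x) = x (mm) survives 2x upsampling almost exactly
  n <- 12
  ramp <- array(rep(2 * (0:(n - 1)), times = n * n), dim = c(n, n, n))
  rs <- resampleImageIsotropic(vol(ramp, spacing = c(2, 2, 2)), 1.0)
  expected <- 0:(dim(rs@values)[1] - 1)
  got <- rs@values[, 4, 4]
  inner <- 3:(length(expected) - 2)
  expect_lt(max(abs(got[inner] - expected[inner])), 1e-6)

  expect_error(resampleImageIsotropic(vol(a), -1),
               class = "gliorad_invalid_argument")
})

test_that("shape-based mask resampling preserves identity, position and topology", {
  m <- ballMask(4)
  expect_identical(resampleMaskIsotropic(m, 1.0), m)

  # single voxel at 2 mm spacing -> connected blob near the voxel center
  sv <- array(0, dim = c(7, 7, 7))
  sv[4, 4, 4] <- 1
  r <- resampleMaskIsotropic(msk(sv, spacing = c(2, 2, 2)), 1.0)
  expect_true(all(r@values %in% c(0, 1)))
  expect_gt(sum(r@values), 0)
  lab <- gliorad:::connComp26(r@values > 0)
  expect_equal(max(lab), 1)
  idx <- which(r@values > 0, arr.ind = TRUE)
  centroid <- colMeans(idx - 1) * 1.0       # target-grid mm coordinates
  expect_lt(sqrt(sum((centroid - c(3, 3, 3) * 2)^2)), 1)

  expect_error(resampleMaskIsotropic(msk(array(0, dim = c(4, 4, 4))), 1),
               class = "gliorad_empty_roi")
})

test_that("sphere masks keep one component and near-preserved volume", {
  for (radius in c(3, 5, 8, 10)) {
    m <- ballMask(radius, spacing = c(1.6, 1.6, 1.6))
    r <- resampleMaskIsotropic(m, 1.0)
    lab <- gliorad:::connComp26(r@values > 0)
    expect_equal(max(lab), 1)
    if (radius >= 5) {
      volIn <- sum(m@values) * 1.6^3
      volOut <- sum(r@values)
      expect_lt(abs(volOut - volIn) / volIn, 0.15)
    }
  }
})

test_that("signed distance map matches exhaustive voxel-wise distances", {
  set.seed(8)
  m <- array(0, dim = c(6, 6, 6))
  m[2:4, 3:5, 2:3] <- 1
  mk <- msk(m, spacing = c(1, 2, 1.5))
  sdm <- gliorad:::signedDistanceMap(mk)
  coords <- as.matrix(expand.grid(x = 0:5, y = 0:5, z = 0:5))
  coords <- sweep(coords, 2, c(1, 2, 1.5), "*")
  inside <- as.vector(m > 0)
  bf <- numeric(length(inside))
  for (i in seq_along(inside)) {
    other <- coords[inside != inside[i], , drop = FALSE]
    d2 <- colSums((t(other) - coords[i, ])^2)
    bf[i] <- sqrt(min(d2)) * (if (inside[i]) 1 else -1)
  }
  expect_equal(as.vector(sdm), bf, tolerance = 1e-10)
})
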