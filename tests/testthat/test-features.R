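test_that("feature-space enumeration has the designed cardinality", {
  fs <- enumerateFeatureSpace()
  expect_equal(nrow(fs), 5912)
  expect_equal(anyDuplicated(fs$id), 0)

  # closed form 8 + S * (9 * 38 + 9 * 5 * 58) for S sequences
  for (S in 1:2) {
    cfgS <- extractionConfig(sequences = c("CE-T1", "T2")[seq_len(S)])
    expect_equal(nrow(enumerateFeatureSpace(cfgS)),
                 8 + S * (9 * 38 + 9 * 5 * 58))
  }
  # single sequence, original image only, one bit setting
  cfg1 <- extractionConfig(sequences = "CE-T1", filters = "orig", bits = 8)
  expect_equal(nrow(enumerateFeatureSpace(cfg1)), 8 + 18 + 20 + 58)

  expect_error(extractionConfig(filters = "XYZ"), class = "gliorad_config")
})

test_that("shape features match hand geometry", {
  one <- msk(c(1, rep(0, 26)), d = c(3, 3, 3))
  f1 <- shapeFeatures(one)
  expect_equal(f1[["volume"]], 1)
  expect_equal(f1[["surface_area"]], 6)
  expect_equal(f1[["max_3d_diameter"]], 0)

  cube <- msk(rep(1, 27), d = c(3, 3, 3))
  fc <- shapeFeatures(cube)
  expect_equal(fc[["volume"]], 27)
  expect_equal(fc[["surface_area"]], 54)
  expect_equal(fc[["max_3d_diameter"]], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(fc[["surface_to_volume_ratio"]], 2)

  # digital-ball sphericity grows with radius toward the face-count
  # limit: the voxelized surface of a ball tends to 6*pi*r^2 (1.5x the
  # smooth sphere), so sphericity approaches 2/3 from below
  sph <- vapply(c(5, 10, 15), function(r)
    shapeFeatures(ballMask(r))[["sphericity"]], numeric(1))
  expect_true(all(diff(sph) > 0))
  expect_true(sph[2] > 0.6 && sph[2] < 2 / 3)
  # volume and diameter do match the analytic ball closely
  f10 <- shapeFeatures(ballMask(10))
  expect_lt(abs(f10[["volume"]] - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.01)
  expect_equal(f10[["max_3d_diameter"]], 20)

  expect_error(shapeFeatures(msk(array(0, dim = c(3, 3, 3)))),
               class = "gliorad_empty_roi")
})

test_that("intensity features match hand arithmetic and stay finite", {
  im <- vol(c(1, 2, 3, 9, 9, 9, 9, 9), d = c(2, 2, 2))
  mk <- msk(c(1, 1, 1, 0, 0, 0, 0, 0), d = c(2, 2, 2))
  f <- intensityFeatures(im, mk)
  expect_named(f, FEATURE_REGISTRY$intensity)
  expect_equal(f[["median"]], 2)
  expect_equal(f[["root_mean_square"]], sqrt(14 / 3), tolerance = 1e-12)
  expect_equal(f[["energy"]], 14)

  f2 <- intensityFeatures(vol(c(3, 4, rep(0, 6)), d = c(2, 2, 2)),
                          msk(c(1, 1, rep(0, 6)), d = c(2, 2, 2)))
  expect_equal(f2[["root_mean_square"]], sqrt(12.5), tolerance = 1e-12)

  cst <- intensityFeatures(vol(rep(2, 8), d = c(2, 2, 2)),
                           msk(rep(1, 8), d = c(2, 2, 2)))
  expect_equal(cst[["variance"]], 0)
  expect_equal(cst[["mean_absolute_deviation"]], 0)
  expect_equal(cst[["range"]], 0)
  expect_true(all(is.finite(cst)))
})

test_that("histogram features follow the discretized-level definitions", {
  # constant ROI: all mass in one bin
  f <- histogramFeatures(vol(rep(4, 27), d = c(3, 3, 3)),
                         msk(rep(1, 27), d = c(3, 3, 3)))
  expect_named(f, FEATURE_REGISTRY$histogram)
  expect_equal(f[["uniformity"]], 1)
  expect_equal(f[["entropy"]], 0)

  # two equal-mass levels: entropy 1 bit, uniformity 0.5
  set.seed(2)
  v <- rep(c(-1, 1), length.out = 64)
  f2 <- histogramFeatures(vol(v, d = c(4, 4, 4)),
                          msk(rep(1, 64), d = c(4, 4, 4)))
  expect_equal(f2[["entropy"]], 1)
  expect_equal(f2[["uniformity"]], 0.5)

  # probabilities recomputed from counts agree
  set.seed(3)
  im <- vol(rnorm(125), d = c(5, 5, 5))
  mk <- msk(runif(125) < 0.8, d = c(5, 5, 5))
  q <- quantizeRoi(im, mk, 6L)
  counts <- tabulate(q@levels[q@levels > 0], nbins = 64)
  p <- counts / sum(counts)
  f3 <- histogramFeatures(im, mk)
  expect_equal(f3[["uniformity"]], sum(p^2), tolerance = 1e-12)
  expect_equal(f3[["entropy"]], -sum(p[p > 0] * log2(p[p > 0])),
               tolerance = 1e-12)
  expect_equal(f3[["mean"]], sum(seq_len(64) * p), tolerance = 1e-12)
})

test_that("subject extraction is complete, deterministic and translation invariant", {
  s <- tinySubject(1)
  v <- extractSubject(s)
  expect_length(v, 5912)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), enumerateFeatureSpace()$id)

  expect_identical(extractSubject(tinySubject(1)), v)

  # translate mask and intensities together by 5 voxels along x (tumor and
  # its filter-support neighborhood stay clear of the volume faces)
  s2 <- tinySubject(1)
  shift <- function(a, by) {
    out <- array(0, dim = dim(a))
    out[(1 + by):dim(a)[1], , ] <- a[1:(dim(a)[1] - by), , ]
    out
  }
  s3 <- new("PhantomSubject", subjectId = "shifted", grade = s2@grade,
            ceT1 = vol(shift(s2@ceT1@values, 5), state = "zscored"),
            t2 = vol(shift(s2@t2@values, 5), state = "zscored",
                     modality = "T2"),
            tumorMask = msk(shift(s2@tumorMask@values, 5)),
            brainMask = s2@brainMask)
  v3 <- extractSubject(s3)
  expect_equal(v3, v, tolerance = 1e-9)
})

test_that("feature tables assemble, subset and round-trip through CSV", {
  cohort <- list(tinySubject(1), tinySubject(2), tinySubject(3),
                 tinySubject(4))
  cohort[[3]]@grade <- "IV"
  cohort[[4]]@grade <- "IV"
  ft <- buildFeatureTable(cohort, preprocess = FALSE)
  expect_s4_class(ft, "FeatureTable")
  expect_equal(dim(ft), c(5912L, 4L))
  expect_equal(grades(ft), c("III", "III", "IV", "IV"))

  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  back <- readFeatureTable(path)
  expect_equal(featureValues(back), featureValues(ft), tolerance = 1e-12)
  expect_equal(grades(back), grades(ft))
})
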