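test_that("quantizer follows the mu +/- 3 sigma fixed-bin rule", {
  # hand-evaluated: mu = 0, population sigma = sqrt(5), 2 bits
  im <- vol(c(-3, -1, 1, 3, 0, 0, 0, 0), d = c(2, 2, 2))
  mk <- msk(c(1, 1, 1, 1, 0, 0, 0, 0), d = c(2, 2, 2))
  q <- quantizeRoi(im, mk, 2)
  expect_identical(as.integer(q@levels[mk@values > 0]), c(2L, 2L, 3L, 3L))
  expect_identical(q@nLevels, 4L)

  # constant ROI: sigma = 0 rule
  qc <- quantizeRoi(vol(rep(7, 8), d = c(2, 2, 2)), msk(rep(1, 8),
                                                        d = c(2, 2, 2)), 4)
  expect_true(all(qc@levels == 1L))

  # levels always within [1, 2^bits]
  for (s in 1:5) {
    set.seed(s)
    im <- vol(rnorm(125, sd = s), d = c(5, 5, 5))
    mk <- msk(runif(125) < 0.7, d = c(5, 5, 5))
    for (b in c(4L, 8L)) {
      q <- quantizeRoi(im, mk, b)
      lv <- q@levels[q@levels > 0]
      expect_true(all(lv >= 1 & lv <= 2^b))
    }
  }
})

test_that("matrix builders reproduce hand-worked tiny cases", {
  # 1x1x2 ROI, levels 1 and 2: one pair, symmetrized and normalized
  q <- quantFromLevels(array(c(1L, 2L), dim = c(1, 1, 2)), 2)
  expect_equal(glcm(q)@table, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # uniform ROI: single nonzero diagonal GLCM entry = 1
  qu <- quantFromLevels(array(1L, dim = c(2, 2, 2)), 2)
  expect_equal(glcm(qu)@table[1, 1], 1)
  expect_equal(sum(glcm(qu)@table), 1)

  # 1x1x3 uniform ROI: one length-3 run along the long axis; the other 12
  # merged directions contribute singleton runs
  q3 <- quantFromLevels(array(1L, dim = c(1, 1, 3)), 1)
  tab <- glrlm(q3)@table
  expect_equal(tab[1, 3], 1)
  expect_equal(tab[1, 1], 36) # 3 voxels x 12 off-axis directions
  # single-voxel ROI: every direction yields the same run length 1
  qv <- quantFromLevels(array(c(1L, rep(0L, 7)), dim = c(2, 2, 2)), 1)
  expect_equal(matrixFeatures(glrlm(qv))[["run_length_variance"]], 0)

  # 1x1x4 levels 1,1,2,2: runs (1, len 2) and (2, len 2) along the long axis
  q4 <- quantFromLevels(array(c(1L, 1L, 2L, 2L), dim = c(1, 1, 4)), 2)
  tab4 <- glrlm(q4)@table
  expect_equal(tab4[1, 2], 1)
  expect_equal(tab4[2, 2], 1)

  # two diagonally-touching voxels form one 26-connected zone
  lev <- array(0L, dim = c(3, 3, 3))
  lev[1, 1, 1] <- 1L; lev[2, 2, 2] <- 1L
  tabz <- glszm(quantFromLevels(lev, 1))@table
  expect_equal(tabz[1, 2], 1)
  expect_equal(sum(tabz), 1)

  # uniform 3x3x3 cube: center voxel has dependence count 26
  qn <- quantFromLevels(array(1L, dim = c(3, 3, 3)), 1)
  expect_equal(ngldm(qn)@table[1, 27], 1)
  # single-voxel ROI: one count at k = 0
  q1 <- quantFromLevels(array(c(1L, rep(0L, 7)), dim = c(2, 2, 2)), 1)
  expect_equal(ngldm(q1)@table[1, 1], 1)

  # NGTDM 1x1x3 levels 1,2,1 (hand evaluation of s_i)
  qng <- quantFromLevels(array(c(1L, 2L, 1L), dim = c(1, 1, 3)), 2)
  tabn <- ngtdm(qng)@table
  expect_equal(tabn[1, 2], 2) # s_1 = |1-2| + |1-2|
  expect_equal(tabn[2, 2], 1) # s_2 = |2 - mean(1,1)|
  expect_equal(tabn[, 1], c(2, 1))
})

test_that("matrix builders agree exactly with brute-force enumeration", {
  set.seed(99)
  for (rep in 1:40) {
    d <- sample(2:6, 3, replace = TRUE)
    ng <- sample(2:8, 1)
    lev <- randomLevels(d, ng)
    if (!any(lev > 0)) next
    q <- quantFromLevels(lev, ng)
    expect_equal(glcm(q)@table, bfGlcm(lev, ng))
    expect_equal(glrlm(q)@table, bfGlrlm(lev, ng))
    expect_equal(glszm(q)@table, bfGlszm(lev, ng))
    expect_equal(ngldm(q)@table, bfNgldm(lev, ng))
    expect_equal(ngtdm(q)@table, bfNgtdm(lev, ng))
  }
})

test_that("matrix mass invariants hold on random ROIs", {
  set.seed(7)
  for (rep in 1:10) {
    d <- sample(3:6, 3, replace = TRUE)
    ng <- 4
    lev <- randomLevels(d, ng)
    if (!any(lev > 0)) next
    q <- quantFromLevels(lev, ng)
    nv <- sum(lev > 0)
    g <- glcm(q)@table
    expect_equal(g, t(g))                       # symmetry
    expect_equal(sum(g), 1)                     # unit mass
    # each voxel lies in exactly one run per direction, so the merged
    # matrix holds between nv/maxlen and 13 * nv runs
    expect_lte(sum(glrlm(q)@table), 13 * nv)
    expect_gte(sum(glrlm(q)@table), nv / max(d))
    z <- glszm(q)@table
    expect_equal(sum(z %*% seq_len(ncol(z))), nv) # sum size*count = voxels
    expect_equal(sum(ngldm(q)@table), nv)       # one count per voxel
  }
})

test_that("gray-level relabeling permutes matrix rows accordingly", {
  set.seed(3)
  ng <- 4
  lev <- randomLevels(c(4, 4, 4), ng, density = 0.8)
  perm <- sample(ng)
  lev2 <- array(0L, dim = dim(lev))
  lev2[lev > 0] <- perm[lev[lev > 0]]
  inv <- order(perm)
  for (builder in list(glrlm, glszm)) {
    t1 <- builder(quantFromLevels(lev, ng))@table
    t2 <- builder(quantFromLevels(lev2, ng))@table
    expect_equal(t2[perm, , drop = FALSE][seq_len(ng), ], t1)
  }
  g1 <- glcm(quantFromLevels(lev, ng))@table
  g2 <- glcm(quantFromLevels(lev2, ng))@table
  expect_equal(g2[perm, perm], g1)
})

test_that("matrix feature formulas match hand evaluation", {
  # GLCM [[0, .5], [.5, 0]]: joint entropy 1 bit, contrast 1
  q <- quantFromLevels(array(c(1L, 2L), dim = c(1, 1, 2)), 2)
  f <- matrixFeatures(glcm(q))
  expect_equal(f[["joint_entropy"]], 1)
  expect_equal(f[["contrast"]], 1)
  expect_named(f, FEATURE_REGISTRY$GLCM)

  # uniform ROI: zero-variance texture distributions
  qu <- quantFromLevels(array(1L, dim = c(3, 3, 3)), 2)
  expect_equal(matrixFeatures(glszm(qu))[["gray_level_variance"]], 0)
  expect_equal(matrixFeatures(glrlm(qu))[["gray_level_variance"]], 0)
  expect_equal(matrixFeatures(ngtdm(qu))[["coarseness"]], 1e12)

  # degenerate single-voxel ROI: all-zero GLCM features with a warning
  q1 <- quantFromLevels(array(c(1L, rep(0L, 26)), dim = c(3, 3, 3)), 2)
  expect_warning(f1 <- matrixFeatures(glcm(q1)), class = "gliorad_warning")
  expect_true(all(f1 == 0))
})

test_that("family registry sizes match the feature-space design", {
  expect_length(FEATURE_REGISTRY$shape, 8)
  expect_length(FEATURE_REGISTRY$intensity, 18)
  expect_length(FEATURE_REGISTRY$histogram, 20)
  expect_length(FEATURE_REGISTRY$GLCM, 11)
  expect_length(FEATURE_REGISTRY$GLRLM, 13)
  expect_length(FEATURE_REGISTRY$GLSZM, 13)
  expect_length(FEATURE_REGISTRY$NGLDM, 16)
  expect_length(FEATURE_REGISTRY$NGTDM, 5)
})
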