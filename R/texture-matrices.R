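#' Quantize ROI intensities over the mean +/- 3 SD range
#'
#' Voxel values inside the mask are clipped to `[mu - 3 sigma, mu + 3
#' sigma]` (ROI mean and population SD), then binned into `2^bits`
#' equal-width levels: `level = min(Ng, 1 + floor(Ng * (v - lo) / (hi -
#' lo)))`. A constant ROI (`sigma = 0`) maps every voxel to level 1.
#'
#' @param image a [VolumeImage-class].
#' @param mask a non-empty [RoiMask-class] on the same grid.
#' @param bits quantization depth, 4 to 8 (levels `Ng = 2^bits`).
#' @return A [QuantizedRoi-class].
#' @export
quantizeRoi <- function(image, mask, bits) {
  bits <- as.integer(bits)
  if (!bits %in% 1:16) # texture registry uses 4..8, histogram 6
    gliostop("gliorad_invalid_argument", "bits out of range")
  m <- mask@values > 0
  if (!any(m)) gliostop("gliorad_empty_roi", "ROI mask is empty")
  ng <- as.integer(2^bits)
  x <- image@values[m]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  lev <- array(0L, dim = dim(image@values))
  if (sigma == 0) {
    lev[m] <- 1L
  } else {
    lo <- mu - 3 * sigma
    hi <- mu + 3 * sigma
    xc <- pmin(pmax(x, lo), hi)
    lev[m] <- as.integer(pmin(ng, 1 + floor(ng * (xc - lo) / (hi - lo))))
  }
  new("QuantizedRoi", levels = lev, nLevels = ng, mask = mask)
}

glmMeta <- list(directions = 13L, connectivity = 26L, distance = 1L)

#' Gray-level co-occurrence matrix (3D, merged directions)
#'
#' Co-occurrences at Chebyshev distance 1 over the 13 unique 3D direction
#' vectors, both voxels in-ROI, merged into one matrix, symmetrized and
#' normalized to unit mass.
#'
#' @param q a [QuantizedRoi-class].
#' @return A [GrayLevelMatrix-class] with family `"GLCM"`.
#' @export
glcm <- function(q) {
  tab <- cpp_glcm(as.integer(q@levels), dim(q@levels), q@nLevels)
  new("GrayLevelMatrix", family = "GLCM", table = tab,
      nVoxels = as.integer(sum(q@levels > 0)), meta = glmMeta)
}

#' Gray-level run length matrix (3D, merged directions)
#'
#' Maximal same-level runs confined to in-ROI voxels along each of the 13
#' unique directions, merged into one (level x run length) count matrix.
#'
#' @param q a [QuantizedRoi-class].
#' @return A [GrayLevelMatrix-class] with family `"GLRLM"`.
#' @export
glrlm <- function(q) {
  tab <- cpp_glrlm(as.integer(q@levels), dim(q@levels), q@nLevels)
  new("GrayLevelMatrix", family = "GLRLM", table = tab,
      nVoxels = as.integer(sum(q@levels > 0)), meta = glmMeta)
}

#' Gray-level size zone matrix (26-connected zones)
#'
#' Zones are 26-connected components of equal level within the ROI; the
#' matrix counts zones by (level, zone size).
#'
#' @param q a [QuantizedRoi-class].
#' @return A [GrayLevelMatrix-class] with family `"GLSZM"`.
#' @export
glszm <- function(q) {
  tab <- cpp_glszm(as.integer(q@levels), dim(q@levels), q@nLevels)
  new("GrayLevelMatrix", family = "GLSZM", table = tab,
      nVoxels = as.integer(sum(q@levels > 0)), meta = glmMeta)
}

#' Neighboring gray-level dependence matrix
#'
#' For each in-ROI voxel, the dependence count k is the number of in-ROI
#' 26-neighbors whose level differs from the center by at most `alpha`
#' (default 0); the matrix counts voxels by (level, k + 1).
#'
#' @param q a [QuantizedRoi-class].
#' @param alpha coarseness tolerance (default 0).
#' @return A [GrayLevelMatrix-class] with family `"NGLDM"`.
#' @export
ngldm <- function(q, alpha = 0L) {
  tab <- cpp_ngldm(as.integer(q@levels), dim(q@levels), q@nLevels,
                   as.integer(alpha))
  new("GrayLevelMatrix", family = "NGLDM", table = tab,
      nVoxels = as.integer(sum(q@levels > 0)),
      meta = c(glmMeta, alpha = as.integer(alpha)))
}

#' Neighborhood gray-tone difference matrix
#'
#' Per level i, `s_i` sums `|i - mean level of the in-ROI 26-neighbors|`
#' over in-ROI voxels of level i; voxels without any in-ROI neighbor are
#' excluded. The table holds the per-level voxel counts `n_i` (column 1)
#' and `s_i` (column 2).
#'
#' @param q a [QuantizedRoi-class].
#' @return A [GrayLevelMatrix-class] with family `"NGTDM"`.
#' @export
ngtdm <- function(q) {
  tab <- cpp_ngtdm(as.integer(q@levels), dim(q@levels), q@nLevels)
  new("GrayLevelMatrix", family = "NGTDM", table = tab,
      nVoxels = as.integer(sum(q@levels > 0)), meta = glmMeta)
}
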