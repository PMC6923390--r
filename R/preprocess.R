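#' Whole-brain Z-score normalization
#'
#' Transforms every voxel as `(v - mu) / sigma`, where `mu` and `sigma` are
#' the mean and population SD of the voxel values inside the brain mask.
#' Voxels outside the brain are transformed with the same statistics, so the
#' map is affine over the whole grid and within-mask values have mean 0 and
#' SD 1 afterwards.
#'
#' @param image a [VolumeImage-class] (any state; normalizing an already
#'   Z-scored image is an identity up to rounding).
#' @param brainMask non-empty [RoiMask-class] on the same grid.
#' @return A Z-scored [VolumeImage-class].
#' @export
zscoreNormalize <- function(image, brainMask) {
  v <- image@values
  m <- brainMask@values > 0
  if (!any(m)) gliostop("gliorad_empty_roi", "brain mask is empty")
  x <- v[m]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2)) # population SD
  if (sigma == 0)
    gliostop("gliorad_degenerate_intensity",
             "constant image cannot be Z-scored (sigma = 0)")
  VolumeImage((v - mu) / sigma, image@spacing, image@origin,
              modality = image@modality, state = "zscored")
}

# Cubic spline interpolation of a 3D grid at new axis positions, as a
# tensor product of 1D natural cubic splines, one axis at a time.
# Evaluation positions are clamped to the input extent (nearest-edge
# extension), so no NaNs are produced.
splineResampleAxis <- function(arr, oldPos, newPos, axis) {
  d <- dim(arr)
  newPos <- pmin(pmax(newPos, min(oldPos)), max(oldPos))
  if (length(oldPos) < 4L) {
    # too few samples for a cubic fit: linear/constant fallback
    interp <- function(col) stats::approx(oldPos, col, xout = newPos,
                                          rule = 2)$y
  } else {
    interp <- function(col) splinefun(oldPos, col, method = "natural")(newPos)
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  mat <- matrix(a, nrow = d[axis])
  res <- apply(mat, 2, interp)
  res <- array(res, dim = c(length(newPos), d[perm[2]], d[perm[3]]))
  aperm(res, order(perm))
}

targetGrid <- function(n, spacing, target) {
  extent <- (n - 1) * spacing
  nOut <- max(2L, floor(extent / target + 1e-9) + 1L)
  list(n = nOut, pos = seq(0, by = target, length.out = nOut))
}

#' Resample a volume to isotropic voxels by tricubic interpolation
#'
#' Values are interpolated with tensor-product cubic splines; the field of
#' view is preserved to within one voxel and out-of-range evaluation uses
#' nearest-edge extension.
#'
#' @param image a [VolumeImage-class].
#' @param targetMm target isotropic spacing in mm (default 1).
#' @return A [VolumeImage-class] with spacing `c(targetMm, targetMm,
#'   targetMm)`.
#' @export
resampleImageIsotropic <- function(image, targetMm = 1.0) {
  if (targetMm <= 0)
    gliostop("gliorad_invalid_argument", "target spacing must be > 0")
  arr <- image@values
  d <- dim(arr)
  for (axis in 1:3) {
    oldPos <- seq(0, by = image@spacing[axis], length.out = dim(arr)[axis])
    tg <- targetGrid(d[axis], image@spacing[axis], targetMm)
    arr <- splineResampleAxis(arr, oldPos, tg$pos, axis)
  }
  VolumeImage(arr, rep(targetMm, 3), image@origin,
              modality = image@modality, state = image@state)
}

# Signed Euclidean distance map in mm: positive inside the mask (distance
# to the nearest background voxel center), negative outside.
signedDistanceMap <- function(mask) {
  v <- mask@values > 0
  d <- dim(v)
  dOut <- sqrt(cpp_edt_sq(as.logical(!v), dim(v), mask@spacing))
  dIn <- sqrt(cpp_edt_sq(as.logical(v), dim(v), mask@spacing))
  array(dOut - dIn, dim = d)
}

#' Resample a binary mask by shape-based interpolation
#'
#' The signed Euclidean distance map of the mask (positive inside) is
#' interpolated with cubic splines to the isotropic target grid and
#' thresholded at >= 0, preserving shape rather than intensity. A mask
#' already on the target grid is returned unchanged.
#'
#' @param mask a non-empty [RoiMask-class].
#' @param targetMm target isotropic spacing in mm (default 1).
#' @return A strictly binary [RoiMask-class] on the target grid.
#' @export
resampleMaskIsotropic <- function(mask, targetMm = 1.0) {
  if (targetMm <= 0)
    gliostop("gliorad_invalid_argument", "target spacing must be > 0")
  if (!any(mask@values > 0))
    gliostop("gliorad_empty_roi", "cannot resample an empty mask")
  if (all(abs(mask@spacing - targetMm) < 1e-9)) return(mask)
  sdm <- signedDistanceMap(mask)
  d <- dim(sdm)
  arr <- sdm
  for (axis in 1:3) {
    oldPos <- seq(0, by = mask@spacing[axis], length.out = dim(arr)[axis])
    tg <- targetGrid(d[axis], mask@spacing[axis], targetMm)
    arr <- splineResampleAxis(arr, oldPos, tg$pos, axis)
  }
  RoiMask((arr >= 0) * 1, rep(targetMm, 3), mask@origin)
}

#' Preprocess one subject to the analysis grid
#'
#' Resamples both channels and masks to isotropic `targetMm` voxels (images
#' by tricubic splines, masks by shape-based interpolation) when needed,
#' then Z-scores each channel over the brain mask. Resampling precedes
#' normalization so the normalization statistics refer to the analysis
#' grid.
#'
#' @param subject a [PhantomSubject-class] (or any object with the same
#'   slots, e.g. read from a manifest).
#' @param targetMm analysis voxel size in mm.
#' @return The subject with Z-scored isotropic channels and aligned masks.
#' @export
preprocessSubject <- function(subject, targetMm = 1.0) {
  iso <- function(img) {
    if (all(abs(img@spacing - targetMm) < 1e-9)) img
    else resampleImageIsotropic(img, targetMm)
  }
  ce <- iso(subject@ceT1)
  t2 <- iso(subject@t2)
  tm <- resampleMaskIsotropic(subject@tumorMask, targetMm)
  bm <- resampleMaskIsotropic(subject@brainMask, targetMm)
  # guard against one-voxel count mismatch from field-of-view rounding
  dims <- pmin(dim(ce@values), dim(t2@values), dim(tm@values), dim(bm@values))
  crop <- function(a) a[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]),
                        drop = FALSE]
  ce@values <- crop(ce@values); t2@values <- crop(t2@values)
  tm@values <- crop(tm@values); bm@values <- crop(bm@values)
  tm@values <- tm@values * bm@values # tumor stays inside the brain
  new("PhantomSubject", subjectId = subject@subjectId, grade = subject@grade,
      ceT1 = zscoreNormalize(ce, bm), t2 = zscoreNormalize(t2, bm),
      tumorMask = tm, brainMask = bm)
}
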