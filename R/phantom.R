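#' Configure the synthetic two-class glioma phantom
#'
#' Builds the configuration of the seeded phantom generator. The defaults
#' define the documented planted-effect conditions: a grade-IV tumor is
#' brighter on CE-T1 by `intensityShift` Z-units, has rougher internal
#' texture (shorter correlation length by `textureSmoothnessRatio`), and is
#' larger by `tumorRadiusRatio`; both channels carry additive Gaussian
#' noise. Class sizes default to the 1:2 (III:IV) imbalance typical of
#' malignant-glioma cohorts.
#'
#' @param nPerClass subjects per grade; either a single count used for both
#'   classes or a named vector `c(III = ..., IV = ...)`.
#' @param gridShape voxels per axis (scalar or length 3), all >= 16.
#' @param voxelSizeMm isotropic voxel size in mm.
#' @param intensityShift grade-IV CE-T1 tumor intensity shift in Z-units.
#' @param textureSmoothnessRatio > 0; the grade-III texture smoothing
#'   kernel is this factor wider than the grade-IV kernel (1 = no
#'   difference).
#' @param tumorRadiusRatio > 0; grade-IV tumor radius relative to grade III.
#' @param noiseSigma additive Gaussian noise SD in Z-units.
#' @param seed integer base seed; per-subject substreams derive from it.
#' @param cohortTag `"primary"` or `"validation"`.
#' @return A [PhantomConfig-class].
#' @export
phantomConfig <- function(nPerClass = c(III = 18L, IV = 36L),
                          gridShape = 64L, voxelSizeMm = 1.0,
                          intensityShift = 1.5,
                          textureSmoothnessRatio = 2.0,
                          tumorRadiusRatio = 1.25,
                          noiseSigma = 0.3, seed = 1L,
                          cohortTag = "primary") {
  if (length(nPerClass) == 1L) nPerClass <- c(III = nPerClass, IV = nPerClass)
  nPerClass <- setNames(as.integer(nPerClass), c("III", "IV"))
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  new("PhantomConfig", nPerClass = nPerClass,
      gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
      intensityShift = intensityShift,
      textureSmoothnessRatio = textureSmoothnessRatio,
      tumorRadiusRatio = tumorRadiusRatio, noiseSigma = noiseSigma,
      seed = as.integer(seed), cohortTag = cohortTag)
}

# Smooth Gaussian random field with unit SD: white noise convolved with a
# Gaussian kernel (circular convolution via FFT; the periodic wrap only
# touches boundary correlations, outside the brain), renormalized to unit
# empirical SD over the grid.
smoothField <- function(d, sigma) {
  w <- array(rnorm(prod(d)), dim = d)
  if (sigma > 0) {
    k1 <- function(n) {
      pos <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1)))
      k <- exp(-pos^2 / (2 * sigma^2))
      stats::fft(k / sum(k))
    }
    K <- outer(outer(k1(d[1]), k1(d[2])), k1(d[3]))
    w <- Re(stats::fft(stats::fft(w) * K, inverse = TRUE)) / prod(d)
  }
  s <- sd(w)
  if (s == 0) w else w / s
}

# Grow the tumor mask: radial seed bump plus a bumpy random field,
# thresholded inside the brain, keeping the 26-component of the center.
growTumorMask <- function(d, center, radius, brain) {
  co <- lapply(1:3, function(a) seq_len(d[a]) - center[a])
  dist2 <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  bump <- 2 * exp(-dist2 / radius^2)
  field <- bump + 0.6 * smoothField(d, 2)
  cand <- field > 1 & brain
  if (!any(cand)) return(NULL)
  lab <- connComp26(cand)
  cidx <- 1L + (center[1] - 1L) + d[1] * ((center[2] - 1L) +
                                            d[2] * (center[3] - 1L))
  keep <- lab[cidx]
  if (keep == 0L) keep <- which.max(tabulate(lab[lab > 0]))
  lab == keep
}

generateSubject <- function(config, grade, index) {
  d <- config@gridShape
  set.seed(subSeed(config@seed, index))

  # ellipsoidal brain mask
  semi <- 0.42 * d
  ctr <- (d + 1) / 2
  co <- lapply(1:3, function(a) (seq_len(d[a]) - ctr[a]) / semi[a])
  rr <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  brain <- rr <= 1

  # tumor geometry: random center well inside the brain
  baseR <- 0.14 * min(d)
  radius <- if (grade == "IV") baseR * config@tumorRadiusRatio else baseR
  mask <- NULL
  for (attempt in 1:10) {
    center <- round(ctr + runif(3, -0.2, 0.2) * d)
    m <- growTumorMask(d, center, radius * (1 + 0.15 * (attempt - 1)), brain)
    if (!is.null(m) && sum(m) >= 8) { mask <- m; break }
  }
  if (is.null(mask))
    gliostop("gliorad_degenerate_phantom",
             "tumor blob empty after 10 attempts (subject %d)", index)

  # smooth background tissue field per channel (unit SD over the grid)
  bgCe <- smoothField(d, 6)
  bgT2 <- smoothField(d, 6)

  # in-tumor texture: class-specific correlation length, grade IV rougher
  sigmaTex <- if (grade == "IV") 1.0 else 1.0 * config@textureSmoothnessRatio
  texCe <- smoothField(d, sigmaTex)
  texT2 <- smoothField(d, sigmaTex)

  shift <- if (grade == "IV") config@intensityShift else 0
  ce <- bgCe
  t2 <- bgT2
  ce[mask] <- ce[mask] + 1.0 + shift + 0.5 * texCe[mask]
  t2[mask] <- t2[mask] + 0.8 + 0.5 * texT2[mask]
  ce[!brain] <- 0
  t2[!brain] <- 0
  if (config@noiseSigma > 0) {
    ce <- ce + rnorm(prod(d), sd = config@noiseSigma)
    t2 <- t2 + rnorm(prod(d), sd = config@noiseSigma)
  }

  sp <- rep(config@voxelSizeMm, 3)
  new("PhantomSubject",
      subjectId = sprintf("%s%03d", config@cohortTag, index), grade = grade,
      ceT1 = VolumeImage(ce, sp, modality = "CE-T1"),
      t2 = VolumeImage(t2, sp, modality = "T2"),
      tumorMask = RoiMask(mask * 1, sp),
      brainMask = RoiMask(brain * 1, sp))
}

#' Generate a synthetic two-class cohort
#'
#' Produces paired CE-T1/T2 volumes, tumor masks and brain masks for
#' `nPerClass` subjects per grade, with the class effects configured in
#' [phantomConfig()]. Each subject draws from its own RNG substream derived
#' from `(seed, subject index)`, so the same configuration reproduces
#' bit-identical volumes and extending the cohort does not perturb earlier
#' subjects.
#'
#' @param config a [PhantomConfig-class].
#' @return List of [PhantomSubject-class], grade III subjects first.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  grades <- c(rep("III", config@nPerClass[["III"]]),
              rep("IV", config@nPerClass[["IV"]]))
  lapply(seq_along(grades), function(i)
    generateSubject(config, grades[i], i))
}

#' Write a cohort to NIfTI files with a CSV manifest
#'
#' One `.nii.gz` file per channel and mask, plus a manifest CSV with
#' columns `subject_id`, `grade`, `cohort`, `ce_t1_path`, `t2_path`,
#' `tumor_mask_path`, `brain_mask_path`.
#'
#' @param subjects list of [PhantomSubject-class].
#' @param outDir writable output directory (created if absent).
#' @param cohortTag cohort label written into the manifest.
#' @return Path to the manifest CSV, invisibly.
#' @export
writeCohort <- function(subjects, outDir, cohortTag = "primary") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir))
    gliostop("gliorad_io", "cannot create output directory '%s'", outDir)
  rows <- lapply(subjects, function(s) {
    paths <- file.path(outDir, sprintf("%s_%s.nii.gz", s@subjectId,
                                       c("ce_t1", "t2", "tumor", "brain")))
    writeVolumeNifti(s@ceT1, paths[1])
    writeVolumeNifti(s@t2, paths[2])
    writeMaskNifti(s@tumorMask, paths[3])
    writeMaskNifti(s@brainMask, paths[4])
    data.frame(subject_id = s@subjectId, grade = s@grade,
               cohort = cohortTag, ce_t1_path = paths[1], t2_path = paths[2],
               tumor_mask_path = paths[3], brain_mask_path = paths[4],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(outDir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest back into subjects
#'
#' @param manifestPath path to a manifest CSV written by [writeCohort()].
#' @return List of [PhantomSubject-class].
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    gliostop("gliorad_io", "manifest '%s' not found", manifestPath)
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    r <- man[i, ]
    for (p in c(r$ce_t1_path, r$t2_path, r$tumor_mask_path, r$brain_mask_path))
      if (!file.exists(p))
        gliostop("gliorad_io", "file '%s' for subject %s not found",
                 p, r$subject_id)
    new("PhantomSubject", subjectId = r$subject_id, grade = r$grade,
        ceT1 = readVolumeNifti(r$ce_t1_path, modality = "CE-T1"),
        t2 = readVolumeNifti(r$t2_path, modality = "T2"),
        tumorMask = readMaskNifti(r$tumor_mask_path),
        brainMask = readMaskNifti(r$brain_mask_path))
  })
}

# --- NIfTI I/O (RNifti backend) ---------------------------------------------

writeVolumeNifti <- function(image, path) {
  im <- RNifti::asNifti(image@values)
  RNifti::pixdim(im) <- image@spacing
  RNifti::writeNifti(im, path)
  path
}

writeMaskNifti <- function(mask, path) {
  im <- RNifti::asNifti(mask@values)
  RNifti::pixdim(im) <- mask@spacing
  RNifti::writeNifti(im, path)
  path
}

readVolumeNifti <- function(path, modality = "CE-T1", state = "raw") {
  im <- RNifti::readNifti(path)
  VolumeImage(array(as.numeric(im), dim = dim(im)), RNifti::pixdim(im),
              modality = modality, state = state)
}

readMaskNifti <- function(path) {
  im <- RNifti::readNifti(path)
  RoiMask(array(as.numeric(im) != 0, dim = dim(im)) * 1, RNifti::pixdim(im))
}
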