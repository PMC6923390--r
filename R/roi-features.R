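# Shape, intensity and histogram feature sets, and per-subject extraction
# of the full feature space.

#' Morphological features of a tumor mask
#'
#' Voxel-model morphology on an isotropic mask: volume as voxel count times
#' voxel volume, surface area by counting exposed voxel faces, and the
#' derived sphericity/compactness family; the maximum 3D diameter is the
#' largest pairwise Euclidean distance between boundary-voxel centers.
#'
#' @param mask a non-empty [RoiMask-class] (isotropic spacing assumed).
#' @return Named numeric vector of the 8 registered shape features.
#' @export
shapeFeatures <- function(mask) {
  m <- mask@values > 0
  if (!any(m)) gliostop("gliorad_empty_roi", "empty mask")
  sp <- mask@spacing
  m <- cropTo(m, roiBbox(m, margin = 1L)) # morphology is crop-invariant
  d <- dim(m)
  nv <- sum(m)
  vol <- nv * prod(sp)

  padShift <- function(a, axis, dir) {
    # neighbor occupancy along an axis; outside the grid counts as empty
    idx <- seq_len(d[axis]) + dir
    valid <- idx >= 1 & idx <= d[axis]
    out <- array(FALSE, dim = d)
    src <- idx[valid]
    switch(axis,
           { out[valid, , ] <- a[src, , ] },
           { out[, valid, ] <- a[, src, ] },
           { out[, , valid] <- a[, , src] })
    out
  }
  area <- 0
  exposedAny <- array(FALSE, dim = d)
  for (axis in 1:3) {
    faceArea <- prod(sp[-axis])
    for (dir in c(-1L, 1L)) {
      exposed <- m & !padShift(m, axis, dir)
      area <- area + sum(exposed) * faceArea
      exposedAny <- exposedAny | exposed
    }
  }

  bIdx <- which(exposedAny)
  coords <- cbind((bIdx - 1) %% d[1],
                  ((bIdx - 1) %/% d[1]) %% d[2],
                  (bIdx - 1) %/% (d[1] * d[2]))
  coords <- sweep(coords, 2, sp, "*")
  maxDiam <- if (nrow(coords) < 2) 0 else {
    # pairwise distances in blocks to bound memory on large boundaries
    mx <- 0
    step <- 512L
    for (s in seq(1, nrow(coords), by = step)) {
      rowsA <- coords[s:min(s + step - 1L, nrow(coords)), , drop = FALSE]
      d2 <- outer(rowSums(rowsA^2), rowSums(coords^2), "+") -
        2 * rowsA %*% t(coords)
      mx <- max(mx, max(d2))
    }
    sqrt(max(mx, 0))
  }

  rEq <- (3 * vol / (4 * pi))^(1 / 3)
  c(volume = vol,
    surface_area = area,
    surface_to_volume_ratio = area / vol,
    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    compactness_1 = vol / (sqrt(pi) * area^1.5),
    compactness_2 = 36 * pi * vol^2 / area^3,
    spherical_disproportion = area / (4 * pi * rEq^2),
    max_3d_diameter = maxDiam)
}

momentSkew <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

momentKurt <- function(x) {
  # excess kurtosis; 0 for degenerate distributions
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

intensityStats <- function(x) {
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  inRobust <- x >= q[1] & x <= q[4]
  xr <- x[inRobust]
  c(mean = mu,
    variance = sigma^2,
    skewness = momentSkew(x),
    kurtosis = momentKurt(x),
    median = median(x),
    minimum = min(x),
    maximum = max(x),
    p10 = q[1],
    p90 = q[4],
    interquartile_range = q[3] - q[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mu)),
    robust_mean_absolute_deviation =
      if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    median_absolute_deviation = mean(abs(x - median(x))),
    coefficient_of_variation = safeDiv(sigma, mu),
    quartile_coefficient_of_dispersion = safeDiv(q[3] - q[2], q[3] + q[2]),
    energy = sum(x^2),
    root_mean_square = sqrt(mean(x^2)))
}

#' Intensity features over the ROI
#'
#' The 18 registered first-order statistics of the in-ROI voxel values
#' (moments, order statistics, dispersion measures, energy). Ratio
#' statistics whose denominator vanishes are reported as 0 so that every
#' feature stays finite.
#'
#' @param image a [VolumeImage-class].
#' @param mask a non-empty [RoiMask-class] on the same grid.
#' @return Named numeric vector of 18 features.
#' @export
intensityFeatures <- function(image, mask) {
  m <- mask@values > 0
  if (!any(m)) gliostop("gliorad_empty_roi", "empty ROI")
  out <- intensityStats(image@values[m])
  stopifnot(identical(names(out), FEATURE_REGISTRY$intensity))
  out
}

#' Histogram features over the ROI
#'
#' In-ROI values are discretized with the same mean +/- 3 SD fixed-bin
#' quantizer as the texture features, at a fixed depth of `bits` (default
#' 6, i.e. 64 bins); the 20 registered features are statistics of the
#' discretized levels and of the bin-count histogram (entropy in bits,
#' uniformity, mode, and the extreme histogram gradients).
#'
#' @param image a [VolumeImage-class].
#' @param mask a non-empty [RoiMask-class] on the same grid.
#' @param bits histogram depth (default 6).
#' @return Named numeric vector of 20 features.
#' @export
histogramFeatures <- function(image, mask, bits = 6L) {
  q <- quantizeRoi(image, mask, bits)
  lv <- as.numeric(q@levels[q@levels > 0])
  ng <- q@nLevels
  counts <- tabulate(lv, nbins = ng)
  p <- counts / sum(counts)
  grad <- numeric(ng)
  if (ng >= 2) {
    grad[1] <- counts[2] - counts[1]
    grad[ng] <- counts[ng] - counts[ng - 1]
    if (ng > 2) grad[2:(ng - 1)] <- (counts[3:ng] - counts[1:(ng - 2)]) / 2
  }
  qs <- quantile(lv, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  mu <- mean(lv)
  sigma <- sqrt(mean((lv - mu)^2))
  inRobust <- lv >= qs[1] & lv <= qs[4]
  lr <- lv[inRobust]
  out <- c(mean = mu,
           variance = sigma^2,
           skewness = momentSkew(lv),
           kurtosis = momentKurt(lv),
           median = median(lv),
           minimum = min(lv),
           maximum = max(lv),
           mode = which.max(counts), # smallest level on ties
           p10 = qs[1],
           p90 = qs[4],
           interquartile_range = qs[3] - qs[2],
           range = max(lv) - min(lv),
           mean_absolute_deviation = mean(abs(lv - mu)),
           robust_mean_absolute_deviation =
             if (length(lr)) mean(abs(lr - mean(lr))) else 0,
           coefficient_of_variation = safeDiv(sigma, mu),
           quartile_coefficient_of_dispersion =
             safeDiv(qs[3] - qs[2], qs[3] + qs[2]),
           entropy = ent2(p),
           uniformity = sum(p^2),
           max_gradient = max(grad),
           min_gradient = min(grad))
  stopifnot(identical(names(out), FEATURE_REGISTRY$histogram))
  out
}

# Hot-path texture extraction on plain arrays (no S4 construction): the
# public quantizeRoi/glcm/... chain computes identical values.
textureFeaturesAllBits <- function(image, mask, bits) {
  m <- mask@values > 0
  bbox <- roiBbox(m, margin = 0L)
  m <- cropTo(m, bbox)
  x <- cropTo(image@values, bbox)[m]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  d <- dim(m)
  nv <- as.integer(sum(m))
  out <- list()
  for (b in bits) {
    ng <- as.integer(2^b)
    lev <- array(0L, dim = d)
    if (sigma == 0) {
      lev[m] <- 1L
    } else {
      lo <- mu - 3 * sigma
      hi <- mu + 3 * sigma
      xc <- pmin(pmax(x, lo), hi)
      lev[m] <- as.integer(pmin(ng, 1 + floor(ng * (xc - lo) / (hi - lo))))
    }
    li <- as.integer(lev)
    tabs <- list(
      GLCM = cpp_glcm(li, d, ng), GLRLM = cpp_glrlm(li, d, ng),
      GLSZM = cpp_glszm(li, d, ng), NGLDM = cpp_ngldm(li, d, ng, 0L),
      NGTDM = cpp_ngtdm(li, d, ng))
    for (fam in TEXTURE_FAMILIES) {
      tab <- tabs[[fam]]
      out[[paste(fam, b)]] <- if (sum(tab) == 0) {
        gliowarn("gliorad_degenerate_roi",
                 "all-zero %s matrix: features reported as 0", fam)
        setNames(numeric(length(FEATURE_REGISTRY[[fam]])),
                 FEATURE_REGISTRY[[fam]])
      } else switch(fam,
        GLCM = glcmFeatures(tab), GLRLM = glrlmFeatures(tab, nv),
        GLSZM = glszmFeatures(tab, nv), NGLDM = ngldmFeatures(tab),
        NGTDM = ngtdmFeatures(tab))
    }
  }
  out
}

# Bounding box of a mask with margin (clipped to the grid). All ROI
# features are translation invariant and local, so extraction can run on
# the cropped grid; a margin of the wavelet filter length keeps in-ROI
# sub-band values bit-identical to a full-grid decomposition.
roiBbox <- function(mask, margin) {
  d <- dim(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  lapply(1:3, function(a)
    seq(max(1L, min(idx[, a]) - margin), min(d[a], max(idx[, a]) + margin)))
}

cropTo <- function(arr, bbox) arr[bbox[[1]], bbox[[2]], bbox[[3]], drop = FALSE]

#' Extract the full feature row of one subject
#'
#' Computes one finite value per descriptor of [enumerateFeatureSpace()]:
#' shape once from the tumor mask, then per sequence and image version the
#' intensity and histogram sets, then per quantization depth all five
#' texture families. The subject must be preprocessed (Z-scored channels on
#' the isotropic analysis grid). Quantization statistics are recomputed per
#' filtered image, since sub-band value ranges differ from the original.
#'
#' @param subject a preprocessed [PhantomSubject-class].
#' @param config an [extractionConfig()] list.
#' @param space precomputed [enumerateFeatureSpace()] result (optional).
#' @return Named numeric vector in canonical descriptor order.
#' @export
extractSubject <- function(subject, config = extractionConfig(),
                           space = enumerateFeatureSpace(config)) {
  bank <- waveletBank(config$waveletOrder)
  vals <- numeric(0)

  vals <- c(vals, shapeFeatures(subject@tumorMask))

  bbox <- roiBbox(subject@tumorMask@values, margin = 6L * config$waveletOrder)
  sp <- subject@tumorMask@spacing
  cmask <- RoiMask(cropTo(subject@tumorMask@values, bbox), sp)

  channels <- list(`CE-T1` = subject@ceT1, `T2` = subject@t2)
  for (sq in config$sequences) {
    img <- channels[[sq]]
    if (is.null(img))
      gliostop("gliorad_config", "subject lacks sequence '%s'", sq)
    cimg <- VolumeImage(cropTo(img@values, bbox), sp,
                        modality = img@modality, state = img@state)
    needWavelet <- any(config$filters != "orig")
    bands <- if (needWavelet) decomposeWavelet(cimg, bank) else list()
    for (fl in config$filters) {
      version <- if (fl == "orig") cimg else bands[[fl]]
      vals <- c(vals, intensityFeatures(version, cmask),
                histogramFeatures(version, cmask, config$histogramBits))
      tex <- textureFeaturesAllBits(version, cmask, config$bits)
      # canonical order is family-major, bits-minor
      for (fam in TEXTURE_FAMILIES)
        for (b in config$bits)
          vals <- c(vals, tex[[paste(fam, b)]])
    }
  }
  names(vals) <- space$id
  if (!all(is.finite(vals)))
    gliostop("gliorad_nonfinite",
             "non-finite feature values: %s",
             paste(head(space$id[!is.finite(vals)], 5), collapse = ", "))
  vals
}

#' Build a FeatureTable for a cohort
#'
#' Preprocesses each subject ([preprocessSubject()]) and extracts the full
#' feature row, assembling a [FeatureTable-class] (features x subjects
#' SummarizedExperiment).
#'
#' @param cohort list of [PhantomSubject-class], or a manifest CSV path
#'   written by [writeCohort()].
#' @param config an [extractionConfig()] list.
#' @param cohortTag cohort label stored per subject (defaults to
#'   `"primary"`).
#' @param preprocess set `FALSE` if subjects are already Z-scored and
#'   isotropic.
#' @param verbose log per-subject timing to the console.
#' @return A [FeatureTable-class].
#' @export
buildFeatureTable <- function(cohort, config = extractionConfig(),
                              cohortTag = "primary", preprocess = TRUE,
                              verbose = FALSE) {
  if (is.character(cohort)) cohort <- readCohort(cohort)
  space <- enumerateFeatureSpace(config)
  rows <- lapply(cohort, function(s) {
    t0 <- proc.time()[3]
    if (preprocess) s <- preprocessSubject(s)
    v <- extractSubject(s, config, space)
    if (verbose)
      message(sprintf("extracted %s (%d features, %.1fs)", s@subjectId,
                      length(v), proc.time()[3] - t0))
    v
  })
  mat <- do.call(cbind, rows) # features x subjects
  colnames(mat) <- vapply(cohort, function(s) s@subjectId, character(1))
  rownames(mat) <- space$id
  featureTable(mat,
               grade = vapply(cohort, function(s) s@grade, character(1)),
               cohort = rep(cohortTag, length(cohort)),
               rowData = space)
}

#' Construct a FeatureTable from a features-by-subjects matrix
#'
#' @param mat numeric matrix, features as rows, subjects as columns;
#'   rownames are descriptor ids, colnames subject ids.
#' @param grade character vector of grades (`"III"`/`"IV"`) per subject.
#' @param cohort cohort tag per subject (recycled).
#' @param rowData optional data.frame of descriptor components.
#' @return A [FeatureTable-class].
#' @export
featureTable <- function(mat, grade, cohort = "primary", rowData = NULL) {
  cd <- S4Vectors::DataFrame(subject_id = colnames(mat),
                             grade = grade,
                             cohort = rep_len(cohort, ncol(mat)))
  args <- list(assays = list(features = mat), colData = cd)
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("FeatureTable", se)
}

#' Write / read a FeatureTable as CSV
#'
#' The CSV is subjects-by-features with leading `subject_id`, `grade`,
#' `cohort` columns and descriptor id strings as feature headers.
#'
#' @param ft a [FeatureTable-class].
#' @param path output CSV path.
#' @return `writeFeatureTable` the path, invisibly; `readFeatureTable` a
#'   [FeatureTable-class].
#' @export
writeFeatureTable <- function(ft, path) {
  df <- data.frame(subject_id = subjectIds(ft), grade = grades(ft),
                   cohort = cohortTags(ft), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(featureValues(ft), check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- df[, 1:3]
  mat <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  colnames(mat) <- meta$subject_id
  featureTable(mat, grade = meta$grade, cohort = meta$cohort)
}
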