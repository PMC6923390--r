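# IBSI-style feature formulas for the five gray-level matrix families.
# Entropies are in bits (log base 2) with 0 log 0 = 0; ratio features are
# guarded to stay finite on degenerate (single-level / tiny) ROIs.

ent2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

safeDiv <- function(num, den) if (abs(den) < 1e-12) 0 else num / den

glcmFeatures <- function(tab) {
  ng <- nrow(tab)
  i <- row(tab); j <- col(tab)
  p <- tab
  px <- rowSums(p)
  mux <- sum(seq_len(ng) * px)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  # symmetric matrix: x and y marginals coincide; diagonal-band sums via
  # grouped row sums (fast at 256 levels)
  kdiag <- 0:(ng - 1)
  pxmy <- as.numeric(rowsum(as.vector(p), as.vector(abs(i - j)),
                            reorder = TRUE))
  if (length(pxmy) < ng) pxmy <- c(pxmy, numeric(ng - length(pxmy)))
  ksum <- 2:(2 * ng)
  pxpySums <- rowsum(as.vector(p), as.vector(i + j), reorder = TRUE)
  pxpy <- numeric(2 * ng - 1)
  pxpy[as.integer(rownames(pxpySums)) - 1L] <- as.numeric(pxpySums)
  c(joint_energy = sum(p^2),
    contrast = sum(p * (i - j)^2),
    correlation = safeDiv(sum(i * j * p) - mux^2, sx^2),
    joint_entropy = ent2(p),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    dissimilarity = sum(p * abs(i - j)),
    sum_average = sum(ksum * pxpy),
    sum_entropy = ent2(pxpy),
    difference_entropy = ent2(pxmy),
    cluster_shade = sum((i + j - 2 * mux)^3 * p),
    cluster_prominence = sum((i + j - 2 * mux)^4 * p))
}

glrlmFeatures <- function(tab, nVoxels) {
  ns <- sum(tab)
  if (ns == 0) return(setNames(numeric(13), FEATURE_REGISTRY$GLRLM))
  i <- row(tab); l <- col(tab)
  ri <- rowSums(tab)
  rl <- colSums(tab)
  lev <- seq_len(nrow(tab)); len <- seq_len(ncol(tab))
  pI <- ri / ns; pL <- rl / ns
  muI <- sum(lev * pI); muL <- sum(len * pL)
  c(short_run_emphasis = sum(tab / l^2) / ns,
    long_run_emphasis = sum(tab * l^2) / ns,
    low_gray_level_run_emphasis = sum(tab / i^2) / ns,
    high_gray_level_run_emphasis = sum(tab * i^2) / ns,
    short_run_low_gray_level_emphasis = sum(tab / (i^2 * l^2)) / ns,
    short_run_high_gray_level_emphasis = sum(tab * i^2 / l^2) / ns,
    long_run_low_gray_level_emphasis = sum(tab * l^2 / i^2) / ns,
    long_run_high_gray_level_emphasis = sum(tab * i^2 * l^2) / ns,
    gray_level_non_uniformity = sum(ri^2) / ns,
    run_length_non_uniformity = sum(rl^2) / ns,
    run_percentage = ns / nVoxels,
    gray_level_variance = sum((lev - muI)^2 * pI),
    run_length_variance = sum((len - muL)^2 * pL))
}

glszmFeatures <- function(tab, nVoxels) {
  ns <- sum(tab)
  if (ns == 0) return(setNames(numeric(13), FEATURE_REGISTRY$GLSZM))
  i <- row(tab); z <- col(tab)
  si <- rowSums(tab)
  sz <- colSums(tab)
  lev <- seq_len(nrow(tab))
  pI <- si / ns
  muI <- sum(lev * pI)
  c(small_zone_emphasis = sum(tab / z^2) / ns,
    large_zone_emphasis = sum(tab * z^2) / ns,
    low_gray_level_zone_emphasis = sum(tab / i^2) / ns,
    high_gray_level_zone_emphasis = sum(tab * i^2) / ns,
    small_zone_low_gray_level_emphasis = sum(tab / (i^2 * z^2)) / ns,
    small_zone_high_gray_level_emphasis = sum(tab * i^2 / z^2) / ns,
    large_zone_low_gray_level_emphasis = sum(tab * z^2 / i^2) / ns,
    large_zone_high_gray_level_emphasis = sum(tab * i^2 * z^2) / ns,
    gray_level_non_uniformity = sum(si^2) / ns,
    gray_level_non_uniformity_normalized = sum(si^2) / ns^2,
    zone_size_non_uniformity = sum(sz^2) / ns,
    zone_percentage = ns / nVoxels,
    gray_level_variance = sum((lev - muI)^2 * pI))
}

ngldmFeatures <- function(tab) {
  ns <- sum(tab)
  if (ns == 0) return(setNames(numeric(16), FEATURE_REGISTRY$NGLDM))
  i <- row(tab); k <- col(tab) # k = dependence count + 1
  di <- rowSums(tab)
  dk <- colSums(tab)
  lev <- seq_len(nrow(tab)); dep <- seq_len(ncol(tab))
  pI <- di / ns; pK <- dk / ns
  muI <- sum(lev * pI); muK <- sum(dep * pK)
  p <- tab / ns
  c(low_dependence_emphasis = sum(tab / k^2) / ns,
    high_dependence_emphasis = sum(tab * k^2) / ns,
    low_gray_level_count_emphasis = sum(tab / i^2) / ns,
    high_gray_level_count_emphasis = sum(tab * i^2) / ns,
    low_dependence_low_gray_level_emphasis = sum(tab / (i^2 * k^2)) / ns,
    low_dependence_high_gray_level_emphasis = sum(tab * i^2 / k^2) / ns,
    high_dependence_low_gray_level_emphasis = sum(tab * k^2 / i^2) / ns,
    high_dependence_high_gray_level_emphasis = sum(tab * i^2 * k^2) / ns,
    gray_level_non_uniformity = sum(di^2) / ns,
    gray_level_non_uniformity_normalized = sum(di^2) / ns^2,
    dependence_count_non_uniformity = sum(dk^2) / ns,
    dependence_count_non_uniformity_normalized = sum(dk^2) / ns^2,
    gray_level_variance = sum((lev - muI)^2 * pI),
    dependence_count_variance = sum((dep - muK)^2 * pK),
    dependence_count_entropy = ent2(p),
    dependence_count_energy = sum(p^2))
}

ngtdmFeatures <- function(tab) {
  nTot <- sum(tab[, 1])
  if (nTot == 0) return(setNames(numeric(5), FEATURE_REGISTRY$NGTDM))
  lev <- seq_len(nrow(tab))
  pi <- tab[, 1] / nTot
  si <- tab[, 2]
  pres <- pi > 0
  ngp <- sum(pres)
  eps <- 1e-12
  coarseness <- 1 / (eps + sum(pi * si))
  if (ngp <= 1) {
    contrast <- 0
    busyness <- 0
    complexity <- 0
    strength <- 0
  } else {
    ii <- lev[pres]; pp <- pi[pres]; ss <- si[pres]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- sum(outer(pp, pp) * dif2) / (ngp * (ngp - 1)) *
      sum(ss) / nTot
    denom <- sum(abs(outer(ii * pp, ii * pp, "-")))
    busyness <- safeDiv(sum(pp * ss), denom)
    psum <- outer(pp, pp, "+")
    complexity <- sum(abs(outer(ii, ii, "-")) *
                        (outer(pp * ss, pp * ss, "+")) / psum) / nTot
    strength <- safeDiv(sum(psum * dif2), eps + sum(ss))
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' Compute the registered features of a gray-level matrix
#'
#' Dispatches on the matrix family and returns exactly the registered
#' feature set for that family (GLCM 11, GLRLM 13, GLSZM 13, NGLDM 16,
#' NGTDM 5). An all-zero matrix (e.g. a single-voxel ROI with no valid
#' pairs) yields all-zero features with a warning rather than an error, so
#' cohort extraction never aborts.
#'
#' @param m a [GrayLevelMatrix-class].
#' @return Named numeric vector of feature values, in registry order.
#' @export
matrixFeatures <- function(m) {
  if (sum(m@table) == 0) {
    gliowarn("gliorad_degenerate_roi",
             "all-zero %s matrix: features reported as 0", m@family)
    nm <- FEATURE_REGISTRY[[m@family]]
    return(setNames(numeric(length(nm)), nm))
  }
  out <- switch(m@family,
                GLCM = glcmFeatures(m@table),
                GLRLM = glrlmFeatures(m@table, m@nVoxels),
                GLSZM = glszmFeatures(m@table, m@nVoxels),
                NGLDM = ngldmFeatures(m@table),
                NGTDM = ngtdmFeatures(m@table))
  stopifnot(identical(names(out), FEATURE_REGISTRY[[m@family]]))
  out
}
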