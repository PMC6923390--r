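#' The registered feature families
#'
#' Named list of feature-name vectors per family. The family sizes are
#' fixed by the feature-space design: shape 8, intensity 18, histogram 20,
#' GLCM 11, GLRLM 13, GLSZM 13, NGLDM 16, NGTDM 5. Shape features are
#' computed once per subject from the tumor mask; intensity and histogram
#' features per image version (original + 8 wavelet sub-bands per
#' sequence); texture features additionally per quantization depth
#' (4-8 bit), giving 8 + 2 x (9 x 38 + 9 x 5 x 58) = 5912 features for the
#' two-sequence default.
#'
#' @export
FEATURE_REGISTRY <- list(
  shape = c("volume", "surface_area", "surface_to_volume_ratio",
            "sphericity", "compactness_1", "compactness_2",
            "spherical_disproportion", "max_3d_diameter"),
  intensity = c("mean", "variance", "skewness", "kurtosis", "median",
                "minimum", "maximum", "p10", "p90", "interquartile_range",
                "range", "mean_absolute_deviation",
                "robust_mean_absolute_deviation",
                "median_absolute_deviation", "coefficient_of_variation",
                "quartile_coefficient_of_dispersion", "energy",
                "root_mean_square"),
  histogram = c("mean", "variance", "skewness", "kurtosis", "median",
                "minimum", "maximum", "mode", "p10", "p90",
                "interquartile_range", "range", "mean_absolute_deviation",
                "robust_mean_absolute_deviation",
                "coefficient_of_variation",
                "quartile_coefficient_of_dispersion", "entropy",
                "uniformity", "max_gradient", "min_gradient"),
  GLCM = c("joint_energy", "contrast", "correlation", "joint_entropy",
           "inverse_difference_moment", "dissimilarity", "sum_average",
           "sum_entropy", "difference_entropy", "cluster_shade",
           "cluster_prominence"),
  GLRLM = c("short_run_emphasis", "long_run_emphasis",
            "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
            "short_run_low_gray_level_emphasis",
            "short_run_high_gray_level_emphasis",
            "long_run_low_gray_level_emphasis",
            "long_run_high_gray_level_emphasis",
            "gray_level_non_uniformity", "run_length_non_uniformity",
            "run_percentage", "gray_level_variance", "run_length_variance"),
  GLSZM = c("small_zone_emphasis", "large_zone_emphasis",
            "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
            "small_zone_low_gray_level_emphasis",
            "small_zone_high_gray_level_emphasis",
            "large_zone_low_gray_level_emphasis",
            "large_zone_high_gray_level_emphasis",
            "gray_level_non_uniformity",
            "gray_level_non_uniformity_normalized",
            "zone_size_non_uniformity", "zone_percentage",
            "gray_level_variance"),
  NGLDM = c("low_dependence_emphasis", "high_dependence_emphasis",
            "low_gray_level_count_emphasis", "high_gray_level_count_emphasis",
            "low_dependence_low_gray_level_emphasis",
            "low_dependence_high_gray_level_emphasis",
            "high_dependence_low_gray_level_emphasis",
            "high_dependence_high_gray_level_emphasis",
            "gray_level_non_uniformity",
            "gray_level_non_uniformity_normalized",
            "dependence_count_non_uniformity",
            "dependence_count_non_uniformity_normalized",
            "gray_level_variance", "dependence_count_variance",
            "dependence_count_entropy", "dependence_count_energy"),
  NGTDM = c("coarseness", "contrast", "busyness", "complexity", "strength"))

TEXTURE_FAMILIES <- c("GLCM", "GLRLM", "GLSZM", "NGLDM", "NGTDM")

#' Default extraction configuration
#'
#' @param sequences MRI sequences to extract from.
#' @param filters image versions: `"orig"` plus wavelet sub-band labels.
#' @param bits texture quantization depths.
#' @param waveletOrder Coiflet order of the filter bank.
#' @param histogramBits fixed histogram discretization depth.
#' @return List of extraction settings.
#' @export
extractionConfig <- function(sequences = c("CE-T1", "T2"),
                             filters = c("orig", SUBBAND_LABELS),
                             bits = 4:8, waveletOrder = 1L,
                             histogramBits = 6L) {
  if (!all(filters %in% c("orig", SUBBAND_LABELS)))
    gliostop("gliorad_config", "unknown filter label")
  list(sequences = sequences, filters = filters, bits = as.integer(bits),
       waveletOrder = as.integer(waveletOrder),
       histogramBits = as.integer(histogramBits))
}

descriptorId <- function(sequence, filter, quant, family, name) {
  paste(sequence, filter, quant, family, name, sep = "|")
}

#' Enumerate the radiomic feature space
#'
#' Produces the canonical ordered list of feature descriptors: 8 shape
#' features computed once from the mask, then per sequence and per image
#' version (original + 8 wavelet sub-bands) the 18 intensity and 20
#' histogram features, then per texture family and quantization depth the
#' 58 texture features. The default two-sequence configuration yields
#' exactly 5912 unique descriptors.
#'
#' @param config an [extractionConfig()] list.
#' @return data.frame with columns `sequence`, `filter`, `quant`, `family`,
#'   `name`, `id` in canonical order.
#' @export
enumerateFeatureSpace <- function(config = extractionConfig()) {
  rows <- list(
    data.frame(sequence = "mask", filter = "orig", quant = "none",
               family = "shape", name = FEATURE_REGISTRY$shape,
               stringsAsFactors = FALSE))
  for (sq in config$sequences) {
    for (fl in config$filters) {
      rows[[length(rows) + 1L]] <-
        data.frame(sequence = sq, filter = fl, quant = "none",
                   family = "intensity", name = FEATURE_REGISTRY$intensity,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(sequence = sq, filter = fl, quant = "none",
                   family = "histogram", name = FEATURE_REGISTRY$histogram,
                   stringsAsFactors = FALSE)
      for (fam in TEXTURE_FAMILIES) {
        for (b in config$bits) {
          rows[[length(rows) + 1L]] <-
            data.frame(sequence = sq, filter = fl,
                       quant = sprintf("%dbit", b), family = fam,
                       name = FEATURE_REGISTRY[[fam]],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$id <- descriptorId(out$sequence, out$filter, out$quant, out$family,
                         out$name)
  if (anyDuplicated(out$id))
    gliostop("gliorad_config", "duplicate feature descriptors")
  out
}
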