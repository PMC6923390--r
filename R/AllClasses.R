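#' VolumeImage: a 3D scalar MR volume
#'
#' A 3D scalar grid with physical voxel spacing and origin. The `state`
#' field records whether voxel values are raw scanner units or whole-brain
#' Z-scores; several pipeline stages require Z-scored input.
#'
#' @slot values 3D numeric array of voxel values (x, y, z order).
#' @slot spacing numeric(3), voxel spacing in mm (all > 0).
#' @slot origin numeric(3), world position of voxel (1,1,1) center in mm.
#' @slot modality character, `"CE-T1"` or `"T2"` (free-form tolerated).
#' @slot state character, `"raw"` or `"zscored"`.
#'
#' @exportClass VolumeImage
setClass("VolumeImage",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 modality = "character", state = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            modality = "CE-T1", state = "raw"))

setValidity("VolumeImage", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (!all(is.finite(v))) return("voxel values must be finite")
  if (!object@state %in% c("raw", "zscored"))
    return("state must be 'raw' or 'zscored'")
  TRUE
})

#' RoiMask: a binary 3D mask aligned to a VolumeImage
#'
#' @slot values 3D array with values in {0, 1}.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot origin numeric(3), world position of voxel (1,1,1) center in mm.
#'
#' @exportClass RoiMask
setClass("RoiMask",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("RoiMask", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers")
  if (!all(v %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' QuantizedRoi: ROI gray levels after fixed-bin quantization
#'
#' Integer level array with 0 outside the ROI and 1..nLevels inside,
#' produced by [quantizeRoi()] over the ROI mean +/- 3 SD range.
#'
#' @slot levels 3D integer array (0 outside ROI).
#' @slot nLevels integer, number of gray levels (2^bits).
#' @slot mask the [RoiMask-class] that defined the ROI.
#'
#' @exportClass QuantizedRoi
setClass("QuantizedRoi",
  representation(levels = "array", nLevels = "integer", mask = "RoiMask"))

setValidity("QuantizedRoi", function(object) {
  lv <- object@levels[object@levels > 0]
  if (length(lv) == 0L) return("quantized ROI is empty")
  if (any(lv > object@nLevels)) return("levels exceed nLevels")
  TRUE
})

#' GrayLevelMatrix: one of the five texture matrix families
#'
#' @slot family one of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"NGLDM"`, `"NGTDM"`.
#'   The GLCM is symmetrized and normalized to unit mass; the other
#'   families hold raw counts. The NGTDM table has two columns: per-level
#'   voxel counts and summed absolute deviations from neighborhood means.
#' @slot table numeric matrix.
#' @slot nVoxels integer, in-ROI voxel count of the source ROI.
#' @slot meta list of aggregation settings (directions, connectivity, alpha).
#'
#' @exportClass GrayLevelMatrix
setClass("GrayLevelMatrix",
  representation(family = "character", table = "matrix",
                 nVoxels = "integer", meta = "list"))

setValidity("GrayLevelMatrix", function(object) {
  if (!object@family %in% c("GLCM", "GLRLM", "GLSZM", "NGLDM", "NGTDM"))
    return("unknown matrix family")
  if (any(object@table < 0)) return("matrix entries must be non-negative")
  TRUE
})

#' WaveletBank: single-level undecimated 3D Coiflet filter bank
#'
#' @slot family character, filter family (only `"coif"`).
#' @slot order integer, Coiflet order in 1..5 (filter length 6 * order).
#' @slot mode character, boundary extension (only `"symmetric"`).
#' @slot lo numeric, low-pass analysis filter.
#' @slot hi numeric, high-pass analysis filter.
#'
#' @exportClass WaveletBank
setClass("WaveletBank",
  representation(family = "character", order = "integer", mode = "character",
                 lo = "numeric", hi = "numeric"))

#' PhantomConfig: parameters of the synthetic two-class cohort generator
#'
#' @slot nPerClass named integer(2), subjects per grade, names `III`, `IV`.
#' @slot gridShape integer(3), voxels per axis.
#' @slot voxelSizeMm numeric(1), isotropic voxel size in mm.
#' @slot intensityShift numeric, added CE-T1 tumor intensity for grade IV,
#'   in units of the brain-tissue SD (Z-units).
#' @slot textureSmoothnessRatio numeric > 0, ratio of the grade-III to
#'   grade-IV tumor texture correlation length (grade IV is rougher).
#' @slot tumorRadiusRatio numeric > 0, grade-IV over grade-III tumor radius.
#' @slot noiseSigma numeric >= 0, additive Gaussian noise SD (Z-units).
#' @slot seed integer, base seed; per-subject substreams are derived from it.
#' @slot cohortTag character, `"primary"` or `"validation"`.
#'
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(nPerClass = "integer", gridShape = "integer",
                 voxelSizeMm = "numeric", intensityShift = "numeric",
                 textureSmoothnessRatio = "numeric",
                 tumorRadiusRatio = "numeric", noiseSigma = "numeric",
                 seed = "integer", cohortTag = "character"))

setValidity("PhantomConfig", function(object) {
  if (length(object@nPerClass) != 2L || any(object@nPerClass < 1L))
    return("nPerClass must be two counts >= 1 (III, IV)")
  if (!identical(names(object@nPerClass), c("III", "IV")))
    return("nPerClass must be named III, IV")
  if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
    return("gridShape must be 3 integers >= 16")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@textureSmoothnessRatio <= 0 || object@tumorRadiusRatio <= 0)
    return("class-effect ratios must be > 0")
  if (!object@cohortTag %in% c("primary", "validation"))
    return("cohortTag must be 'primary' or 'validation'")
  TRUE
})

#' PhantomSubject: one synthetic subject (two channels + masks)
#'
#' @slot subjectId character.
#' @slot grade character, `"III"` or `"IV"`.
#' @slot ceT1,t2 [VolumeImage-class] channels on a common grid.
#' @slot tumorMask,brainMask [RoiMask-class] on the same grid; the tumor
#'   mask is non-empty, 26-connected and contained in the brain mask.
#'
#' @exportClass PhantomSubject
setClass("PhantomSubject",
  representation(subjectId = "character", grade = "character",
                 ceT1 = "VolumeImage", t2 = "VolumeImage",
                 tumorMask = "RoiMask", brainMask = "RoiMask"))

setValidity("PhantomSubject", function(object) {
  if (!object@grade %in% c("III", "IV")) return("grade must be III or IV")
  d <- dim(object@ceT1@values)
  for (x in list(object@t2@values, object@tumorMask@values,
                 object@brainMask@values))
    if (!identical(dim(x), d)) return("channels and masks must share a grid")
  if (sum(object@tumorMask@values) == 0) return("tumor mask is empty")
  if (any(object@tumorMask@values > object@brainMask@values))
    return("tumor mask must lie inside the brain mask")
  TRUE
})

#' FeatureTable: subjects-by-features radiomic value matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with features as rows
#' (rowData holds the descriptor components: sequence, filter, quant,
#' family, name) and subjects as columns (colData holds `subject_id`,
#' `grade`, `cohort`). The single assay `"features"` contains finite
#' feature values; row order is the canonical enumeration order of
#' [enumerateFeatureSpace()].
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "grade", "cohort")
  if (!all(need %in% colnames(cd)))
    return("colData must contain subject_id, grade, cohort")
  if (!all(cd$grade %in% c("III", "IV")))
    return("grades must be III or IV")
  if (!all(is.finite(SummarizedExperiment::assay(object, "features"))))
    return("feature values must be finite")
  TRUE
})

#' SelectionResult: outcome of two-stage feature selection
#'
#' @slot screened character, descriptor ids passing the WMW screen.
#' @slot pvalues named numeric, two-sided WMW p-values for all features.
#' @slot selected character, descriptor ids with nonzero LASSO slope.
#' @slot beta named numeric, slopes for the screened features.
#' @slot intercept numeric(1).
#' @slot lambda numeric(1), penalty chosen by repeated CV.
#' @slot cvCurve data.frame with columns `lambda`, `meanAUC`.
#' @slot center,scale named numeric, training standardization statistics
#'   for the screened features.
#'
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(screened = "character", pvalues = "numeric",
                 selected = "character", beta = "numeric",
                 intercept = "numeric", lambda = "numeric",
                 cvCurve = "data.frame", center = "numeric",
                 scale = "numeric"))

setValidity("SelectionResult", function(object) {
  if (!all(object@selected %in% object@screened))
    return("selected features must be a subset of the screened set")
  TRUE
})

#' EvaluationReport: per-model classification metrics
#'
#' @slot metrics data.frame with one row per model: `model`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc` (grade IV positive).
#' @slot roc named list of data.frames (`fpr`, `tpr`) per model.
#' @slot scores data.frame of per-subject out-of-fold (or validation)
#'   scores: `subject_id`, `grade`, one column per model.
#' @slot foldSelections list of per-fold selected descriptor sets (LOOCV).
#' @slot failedFolds integer, indices of folds where selection was empty.
#' @slot kind character, `"loocv"` or `"validation"`.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(metrics = "data.frame", roc = "list", scores = "data.frame",
                 foldSelections = "list", failedFolds = "integer",
                 kind = "character"))
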