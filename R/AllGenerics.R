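#' @rdname VolumeImage-class
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world position of the first voxel center.
#' @param modality `"CE-T1"` or `"T2"`.
#' @param state `"raw"` or `"zscored"`.
#' @return A [VolumeImage-class].
#' @export
VolumeImage <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        modality = "CE-T1", state = "raw") {
  new("VolumeImage", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality, state = state)
}

#' @rdname RoiMask-class
#' @param values 3D array of 0/1 (logical accepted).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world position of the first voxel center.
#' @return A [RoiMask-class].
#' @export
RoiMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(as.numeric(values != 0), dim = dim(values))
  new("RoiMask", values = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Extract the voxel array of an image or mask
#' @param x a [VolumeImage-class] or [RoiMask-class].
#' @return The 3D value array.
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname voxelValues
#' @export
setMethod("voxelValues", "VolumeImage", function(x) x@values)

#' @rdname voxelValues
#' @export
setMethod("voxelValues", "RoiMask", function(x) x@values)

#' Voxel spacing in mm
#' @param x a [VolumeImage-class] or [RoiMask-class].
#' @return numeric(3).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "RoiMask", function(x) x@spacing)

#' Normalization state of a volume
#' @param x a [VolumeImage-class].
#' @return `"raw"` or `"zscored"`.
#' @export
normalizationState <- function(x) x@state

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeImage %s [%d x %d x %d] spacing %s mm, %s\n",
              object@modality, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = "x"),
              object@state))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("RoiMask [%d x %d x %d] spacing %s mm, %d voxels set\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = "x"),
              as.integer(sum(object@values))))
})

setMethod("show", "PhantomSubject", function(object) {
  cat(sprintf("PhantomSubject %s (grade %s), tumor %d voxels\n",
              object@subjectId, object@grade,
              as.integer(sum(object@tumorMask@values))))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d screened, %d selected at lambda = %.4g\n",
    length(object@screened), length(object@selected), object@lambda))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%s)\n", object@kind))
  print(object@metrics, row.names = FALSE)
  if (length(object@failedFolds))
    cat(sprintf("failed folds: %d\n", length(object@failedFolds)))
})

setMethod("show", "GrayLevelMatrix", function(object) {
  cat(sprintf("GrayLevelMatrix %s [%d x %d], mass %.4g\n", object@family,
              nrow(object@table), ncol(object@table), sum(object@table)))
})

#' Accessors for FeatureTable
#'
#' `featureValues` returns the subjects-by-features numeric matrix (the
#' transpose of the internal features-by-subjects assay); `grades`,
#' `cohortTags` and `subjectIds` return per-subject annotations;
#' `descriptors` returns the canonical descriptor id strings.
#'
#' @param x a [FeatureTable-class].
#' @return See description.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname featureValues
#' @export
setGeneric("grades", function(x) standardGeneric("grades"))

#' @rdname featureValues
#' @export
setMethod("grades", "FeatureTable", function(x)
  as.character(SummarizedExperiment::colData(x)$grade))

#' @rdname featureValues
#' @export
setGeneric("cohortTags", function(x) standardGeneric("cohortTags"))

#' @rdname featureValues
#' @export
setMethod("cohortTags", "FeatureTable", function(x)
  as.character(SummarizedExperiment::colData(x)$cohort))

#' @rdname featureValues
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname featureValues
#' @export
setMethod("subjectIds", "FeatureTable", function(x)
  as.character(SummarizedExperiment::colData(x)$subject_id))

#' @rdname featureValues
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname featureValues
#' @export
setMethod("descriptors", "FeatureTable", function(x) rownames(x))

#' Selected and screened descriptor sets
#' @param x a [SelectionResult-class].
#' @return Character vector of descriptor ids.
#' @export
selectedFeatures <- function(x) x@selected

#' @rdname selectedFeatures
#' @export
screenedFeatures <- function(x) x@screened

#' Per-model metric table of an evaluation report
#' @param x an [EvaluationReport-class].
#' @return data.frame with accuracy, sensitivity, specificity, AUC per model.
#' @export
metrics <- function(x) x@metrics
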