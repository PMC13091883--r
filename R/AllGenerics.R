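#' @name accessors
#' @title Accessors for recallFC containers
#'
#' @description Slot accessors for the package's S4 containers. Use these in
#' preference to direct slot access.
#'
#' @param object A recallFC S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("featureArray", function(object) standardGeneric("featureArray"))

#' @rdname accessors
#' @export
setMethod("featureArray", "FeatureTensor", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("sceneIds", function(object) standardGeneric("sceneIds"))

#' @rdname accessors
#' @export
setMethod("sceneIds", "FeatureTensor", function(object) object@scene_ids)

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setMethod("subjectIds", "FeatureTensor", function(object) object@subject_ids)

#' @rdname accessors
#' @export
setGeneric("roiIds", function(object) standardGeneric("roiIds"))

#' @rdname accessors
#' @export
setMethod("roiIds", "FeatureTensor", function(object) object@roi_ids)

#' @rdname accessors
#' @export
setGeneric("storyId", function(object) standardGeneric("storyId"))

#' @rdname accessors
#' @export
setMethod("storyId", "FeatureTensor", function(object) object@story)

#' @rdname accessors
#' @export
setGeneric("lowRank", function(object) standardGeneric("lowRank"))

#' @rdname accessors
#' @export
setMethod("lowRank", "SceneDecomposition", function(object) object@L)

#' @rdname accessors
#' @export
setGeneric("sparsePart", function(object) standardGeneric("sparsePart"))

#' @rdname accessors
#' @export
setMethod("sparsePart", "SceneDecomposition", function(object) object@S)

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setMethod("converged", "SceneDecomposition", function(object) object@converged)

#' @rdname accessors
#' @export
setGeneric("residualTrace", function(object) standardGeneric("residualTrace"))

#' @rdname accessors
#' @export
setMethod("residualTrace", "SceneDecomposition",
          function(object) object@residual_trace)

#' @rdname accessors
#' @export
setGeneric("proposals", function(object) standardGeneric("proposals"))

#' @rdname accessors
#' @export
setMethod("proposals", "AnnotatorSegmentation", function(object) object@proposals)

#' @rdname accessors
#' @export
setGeneric("annotatorId", function(object) standardGeneric("annotatorId"))

#' @rdname accessors
#' @export
setMethod("annotatorId", "AnnotatorSegmentation",
          function(object) object@annotator)

#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(object) standardGeneric("reportMetrics"))

#' @rdname accessors
#' @export
setMethod("reportMetrics", "ClassificationReport",
          function(object) object@metrics)

#' @rdname accessors
#' @export
setGeneric("foldRecords", function(object) standardGeneric("foldRecords"))

#' @rdname accessors
#' @export
setMethod("foldRecords", "ClassificationReport", function(object) object@folds)

#' @rdname accessors
#' @export
setGeneric("shuffleSummary", function(object) standardGeneric("shuffleSummary"))

#' @rdname accessors
#' @export
setMethod("shuffleSummary", "ClassificationReport",
          function(object) object@shuffle)
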