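#' Acquisition timing geometry of an fMRI run
#'
#' Captures the scanner-side timing needed to convert narrative-relative
#' scene times (seconds) into acquisition frame (TR) indices: the repetition
#' time, the number of lead-in TRs acquired before the audio clip starts,
#' the silence inside the clip before the story begins, and the total run
#' length.
#'
#' @slot tr_s Seconds per repetition time (TR). Default protocols for
#'   naturalistic listening use 1.5 s.
#' @slot lead_in_trs Integer count of TRs acquired before clip onset.
#' @slot clip_story_onset_s Seconds of in-clip silence before the narrative
#'   starts.
#' @slot run_trs Total number of TRs in the run.
#'
#' @seealso [acquisitionTiming()], [sceneToTRWindow()]
#' @export
setClass("AcquisitionTiming",
  representation(
    tr_s = "numeric",
    lead_in_trs = "integer",
    clip_story_onset_s = "numeric",
    run_trs = "integer"
  )
)

setValidity("AcquisitionTiming", function(object) {
  msg <- character()
  if (!is_number(object@tr_s) || object@tr_s <= 0)
    msg <- c(msg, "tr_s must be a single positive number")
  if (length(object@lead_in_trs) != 1L || is.na(object@lead_in_trs) ||
      object@lead_in_trs < 0L)
    msg <- c(msg, "lead_in_trs must be a single non-negative integer")
  if (!is_number(object@clip_story_onset_s) || object@clip_story_onset_s < 0)
    msg <- c(msg, "clip_story_onset_s must be non-negative")
  if (length(object@run_trs) != 1L || is.na(object@run_trs) ||
      object@run_trs <= object@lead_in_trs)
    msg <- c(msg, "run_trs must exceed lead_in_trs")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionTiming object
#'
#' @param tr_s Seconds per TR (default 1.5).
#' @param lead_in_trs TRs acquired before clip onset (default 8).
#' @param clip_story_onset_s In-clip silence before the story, seconds.
#' @param run_trs Total TRs in the run.
#' @return An [AcquisitionTiming-class] object.
#' @examples
#' acquisitionTiming(run_trs = 294)
#' @export
acquisitionTiming <- function(tr_s = 1.5, lead_in_trs = 8L,
                              clip_story_onset_s = 0, run_trs) {
  new("AcquisitionTiming",
    tr_s = tr_s, lead_in_trs = as.integer(lead_in_trs),
    clip_story_onset_s = clip_story_onset_s, run_trs = as.integer(run_trs)
  )
}

setMethod("show", "AcquisitionTiming", function(object) {
  cat(sprintf(
    "AcquisitionTiming: TR = %g s, lead-in %d TRs, story onset %g s in clip, %d TRs/run\n",
    object@tr_s, object@lead_in_trs, object@clip_story_onset_s, object@run_trs
  ))
})

#' Half-open window of acquisition frames
#'
#' A 0-based, half-open interval `[start_tr, end_tr)` of TR indices within a
#' run. Half-open windows concatenate without overlap and slice time-series
#' matrices with `start_tr + 1 .. end_tr` in 1-based R indexing.
#'
#' @slot start_tr 0-based first frame (inclusive).
#' @slot end_tr 0-based end frame (exclusive).
#' @seealso [trWindow()], [sceneToTRWindow()]
#' @export
setClass("TRWindow",
  representation(start_tr = "integer", end_tr = "integer")
)

setValidity("TRWindow", function(object) {
  if (length(object@start_tr) != 1L || length(object@end_tr) != 1L)
    return("start_tr and end_tr must be single integers")
  if (is.na(object@start_tr) || is.na(object@end_tr))
    return("start_tr and end_tr must not be NA")
  if (object@start_tr < 0L) return("start_tr must be >= 0")
  if (object@end_tr <= object@start_tr) return("end_tr must exceed start_tr")
  TRUE
})

#' Construct a TRWindow
#' @param start_tr 0-based inclusive start frame.
#' @param end_tr 0-based exclusive end frame.
#' @return A [TRWindow-class] object.
#' @examples trWindow(14, 54)
#' @export
trWindow <- function(start_tr, end_tr) {
  new("TRWindow", start_tr = as.integer(start_tr), end_tr = as.integer(end_tr))
}

setMethod("show", "TRWindow", function(object) {
  cat(sprintf(
    "TRWindow: [%d, %d) (%d TRs)\n",
    object@start_tr, object@end_tr, object@end_tr - object@start_tr
  ))
})

#' One annotator's scene segmentation of a narrative
#'
#' Holds an ordered set of scene proposals for one annotator: onset/offset in
#' narrative-relative seconds and the identifiers of the recall questions
#' anchored to each scene. Structural invariants (positive durations,
#' non-empty question sets, sorted onsets) are enforced here; contiguity and
#' duration-range checks against a [durationBounds()] policy are performed by
#' [validateSegmentation()].
#'
#' @slot annotator Annotator identifier (unique within a study).
#' @slot proposals A data.frame with columns `onset_s`, `offset_s` and a
#'   list-column `questions` of character vectors.
#' @slot narrative_duration_s Length of the narrative in seconds.
#' @seealso [annotatorSegmentation()], [consensusScenes()]
#' @export
setClass("AnnotatorSegmentation",
  representation(
    annotator = "character",
    proposals = "data.frame",
    narrative_duration_s = "numeric"
  )
)

setValidity("AnnotatorSegmentation", function(object) {
  msg <- character()
  if (!is_string(object@annotator) || !nzchar(object@annotator))
    msg <- c(msg, "annotator must be a non-empty string")
  p <- object@proposals
  need <- c("onset_s", "offset_s", "questions")
  if (!all(need %in% names(p))) {
    msg <- c(msg, sprintf(
      "proposals must have columns %s", paste(need, collapse = ", ")
    ))
    return(msg)
  }
  if (nrow(p) == 0L) msg <- c(msg, "proposals must be non-empty")
  if (any(p$onset_s < 0)) msg <- c(msg, "onsets must be >= 0")
  if (any(p$offset_s <= p$onset_s))
    msg <- c(msg, "every offset must exceed its onset")
  if (is.unsorted(p$onset_s)) msg <- c(msg, "proposals must be sorted by onset")
  if (any(!vapply(p$questions, length, 1L)))
    msg <- c(msg, "every proposal needs at least one recall question")
  if (!is_number(object@narrative_duration_s) ||
      object@narrative_duration_s <= 0)
    msg <- c(msg, "narrative_duration_s must be a positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatorSegmentation
#'
#' Unsorted proposals are sorted by onset with a warning.
#'
#' @param annotator Annotator identifier.
#' @param onset_s,offset_s Numeric vectors of scene onsets/offsets (seconds).
#' @param questions List of character vectors: recall-question IDs per scene.
#' @param narrative_duration_s Narrative length in seconds.
#' @return An [AnnotatorSegmentation-class] object.
#' @examples
#' annotatorSegmentation("annA", c(0, 60), c(60, 150),
#'                       list("q1", c("q2", "q3")), 150)
#' @export
annotatorSegmentation <- function(annotator, onset_s, offset_s, questions,
                                  narrative_duration_s) {
  stopifnot(length(onset_s) == length(offset_s),
            length(onset_s) == length(questions))
  questions <- lapply(questions, as.character)
  if (is.unsorted(onset_s)) {
    warning(sprintf("proposals of annotator '%s' were unsorted; sorting by onset",
                    annotator))
    o <- order(onset_s, offset_s)
    onset_s <- onset_s[o]; offset_s <- offset_s[o]; questions <- questions[o]
  }
  p <- data.frame(onset_s = as.numeric(onset_s),
                  offset_s = as.numeric(offset_s))
  p$questions <- questions
  new("AnnotatorSegmentation", annotator = annotator, proposals = p,
      narrative_duration_s = narrative_duration_s)
}

setMethod("show", "AnnotatorSegmentation", function(object) {
  cat(sprintf(
    "AnnotatorSegmentation '%s': %d proposals over %g s\n",
    object@annotator, nrow(object@proposals), object@narrative_duration_s
  ))
})

#' Scene x subject x edge feature tensor
#'
#' Container for per-scene, per-subject vectorized functional-connectivity
#' features of one story and one ROI set: an array of shape (W scenes,
#' M subjects, r edges) with r = (R^2 - R) / 2 strictly-lower-triangle
#' Pearson correlations for R ROIs.
#'
#' @slot data Numeric array (W, M, r).
#' @slot scene_ids Integer scene indices (length W).
#' @slot subject_ids Character subject identifiers (length M).
#' @slot roi_ids Character ROI labels (length R); the edge order is the
#'   row-major strictly-lower-triangle traversal of the R x R matrix.
#' @slot story Story identifier (single string).
#' @seealso [sceneFCTensor()], [assembleFeatureTensor()],
#'   [flattenFeatureTensor()]
#' @export
setClass("FeatureTensor",
  representation(
    data = "array",
    scene_ids = "integer",
    subject_ids = "character",
    roi_ids = "character",
    story = "character"
  )
)

setValidity("FeatureTensor", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array (W, M, r)")
  R <- length(object@roi_ids)
  r <- (R^2 - R) / 2
  if (d[1] != length(object@scene_ids))
    msg <- c(msg, "dim 1 must match length(scene_ids)")
  if (d[2] != length(object@subject_ids))
    msg <- c(msg, "dim 2 must match length(subject_ids)")
  if (d[3] != r)
    msg <- c(msg, sprintf("dim 3 is %d but (R^2-R)/2 = %d for %d ROIs",
                          d[3], r, R))
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (length(object@story) != 1L) msg <- c(msg, "story must be a single string")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "FeatureTensor '%s': %d scenes x %d subjects x %d edges (%d ROIs)\n",
    object@story, d[1], d[2], d[3], length(object@roi_ids)
  ))
})

#' Low-rank plus sparse decomposition of one scene's stacked FC
#'
#' Result of robust principal component analysis on a scene's subjects x
#' edges matrix Z: a shared low-rank component L (stimulus-driven structure
#' common across subjects) and a sparse component S (idiosyncratic,
#' subject-specific deviations) with Z = L + S up to the solver tolerance.
#'
#' @slot scene Scene index.
#' @slot L Low-rank component matrix (same shape as the input).
#' @slot S Sparse component matrix.
#' @slot lambda Sparsity weight used.
#' @slot iterations Number of solver iterations run.
#' @slot residual Final relative Frobenius residual ||Z - L - S||_F /
#'   max(||Z||_F, 1).
#' @slot converged Logical: residual reached tolerance within max_iter.
#' @slot residual_trace Per-iteration relative residuals.
#' @seealso [rpcaDecompose()], [decomposeAllScenes()]
#' @export
setClass("SceneDecomposition",
  representation(
    scene = "integer",
    L = "matrix",
    S = "matrix",
    lambda = "numeric",
    iterations = "integer",
    residual = "numeric",
    converged = "logical",
    residual_trace = "numeric"
  )
)

setValidity("SceneDecomposition", function(object) {
  if (!identical(dim(object@L), dim(object@S)))
    return("L and S must have identical dimensions")
  if (!is_number(object@lambda) || object@lambda <= 0)
    return("lambda must be positive")
  TRUE
})

setMethod("show", "SceneDecomposition", function(object) {
  cat(sprintf(
    "SceneDecomposition (scene %d): %d x %d, rank(L) = %d, %.1f%% of S nonzero,\n  residual %.2e after %d iterations (%s)\n",
    object@scene, nrow(object@L), ncol(object@L),
    qr(object@L)$rank, 100 * mean(object@S != 0),
    object@residual, object@iterations,
    if (object@converged) "converged" else "NOT converged"
  ))
})

#' Cross-validated classification report
#'
#' Pooled held-out results of a leave-one-out cross-validation run: overall
#' accuracy with a bootstrap confidence interval, balanced accuracy, AUC,
#' per-sample held-out predictions, a calibration table, and (optionally)
#' a label-shuffling null summary attached by [shuffleNull()].
#'
#' @slot variant Feature variant: `"fc"`, `"low_rank"` or `"sparse"`.
#' @slot classifier Classifier family used.
#' @slot unit Cross-validation unit: `"sample"` or `"subject"`.
#' @slot metrics Named numeric vector: `accuracy`, `balanced_accuracy`, `auc`.
#' @slot ci95 Length-2 numeric: bootstrap 95% CI for accuracy.
#' @slot folds Per-sample data.frame: fold, subject, story, truth,
#'   prob_high, pred, correct.
#' @slot calibration Calibration-bin data.frame (see [calibrationCurve()]).
#' @slot shuffle List: label-shuffle null summary, or empty if not run.
#' @slot seed Seed used for stochastic components.
#' @seealso [runLOOCV()], [shuffleNull()]
#' @export
setClass("ClassificationReport",
  representation(
    variant = "character",
    classifier = "character",
    unit = "character",
    metrics = "numeric",
    ci95 = "numeric",
    folds = "data.frame",
    calibration = "data.frame",
    shuffle = "list",
    seed = "integer"
  )
)

setValidity("ClassificationReport", function(object) {
  msg <- character()
  m <- object@metrics
  if (!all(c("accuracy", "balanced_accuracy", "auc") %in% names(m)))
    msg <- c(msg, "metrics must contain accuracy, balanced_accuracy, auc")
  rates <- m[is.finite(m)]
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "all rates must lie in [0, 1]")
  if (length(object@ci95) != 2L)
    msg <- c(msg, "ci95 must have two elements")
  else if (all(is.finite(object@ci95)) && "accuracy" %in% names(m) &&
           (object@ci95[1] > m[["accuracy"]] + 1e-12 ||
            object@ci95[2] < m[["accuracy"]] - 1e-12))
    msg <- c(msg, "ci95 must bracket the accuracy")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassificationReport", function(object) {
  m <- object@metrics
  cat(sprintf(
    "ClassificationReport [%s | %s | %s-level LOOCV]\n  accuracy %.3f (95%% CI %.3f-%.3f), balanced %.3f, AUC %.3f, %d held-out samples\n",
    object@variant, object@classifier, object@unit,
    m[["accuracy"]], object@ci95[1], object@ci95[2],
    m[["balanced_accuracy"]], m[["auc"]], nrow(object@folds)
  ))
  if (length(object@shuffle)) {
    cat(sprintf(
      "  shuffle null: mean %.3f, sd %.3f over %d shuffles; observed percentile %.3f\n",
      object@shuffle$null_mean, object@shuffle$null_sd,
      length(object@shuffle$null_accuracy), object@shuffle$percentile
    ))
  }
})
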