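#' Per-scene Pearson functional connectivity
#'
#' Computes the R x R matrix of Pearson correlations between ROI time series
#' over one scene's TR window. Correlations are undefined for a constant
#' series, so a constant ROI within the window is an error naming the ROI.
#'
#' @param ts Numeric matrix, run TRs x R ROIs, with ROI labels as column
#'   names.
#' @param window A [TRWindow-class] (must span at least 3 TRs).
#' @param rois Optional character vector or index selecting a subset of ROIs
#'   (e.g. one network).
#' @return Symmetric correlation matrix with unit diagonal, dimnames = ROI
#'   labels.
#' @examples
#' ts <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("r", 1:4)))
#' fc <- computeSceneFC(ts, trWindow(0, 50))
#' @export
computeSceneFC <- function(ts, window, rois = NULL) {
  stopifnot(is.matrix(ts), is(window, "TRWindow"))
  if (!is.null(rois)) ts <- ts[, rois, drop = FALSE]
  if (ncol(ts) < 2L)
    stop2("need at least two ROIs", "recallFC_fc_error")
  if (window@end_tr > nrow(ts))
    stop2("window extends past the end of the time series", "recallFC_fc_error")
  n <- window@end_tr - window@start_tr
  if (n < 3L)
    stop2(sprintf("window of %d TRs is too short for correlation (need >= 3)", n),
          "recallFC_fc_error")
  x <- ts[(window@start_tr + 1L):window@end_tr, , drop = FALSE]
  if (anyNA(x)) stop2("time series contain missing values", "recallFC_fc_error")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop2(sprintf("constant ROI series within window: %s",
                  paste(bad, collapse = ", ")), "recallFC_fc_error")
  }
  fc <- cor(x)
  # guard against tiny asymmetries from floating point
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Vectorize the strictly lower triangle of a symmetric FC matrix
#'
#' Extracts the r = (R^2 - R)/2 unique off-diagonal values in row-major
#' order of the strictly lower triangle: (2,1), (3,1), (3,2), (4,1), ... —
#' i.e. edge k pairs row i with column j < i, rows visited in order. This
#' ordering is the package-wide edge convention.
#'
#' @param fc Symmetric numeric matrix (asymmetry beyond 1e-9 is an error).
#' @return Numeric vector of length (R^2 - R)/2.
#' @examples
#' vectorizeLowerTriangle(diag(2) + 0.3 - 0.3 * diag(2))
#' @export
vectorizeLowerTriangle <- function(fc) {
  stopifnot(is.matrix(fc), nrow(fc) == ncol(fc))
  if (max(abs(fc - t(fc))) > 1e-9)
    stop2("matrix is asymmetric beyond 1e-9", "recallFC_fc_error")
  tf <- t(fc)
  tf[upper.tri(tf)]
}

#' Rebuild a symmetric matrix from its vectorized lower triangle
#'
#' Inverse of [vectorizeLowerTriangle()] up to the diagonal, which is set to
#' `diag` (1 for correlation matrices).
#'
#' @param v Numeric vector of length (R^2 - R)/2.
#' @param diag Value placed on the diagonal (default 1).
#' @return Symmetric R x R matrix.
#' @export
devectorizeLowerTriangle <- function(v, diag = 1) {
  r <- length(v)
  R <- (1 + sqrt(1 + 8 * r)) / 2
  if (abs(R - round(R)) > 1e-8)
    stop2(sprintf("length %d is not (R^2-R)/2 for any integer R", r),
          "recallFC_fc_error")
  R <- as.integer(round(R))
  m <- matrix(0, R, R)
  tm <- t(m)
  tm[upper.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  base::diag(m) <- diag
  m
}

#' Assemble per-scene, per-subject FC matrices into a feature tensor
#'
#' Takes a complete scenes x subjects grid of symmetric FC matrices with a
#' common ROI set and stacks their vectorized lower triangles into a
#' [FeatureTensor-class] of shape (W, M, r).
#'
#' @param fc_grid List of length W (scenes); each element a named list of
#'   length M (subjects) of symmetric R x R matrices.
#' @param scene_ids Integer scene indices (default `seq_along(fc_grid)`).
#' @param subject_ids Subject identifiers (default names of the first scene's
#'   list).
#' @param roi_ids ROI labels (default dimnames of the first matrix).
#' @param story Story identifier (default `""`).
#' @param fisher_z Apply the Fisher z-transform (`atanh`) to correlations
#'   before stacking (default `FALSE`; values clipped to +/- (1 - 1e-12)
#'   first).
#' @return A [FeatureTensor-class].
#' @export
assembleFeatureTensor <- function(fc_grid, scene_ids = seq_along(fc_grid),
                                  subject_ids = NULL, roi_ids = NULL,
                                  story = "", fisher_z = FALSE) {
  W <- length(fc_grid)
  if (W == 0L) stop2("fc_grid is empty", "recallFC_fc_error")
  if (is.null(subject_ids)) subject_ids <- names(fc_grid[[1]])
  if (is.null(subject_ids))
    subject_ids <- paste0("sub", seq_along(fc_grid[[1]]))
  M <- length(subject_ids)

  missing_cells <- character()
  for (t in seq_len(W)) {
    have <- if (!is.null(names(fc_grid[[t]]))) names(fc_grid[[t]])
            else paste0("sub", seq_along(fc_grid[[t]]))
    lost <- setdiff(subject_ids, have)
    if (length(lost))
      missing_cells <- c(missing_cells,
                         sprintf("scene %s / subject %s", scene_ids[t], lost))
  }
  if (length(missing_cells))
    stop2(paste0("missing FC cells: ", paste(missing_cells, collapse = "; ")),
          "recallFC_fc_error")

  first <- fc_grid[[1]][[1]]
  R <- nrow(first)
  if (is.null(roi_ids)) {
    roi_ids <- colnames(first)
    if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(R))
  }
  r <- (R^2 - R) / 2
  arr <- array(NA_real_, dim = c(W, M, r))
  for (t in seq_len(W)) {
    for (m in seq_len(M)) {
      fc <- fc_grid[[t]][[m]]
      if (!is.matrix(fc) || nrow(fc) != R)
        stop2(sprintf(
          "scene %s / subject %s: FC has %s ROIs, expected %d",
          scene_ids[t], subject_ids[m],
          if (is.matrix(fc)) nrow(fc) else "invalid", R
        ), "recallFC_fc_error")
      v <- vectorizeLowerTriangle(fc)
      if (fisher_z) v <- atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12))
      arr[t, m, ] <- v
    }
  }
  new("FeatureTensor", data = arr, scene_ids = as.integer(scene_ids),
      subject_ids = subject_ids, roi_ids = roi_ids, story = story)
}

#' Compute a feature tensor directly from subject time series
#'
#' Convenience wrapper: computes [computeSceneFC()] for every scene window
#' and subject, then assembles the [FeatureTensor-class].
#'
#' @param ts_list Named list of subject time-series matrices (run TRs x R).
#' @param windows List of [TRWindow-class] objects, one per scene.
#' @param rois Optional ROI subset (passed to [computeSceneFC()]).
#' @param scene_ids Integer scene indices (default `seq_along(windows)`).
#' @param story Story identifier.
#' @param fisher_z See [assembleFeatureTensor()].
#' @return A [FeatureTensor-class].
#' @export
sceneFCTensor <- function(ts_list, windows, rois = NULL,
                          scene_ids = seq_along(windows), story = "",
                          fisher_z = FALSE) {
  stopifnot(length(ts_list) >= 1L, length(windows) >= 1L)
  grid <- lapply(windows, function(w) {
    lapply(ts_list, computeSceneFC, window = w, rois = rois)
  })
  assembleFeatureTensor(grid, scene_ids = scene_ids,
                        subject_ids = names(ts_list), story = story,
                        roi_ids = NULL, fisher_z = fisher_z)
}

#' Flatten a feature tensor (or several) into a sample matrix
#'
#' Reshapes (W, M, r) tensors into a ((W * M) x r) design matrix with one row
#' per scene-subject sample, plus the index map needed for leakage-aware
#' cross-validation. Samples are ordered scene-major within each tensor and
#' tensors (stories) are stacked in the order given.
#'
#' @param tensors A [FeatureTensor-class] or list of them (one per story).
#' @return List with `x` (matrix, rownames `story.scene.subject`) and `map`
#'   (data.frame: `story`, `scene`, `subject`).
#' @export
flattenFeatureTensor <- function(tensors) {
  if (is(tensors, "FeatureTensor")) tensors <- list(tensors)
  parts <- lapply(tensors, function(tn) {
    d <- dim(tn@data)
    x <- matrix(aperm(tn@data, c(2, 1, 3)), d[1] * d[2], d[3])
    map <- data.frame(
      story = tn@story,
      scene = rep(tn@scene_ids, each = d[2]),
      subject = rep(tn@subject_ids, d[1]),
      stringsAsFactors = FALSE
    )
    list(x = x, map = map)
  })
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  map <- do.call(rbind, lapply(parts, `[[`, "map"))
  colnames(x) <- paste0("edge", seq_len(ncol(x)))
  rownames(x) <- paste(map$story, map$scene, map$subject, sep = ".")
  list(x = x, map = map)
}
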