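#' Scene-level recall score for one subject
#'
#' A scene's behavioural label is the arithmetic mean of the subject's
#' per-question recall scores over the recall questions anchored to that
#' scene.
#'
#' @param records Data.frame of recall answers: `subject_id`, `question_id`,
#'   `score` in `[0, 1]`, one row per (subject, question).
#' @param questions Character vector of the scene's question IDs (or a
#'   one-row consensus-scene data.frame, whose `questions` list-column is
#'   used).
#' @param subject_id Subject identifier.
#' @param missing Policy when the subject has not answered every scene
#'   question: `"error"` (default) or `"available"` (mean over answered
#'   questions, with a warning).
#' @return Mean score in `[0, 1]`.
#' @examples
#' rec <- data.frame(subject_id = "s1", question_id = c("q1", "q2", "q3"),
#'                   score = c(1, 0, 1))
#' sceneRecallScore(rec, c("q1", "q2", "q3"), "s1")  # 0.667
#' @export
sceneRecallScore <- function(records, questions, subject_id,
                             missing = c("error", "available")) {
  missing <- match.arg(missing)
  if (is.data.frame(questions)) questions <- unlist(questions$questions)
  questions <- as.character(questions)
  if (!length(questions))
    stop2("scene has no recall questions", "recallFC_label_error")
  rows <- records[records$subject_id == subject_id &
                    records$question_id %in% questions, , drop = FALSE]
  lost <- setdiff(questions, rows$question_id)
  if (length(lost)) {
    if (missing == "error")
      stop2(sprintf("subject '%s' has no answer for question(s): %s",
                    subject_id, paste(lost, collapse = ", ")),
            "recallFC_missing_answers")
    warning(sprintf("subject '%s': averaging over %d of %d questions",
                    subject_id, nrow(rows), length(questions)))
    if (nrow(rows) == 0L)
      stop2(sprintf("subject '%s' answered none of the scene's questions",
                    subject_id), "recallFC_missing_answers")
  }
  mean(rows$score)
}

#' Scene x subject table of mean recall scores
#'
#' Applies [sceneRecallScore()] over every (scene, subject) pair.
#'
#' @param records Recall answer data.frame (see [sceneRecallScore()]).
#' @param scenes Consensus scene data.frame with `scene` and `questions`
#'   columns.
#' @param subjects Subject IDs (default: all subjects in `records`).
#' @param missing Missing-answer policy (see [sceneRecallScore()]).
#' @return Data.frame: `scene`, `subject`, `mean_score`, `n_questions`.
#' @export
sceneRecallScores <- function(records, scenes,
                              subjects = sort(unique(records$subject_id)),
                              missing = c("error", "available")) {
  missing <- match.arg(missing)
  out <- expand.grid(subject = subjects, scene = scenes$scene,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("scene", "subject")]
  qs <- scenes$questions[match(out$scene, scenes$scene)]
  out$mean_score <- vapply(seq_len(nrow(out)), function(i) {
    sceneRecallScore(records, qs[[i]], out$subject[i], missing = missing)
  }, 1)
  out$n_questions <- vapply(qs, length, 1L)
  rownames(out) <- NULL
  out
}

#' Binarize scene recall scores into high/low labels
#'
#' Two rules are provided because studies report the class balance rather
#' than the cut point. `"threshold"` labels a scene-subject sample high when
#' its mean score is at least `theta` (default 0.5). `"quantile"` labels the
#' lowest `q` fraction of scores low (default `q = 0.25`, reproducing a
#' roughly 1:3 low:high balance). Ties at the boundary go to high in both
#' rules.
#'
#' @param scores Numeric vector of mean scores, or the data.frame from
#'   [sceneRecallScores()] (a `class` column is then appended).
#' @param rule `"threshold"` or `"quantile"`.
#' @param theta Threshold for the threshold rule (default 0.5).
#' @param q Low-class fraction for the quantile rule (default 0.25). All
#'   scores identical is a degenerate distribution and an error under this
#'   rule.
#' @return Factor with levels `c("low", "high")` (or the input data.frame
#'   with a `class` column).
#' @examples
#' binarizeLabels(c(0.2, 0.4, 0.8, 1.0))                      # threshold 0.5
#' binarizeLabels(c(0.1, 0.6, 0.7, 0.9), rule = "quantile")   # one low
#' @export
binarizeLabels <- function(scores, rule = c("threshold", "quantile"),
                           theta = 0.5, q = 0.25) {
  rule <- match.arg(rule)
  df <- NULL
  if (is.data.frame(scores)) {
    df <- scores
    scores <- scores$mean_score
  }
  if (rule == "threshold") {
    cls <- ifelse(scores >= theta, "high", "low")
  } else {
    if (length(unique(scores)) == 1L)
      stop2("degenerate distribution: all scores identical",
            "recallFC_label_error")
    if (q <= 0 || q >= 1)
      stop2("q must lie strictly in (0, 1)", "recallFC_label_error")
    k <- floor(q * length(scores))
    if (k == 0L) {
      cls <- rep("high", length(scores))
    } else {
      cut <- sort(scores)[k]
      # low strictly below the k-th order statistic's successor; ties at the
      # boundary value go to high
      cut_next <- sort(scores)[min(k + 1L, length(scores))]
      cls <- ifelse(scores <= cut & scores < cut_next, "low", "high")
    }
  }
  cls <- factor(cls, levels = c("low", "high"))
  if (!is.null(df)) {
    df$class <- cls
    return(df)
  }
  cls
}
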