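#' Scene duration bounds policy
#'
#' Scene durations are constrained to a predefined range so that windows are
#' long enough for stable connectivity estimates but short enough not to blur
#' distinct narrative events. The conventional range for naturalistic
#' listening is 45 to 120 seconds.
#'
#' @param min_s Minimum scene duration, seconds (default 45).
#' @param max_s Maximum scene duration, seconds (default 120).
#' @param epsilon_s Tolerance for continuity checks on annotator input,
#'   seconds (default 0.5). Consensus output is exactly contiguous.
#' @return A list of class `DurationBounds`.
#' @examples
#' durationBounds()
#' @export
durationBounds <- function(min_s = 45, max_s = 120, epsilon_s = 0.5) {
  if (!is_number(min_s) || !is_number(max_s) || min_s <= 0 || min_s >= max_s)
    stop2("durationBounds requires 0 < min_s < max_s", "recallFC_bounds_error")
  if (!is_number(epsilon_s) || epsilon_s < 0)
    stop2("epsilon_s must be non-negative", "recallFC_bounds_error")
  structure(list(min_s = min_s, max_s = max_s, epsilon_s = epsilon_s),
            class = "DurationBounds")
}

#' Validate one annotator's segmentation against the duration/continuity rules
#'
#' Each proposal is checked for (i) duration inside `[min_s, max_s]` and
#' (ii) continuity at its boundaries: consecutive proposals must touch within
#' `epsilon_s`, the first onset must be 0 within tolerance, and the last
#' offset must reach the narrative end within tolerance.
#'
#' @param seg An [AnnotatorSegmentation-class].
#' @param bounds A [durationBounds()] policy.
#' @return A data.frame with one row per proposal: `proposal`, `onset_s`,
#'   `offset_s`, `duration_s`, `duration_ok`, `continuity_ok`, `valid`, and
#'   a `reasons` character column. Gap/overlap locations are attached as the
#'   `"discontinuities"` attribute (data.frame: `after_proposal`, `gap_s`).
#' @examples
#' seg <- annotatorSegmentation("a", c(0, 60), c(60, 150),
#'                              list("q1", "q2"), 150)
#' validateSegmentation(seg, durationBounds())
#' @export
validateSegmentation <- function(seg, bounds = durationBounds()) {
  stopifnot(is(seg, "AnnotatorSegmentation"), inherits(bounds, "DurationBounds"))
  p <- seg@proposals
  if (nrow(p) == 0L)
    stop2("segmentation has no proposals", "recallFC_empty_segmentation")
  eps <- bounds$epsilon_s
  n <- nrow(p)
  dur <- p$offset_s - p$onset_s
  duration_ok <- dur >= bounds$min_s & dur <= bounds$max_s

  # boundary deviations: before proposal i (i = 1 uses narrative start)
  lead_gap <- c(p$onset_s[1], if (n > 1) p$onset_s[-1] - p$offset_s[-n])
  tail_gap <- seg@narrative_duration_s - p$offset_s[n]
  cont_before <- abs(lead_gap) <= eps
  cont_after <- c(cont_before[-1], abs(tail_gap) <= eps)
  continuity_ok <- cont_before & cont_after

  reasons <- vapply(seq_len(n), function(i) {
    r <- character()
    if (dur[i] < bounds$min_s)
      r <- c(r, sprintf("duration < %g", bounds$min_s))
    if (dur[i] > bounds$max_s)
      r <- c(r, sprintf("duration > %g", bounds$max_s))
    if (!cont_before[i])
      r <- c(r, sprintf("discontinuity before proposal (%+.3g s)", lead_gap[i]))
    if (!cont_after[i]) {
      g <- if (i < n) lead_gap[i + 1] else tail_gap
      r <- c(r, sprintf("discontinuity after proposal (%+.3g s)", g))
    }
    paste(r, collapse = "; ")
  }, character(1))

  out <- data.frame(
    proposal = seq_len(n), onset_s = p$onset_s, offset_s = p$offset_s,
    duration_s = dur, duration_ok = duration_ok,
    continuity_ok = continuity_ok, valid = duration_ok & continuity_ok,
    reasons = reasons, stringsAsFactors = FALSE
  )
  bad <- which(abs(lead_gap) > eps)
  attr(out, "discontinuities") <- data.frame(
    after_proposal = bad - 1L, gap_s = lead_gap[bad]
  )
  out
}

# Union-find over proposal indices
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Group scene proposals across annotators by shared recall questions
#'
#' Proposals from distinct annotators are linked whenever their
#' recall-question sets intersect; groups are the connected components of
#' that graph (transitive closure, so the grouping is deterministic and
#' independent of input order). Groups supported by fewer than `min_support`
#' distinct annotators are returned separately as unsupported.
#'
#' @param segmentations List of [AnnotatorSegmentation-class] objects with
#'   distinct annotator IDs (at least 2).
#' @param min_support Minimum number of distinct supporting annotators for a
#'   consensus group (default 2).
#' @return List with elements `groups` and `unsupported`, each a list of
#'   data.frames with columns `annotator`, `onset_s`, `offset_s` and
#'   list-column `questions`.
#' @export
matchProposals <- function(segmentations, min_support = 2L) {
  if (length(segmentations) < 2L)
    stop2("need at least two annotator segmentations", "recallFC_match_error")
  ids <- vapply(segmentations, annotatorId, character(1))
  if (anyDuplicated(ids))
    stop2(sprintf("duplicate annotator id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          "recallFC_match_error")

  flat <- do.call(rbind, lapply(segmentations, function(s) {
    p <- s@proposals
    data.frame(annotator = s@annotator, onset_s = p$onset_s,
               offset_s = p$offset_s, stringsAsFactors = FALSE)
  }))
  flat$questions <- do.call(c, lapply(segmentations,
                                      function(s) s@proposals$questions))
  n <- nrow(flat)

  parent <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (flat$annotator[i] != flat$annotator[j] &&
          length(intersect(flat$questions[[i]], flat$questions[[j]]))) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  groups <- split(seq_len(n), comp)
  # deterministic order: by earliest onset, then offset, then smallest question
  ord <- order(
    vapply(groups, function(ix) min(flat$onset_s[ix]), 1),
    vapply(groups, function(ix) min(flat$offset_s[ix]), 1),
    vapply(groups, function(ix) min(unlist(flat$questions[ix])), "")
  )
  groups <- groups[ord]
  dfs <- lapply(groups, function(ix) flat[ix, , drop = FALSE])
  support <- vapply(dfs, function(g) length(unique(g$annotator)), 1L)
  list(groups = unname(dfs[support >= min_support]),
       unsupported = unname(dfs[support < min_support]))
}

#' Build consensus scenes by averaging matched proposal boundaries
#'
#' Each supported group becomes one consensus scene whose onset (offset) is
#' the arithmetic mean of its members' onsets (offsets); its question set is
#' the union over members. Scenes are sorted by (onset, offset, smallest
#' question ID) and indexed from 1. Scenes whose averaged duration falls
#' outside `bounds` are flagged, not dropped (dropping would break narrative
#' continuity).
#'
#' @param groups The `groups` element returned by [matchProposals()].
#' @param bounds A [durationBounds()] policy.
#' @param narrative_duration_s Narrative length in seconds.
#' @return A data.frame with columns `scene`, `onset_s`, `offset_s`,
#'   `n_support`, `duration_flag`, and list-columns `supporters`,
#'   `questions`.
#' @export
buildConsensusScenes <- function(groups, bounds = durationBounds(),
                                 narrative_duration_s) {
  if (!length(groups))
    stop2("no consensus: no group has the required annotator support",
          "recallFC_no_consensus")
  onset <- vapply(groups, function(g) mean(g$onset_s), 1)
  offset <- vapply(groups, function(g) mean(g$offset_s), 1)
  supporters <- lapply(groups, function(g) sort(unique(g$annotator)))
  questions <- lapply(groups, function(g) sort(unique(unlist(g$questions))))
  minq <- vapply(questions, function(q) q[1], "")
  o <- order(onset, offset, minq)
  out <- data.frame(
    scene = seq_along(groups),
    onset_s = onset[o], offset_s = offset[o],
    n_support = vapply(supporters, length, 1L)[o]
  )
  dur <- out$offset_s - out$onset_s
  out$duration_flag <- dur < bounds$min_s | dur > bounds$max_s
  out$supporters <- supporters[o]
  out$questions <- questions[o]
  out
}

#' Restore exact contiguity of averaged consensus scenes
#'
#' Boundary averaging can leave small gaps or overlaps between adjacent
#' consensus scenes. Each internal boundary is replaced by the midpoint of
#' the previous scene's offset and the next scene's onset; the first onset is
#' clamped to 0 and the last offset to the narrative duration, so the output
#' exactly partitions `[0, narrative_duration_s]`.
#'
#' @param scenes Consensus scene data.frame from [buildConsensusScenes()],
#'   sorted and non-nested.
#' @param narrative_duration_s Narrative length in seconds.
#' @return The scene data.frame with repaired, exactly contiguous boundaries.
#' @examples
#' sc <- data.frame(scene = 1:2, onset_s = c(0, 62), offset_s = c(58, 120))
#' repairContinuity(sc, 120)
#' @export
repairContinuity <- function(scenes, narrative_duration_s) {
  n <- nrow(scenes)
  if (n == 0L) stop2("no scenes to repair", "recallFC_no_consensus")
  onset <- scenes$onset_s
  offset <- scenes$offset_s
  if (n > 1L) {
    mid <- (offset[-n] + onset[-1]) / 2
    # repaired boundaries (including narrative start/end) must stay increasing
    b <- c(0, mid, narrative_duration_s)
    bad <- which(diff(b) <= 0)
    if (length(bad))
      stop2(sprintf(
        "continuity repair would invert scene order at boundary(ies): %s",
        paste(bad, collapse = ", ")
      ), "recallFC_repair_error")
    offset[-n] <- mid
    onset[-1] <- mid
  }
  onset[1] <- 0
  offset[n] <- narrative_duration_s
  scenes$onset_s <- onset
  scenes$offset_s <- offset
  scenes
}

#' Merge multiple annotators' segmentations into consensus scenes
#'
#' End-to-end consensus: validates every annotator's proposals against the
#' duration/continuity policy, groups proposals across annotators by shared
#' recall questions, averages boundaries within each supported group, and
#' repairs contiguity so the result exactly partitions the narrative.
#'
#' Proposals that fail hard validation (duration out of range, discontinuous)
#' are dropped with a warning before matching; they cannot support a
#' consensus scene. The result is invariant to the order in which annotators
#' are supplied.
#'
#' @param segmentations List of [AnnotatorSegmentation-class] objects (>= 2,
#'   distinct IDs, identical `narrative_duration_s`).
#' @param bounds A [durationBounds()] policy.
#' @param min_support Minimum distinct annotators per consensus scene
#'   (default 2).
#' @param drop_invalid Drop proposals failing validation with a warning
#'   (default), or raise an error (`FALSE`).
#' @return Consensus scene data.frame (see [buildConsensusScenes()]) with
#'   exactly contiguous boundaries covering `[0, narrative_duration]`.
#' @examples
#' a <- annotatorSegmentation("a", c(0, 60), c(60, 120), list("q1", "q2"), 120)
#' b <- annotatorSegmentation("b", c(0, 58), c(58, 120),
#'                            list("q1", c("q2", "q3")), 120)
#' consensusScenes(list(a, b))
#' @export
consensusScenes <- function(segmentations, bounds = durationBounds(),
                            min_support = 2L, drop_invalid = TRUE) {
  durs <- vapply(segmentations, function(s) s@narrative_duration_s, 1)
  if (length(unique(durs)) != 1L)
    stop2("annotators disagree on narrative_duration_s", "recallFC_match_error")
  D <- durs[1]

  kept <- lapply(segmentations, function(s) {
    rep <- validateSegmentation(s, bounds)
    if (all(rep$valid)) return(s)
    if (!drop_invalid)
      stop2(sprintf("annotator '%s' has invalid proposals: %s", s@annotator,
                    paste(which(!rep$valid), collapse = ", ")),
            "recallFC_validation_error")
    warning(sprintf(
      "annotator '%s': dropping %d invalid proposal(s) (%s)",
      s@annotator, sum(!rep$valid),
      paste(rep$reasons[!rep$valid], collapse = " | ")
    ))
    keep <- rep$valid
    if (!any(keep)) return(NULL)
    p <- s@proposals[keep, , drop = FALSE]
    annotatorSegmentation(s@annotator, p$onset_s, p$offset_s, p$questions, D)
  })
  kept <- Filter(Negate(is.null), kept)
  if (length(kept) < 2L)
    stop2("fewer than two annotators remain after validation",
          "recallFC_no_consensus")

  m <- matchProposals(kept, min_support = min_support)
  scenes <- buildConsensusScenes(m$groups, bounds, D)
  repairContinuity(scenes, D)
}
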