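#' Convert a duration in seconds to a count of acquisition frames
#'
#' Uses the ceiling convention: a duration is covered by the smallest whole
#' number of TRs at least as long. A 400 s narrative at TR = 1.5 s spans
#' 267 TRs; a 536 s narrative spans 358. A tiny numeric guard prevents exact
#' multiples from being rounded up by floating-point error.
#'
#' @param duration_s Duration in seconds (>= 0).
#' @param tr_s Seconds per TR (default 1.5).
#' @return Integer TR count.
#' @examples
#' secondsToTRCount(400)  # 267
#' secondsToTRCount(536)  # 358
#' @export
secondsToTRCount <- function(duration_s, tr_s = 1.5) {
  if (any(!is.finite(duration_s)) || any(duration_s < 0))
    stop2("duration_s must be non-negative", "recallFC_timing_error")
  if (!is_number(tr_s) || tr_s <= 0)
    stop2("tr_s must be positive", "recallFC_timing_error")
  as.integer(ceiling(duration_s / tr_s - 1e-9))
}

#' Convert a count of acquisition frames to seconds
#'
#' Exact multiplication: 294 TRs at TR = 1.5 s is 441 s; 390 TRs is 585 s.
#'
#' @param n_trs TR count (>= 0).
#' @param tr_s Seconds per TR (default 1.5).
#' @return Duration in seconds.
#' @examples
#' trCountToSeconds(294)  # 441
#' @export
trCountToSeconds <- function(n_trs, tr_s = 1.5) {
  if (any(!is.finite(n_trs)) || any(n_trs < 0))
    stop2("n_trs must be non-negative", "recallFC_timing_error")
  if (!is_number(tr_s) || tr_s <= 0)
    stop2("tr_s must be positive", "recallFC_timing_error")
  n_trs * tr_s
}

#' Map a narrative-relative scene to a window of acquisition frames
#'
#' The scene's narrative-relative onset/offset are shifted into global run
#' time by the acquisition geometry (`lead_in_trs * tr_s +
#' clip_story_onset_s`), then converted to a 0-based, half-open TR window
#' `[floor(onset / tr), ceiling(offset / tr))` so the window fully covers the
#' scene.
#'
#' @param onset_s,offset_s Scene boundaries in narrative-relative seconds, or
#'   a one-row consensus-scene data.frame in `onset_s` (then `offset_s` may
#'   be missing).
#' @param timing An [AcquisitionTiming-class].
#' @return A [TRWindow-class].
#' @examples
#' tm <- acquisitionTiming(tr_s = 1.5, lead_in_trs = 8,
#'                         clip_story_onset_s = 9, run_trs = 294)
#' sceneToTRWindow(0, 60, tm)  # TRs [14, 54)
#' @export
sceneToTRWindow <- function(onset_s, offset_s, timing) {
  if (is.data.frame(onset_s)) {
    offset_s <- onset_s$offset_s
    onset_s <- onset_s$onset_s
  }
  stopifnot(is(timing, "AcquisitionTiming"),
            length(onset_s) == 1L, length(offset_s) == 1L,
            offset_s > onset_s, onset_s >= 0)
  shift <- timing@lead_in_trs * timing@tr_s + timing@clip_story_onset_s
  g_on <- shift + onset_s
  g_off <- shift + offset_s
  start_tr <- as.integer(floor(g_on / timing@tr_s + 1e-9))
  end_tr <- as.integer(ceiling(g_off / timing@tr_s - 1e-9))
  if (end_tr > timing@run_trs)
    stop2(sprintf(
      "scene [%g, %g) s maps to TR window [%d, %d) beyond run end (%d TRs)",
      onset_s, offset_s, start_tr, end_tr, timing@run_trs
    ), "recallFC_timing_error")
  trWindow(start_tr, end_tr)
}

#' Map a table of contiguous scenes to non-overlapping TR windows
#'
#' Applies [sceneToTRWindow()] to each scene and resolves boundary frames
#' that the floor/ceiling convention would assign to two adjacent scenes:
#' such a frame is given to the later scene (the earlier window is
#' truncated).
#'
#' @param scenes Consensus scene data.frame (columns `scene`, `onset_s`,
#'   `offset_s`), sorted by onset.
#' @param timing An [AcquisitionTiming-class].
#' @return Named list of [TRWindow-class] objects, one per scene, names taken
#'   from `scenes$scene`.
#' @export
scenesToTRWindows <- function(scenes, timing) {
  wins <- lapply(seq_len(nrow(scenes)), function(i) {
    tryCatch(
      sceneToTRWindow(scenes$onset_s[i], scenes$offset_s[i], timing),
      recallFC_timing_error = function(e) {
        stop2(sprintf("scene %s: %s", scenes$scene[i], conditionMessage(e)),
              "recallFC_timing_error")
      }
    )
  })
  if (length(wins) > 1L) {
    for (i in seq_len(length(wins) - 1L)) {
      if (wins[[i + 1L]]@start_tr < wins[[i]]@end_tr) {
        if (wins[[i + 1L]]@start_tr <= wins[[i]]@start_tr)
          stop2(sprintf("scene %s window vanishes after overlap resolution",
                        scenes$scene[i]), "recallFC_timing_error")
        wins[[i]] <- trWindow(wins[[i]]@start_tr, wins[[i + 1L]]@start_tr)
      }
    }
  }
  names(wins) <- as.character(scenes$scene)
  wins
}
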