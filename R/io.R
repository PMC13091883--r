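#' Read one annotator's segmentation from JSON
#'
#' Expected schema: `{"annotator": str, "story": str (optional),
#' "narrative_duration_s": num, "scenes": [{"onset_s": num, "offset_s": num,
#' "questions": [str, ...]}, ...]}`. The parsed proposals are sorted and
#' checked for gross structural problems; overlapping scenes beyond
#' `epsilon_s` are rejected.
#'
#' @param path JSON file path.
#' @param epsilon_s Overlap tolerance in seconds (default 0.5).
#' @return An [AnnotatorSegmentation-class]; the story tag (if present) is
#'   attached as the `"story"` attribute.
#' @export
readAnnotatorSegmentation <- function(path, epsilon_s = 0.5) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop2(
                  sprintf("%s: not valid JSON (%s)", path, conditionMessage(e)),
                  "recallFC_schema_error"))
  for (f in c("annotator", "narrative_duration_s", "scenes"))
    if (is.null(j[[f]]))
      stop2(sprintf("%s: missing field at /%s", path, f),
            "recallFC_schema_error")
  sc <- j$scenes
  if (!length(sc))
    stop2(sprintf("%s: /scenes is empty", path), "recallFC_schema_error")
  get_num <- function(i, f) {
    v <- sc[[i]][[f]]
    if (!is.numeric(v) || length(v) != 1L)
      stop2(sprintf("%s: /scenes/%d/%s must be a number", path, i, f),
            "recallFC_schema_error")
    v
  }
  onset <- vapply(seq_along(sc), get_num, 1, f = "onset_s")
  offset <- vapply(seq_along(sc), get_num, 1, f = "offset_s")
  if (any(onset < 0))
    stop2(sprintf("%s: negative onset at /scenes/%d/onset_s", path,
                  which(onset < 0)[1]), "recallFC_schema_error")
  if (any(offset <= onset))
    stop2(sprintf("%s: offset <= onset at /scenes/%d", path,
                  which(offset <= onset)[1]), "recallFC_schema_error")
  questions <- lapply(seq_along(sc), function(i) {
    q <- unlist(sc[[i]]$questions)
    if (!length(q))
      stop2(sprintf("%s: empty /scenes/%d/questions", path, i),
            "recallFC_schema_error")
    as.character(q)
  })
  o <- order(onset, offset)
  onset <- onset[o]; offset <- offset[o]; questions <- questions[o]
  ovl <- which(onset[-1] < offset[-length(offset)] - epsilon_s)
  if (length(ovl))
    stop2(sprintf("%s: scenes %d and %d overlap by more than %g s", path,
                  ovl[1], ovl[1] + 1L, epsilon_s), "recallFC_schema_error")
  seg <- annotatorSegmentation(j$annotator, onset, offset, questions,
                               j$narrative_duration_s)
  attr(seg, "story") <- j$story
  seg
}

#' Write one annotator's segmentation to JSON
#' @param seg An [AnnotatorSegmentation-class].
#' @param path Output file.
#' @param story Optional story tag stored in the file.
#' @return `path`, invisibly.
#' @export
writeAnnotatorSegmentation <- function(seg, path, story = NULL) {
  p <- seg@proposals
  obj <- list(
    annotator = seg@annotator,
    narrative_duration_s = seg@narrative_duration_s,
    scenes = lapply(seq_len(nrow(p)), function(i) list(
      onset_s = p$onset_s[i], offset_s = p$offset_s[i],
      questions = as.list(p$questions[[i]])
    ))
  )
  if (!is.null(story)) obj$story <- story
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write consensus scenes to JSON
#' @param scenes Consensus scene data.frame (see [consensusScenes()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeConsensusScenes <- function(scenes, path) {
  obj <- lapply(seq_len(nrow(scenes)), function(i) list(
    scene = scenes$scene[i], onset_s = scenes$onset_s[i],
    offset_s = scenes$offset_s[i],
    supporters = as.list(scenes$supporters[[i]]),
    questions = as.list(scenes$questions[[i]]),
    duration_flag = scenes$duration_flag[i]
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read consensus scenes from JSON
#' @param path JSON file written by [writeConsensusScenes()].
#' @return Consensus scene data.frame.
#' @export
readConsensusScenes <- function(path) {
  j <- jsonlite::read_json(path)
  out <- data.frame(
    scene = vapply(j, function(s) as.integer(s$scene), 1L),
    onset_s = vapply(j, function(s) as.numeric(s$onset_s), 1),
    offset_s = vapply(j, function(s) as.numeric(s$offset_s), 1),
    n_support = vapply(j, function(s) length(s$supporters), 1L),
    duration_flag = vapply(j, function(s) isTRUE(s$duration_flag), TRUE)
  )
  out$supporters <- lapply(j, function(s) as.character(unlist(s$supporters)))
  out$questions <- lapply(j, function(s) as.character(unlist(s$questions)))
  out
}

#' Read per-question recall answers from CSV
#'
#' Expects header `subject_id,question_id,score` with scores in `[0, 1]`.
#' Out-of-range scores are reported with their line number; duplicate
#' (subject, question) pairs and empty files are errors.
#'
#' @param path CSV file path.
#' @return Data.frame `subject_id`, `question_id`, `score`.
#' @export
readRecallCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "question_id", "score")
  if (!identical(names(df)[seq_along(need)], need))
    stop2(sprintf("%s: header must be %s", path, paste(need, collapse = ",")),
          "recallFC_schema_error")
  if (nrow(df) == 0L)
    stop2(sprintf("%s: no records", path), "recallFC_schema_error")
  bad <- which(!is.finite(df$score) | df$score < 0 | df$score > 1)
  if (length(bad))
    stop2(sprintf("%s: score out of [0, 1] at line %d", path, bad[1] + 1L),
          "recallFC_schema_error")
  dup <- duplicated(df[, c("subject_id", "question_id")])
  if (any(dup))
    stop2(sprintf("%s: duplicate (subject, question) at line %d", path,
                  which(dup)[1] + 1L), "recallFC_schema_error")
  df
}

#' Write recall answers to CSV
#' @param records Data.frame `subject_id`, `question_id`, `score`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeRecallCSV <- function(records, path) {
  write.csv(records[, c("subject_id", "question_id", "score")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one subject's ROI time series from TSV
#'
#' Tab-separated, header row of ROI IDs, one row per TR.
#'
#' @param path TSV file path.
#' @return Numeric matrix (TRs x ROIs) with ROI column names.
#' @export
readROITimeSeries <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m))
    stop2(sprintf("%s: time series must be numeric with no missing values",
                  path), "recallFC_schema_error")
  m
}

#' Write one subject's ROI time series to TSV
#' @param ts Numeric matrix (TRs x ROIs) with ROI column names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeROITimeSeries <- function(ts, path) {
  write.table(ts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the ROI network manifest (CSV with columns roi, network)
#' @param path CSV file path.
#' @return Data.frame `roi`, `network`.
#' @export
readROIManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("roi", "network") %in% names(df)))
    stop2(sprintf("%s: manifest needs columns roi, network", path),
          "recallFC_schema_error")
  df
}

#' @rdname readROIManifest
#' @param manifest Data.frame `roi`, `network`.
#' @export
writeROIManifest <- function(manifest, path) {
  write.csv(manifest[, c("roi", "network")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write a feature tensor as a raw binary array with JSON sidecar
#'
#' The container is deliberately simple and language-portable: little-endian
#' float64 values of the (W, M, r) array in R's column-major element order,
#' plus a JSON sidecar documenting dtype, byte order, dimensions and the
#' scene/subject/ROI index maps.
#'
#' @param tensor A [FeatureTensor-class].
#' @param prefix Output path prefix; writes `<prefix>.bin` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
writeFeatureTensor <- function(tensor, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(tensor@data), con, size = 8L, endian = "little")
  sidecar <- list(
    dtype = "float64", byte_order = "little", order = "column-major",
    dim = dim(tensor@data), dim_names = c("scene", "subject", "edge"),
    scene_ids = tensor@scene_ids, subject_ids = tensor@subject_ids,
    roi_ids = tensor@roi_ids, story = tensor@story,
    edge_order = "row-major strictly lower triangle"
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a feature tensor written by [writeFeatureTensor()]
#' @param prefix Path prefix used when writing.
#' @return A [FeatureTensor-class].
#' @export
readFeatureTensor <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  d <- as.integer(sidecar$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
  new("FeatureTensor", data = array(vals, dim = d),
      scene_ids = as.integer(sidecar$scene_ids),
      subject_ids = as.character(sidecar$subject_ids),
      roi_ids = as.character(sidecar$roi_ids),
      story = as.character(sidecar$story))
}

#' Write a scene decomposition (paired L/S binaries with JSON sidecar)
#' @param decomp A [SceneDecomposition-class].
#' @param prefix Output path prefix; writes `<prefix>_L.bin`,
#'   `<prefix>_S.bin` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
writeDecomposition <- function(decomp, prefix) {
  for (part in c("L", "S")) {
    con <- file(sprintf("%s_%s.bin", prefix, part), "wb")
    writeBin(as.vector(slot(decomp, part)), con, size = 8L,
             endian = "little")
    close(con)
  }
  sidecar <- list(
    scene = decomp@scene, dim = dim(decomp@L), dtype = "float64",
    byte_order = "little", order = "column-major", lambda = decomp@lambda,
    iterations = decomp@iterations, residual = decomp@residual,
    converged = decomp@converged
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a scene decomposition written by [writeDecomposition()]
#' @param prefix Path prefix used when writing.
#' @return A [SceneDecomposition-class].
#' @export
readDecomposition <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  d <- as.integer(sidecar$dim)
  mats <- lapply(c("L", "S"), function(part) {
    con <- file(sprintf("%s_%s.bin", prefix, part), "rb")
    on.exit(close(con))
    matrix(readBin(con, "double", n = prod(d), size = 8L, endian = "little"),
           d[1], d[2])
  })
  new("SceneDecomposition", scene = as.integer(sidecar$scene),
      L = mats[[1]], S = mats[[2]], lambda = sidecar$lambda,
      iterations = as.integer(sidecar$iterations),
      residual = sidecar$residual, converged = sidecar$converged,
      residual_trace = numeric())
}

#' Read/write the per-story acquisition timing config (YAML)
#'
#' The config maps story names to blocks with `tr_s`, `lead_in_trs`,
#' `clip_story_onset_s`, `run_trs`, `narrative_duration_s` and `subjects`.
#'
#' @param path YAML file path.
#' @return Named list per story: `timing` ([AcquisitionTiming-class]),
#'   `narrative_duration_s`, `subjects`.
#' @export
readTimingConfig <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(b) list(
    timing = acquisitionTiming(b$tr_s, b$lead_in_trs, b$clip_story_onset_s,
                               b$run_trs),
    narrative_duration_s = b$narrative_duration_s,
    subjects = as.character(unlist(b$subjects))
  ))
}

#' @rdname readTimingConfig
#' @param blocks Named list per story with the fields above (timing given as
#'   an [AcquisitionTiming-class] under `timing`).
#' @export
writeTimingConfig <- function(blocks, path) {
  y <- lapply(blocks, function(b) list(
    tr_s = b$timing@tr_s, lead_in_trs = b$timing@lead_in_trs,
    clip_story_onset_s = b$timing@clip_story_onset_s,
    run_trs = b$timing@run_trs,
    narrative_duration_s = b$narrative_duration_s,
    subjects = as.list(b$subjects)
  ))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits annotation JSONs (one per story and annotator), a recall CSV, one
#' time-series TSV per subject, the ROI manifest, the timing config, and the
#' generator's synthetic ground truth (true scene boundaries per story) under
#' `truth/`.
#'
#' @param study Study object from [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  blocks <- list()
  all_records <- list()
  for (sn in names(study$stories)) {
    st <- study$stories[[sn]]
    for (seg in st$annotations) {
      writeAnnotatorSegmentation(
        seg, file.path(dir, "annotations",
                       sprintf("%s__%s.json", sn, seg@annotator)),
        story = sn
      )
    }
    for (subj in names(st$timeseries)) {
      writeROITimeSeries(st$timeseries[[subj]],
                         file.path(dir, "timeseries", paste0(subj, ".tsv")))
    }
    all_records[[sn]] <- st$records
    blocks[[sn]] <- list(
      timing = st$timing,
      narrative_duration_s =
        study$config$stories$narrative_duration_s[
          match(sn, study$config$stories$story)],
      subjects = names(st$timeseries)
    )
    true_sc <- st$scenes
    true_out <- lapply(seq_len(nrow(true_sc)), function(i) list(
      scene = true_sc$scene[i], onset_s = true_sc$onset_s[i],
      offset_s = true_sc$offset_s[i],
      questions = as.list(true_sc$questions[[i]])
    ))
    jsonlite::write_json(
      true_out, file.path(dir, "truth", sprintf("%s_true_scenes.json", sn)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  writeRecallCSV(do.call(rbind, all_records), file.path(dir, "recall.csv"))
  writeROIManifest(study$stories[[1]]$manifest,
                   file.path(dir, "roi_manifest.csv"))
  writeTimingConfig(blocks, file.path(dir, "timing.yaml"))
  invisible(dir)
}
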