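#' Default story table for synthetic studies
#'
#' Four audio narratives with 8, 10, 8 and 6 scenes, 45 listeners each
#' (1440 scene-subject samples in total), mean scene length 78 s, 30 or 25
#' recall questions per story, and a few seconds of in-clip silence before
#' each story starts.
#'
#' @return Data.frame: `story`, `narrative_duration_s`, `n_scenes`,
#'   `n_questions`, `clip_story_onset_s`.
#' @export
syntheticStories <- function() {
  data.frame(
    story = c("story1", "story2", "story3", "story4"),
    narrative_duration_s = c(624, 780, 624, 468),
    n_scenes = c(8L, 10L, 8L, 6L),
    n_questions = c(30L, 30L, 25L, 25L),
    clip_story_onset_s = c(9, 15, 9, 12),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic narrative-recall study
#'
#' Bundles every knob of the generator: study scale, annotator disagreement,
#' the planted shared (low-rank) and idiosyncratic (sparse) connectivity
#' structure, observation noise, and the coupling between the planted signal
#' and recall behaviour.
#'
#' @param stories Story table as from [syntheticStories()].
#' @param subjects_per_story Listeners per story (default 45).
#' @param n_rois Total ROI count across both networks (default 20).
#' @param n_dmn ROIs tagged DMN; the remainder are tagged Auditory
#'   (default 12).
#' @param n_annotators Simulated annotators (default 5).
#' @param boundary_jitter_sd_s SD of the clipped-Gaussian jitter applied to
#'   each annotator's scene boundaries, seconds (default 2).
#' @param split_merge_prob Probability that an annotator merges a given pair
#'   of adjacent scenes (default 0.05).
#' @param planted_rank Number of shared latent factors per scene (default 3).
#' @param sparse_density Fraction of edges given a subject-specific coupling
#'   (default 0.02).
#' @param sparse_magnitude Covariance magnitude of those couplings
#'   (default 0.4).
#' @param effect_size Strength of the recall-to-connectivity coupling on the
#'   logit scale (default 2; 0 decouples labels from the data).
#' @param coupling_strength Scale of the factor-variance modulation by the
#'   subject-scene signal strength (default 3, making the stimulus-driven
#'   variance share vary between roughly 1.2x and 8x baseline across
#'   subjects and scenes).
#' @param noise_sd SD of white observation noise added to the ROI signals
#'   (default 1).
#' @param low_class_fraction Target fraction of low-recall scene-subject
#'   samples (default 0.25).
#' @param tr_s,lead_in_trs Acquisition timing (defaults 1.5 s, 8 TRs).
#' @param tail_s Silence after the story, seconds (default 8).
#' @param min_scene_s,max_scene_s Scene duration range (defaults 45, 120).
#' @param seed Default seed used by [simulateStudy()] (default 1).
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(stories = syntheticStories(),
                            subjects_per_story = 45L, n_rois = 20L,
                            n_dmn = 12L, n_annotators = 5L,
                            boundary_jitter_sd_s = 2,
                            split_merge_prob = 0.05, planted_rank = 3L,
                            sparse_density = 0.02, sparse_magnitude = 0.4,
                            effect_size = 2, coupling_strength = 3,
                            noise_sd = 1, low_class_fraction = 0.25,
                            tr_s = 1.5, lead_in_trs = 8L, tail_s = 8,
                            min_scene_s = 45, max_scene_s = 120, seed = 1L) {
  cfg <- list(
    stories = stories, subjects_per_story = as.integer(subjects_per_story),
    n_rois = as.integer(n_rois), n_dmn = as.integer(n_dmn),
    n_annotators = as.integer(n_annotators),
    boundary_jitter_sd_s = boundary_jitter_sd_s,
    split_merge_prob = split_merge_prob,
    planted_rank = as.integer(planted_rank),
    sparse_density = sparse_density, sparse_magnitude = sparse_magnitude,
    effect_size = effect_size, coupling_strength = coupling_strength,
    noise_sd = noise_sd, low_class_fraction = low_class_fraction,
    tr_s = tr_s, lead_in_trs = as.integer(lead_in_trs), tail_s = tail_s,
    min_scene_s = min_scene_s, max_scene_s = max_scene_s,
    seed = as.integer(seed)
  )
  counts <- c(cfg$subjects_per_story, cfg$n_rois, cfg$n_annotators,
              cfg$planted_rank, cfg$stories$n_scenes, cfg$stories$n_questions)
  if (any(counts <= 0))
    stop2("all counts must be positive", "recallFC_config_error")
  probs <- c(cfg$split_merge_prob, cfg$sparse_density, cfg$low_class_fraction)
  if (any(probs < 0 | probs > 1))
    stop2("probabilities must lie in [0, 1]", "recallFC_config_error")
  if (cfg$n_dmn <= 1L || cfg$n_dmn >= cfg$n_rois - 1L)
    stop2("n_dmn must leave at least 2 ROIs in each network",
          "recallFC_config_error")
  if (cfg$boundary_jitter_sd_s < 0 || cfg$noise_sd < 0 ||
      cfg$effect_size < 0)
    stop2("boundary_jitter_sd_s, noise_sd and effect_size must be >= 0",
          "recallFC_config_error")
  structure(cfg, class = "SyntheticConfig")
}

#' ROI manifest for a synthetic configuration
#' @param cfg A [syntheticConfig()].
#' @return Data.frame `roi`, `network` (DMN first, then Auditory).
#' @export
syntheticROIManifest <- function(cfg) {
  data.frame(
    roi = sprintf("ROI%02d", seq_len(cfg$n_rois)),
    network = rep(c("DMN", "Auditory"), c(cfg$n_dmn, cfg$n_rois - cfg$n_dmn)),
    stringsAsFactors = FALSE
  )
}

#' Generate a story's true scene partition with question assignments
#'
#' Draws contiguous scene durations uniformly in the configured range,
#' rescales them to sum exactly to the narrative duration, and rejects draws
#' that leave any rescaled duration out of range. Every recall question is
#' assigned to exactly one scene and every scene receives at least one
#' question.
#'
#' @param cfg A [syntheticConfig()].
#' @param story Story name or row index into `cfg$stories`.
#' @param seed Optional seed (RNG state restored afterwards).
#' @return Data.frame: `scene`, `onset_s`, `offset_s`, list-column
#'   `questions`.
#' @export
generateTrueScenes <- function(cfg, story = 1L, seed = NULL) {
  st <- story_row(cfg, story)
  k <- st$n_scenes
  D <- st$narrative_duration_s
  if (k * cfg$min_scene_s > D || k * cfg$max_scene_s < D)
    stop2(sprintf(
      "infeasible: %d scenes of %g-%g s cannot sum to %g s",
      k, cfg$min_scene_s, cfg$max_scene_s, D
    ), "recallFC_config_error")
  with_seed_opt(seed, {
    repeat {
      if (k == 1L) {
        dur <- D
        break
      }
      dur <- runif(k, cfg$min_scene_s, cfg$max_scene_s)
      dur <- dur * D / sum(dur)
      if (all(dur >= cfg$min_scene_s & dur <= cfg$max_scene_s)) break
    }
    bounds <- c(0, cumsum(dur))
    bounds[k + 1L] <- D
    qid <- sprintf("%s_q%02d", st$story, seq_len(st$n_questions))
    home <- integer(st$n_questions)
    first <- sample.int(st$n_questions, k)
    home[first] <- seq_len(k)
    rest <- setdiff(seq_len(st$n_questions), first)
    if (length(rest))
      home[rest] <- sample.int(k, length(rest), replace = TRUE)
    out <- data.frame(scene = seq_len(k), onset_s = bounds[-(k + 1L)],
                      offset_s = bounds[-1L])
    out$questions <- lapply(seq_len(k), function(t) sort(qid[home == t]))
    out
  })
}

story_row <- function(cfg, story) {
  if (is.character(story)) {
    i <- match(story, cfg$stories$story)
    if (is.na(i)) stop2(sprintf("unknown story '%s'", story),
                        "recallFC_config_error")
  } else i <- as.integer(story)
  as.list(cfg$stories[i, , drop = FALSE])
}

#' Simulate annotators' scene proposals around the true partition
#'
#' Each annotator starts from the true partition, optionally merges adjacent
#' scenes (each interior boundary is removed independently with probability
#' `split_merge_prob`, merged scenes pooling their question sets), then
#' jitters the remaining interior boundaries with a Gaussian clipped to 40%
#' of the shorter neighbouring scene so ordering and continuity are preserved
#' by construction. With zero jitter and zero merge probability every
#' annotator reproduces the truth exactly.
#'
#' @param true_scenes Output of [generateTrueScenes()].
#' @param cfg A [syntheticConfig()].
#' @param annotators Annotator IDs (default `ann1..annN`).
#' @param seed Optional seed.
#' @return List of [AnnotatorSegmentation-class] objects.
#' @export
generateAnnotatorProposals <- function(true_scenes, cfg,
                                       annotators =
                                         paste0("ann", seq_len(cfg$n_annotators)),
                                       seed = NULL) {
  D <- true_scenes$offset_s[nrow(true_scenes)]
  with_seed_opt(seed, {
    lapply(annotators, function(a) {
      k <- nrow(true_scenes)
      keep_boundary <- if (k > 1L)
        runif(k - 1L) >= cfg$split_merge_prob else logical(0)
      grp <- cumsum(c(TRUE, keep_boundary))
      onsets <- tapply(true_scenes$onset_s, grp, min)
      offsets <- tapply(true_scenes$offset_s, grp, max)
      questions <- lapply(split(true_scenes$questions, grp),
                          function(qs) sort(unique(unlist(qs))))
      m <- length(onsets)
      if (m > 1L && cfg$boundary_jitter_sd_s > 0) {
        dur <- offsets - onsets
        for (j in seq_len(m - 1L)) {
          lim <- 0.4 * min(dur[j], dur[j + 1L])
          delta <- max(-lim, min(lim, rnorm(1, 0, cfg$boundary_jitter_sd_s)))
          offsets[j] <- offsets[j] + delta
          onsets[j + 1L] <- onsets[j + 1L] + delta
        }
      }
      annotatorSegmentation(a, as.numeric(onsets), as.numeric(offsets),
                            questions, D)
    })
  })
}

#' Simulate ROI time series with planted shared and idiosyncratic structure
#'
#' Within each scene, `planted_rank` latent stimulus time courses are shared
#' by all subjects; subject `m` expresses factor `j` with variance
#' `1 + w[t, m] * 0.5^(j - 1)`, where
#' `w = coupling_strength * aptitude_m * salience_t` is
#' the subject-scene signal strength that also drives recall. This makes the
#' stacked scene FC matrices low-rank across subjects while their correlation
#' patterns still vary monotonically with `w` (even with zero observation
#' noise). Idiosyncratic structure is added as subject-specific couplings on
#' a random `sparse_density` fraction of ROI pairs; white observation noise
#' has SD `noise_sd`. TRs outside the story (lead-in, in-clip silence, tail)
#' contain unit-variance scanner noise only.
#'
#' @param true_scenes Output of [generateTrueScenes()].
#' @param cfg A [syntheticConfig()].
#' @param story Story name or index (for timing and subject IDs).
#' @param seed Optional seed.
#' @return List with `timeseries` (named list of run-TRs x R matrices),
#'   `timing` ([AcquisitionTiming-class]), `windows` (per-scene
#'   [TRWindow-class] list), `manifest`, and `truth` (aptitude, salience,
#'   `w` (scenes x subjects), per-scene population `L0`/`S0` edge matrices).
#' @export
generateROITimeSeries <- function(true_scenes, cfg, story = 1L, seed = NULL) {
  st <- story_row(cfg, story)
  R <- cfg$n_rois
  if (R < 4L) stop2("need at least 4 ROIs", "recallFC_config_error")
  k <- cfg$planted_rank
  Tn <- nrow(true_scenes)
  M <- cfg$subjects_per_story
  subjects <- sprintf("%s_sub%02d", st$story, seq_len(M))
  run_trs <- cfg$lead_in_trs + secondsToTRCount(
    st$clip_story_onset_s + st$narrative_duration_s + cfg$tail_s, cfg$tr_s
  )
  timing <- acquisitionTiming(cfg$tr_s, cfg$lead_in_trs,
                              st$clip_story_onset_s, run_trs)
  windows <- scenesToTRWindows(true_scenes, timing)
  manifest <- syntheticROIManifest(cfg)
  redge <- (R^2 - R) / 2

  with_seed_opt(seed, {
    B <- matrix(rnorm(R * k), R, k) / sqrt(k)
    aptitude <- runif(M, 0.3, 1.7)
    salience <- runif(Tn, 0.8, 1.2)
    w <- cfg$coupling_strength * outer(salience, aptitude)   # T x M

    ts <- lapply(subjects, function(s) {
      m <- matrix(rnorm(run_trs * R), run_trs, R)
      colnames(m) <- manifest$roi
      m
    })
    names(ts) <- subjects

    L0 <- vector("list", Tn)
    S0 <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      win <- windows[[t]]
      nw <- win@end_tr - win@start_tr
      rows <- (win@start_tr + 1L):win@end_tr
      g <- matrix(rnorm(nw * k), nw, k)
      L0[[t]] <- matrix(NA_real_, M, redge)
      S0[[t]] <- matrix(NA_real_, M, redge)
      for (m in seq_len(M)) {
        v <- 1 + w[t, m] * 0.5^(seq_len(k) - 1L)
        X <- g %*% (sqrt(v) * t(B))
        covS <- matrix(0, R, R)
        n_pairs <- round(cfg$sparse_density * redge)
        if (n_pairs > 0L && cfg$sparse_magnitude > 0) {
          pair_idx <- sample.int(redge, n_pairs)
          pairs <- edge_to_pair(pair_idx, R)
          for (p in seq_len(n_pairs)) {
            i <- pairs[p, 1L]; j <- pairs[p, 2L]
            sgn <- sample(c(-1, 1), 1L)
            h <- rnorm(nw) * sqrt(cfg$sparse_magnitude)
            X[, i] <- X[, i] + h
            X[, j] <- X[, j] + sgn * h
            covS[i, i] <- covS[i, i] + cfg$sparse_magnitude
            covS[j, j] <- covS[j, j] + cfg$sparse_magnitude
            covS[i, j] <- covS[i, j] + sgn * cfg$sparse_magnitude
            covS[j, i] <- covS[i, j]
          }
        }
        if (cfg$noise_sd > 0)
          X <- X + cfg$noise_sd * matrix(rnorm(nw * R), nw, R)
        ts[[m]][rows, ] <- X
        covC <- B %*% (v * t(B)) + diag(cfg$noise_sd^2, R)
        corC <- safe_cov2cor(covC)
        corF <- safe_cov2cor(covC + covS)
        L0[[t]][m, ] <- vectorizeLowerTriangle(corC)
        S0[[t]][m, ] <- vectorizeLowerTriangle(corF) -
          L0[[t]][m, ]
      }
    }
    list(
      timeseries = ts, timing = timing, windows = windows,
      manifest = manifest,
      truth = list(scenes = true_scenes, B = B, aptitude = aptitude,
                   salience = salience, w = w, L0 = L0, S0 = S0,
                   subjects = subjects)
    )
  })
}

# Map strictly-lower-triangle edge indices (row-major order, the package
# convention) to (i, j) ROI pairs with i > j.
edge_to_pair <- function(idx, R) {
  ii <- integer(0); jj <- integer(0)
  for (i in 2:R) for (j in seq_len(i - 1L)) {
    ii <- c(ii, i); jj <- c(jj, j)
  }
  cbind(ii[idx], jj[idx])
}

# cov2cor that tolerates zero variances (maps them to zero correlation rows)
safe_cov2cor <- function(m) {
  d <- sqrt(diag(m))
  d[d == 0] <- 1
  out <- m / outer(d, d)
  diag(out) <- 1
  out
}

#' Simulate per-question recall scores coupled to the planted signal
#'
#' The probability of answering a question in scene `t` correctly is
#' `plogis(alpha + effect_size * z[t, m])`, where `z` is the standardized
#' subject-scene signal strength `w` from [generateROITimeSeries()]. The
#' intercept `alpha` is calibrated numerically so that the expected fraction
#' of scene-subject samples whose mean score falls below 0.5 matches
#' `low_class_fraction`.
#'
#' @param true_scenes Output of [generateTrueScenes()] (question sets used).
#' @param w Scenes x subjects signal-strength matrix (from the time-series
#'   truth).
#' @param cfg A [syntheticConfig()].
#' @param story Story name or index.
#' @param seed Optional seed.
#' @return List with `records` (data.frame `subject_id`, `question_id`,
#'   `score`), `truth` (data.frame `scene`, `subject`, `p_correct`,
#'   `mean_score`, `class`) and `alpha`.
#' @export
generateRecallScores <- function(true_scenes, w, cfg, story = 1L,
                                 seed = NULL) {
  st <- story_row(cfg, story)
  Tn <- nrow(true_scenes)
  M <- ncol(w)
  subjects <- sprintf("%s_sub%02d", st$story, seq_len(M))
  z <- if (sd(w) > 0) (w - mean(w)) / sd(w) else w * 0
  nq <- vapply(true_scenes$questions, length, 1L)

  # P(mean score < 0.5) for a scene with n questions at success prob p
  p_low <- function(alpha) {
    p <- plogis(alpha + cfg$effect_size * z)
    mean(vapply(seq_len(Tn), function(t) {
      mean(pbinom(ceiling(nq[t] / 2) - 1L, nq[t], p[t, ]))
    }, 1))
  }
  lim <- 20 + 10 * cfg$effect_size  # wide enough for saturating effects
  alpha <- uniroot(function(a) p_low(a) - cfg$low_class_fraction,
                   lower = -lim, upper = lim, tol = 1e-8)$root

  with_seed_opt(seed, {
    p <- plogis(alpha + cfg$effect_size * z)
    recs <- vector("list", Tn)
    mean_score <- matrix(NA_real_, Tn, M)
    for (t in seq_len(Tn)) {
      qs <- true_scenes$questions[[t]]
      sc <- matrix(rbinom(length(qs) * M, 1L, rep(p[t, ], each = length(qs))),
                   nrow = length(qs))
      mean_score[t, ] <- colMeans(sc)
      recs[[t]] <- data.frame(
        subject_id = rep(subjects, each = length(qs)),
        question_id = rep(qs, M),
        score = as.numeric(sc), stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, recs)
    records <- records[order(records$subject_id, records$question_id), ]
    rownames(records) <- NULL
    truth <- data.frame(
      scene = rep(true_scenes$scene, M),
      subject = rep(subjects, each = Tn),
      p_correct = as.numeric(p), mean_score = as.numeric(mean_score),
      stringsAsFactors = FALSE
    )
    truth$class <- factor(ifelse(truth$mean_score >= 0.5, "high", "low"),
                          levels = c("low", "high"))
    list(records = records, truth = truth, alpha = alpha)
  })
}

#' Simulate a complete multi-story synthetic study
#'
#' Generates, for every story in the configuration: the true scene partition,
#' annotator proposals, subject ROI time series with planted shared/sparse
#' structure, and recall scores coupled to the planted signal. Fully
#' deterministic given `cfg` and `seed`. When `dir` is given, the study is
#' written in the same file formats the analysis pipeline consumes
#' (annotation JSONs, recall CSV, time-series TSVs, ROI manifest, timing
#' config) plus the generator truth under `truth/` (synthetic ground truth,
#' retained for oracle checks).
#'
#' @param cfg A [syntheticConfig()].
#' @param seed Integer seed (default `cfg$seed`).
#' @param dir Optional output directory.
#' @return (Invisibly when `dir` is given.) List with `config`, `seed` and
#'   per-story elements under `stories`: `scenes`, `annotations`, `timing`,
#'   `windows`, `timeseries`, `manifest`, `records`, `recall_truth`, `truth`.
#' @export
simulateStudy <- function(cfg = syntheticConfig(), seed = cfg$seed,
                          dir = NULL) {
  study <- withr::with_seed(as.integer(seed), {
    stories <- lapply(seq_len(nrow(cfg$stories)), function(i) {
      scenes <- generateTrueScenes(cfg, i)
      ann <- generateAnnotatorProposals(scenes, cfg)
      tsr <- generateROITimeSeries(scenes, cfg, i)
      rec <- generateRecallScores(scenes, tsr$truth$w, cfg, i)
      list(scenes = scenes, annotations = ann, timing = tsr$timing,
           windows = tsr$windows, timeseries = tsr$timeseries,
           manifest = tsr$manifest, records = rec$records,
           recall_truth = rec$truth, alpha = rec$alpha, truth = tsr$truth)
    })
    names(stories) <- cfg$stories$story
    list(config = cfg, seed = as.integer(seed), stories = stories)
  })
  if (!is.null(dir)) writeStudy(study, dir)
  if (is.null(dir)) study else invisible(study)
}
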