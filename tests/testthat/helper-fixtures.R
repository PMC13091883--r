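# Shared fixtures, built in code. Expensive simulated studies are cached per
# test run so several test files can reuse them.

seg_of <- function(annotator, onsets, offsets, questions, duration) {
  annotatorSegmentation(annotator, onsets, offsets, questions, duration)
}

# Two-story miniature study configuration (fast; used by io/pipeline tests)
small_cfg <- function(...) {
  syntheticConfig(
    stories = data.frame(
      story = c("s1", "s2"), narrative_duration_s = c(312, 234),
      n_scenes = c(4L, 3L), n_questions = c(12L, 10L),
      clip_story_onset_s = c(9, 12), stringsAsFactors = FALSE
    ),
    subjects_per_story = 8L, n_rois = 10L, n_dmn = 6L, ...
  )
}

# One-story configuration for statistical checks
one_story_cfg <- function(...) {
  syntheticConfig(
    stories = data.frame(
      story = "s1", narrative_duration_s = 624, n_scenes = 8L,
      n_questions = 30L, clip_story_onset_s = 9, stringsAsFactors = FALSE
    ),
    ...
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- maker()
  .fixture_cache[[key]]
}

# Default-scale study (4 stories x 45 subjects = 1440 samples)
default_study <- function(effect_size) {
  key <- sprintf("default_eff%g", effect_size)
  cached(key, function() {
    simulateStudy(syntheticConfig(effect_size = effect_size), seed = 101)
  })
}

default_features <- function(effect_size, network = "DMN",
                             use_true_scenes = FALSE) {
  key <- sprintf("feat_%s_eff%g_true%d", network, effect_size,
                 use_true_scenes)
  cached(key, function() {
    studyFeatures(default_study(effect_size), network = network,
                  use_true_scenes = use_true_scenes)
  })
}

# story-stratified subsample used for shuffle nulls at reduced n
stratified_subsample <- function(map, per_story = 60L, seed = 7L) {
  withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(map)), map$story), sample,
                  size = per_story))
  })
}

# Independent two-pass Pearson correlation oracle (textbook formula)
pearson_oracle <- function(x) {
  n <- nrow(x)
  R <- ncol(x)
  mu <- colMeans(x)
  out <- matrix(1, R, R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      num <- sum((x[, i] - mu[i]) * (x[, j] - mu[j]))
      den <- sqrt(sum((x[, i] - mu[i])^2)) * sqrt(sum((x[, j] - mu[j])^2))
      out[i, j] <- num / den
    }
  }
  out
}

# Brute-force question-sharing grouping oracle: enumerate all cross-annotator
# pairs, then grow components by fixed-point iteration over shared membership.
grouping_oracle <- function(segmentations) {
  flat <- list()
  for (s in segmentations) {
    p <- proposals(s)
    for (i in seq_len(nrow(p))) {
      flat[[length(flat) + 1L]] <- list(
        annotator = annotatorId(s), onset = p$onset_s[i],
        questions = p$questions[[i]]
      )
    }
  }
  n <- length(flat)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && flat[[i]]$annotator != flat[[j]]$annotator &&
        length(intersect(flat[[i]]$questions, flat[[j]]$questions)))
      adj[i, j] <- TRUE
  }
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- apply(reach, 1, function(r) min(which(r)))
  # canonical form: sorted list of sorted member signatures
  sig <- vapply(flat, function(f)
    paste(f$annotator, f$onset, paste(sort(f$questions), collapse = "+")),
    character(1))
  unname(lapply(split(sig, comp), sort))
}

match_groups_signature <- function(m) {
  all_groups <- c(m$groups, m$unsupported)
  unname(lapply(all_groups, function(g) {
    sort(vapply(seq_len(nrow(g)), function(i)
      paste(g$annotator[i], g$onset_s[i],
            paste(sort(g$questions[[i]]), collapse = "+")),
      character(1)))
  }))
}
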