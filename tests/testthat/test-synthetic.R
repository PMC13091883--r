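test_that("true scenes partition the narrative with in-range durations", {
  cfg <- one_story_cfg()
  sc <- generateTrueScenes(cfg, 1, seed = 2)
  dur <- sc$offset_s - sc$onset_s
  expect_equal(nrow(sc), 8L)
  expect_equal(sum(dur), 624)
  expect_true(all(dur >= 45 & dur <= 120))
  expect_equal(sc$onset_s[-1], sc$offset_s[-8])
  # every question appears exactly once, every scene has at least one
  qs <- unlist(sc$questions)
  expect_equal(sort(qs), sort(sprintf("s1_q%02d", 1:30)))
  expect_true(all(vapply(sc$questions, length, 1L) >= 1L))
})

test_that("degenerate and infeasible scene requests are handled", {
  cfg1 <- syntheticConfig(stories = data.frame(
    story = "x", narrative_duration_s = 60, n_scenes = 1L,
    n_questions = 3L, clip_story_onset_s = 0, stringsAsFactors = FALSE
  ), subjects_per_story = 2L, n_rois = 6L, n_dmn = 3L)
  sc <- generateTrueScenes(cfg1, 1, seed = 1)
  expect_equal(c(sc$onset_s, sc$offset_s), c(0, 60))

  cfg2 <- syntheticConfig(stories = data.frame(
    story = "x", narrative_duration_s = 200, n_scenes = 10L,
    n_questions = 12L, clip_story_onset_s = 0, stringsAsFactors = FALSE
  ), subjects_per_story = 2L, n_rois = 6L, n_dmn = 3L)
  expect_error(generateTrueScenes(cfg2, 1, seed = 1),
               class = "recallFC_config_error")
})

test_that("noise-free annotators reproduce the truth and consensus recovers it", {
  cfg <- one_story_cfg(boundary_jitter_sd_s = 0, split_merge_prob = 0)
  sc <- generateTrueScenes(cfg, 1, seed = 3)
  segs <- generateAnnotatorProposals(sc, cfg, seed = 3)
  for (s in segs) {
    expect_equal(proposals(s)$onset_s, sc$onset_s)
    expect_equal(proposals(s)$offset_s, sc$offset_s)
  }
  cons <- consensusScenes(segs)
  expect_equal(cons$onset_s, sc$onset_s)
  expect_equal(cons$offset_s, sc$offset_s)
  expect_equal(cons$questions, sc$questions)
})

test_that("consensus boundary error shrinks with annotator averaging", {
  # Monte-Carlo: mean absolute consensus boundary error stays below
  # 3 * jitter_sd / sqrt(n_annotators)
  cfg <- one_story_cfg(boundary_jitter_sd_s = 3, split_merge_prob = 0)
  sc <- generateTrueScenes(cfg, 1, seed = 4)
  true_b <- sc$offset_s[-nrow(sc)]
  errs <- vapply(1:200, function(i) {
    segs <- generateAnnotatorProposals(sc, cfg, seed = 1000 + i)
    cons <- tryCatch(suppressWarnings(consensusScenes(segs)),
                     error = function(e) NULL)
    if (is.null(cons) || nrow(cons) != nrow(sc)) return(NA_real_)
    mean(abs(cons$offset_s[-nrow(cons)] - true_b))
  }, 1)
  expect_gte(mean(!is.na(errs)), 0.9)  # consensus recovers scene count
  expect_lte(mean(errs, na.rm = TRUE), 3 * 3 / sqrt(cfg$n_annotators))
})

test_that("an always-merging annotator does not break consensus recovery", {
  cfg <- one_story_cfg(boundary_jitter_sd_s = 1)
  sc <- generateTrueScenes(cfg, 1, seed = 5)
  segs <- generateAnnotatorProposals(sc, cfg, seed = 5)
  cfg_all <- one_story_cfg(boundary_jitter_sd_s = 1, split_merge_prob = 1)
  merged <- generateAnnotatorProposals(sc, cfg_all, annotators = "merger",
                                       seed = 6)
  expect_lt(nrow(proposals(merged[[1]])), nrow(sc))
  cons <- suppressWarnings(consensusScenes(c(segs, merged)))
  # merged proposals exceed the duration bound and are dropped by hard
  # validation, so the remaining annotators still recover the scene count
  expect_equal(nrow(cons), nrow(sc))
})

test_that("the noiseless single-factor limit saturates factor-driven FC", {
  cfg <- syntheticConfig(stories = data.frame(
    story = "x", narrative_duration_s = 120, n_scenes = 2L,
    n_questions = 4L, clip_story_onset_s = 0, stringsAsFactors = FALSE
  ), subjects_per_story = 1L, n_rois = 6L, n_dmn = 3L, planted_rank = 1L,
  noise_sd = 0, sparse_density = 0, boundary_jitter_sd_s = 0,
  split_merge_prob = 0)
  sc <- generateTrueScenes(cfg, 1, seed = 7)
  ts <- generateROITimeSeries(sc, cfg, 1, seed = 7)
  fc <- computeSceneFC(ts$timeseries[[1]], ts$windows[[1]])
  expect_true(all(abs(abs(fc) - 1) < 1e-9))
})

test_that("without planted idiosyncrasy the RPCA sparse part is small", {
  s_ratio <- function(density, magnitude, seed = 8) {
    cfg <- one_story_cfg(sparse_density = density,
                         sparse_magnitude = magnitude, effect_size = 0,
                         subjects_per_story = 20L)
    sc <- generateTrueScenes(cfg, 1, seed = seed)
    ts <- generateROITimeSeries(sc, cfg, 1, seed = seed)
    tn <- sceneFCTensor(ts$timeseries, ts$windows, scene_ids = sc$scene,
                        story = "s1")
    Z <- featureArray(tn)[1, , ]
    d <- rpcaDecompose(Z)
    sqrt(sum(sparsePart(d)^2)) / sqrt(sum(Z^2))
  }
  # noise calibration: FC sampling noise alone leaves under 30% of the norm
  # in S; strong planted idiosyncrasy raises it well beyond that
  none <- s_ratio(0, 0)
  planted <- s_ratio(0.1, 1.5)
  expect_lte(none, 0.3)
  expect_gt(planted, none + 0.1)
})

test_that("default scale reproduces the study bookkeeping", {
  cfg <- syntheticConfig()
  expect_equal(sum(cfg$stories$n_scenes), 32L)
  expect_equal(sum(cfg$stories$n_scenes) * cfg$subjects_per_story, 1440L)
  st <- default_study(2)
  n_samples <- sum(vapply(st$stories, function(s)
    nrow(s$scenes) * length(s$timeseries), 1L))
  expect_equal(n_samples, 1440L)
  # realized low fraction near the configured 25%
  lab <- do.call(rbind, lapply(st$stories, function(s) s$recall_truth))
  frac <- mean(lab$class == "low")
  expect_gte(frac, 0.22)
  expect_lte(frac, 0.28)
})

test_that("simulation is deterministic given config and seed", {
  cfg <- small_cfg()
  s1 <- simulateStudy(cfg, seed = 12)
  s2 <- simulateStudy(cfg, seed = 12)
  expect_identical(s1$stories$s1$timeseries, s2$stories$s1$timeseries)
  expect_identical(s1$stories$s2$records, s2$stories$s2$records)
  expect_identical(s1$stories$s1$truth$w, s2$stories$s1$truth$w)
  s3 <- simulateStudy(cfg, seed = 13)
  expect_false(identical(s1$stories$s1$records, s3$stories$s1$records))
})

test_that("population truth matrices describe the planted structure", {
  cfg <- small_cfg(sparse_density = 0.05)
  sc <- generateTrueScenes(cfg, 1, seed = 14)
  ts <- generateROITimeSeries(sc, cfg, 1, seed = 14)
  L0 <- ts$truth$L0[[1]]
  S0 <- ts$truth$S0[[1]]
  expect_equal(dim(L0), c(8L, 45L))  # M x (R^2-R)/2 for R = 10
  expect_true(all(abs(L0) <= 1))
  # idiosyncratic truth is concentrated: mostly near zero with a few strong
  # planted couplings (variance renormalization spreads small ripples to
  # edges sharing an ROI with a planted pair)
  expect_gte(mean(abs(S0) < 0.05), 0.8)
  expect_gte(max(abs(S0)), 0.1)
  # empirical FC is close to the planted population correlation
  fc <- computeSceneFC(ts$timeseries[[1]], ts$windows[[1]])
  v <- vectorizeLowerTriangle(fc)
  expect_lte(sqrt(mean((v - (L0[1, ] + S0[1, ]))^2)), 0.35)
})
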