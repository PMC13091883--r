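test_that("scene recall scores are arithmetic means over the scene's questions", {
  rec <- data.frame(
    subject_id = "s1", question_id = c("q1", "q2", "q3"), score = c(1, 0, 1)
  )
  expect_equal(sceneRecallScore(rec, c("q1", "q2", "q3"), "s1"), 2 / 3)
  expect_equal(sceneRecallScore(rec, c("q1", "q3"), "s1"), 1)
  expect_equal(sceneRecallScore(rec, "q2", "s1"), 0)
})

test_that("mean scene score is invariant to question order", {
  rec <- data.frame(
    subject_id = "s1", question_id = paste0("q", 1:5),
    score = c(0.2, 0.9, 0.5, 1, 0)
  )
  a <- sceneRecallScore(rec, paste0("q", 1:5), "s1")
  b <- sceneRecallScore(rec, paste0("q", 5:1), "s1")
  expect_identical(a, b)
})

test_that("missing answers follow the configured policy", {
  rec <- data.frame(subject_id = "s1", question_id = "q1", score = 1)
  expect_error(sceneRecallScore(rec, c("q1", "q2"), "s1"),
               class = "recallFC_missing_answers")
  expect_warning(
    got <- sceneRecallScore(rec, c("q1", "q2"), "s1", missing = "available"),
    "averaging over"
  )
  expect_equal(got, 1)
  expect_error(
    suppressWarnings(sceneRecallScore(rec, "q9", "s1", missing = "available")),
    class = "recallFC_missing_answers"
  )
})

test_that("threshold binarization labels scores >= theta as high", {
  got <- binarizeLabels(c(0.2, 0.4, 0.8, 1.0))
  expect_equal(as.character(got), c("low", "low", "high", "high"))
  expect_true(all(binarizeLabels(c(0, 0.3, 1), theta = 0) == "high"))
  # tie at the boundary goes to high
  expect_equal(as.character(binarizeLabels(0.5)), "high")
})

test_that("quantile binarization labels the lowest q fraction low", {
  got <- binarizeLabels(c(0.1, 0.6, 0.7, 0.9), rule = "quantile", q = 0.25)
  expect_equal(sum(got == "low"), 1L)
  expect_equal(as.character(got[1]), "low")
  expect_error(binarizeLabels(rep(0.5, 10), rule = "quantile"),
               class = "recallFC_label_error")
})

test_that("quantile label proportions are within 1/n of the target", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    scores <- runif(n)
    got <- binarizeLabels(scores, rule = "quantile", q = 0.25)
    expect_lte(abs(mean(got == "low") - 0.25), 1 / n + 1e-12)
  }
})

test_that("scene x subject score tables align with per-pair computation", {
  set.seed(11)
  cfg <- small_cfg()
  scenes <- generateTrueScenes(cfg, 1, seed = 1)
  ts <- generateROITimeSeries(scenes, cfg, 1, seed = 1)
  rec <- generateRecallScores(scenes, ts$truth$w, cfg, 1, seed = 1)
  tab <- sceneRecallScores(rec$records, scenes)
  expect_equal(nrow(tab), nrow(scenes) * cfg$subjects_per_story)
  i <- sample(nrow(tab), 5)
  for (row in i) {
    expect_equal(
      tab$mean_score[row],
      sceneRecallScore(rec$records,
                       scenes$questions[[match(tab$scene[row], scenes$scene)]],
                       tab$subject[row])
    )
  }
  # generator truth agrees with the recomputed scene means
  key <- paste(tab$scene, tab$subject)
  tkey <- paste(rec$truth$scene, rec$truth$subject)
  expect_equal(tab$mean_score, rec$truth$mean_score[match(key, tkey)])
})
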