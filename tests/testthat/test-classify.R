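make_xy <- function(n = 60, r = 8, sep = FALSE, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * r), n, r)
    colnames(x) <- paste0("f", seq_len(r))
    if (sep) x[, 1] <- sample(c(-1, 1), n, TRUE) * runif(n, 0.5, 2)
    y <- if (sep) factor(ifelse(x[, 1] > 0, "high", "low"),
                         levels = c("low", "high"))
    else factor(sample(c("low", "high"), n, TRUE, c(0.25, 0.75)),
                levels = c("low", "high"))
    list(x = x, y = y)
  })
}

test_that("a separable problem reaches perfect LOOCV accuracy", {
  d <- make_xy(sep = TRUE)
  rep <- runLOOCV(d$x, d$y, classifierSpec("logistic"), n_boot = 100)
  m <- reportMetrics(rep)
  expect_equal(m[["accuracy"]], 1)
  expect_equal(m[["auc"]], 1)
  expect_equal(rep@ci95, c(1, 1))
})

test_that("label-independent features stay inside the binomial chance band", {
  d <- make_xy(n = 120, seed = 3)
  rep <- runLOOCV(d$x, d$y, classifierSpec("logistic"), n_boot = 0)
  maj <- max(table(d$y)) / length(d$y)
  band <- qnorm(0.975) * sqrt(maj * (1 - maj) / length(d$y))
  expect_lte(abs(reportMetrics(rep)[["accuracy"]] - maj), band + 0.05)
})

test_that("reports are bit-identical under identical seed and input", {
  d <- make_xy(n = 50, seed = 4)
  for (fam in c("logistic", "random_forest")) {
    r1 <- runLOOCV(d$x, d$y, classifierSpec(fam, seed = 11), n_boot = 200)
    r2 <- runLOOCV(d$x, d$y, classifierSpec(fam, seed = 11), n_boot = 200)
    expect_identical(reportMetrics(r1), reportMetrics(r2))
    expect_identical(foldRecords(r1), foldRecords(r2))
    expect_identical(r1@ci95, r2@ci95)
  }
})

test_that("subject-grouped folds never split a subject", {
  d <- make_xy(n = 60, seed = 5)
  map <- data.frame(subject = rep(paste0("sub", 1:12), each = 5),
                    story = "s1")
  rep <- runLOOCV(d$x, d$y, classifierSpec("logistic"), unit = "subject",
                  map = map, n_boot = 0)
  folds <- foldRecords(rep)
  # a fold id maps to exactly one subject and holds all 5 of its samples
  per <- table(folds$fold, folds$subject)
  expect_true(all(rowSums(per > 0) == 1))
  expect_true(all(per[per > 0] == 5))
  expect_error(runLOOCV(d$x, d$y, unit = "subject"),
               class = "recallFC_classifier_error")
})

test_that("single-class training folds are skipped with a warning", {
  set.seed(12)
  n <- 12
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(c("low", "low", rep("high", n - 2)), levels = c("low", "high"))
  # holding out a low sample leaves one low in training: fold is skipped
  # (glmnet additionally grumbles about small classes on the kept folds)
  w <- capture_warnings(
    rep <- runLOOCV(x, y, classifierSpec("logistic"), n_boot = 0)
  )
  expect_true(any(grepl("skipped: single-class", w)))
  expect_equal(nrow(foldRecords(rep)), n - 2L)
})

test_that("the shuffle null centres on the majority-class proportion", {
  d <- make_xy(n = 120, r = 4, seed = 6)
  map <- data.frame(subject = rep(paste0("sub", 1:30), each = 4),
                    story = rep(c("s1", "s2"), each = 60))
  nul <- shuffleNull(d$x, d$y, classifierSpec("logistic"),
                     unit = "subject", map = map, n_shuffles = 200, seed = 2)
  maj <- max(table(d$y)) / length(d$y)
  expect_lte(abs(nul$null_mean - maj), 0.03)
  expect_equal(nul$n_shuffles, 200L)
})

test_that("shuffle percentile resolution is guarded", {
  d <- make_xy(n = 30, r = 4, seed = 7)
  expect_warning(
    nul <- shuffleNull(d$x, d$y, classifierSpec("logistic"), n_shuffles = 1,
                       seed = 3, observed = 0.9),
    "95th percentile"
  )
  expect_length(nul$null_accuracy, 1L)
  expect_true(is.na(nul$percentile))
})

test_that("paired accuracy test matches t.test and handles degeneracy", {
  a <- c(0.70, 0.72, 0.71, 0.69, 0.73)
  b <- a + c(0.04, 0.05, 0.06, 0.05, 0.04)
  got <- pairedAccuracyTest(a, b)
  want <- t.test(b, a, paired = TRUE)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$p, want$p.value)
  expect_equal(got$delta, unname(want$estimate))

  same <- pairedAccuracyTest(a, a)
  expect_equal(same$delta, 0)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shifted <- pairedAccuracyTest(a, a + 0.05)
  expect_equal(shifted$delta, 0.05)
  expect_equal(shifted$p, 0)
  expect_true(is.infinite(shifted$t))

  expect_error(pairedAccuracyTest(a[1:2], b[1:2]),
               class = "recallFC_classifier_error")
})

test_that("a simulated reliable gain is significant at alpha = 1e-4", {
  set.seed(8)
  a <- 0.72 + rnorm(20, 0, 0.004)
  b <- a + 0.047 + rnorm(20, 0, 0.004)
  got <- pairedAccuracyTest(a, b)
  expect_lt(got$p, 1e-4)
  expect_equal(got$delta, 0.047, tolerance = 0.05)
})

test_that("calibration bins track Bernoulli sampling at stated probabilities", {
  set.seed(9)
  p <- runif(10000)
  yl <- ifelse(runif(10000) < p, "high", "low")
  cal <- calibrationCurve(p, yl, n_bins = 10)
  occupied <- !cal$empty
  expect_true(all(abs(cal$mean_pred[occupied] - cal$obs_freq[occupied]) <=
                    0.05))

  one <- calibrationCurve(rep(1, 5), rep("high", 5), n_bins = 10)
  expect_equal(sum(!one$empty), 1L)
  expect_equal(one$obs_freq[10], 1)

  few <- calibrationCurve(c(0.1, 0.5, 0.55, 0.9, 0.95),
                          c("low", "high", "low", "high", "high"),
                          n_bins = 10)
  expect_gte(sum(few$empty), 5L)
  expect_error(calibrationCurve(0.5, "high", n_bins = 1),
               class = "recallFC_classifier_error")
})

test_that("all three classifier families produce valid reports", {
  d <- make_xy(n = 40, r = 5, sep = TRUE, seed = 10)
  for (fam in c("logistic", "random_forest", "svm")) {
    rep <- runLOOCV(d$x, d$y, classifierSpec(fam), n_boot = 50)
    m <- reportMetrics(rep)
    expect_true(all(m[c("accuracy", "balanced_accuracy", "auc")] >= 0 &
                      m[c("accuracy", "balanced_accuracy", "auc")] <= 1))
    expect_gte(m[["accuracy"]], 0.8)  # separable problem
    expect_s4_class(rep, "ClassificationReport")
  }
})
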