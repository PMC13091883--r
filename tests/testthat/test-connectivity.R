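test_that("scene FC detects perfect linear dependence", {
  set.seed(1)
  base <- rnorm(40)
  ts <- cbind(a = base, b = 2 * base + 1, c = -base, d = rnorm(40))
  fc <- computeSceneFC(ts, trWindow(0, 40))
  expect_equal(fc["a", "b"], 1)
  expect_equal(fc["a", "c"], -1)
  expect_equal(diag(fc), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(fc, t(fc))
})

test_that("scene FC matches an independent two-pass oracle to 1e-12", {
  set.seed(2)
  for (rep in 1:5) {
    ts <- matrix(rnorm(30 * 4), 30, 4,
                 dimnames = list(NULL, paste0("r", 1:4)))
    fc <- computeSceneFC(ts, trWindow(0, 30))
    expect_equal(unname(fc), pearson_oracle(ts), tolerance = 1e-12)
  }
})

test_that("constant ROIs and short windows are rejected", {
  ts <- cbind(a = rnorm(30), b = rep(1, 30))
  err <- tryCatch(computeSceneFC(ts, trWindow(0, 30)), error = identity)
  expect_s3_class(err, "recallFC_fc_error")
  expect_match(conditionMessage(err), "b")
  expect_error(computeSceneFC(cbind(rnorm(30), rnorm(30)), trWindow(0, 2)),
               class = "recallFC_fc_error")
})

test_that("FC is invariant to affine rescaling of ROI series", {
  set.seed(3)
  ts <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("r", 1:6)))
  fc1 <- computeSceneFC(ts, trWindow(0, 50))
  ts2 <- ts
  ts2[, 2] <- 3.7 * ts2[, 2] - 11
  ts2[, 5] <- 0.02 * ts2[, 5] + 5
  fc2 <- computeSceneFC(ts2, trWindow(0, 50))
  expect_equal(fc1, fc2, tolerance = 1e-10)
})

test_that("lower-triangle vectorization is row-major and invertible", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- 0.1; m[3, 1] <- 0.2; m[3, 2] <- 0.3
  m <- m + t(m); diag(m) <- 1
  expect_equal(vectorizeLowerTriangle(m), c(0.1, 0.2, 0.3))

  m2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(vectorizeLowerTriangle(m2), 0.3)

  set.seed(4)
  fc <- computeSceneFC(matrix(rnorm(40 * 5), 40, 5), trWindow(0, 40))
  back <- devectorizeLowerTriangle(vectorizeLowerTriangle(fc))
  expect_equal(unname(fc - diag(5)), back - diag(5))

  asym <- matrix(c(1, 0.1, 0.5, 1), 2, 2)
  expect_error(vectorizeLowerTriangle(asym), class = "recallFC_fc_error")
})

test_that("edge count equals (R^2 - R) / 2 for R in 2..50", {
  for (R in 2:50) {
    v <- vectorizeLowerTriangle(diag(R))
    expect_length(v, (R^2 - R) / 2)
  }
})

test_that("feature tensor assembly enforces a complete, consistent grid", {
  set.seed(5)
  mk <- function(R) {
    fc <- cor(matrix(rnorm(30 * R), 30, R))
    (fc + t(fc)) / 2
  }
  grid <- lapply(1:2, function(t) {
    out <- lapply(1:3, function(m) mk(4))
    names(out) <- paste0("sub", 1:3)
    out
  })
  tn <- assembleFeatureTensor(grid, story = "s")
  expect_equal(dim(featureArray(tn)), c(2L, 3L, 6L))

  one <- assembleFeatureTensor(list(list(solo = mk(5))))
  expect_equal(dim(featureArray(one)), c(1L, 1L, 10L))

  bad <- grid
  bad[[2]][[2]] <- mk(5)
  expect_error(assembleFeatureTensor(bad), class = "recallFC_fc_error")

  missing <- grid
  missing[[2]] <- missing[[2]][-2]
  err <- tryCatch(assembleFeatureTensor(missing), error = identity)
  expect_s3_class(err, "recallFC_fc_error")
  expect_match(conditionMessage(err), "scene 2 / subject sub2")
})

test_that("flattening orders samples scene-major with a faithful map", {
  set.seed(6)
  arr <- array(rnorm(2 * 3 * 6), c(2, 3, 6))
  tn <- new("FeatureTensor", data = arr, scene_ids = c(4L, 9L),
            subject_ids = paste0("sub", 1:3), roi_ids = paste0("r", 1:4),
            story = "s1")
  fl <- flattenFeatureTensor(tn)
  expect_equal(dim(fl$x), c(6L, 6L))
  expect_equal(fl$map$scene, rep(c(4L, 9L), each = 3))
  expect_equal(fl$x[2, ], unname(arr[1, 2, ]), ignore_attr = TRUE)
  expect_equal(fl$x[5, ], unname(arr[2, 2, ]), ignore_attr = TRUE)
})
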