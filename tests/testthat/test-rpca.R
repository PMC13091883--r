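test_that("soft thresholding shrinks toward zero and clips", {
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(-0.5, 1), 0)
  x <- matrix(c(-3, -1, 0, 2), 2)
  expect_equal(softThreshold(x, 0), x)
  expect_equal(softThreshold(x, 1.5), matrix(c(-1.5, 0, 0, 0.5), 2))
  expect_error(softThreshold(1, -1), class = "recallFC_rpca_error")
})

test_that("singular value thresholding shrinks singular values", {
  set.seed(1)
  u <- rnorm(8); u <- u / sqrt(sum(u^2))
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  Z <- 5 * tcrossprod(u, v)
  out <- singularValueThreshold(Z, 1)
  s <- svd(out)
  expect_equal(s$d[1], 4, tolerance = 1e-10)
  expect_lt(s$d[2], 1e-10)
  # same singular subspace (up to sign)
  expect_equal(abs(sum(s$u[, 1] * u)), 1, tolerance = 1e-10)

  expect_equal(singularValueThreshold(Z, 10), matrix(0, 8, 12))
  expect_equal(singularValueThreshold(Z, 0), Z, tolerance = 1e-10)
  expect_error(singularValueThreshold(matrix(c(1, NA), 1), 1),
               class = "recallFC_rpca_error")
})

test_that("pure low-rank input yields a negligible sparse part", {
  set.seed(2)
  Z <- tcrossprod(rnorm(20), rnorm(40))
  d <- rpcaDecompose(Z)
  expect_true(converged(d))
  expect_lte(sqrt(sum(sparsePart(d)^2)) / sqrt(sum(Z^2)), 1e-4)
  expect_equal(lowRank(d), Z, tolerance = 1e-3)
})

test_that("zero input decomposes to zero", {
  d <- rpcaDecompose(matrix(0, 5, 7))
  expect_equal(lowRank(d), matrix(0, 5, 7))
  expect_equal(sparsePart(d), matrix(0, 5, 7))
  expect_true(converged(d))
})

test_that("planted rank-3 plus 2%-sparse structure is recovered", {
  pl <- plantedLowRankSparse(45, 496, rank = 3, density = 0.02,
                             magnitude = 1, seed = 9)
  d <- rpcaDecompose(pl$Z)
  expect_true(converged(d))
  relL <- sqrt(sum((lowRank(d) - pl$L0)^2)) / sqrt(sum(pl$L0^2))
  expect_lte(relL, 1e-3)
  sv <- svd(lowRank(d))$d
  expect_equal(sum(sv > 1e-6 * sv[1]), 3L)
})

test_that("additivity Z = L + S holds within tolerance on varied inputs", {
  set.seed(3)
  cases <- list(
    matrix(rnorm(12 * 30), 12, 30),
    plantedLowRankSparse(10, 45, rank = 2, density = 0.05, seed = 4)$Z,
    matrix(runif(64, -1, 1), 8, 8)
  )
  for (Z in cases) {
    d <- rpcaDecompose(Z)
    resid <- sqrt(sum((Z - lowRank(d) - sparsePart(d))^2)) /
      max(sqrt(sum(Z^2)), 1)
    expect_lte(resid, 1e-7)
  }
})

test_that("the augmented-Lagrangian residual trace is non-increasing", {
  pl <- plantedLowRankSparse(30, 80, rank = 2, density = 0.03, seed = 5)
  d <- rpcaDecompose(pl$Z)
  expect_true(all(diff(residualTrace(d)) <= 1e-12))
})

test_that("decomposition is scale-equivariant", {
  pl <- plantedLowRankSparse(20, 50, rank = 2, density = 0.04, seed = 6)
  d1 <- rpcaDecompose(pl$Z)
  d2 <- rpcaDecompose(2 * pl$Z)
  expect_equal(lowRank(d2), 2 * lowRank(d1), tolerance = 1e-5)
  expect_equal(sparsePart(d2), 2 * sparsePart(d1), tolerance = 1e-5)
})

test_that("row permutation of the input permutes L identically", {
  pl <- plantedLowRankSparse(15, 40, rank = 2, density = 0.05, seed = 7)
  perm <- sample(15)
  d1 <- rpcaDecompose(pl$Z)
  d2 <- rpcaDecompose(pl$Z[perm, ])
  expect_equal(lowRank(d2), lowRank(d1)[perm, ], tolerance = 1e-9)
  expect_equal(sparsePart(d2), sparsePart(d1)[perm, ], tolerance = 1e-9)
})

test_that("per-scene decomposition is deterministic and shape-preserving", {
  set.seed(8)
  arr <- array(rnorm(2 * 6 * 10), c(2, 6, 10))
  arr[2, , ] <- arr[1, , ]   # identical scenes
  tn <- new("FeatureTensor", data = arr, scene_ids = 1:2,
            subject_ids = paste0("sub", 1:6), roi_ids = paste0("r", 1:5),
            story = "s")
  ds <- decomposeAllScenes(tn)
  expect_length(ds, 2L)
  expect_identical(lowRank(ds[[1]]), lowRank(ds[[2]]))
  expect_identical(sparsePart(ds[[1]]), sparsePart(ds[[2]]))
  expect_equal(dim(lowRank(ds[[1]])), c(6L, 10L))

  # block layout stacks square matrices
  ds_block <- decomposeAllScenes(tn, layout = "stacked_matrices")
  expect_equal(dim(lowRank(ds_block[[1]])), c(30L, 5L))
})

test_that("component tensors reconstruct the input within tolerance", {
  set.seed(9)
  arr <- array(rnorm(2 * 8 * 15), c(2, 8, 15))
  tn <- new("FeatureTensor", data = arr, scene_ids = 1:2,
            subject_ids = paste0("sub", 1:8), roi_ids = paste0("r", 1:6),
            story = "s")
  ds <- decomposeAllScenes(tn)
  recon <- componentTensor(tn, ds, "reconstructed")
  expect_equal(featureArray(recon), featureArray(tn), tolerance = 1e-6)
  L <- componentTensor(tn, ds, "low_rank")
  S <- componentTensor(tn, ds, "sparse")
  expect_equal(featureArray(L) + featureArray(S), featureArray(tn),
               tolerance = 1e-6)
})
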