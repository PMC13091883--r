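#' Elementwise soft-thresholding (ell-1 proximal operator)
#'
#' Shrinks each element toward zero by `tau` and clips at zero:
#' `sign(x) * max(|x| - tau, 0)`.
#'
#' @param x Numeric vector or matrix.
#' @param tau Non-negative threshold.
#' @return Object of the same shape as `x`.
#' @examples
#' softThreshold(c(3, -0.5), 1)  # 2, 0
#' @export
softThreshold <- function(x, tau) {
  if (!is_number(tau) || tau < 0)
    stop2("tau must be a single non-negative number", "recallFC_rpca_error")
  sign(x) * pmax(abs(x) - tau, 0)
}

#' Singular value thresholding (nuclear-norm proximal operator)
#'
#' Soft-thresholds the singular values of a matrix: `U shrink(Sigma, tau) V'`.
#' Singular vector signs are fixed deterministically (the largest-magnitude
#' element of each left singular vector is made positive) so results are
#' bit-stable across runs and platforms.
#'
#' @param Z Numeric matrix with finite entries.
#' @param tau Non-negative threshold.
#' @return Matrix of the same shape; zero matrix when `tau >=` the largest
#'   singular value.
#' @export
singularValueThreshold <- function(Z, tau) {
  if (!is_number(tau) || tau < 0)
    stop2("tau must be a single non-negative number", "recallFC_rpca_error")
  if (anyNA(Z) || any(!is.finite(Z)))
    stop2("matrix has non-finite entries", "recallFC_rpca_error")
  s <- svd(Z)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(Z), ncol(Z)))
  U <- s$u[, keep, drop = FALSE]
  V <- s$v[, keep, drop = FALSE]
  # deterministic sign convention
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  U %*% (d[keep] * t(V))
}

#' Robust PCA: split a matrix into low-rank plus sparse components
#'
#' Solves the principal component pursuit problem
#' `min ||L||_* + lambda ||S||_1  s.t.  Z = L + S`
#' by inexact augmented Lagrange multiplier (ALM) iteration, alternating
#' [singularValueThreshold()] for the low-rank update and [softThreshold()]
#' for the sparse update. Applied to a scene's stacked subjects x edges FC
#' matrix, `L` captures the stimulus-driven connectivity structure shared
#' across subjects and `S` the idiosyncratic subject-specific deviations.
#'
#' The dual variable starts at zero and the penalty at
#' `mu0 = 1.25 / ||Z||_2`, growing by `rho` each iteration; with this
#' schedule the iteration is exactly scale-equivariant (decomposing `c * Z`
#' yields `c * L`, `c * S`).
#'
#' @param Z Numeric matrix (e.g. M subjects x r edges), finite entries.
#' @param lambda Sparsity weight; default `1 / sqrt(max(dim(Z)))`.
#' @param tol Convergence tolerance on the relative residual
#'   `||Z - L - S||_F / max(||Z||_F, 1)` (default 1e-7).
#' @param max_iter Maximum iterations (default 500). Non-convergence returns
#'   the current iterate with `converged = FALSE` and a warning.
#' @param rho Penalty growth factor per iteration (default 1.2; gentle
#'   growth keeps the final L/S split accurate, not only their sum).
#' @param scene Scene index recorded in the result (default 1).
#' @return A [SceneDecomposition-class].
#' @examples
#' Z <- tcrossprod(rnorm(20), rnorm(30))
#' d <- rpcaDecompose(Z)
#' converged(d)
#' @export
rpcaDecompose <- function(Z, lambda = NULL, tol = 1e-7, max_iter = 500L,
                          rho = 1.2, scene = 1L) {
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  if (anyNA(Z) || any(!is.finite(Z)))
    stop2("input matrix has non-finite entries", "recallFC_rpca_error")
  if (is.null(lambda)) lambda <- 1 / sqrt(max(dim(Z)))
  if (!is_number(lambda) || lambda <= 0)
    stop2("lambda must be positive", "recallFC_rpca_error")
  if (!is_number(tol) || tol <= 0)
    stop2("tol must be positive", "recallFC_rpca_error")

  zf <- fnorm(Z)
  denom <- max(zf, 1)
  if (zf == 0) {
    return(new("SceneDecomposition", scene = as.integer(scene),
               L = Z * 0, S = Z * 0, lambda = lambda, iterations = 0L,
               residual = 0, converged = TRUE, residual_trace = numeric()))
  }

  mu <- 1.25 / specnorm(Z)
  mu_max <- mu * 1e7
  S <- matrix(0, nrow(Z), ncol(Z))
  Y <- matrix(0, nrow(Z), ncol(Z))
  trace <- numeric(0)
  convg <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    L <- singularValueThreshold(Z - S + Y / mu, 1 / mu)
    S <- softThreshold(Z - L + Y / mu, lambda / mu)
    resid_mat <- Z - L - S
    Y <- Y + mu * resid_mat
    mu <- min(mu * rho, mu_max)
    res <- fnorm(resid_mat) / denom
    trace <- c(trace, res)
    if (res <= tol) {
      convg <- TRUE
      break
    }
  }
  if (!convg)
    warning(sprintf(
      "RPCA did not reach tol %.1e in %d iterations (residual %.2e)",
      tol, max_iter, trace[length(trace)]
    ))
  new("SceneDecomposition", scene = as.integer(scene), L = L, S = S,
      lambda = lambda, iterations = it, residual = trace[length(trace)],
      converged = convg, residual_trace = trace)
}

#' Decompose every scene of a feature tensor
#'
#' Runs [rpcaDecompose()] independently on each scene's subjects x edges
#' slice `Z_t` of a [FeatureTensor-class]. Deterministic given the tensor and
#' configuration.
#'
#' @param tensor A [FeatureTensor-class].
#' @param lambda,tol,max_iter,rho Passed to [rpcaDecompose()].
#' @param layout `"subjects_by_edges"` (default) decomposes each scene's
#'   M x r matrix of vectorized edges; `"stacked_matrices"` decomposes the
#'   (M * R) x R vertical stack of the reconstructed square FC matrices (an
#'   alternative reading of "concatenated" stacking, kept behind this flag).
#' @return List of [SceneDecomposition-class], one per scene, in scene order.
#'   For the `"stacked_matrices"` layout the L/S matrices have shape
#'   (M * R) x R.
#' @export
decomposeAllScenes <- function(tensor, lambda = NULL, tol = 1e-7,
                               max_iter = 500L, rho = 1.2,
                               layout = c("subjects_by_edges",
                                          "stacked_matrices")) {
  stopifnot(is(tensor, "FeatureTensor"))
  layout <- match.arg(layout)
  W <- dim(tensor@data)[1]
  lapply(seq_len(W), function(t) {
    Zt <- tensor@data[t, , , drop = TRUE]
    if (is.null(dim(Zt))) Zt <- matrix(Zt, nrow = 1)
    if (layout == "stacked_matrices") {
      Zt <- do.call(rbind, lapply(seq_len(nrow(Zt)), function(m) {
        devectorizeLowerTriangle(Zt[m, ])
      }))
    }
    tryCatch(
      rpcaDecompose(Zt, lambda = lambda, tol = tol, max_iter = max_iter,
                    rho = rho, scene = tensor@scene_ids[t]),
      recallFC_rpca_error = function(e) {
        stop2(sprintf("scene %d: %s", tensor@scene_ids[t],
                      conditionMessage(e)), "recallFC_rpca_error")
      }
    )
  })
}

#' Replace a tensor's features by a decomposition component
#'
#' Builds the "low_rank" or "sparse" feature variant: each scene slice of the
#' tensor is replaced by the corresponding component matrix from
#' [decomposeAllScenes()] (subjects-by-edges layout). `"reconstructed"`
#' returns L + S, which equals the input within the solver tolerance and is
#' useful for plumbing checks.
#'
#' @param tensor The [FeatureTensor-class] that was decomposed.
#' @param decompositions List of [SceneDecomposition-class] from
#'   [decomposeAllScenes()].
#' @param component `"low_rank"`, `"sparse"` or `"reconstructed"`.
#' @return A [FeatureTensor-class] with substituted features.
#' @export
componentTensor <- function(tensor, decompositions,
                            component = c("low_rank", "sparse",
                                          "reconstructed")) {
  component <- match.arg(component)
  stopifnot(is(tensor, "FeatureTensor"),
            length(decompositions) == dim(tensor@data)[1])
  arr <- tensor@data
  for (t in seq_along(decompositions)) {
    d <- decompositions[[t]]
    m <- switch(component,
      low_rank = d@L,
      sparse = d@S,
      reconstructed = d@L + d@S
    )
    if (!identical(dim(m), dim(arr)[2:3]))
      stop2(sprintf("scene %d: component shape %s does not match tensor slice",
                    t, paste(dim(m), collapse = "x")), "recallFC_rpca_error")
    arr[t, , ] <- m
  }
  new("FeatureTensor", data = arr, scene_ids = tensor@scene_ids,
      subject_ids = tensor@subject_ids, roi_ids = tensor@roi_ids,
      story = tensor@story)
}

#' Planted low-rank plus sparse test matrix
#'
#' Generates `Z = L0 + S0` with known ground truth: `L0 = U V'` for Gaussian
#' factors (rank `rank`) and `S0` with `density` fraction of entries set to
#' `+/- magnitude`. Used as the recovery oracle for [rpcaDecompose()].
#'
#' @param M,r Matrix dimensions.
#' @param rank Planted rank of `L0`.
#' @param density Fraction of nonzero entries in `S0`.
#' @param magnitude Magnitude of the sparse spikes.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return List with `Z`, `L0`, `S0`.
#' @export
plantedLowRankSparse <- function(M, r, rank = 3L, density = 0.02,
                                 magnitude = 1, seed = NULL) {
  stopifnot(M >= 2, r >= 2, rank >= 1, density >= 0, density <= 1)
  with_seed_opt(seed, {
    U <- matrix(rnorm(M * rank), M, rank)
    V <- matrix(rnorm(r * rank), r, rank)
    L0 <- U %*% t(V) / sqrt(rank)
    S0 <- matrix(0, M, r)
    nnz <- round(density * M * r)
    if (nnz > 0) {
      idx <- sample.int(M * r, nnz)
      S0[idx] <- magnitude * sample(c(-1, 1), nnz, replace = TRUE)
    }
    list(Z = L0 + S0, L0 = L0, S0 = S0)
  })
}
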