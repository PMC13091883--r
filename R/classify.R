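#' Classifier specification
#'
#' Describes one of the three supported classifier families with its
#' regularization and seed. Ridge (ell-2) regularization applies to the
#' logistic and linear-SVM families; tree count and depth to the random
#' forest.
#'
#' @param family `"logistic"`, `"random_forest"` or `"svm"`.
#' @param l2 Ridge strength for logistic/SVM. For logistic regression the
#'   glmnet penalty is `l2 / n_train`; for the SVM the cost is `1 / l2`
#'   (default 1, i.e. unit cost).
#' @param num_trees Random-forest tree count (default 200).
#' @param max_depth Random-forest maximum depth; 0 = unlimited (default).
#' @param seed Seed for stochastic fits (default 1).
#' @return A list of class `ClassifierSpec`.
#' @examples
#' classifierSpec("logistic")
#' @export
classifierSpec <- function(family = c("logistic", "random_forest", "svm"),
                           l2 = 1, num_trees = 200L, max_depth = 0L,
                           seed = 1L) {
  family <- match.arg(family)
  if (family %in% c("logistic", "svm") && (!is_number(l2) || l2 <= 0))
    stop2("l2 must be positive for logistic/svm", "recallFC_classifier_error")
  structure(list(family = family, l2 = l2, num_trees = as.integer(num_trees),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "ClassifierSpec")
}

# Fit on (xtr, ytr), return P(class = "high") for rows of xte.
# y must be a factor with levels c("low", "high").
fit_predict <- function(spec, xtr, ytr, xte) {
  if (is.null(colnames(xtr))) {
    colnames(xtr) <- paste0("f", seq_len(ncol(xtr)))
    colnames(xte) <- colnames(xtr)
  }
  switch(spec$family,
    logistic = {
      fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                            lambda = spec$l2 / nrow(xtr), standardize = TRUE)
      as.numeric(predict(fit, xte, type = "response"))
    },
    random_forest = {
      fit <- ranger::ranger(
        x = xtr, y = ytr, probability = TRUE,
        num.trees = spec$num_trees,
        max.depth = if (spec$max_depth > 0L) spec$max_depth else NULL,
        seed = spec$seed, num.threads = 1L
      )
      p <- predict(fit, xte, num.threads = 1L)$predictions
      as.numeric(p[, "high"])
    },
    svm = {
      withr::with_seed(spec$seed, {
        fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1 / spec$l2,
                          probability = TRUE)
        p <- attr(predict(fit, xte, probability = TRUE), "probabilities")
        as.numeric(p[, "high"])
      })
    }
  )
}

as_label_factor <- function(y) {
  if (is.factor(y)) {
    stopifnot(all(levels(y) %in% c("low", "high")))
    factor(as.character(y), levels = c("low", "high"))
  } else {
    stopifnot(all(y %in% c("low", "high")))
    factor(y, levels = c("low", "high"))
  }
}

pooled_metrics <- function(truth, prob) {
  pred <- factor(ifelse(prob >= 0.5, "high", "low"), levels = c("low", "high"))
  acc <- mean(pred == truth)
  sens <- mean(pred[truth == "high"] == "high")
  spec <- mean(pred[truth == "low"] == "low")
  bacc <- mean(c(sens, spec), na.rm = TRUE)
  auc <- if (length(unique(truth)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = prob, levels = c("low", "high"),
      direction = "<", quiet = TRUE
    )))
  } else NA_real_
  list(pred = pred, accuracy = acc, balanced_accuracy = bacc, auc = auc)
}

#' Leave-one-out cross-validated classification
#'
#' Runs LOOCV with one fold per held-out unit. With `unit = "sample"` every
#' scene-subject sample is held out in turn (so other scenes of the same
#' subject remain in training -- the conventional but leakage-prone framing);
#' with `unit = "subject"` all samples of one subject are held out together,
#' which is the leakage-safe grouping and the recommended mode. Accuracy is
#' the mean held-out correctness; balanced accuracy and AUC are computed from
#' the pooled held-out predictions; the 95% CI is a seeded percentile
#' bootstrap (default 1000 resamples) over per-fold outcomes.
#'
#' @param x Numeric feature matrix, samples x features.
#' @param y Labels: factor with levels `c("low", "high")` (or a character
#'   vector of those values).
#' @param spec A [classifierSpec()].
#' @param unit `"sample"` (default) or `"subject"`.
#' @param map Optional data.frame aligned with rows of `x`, with columns
#'   `subject` and (optionally) `story`; required for `unit = "subject"` and
#'   for within-story shuffling downstream.
#' @param n_boot Bootstrap resamples for the accuracy CI (default 1000; 0
#'   skips the CI).
#' @param n_bins Calibration bins (default 10).
#' @param seed Seed for the bootstrap (default `spec$seed`).
#' @param variant Feature-variant tag stored in the report (default `"fc"`).
#' @return A [ClassificationReport-class]. Folds whose training labels are
#'   single-class (or leave a class with fewer than two observations, which
#'   no classifier here can fit) are skipped with a warning and recorded
#'   (their samples are absent from the pooled results).
#' @export
runLOOCV <- function(x, y, spec = classifierSpec(), unit = c("sample", "subject"),
                     map = NULL, n_boot = 1000L, n_bins = 10L,
                     seed = spec$seed, variant = "fc") {
  unit <- match.arg(unit)
  y <- as_label_factor(y)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (unit == "subject" && (is.null(map) || is.null(map$subject)))
    stop2("unit = 'subject' requires a map with a subject column",
          "recallFC_classifier_error")
  n <- nrow(x)
  subjects <- if (!is.null(map)) as.character(map$subject)
              else as.character(seq_len(n))
  stories <- if (!is.null(map) && !is.null(map$story)) as.character(map$story)
             else rep("story", n)

  folds <- if (unit == "sample") as.list(seq_len(n))
           else unname(split(seq_len(n), subjects))

  prob <- rep(NA_real_, n)
  fold_id <- rep(NA_integer_, n)
  skipped <- 0L
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2L || min(table(y[train])) < 2L) {
      warning(sprintf(
        "fold %d skipped: single-class (or near-degenerate) training labels", f
      ))
      skipped <- skipped + 1L
      next
    }
    prob[test] <- fit_predict(spec, x[train, , drop = FALSE], y[train],
                              x[test, , drop = FALSE])
    fold_id[test] <- f
  }
  tested <- !is.na(prob)
  if (!any(tested))
    stop2("no fold could be evaluated", "recallFC_classifier_error")

  pm <- pooled_metrics(y[tested], prob[tested])
  folds_df <- data.frame(
    fold = fold_id[tested], subject = subjects[tested],
    story = stories[tested], truth = as.character(y[tested]),
    prob_high = prob[tested],
    pred = as.character(pm$pred), stringsAsFactors = FALSE
  )
  folds_df$correct <- folds_df$pred == folds_df$truth

  # per-fold outcomes (fold accuracy) for the bootstrap
  fold_acc <- vapply(split(folds_df$correct, folds_df$fold), mean, 1)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    boots <- with_seed_opt(seed, {
      vapply(seq_len(n_boot), function(b) {
        mean(fold_acc[sample.int(length(fold_acc), replace = TRUE)])
      }, 1)
    })
    ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
    # percentile CI over fold means can exclude the pooled mean only through
    # unequal fold sizes; clamp so the interval always brackets the estimate
    ci[1] <- min(ci[1], pm$accuracy)
    ci[2] <- max(ci[2], pm$accuracy)
  }

  calib <- calibrationCurve(folds_df$prob_high,
                            factor(folds_df$truth, c("low", "high")),
                            n_bins = n_bins)

  new("ClassificationReport",
      variant = variant, classifier = spec$family, unit = unit,
      metrics = c(accuracy = pm$accuracy,
                  balanced_accuracy = pm$balanced_accuracy, auc = pm$auc),
      ci95 = ci, folds = folds_df, calibration = calib,
      shuffle = list(), seed = as.integer(seed))
}

#' Label-shuffling null distribution for a LOOCV classifier
#'
#' Permutes the labels within each story (preserving per-story class balance),
#' reruns the full LOOCV for every permutation, and summarizes the null
#' distribution of accuracies. A planted label-feature association should
#' place the observed accuracy above the upper tail of this null; shuffled
#' labels validate that scene windows and labels are actually aligned.
#'
#' @param x,y,spec,unit,map As in [runLOOCV()].
#' @param n_shuffles Number of label permutations (>= 1). Fewer than 20
#'   shuffles cannot resolve a 95th percentile; a warning is issued.
#' @param seed Seed controlling the permutations (default 7).
#' @param observed Optional observed accuracy (e.g. from [runLOOCV()]); when
#'   supplied, its percentile within the null is reported.
#' @return List: `null_accuracy` (vector), `null_mean`, `null_sd`,
#'   `n_shuffles`, `observed`, `percentile` (fraction of null values strictly
#'   below the observed; NA when `observed` is missing or resolution is
#'   insufficient).
#' @export
shuffleNull <- function(x, y, spec = classifierSpec(),
                        unit = c("sample", "subject"), map = NULL,
                        n_shuffles = 100L, seed = 7L, observed = NULL) {
  unit <- match.arg(unit)
  y <- as_label_factor(y)
  if (n_shuffles < 1L)
    stop2("n_shuffles must be >= 1", "recallFC_classifier_error")
  if (n_shuffles < 20L)
    warning("fewer than 20 shuffles cannot resolve a 95th percentile")
  stories <- if (!is.null(map) && !is.null(map$story)) as.character(map$story)
             else rep("story", length(y))

  null_acc <- with_seed_opt(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      yp <- y
      for (st in unique(stories)) {
        i <- which(stories == st)
        yp[i] <- y[i][sample.int(length(i))]
      }
      rep <- suppressWarnings(
        runLOOCV(x, yp, spec, unit = unit, map = map, n_boot = 0L,
                 seed = spec$seed, variant = "null")
      )
      unname(reportMetrics(rep)[["accuracy"]])
    }, 1)
  })
  pct <- if (!is.null(observed) && n_shuffles >= 20L)
    mean(null_acc < observed) else NA_real_
  list(null_accuracy = null_acc, null_mean = mean(null_acc),
       null_sd = sd(null_acc), n_shuffles = as.integer(n_shuffles),
       observed = if (is.null(observed)) NA_real_ else observed,
       percentile = pct)
}

#' Attach a shuffle-null summary to a classification report
#'
#' Convenience: runs [shuffleNull()] with the report's observed accuracy and
#' stores the summary in the report.
#'
#' @param report A [ClassificationReport-class].
#' @param x,y,spec,unit,map,n_shuffles,seed Passed to [shuffleNull()].
#' @return The report with its `shuffle` slot filled.
#' @export
withShuffleNull <- function(report, x, y, spec = classifierSpec(),
                            unit = report@unit, map = NULL,
                            n_shuffles = 100L, seed = 7L) {
  report@shuffle <- shuffleNull(
    x, y, spec, unit = unit, map = map, n_shuffles = n_shuffles, seed = seed,
    observed = unname(reportMetrics(report)[["accuracy"]])
  )
  report
}

#' Paired accuracy comparison across repeated runs
#'
#' Paired t test on per-run accuracy differences between two pipeline
#' variants evaluated with identical fold structure. With zero variance in
#' the differences the statistic degenerates: a zero mean difference gives
#' `t = 0, p = 1`; a nonzero mean difference with zero variance is reported
#' as `t = +/- Inf, p = 0`.
#'
#' @param acc_a,acc_b Equal-length numeric vectors of per-run accuracies
#'   (>= 3 runs).
#' @return List: `delta` (mean of `acc_b - acc_a`), `t`, `df`, `p`.
#' @examples
#' pairedAccuracyTest(c(.70, .71, .72), c(.75, .76, .77))
#' @export
pairedAccuracyTest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    stop2("paired vectors must have equal length", "recallFC_classifier_error")
  if (length(acc_a) < 3L)
    stop2("need at least 3 paired runs", "recallFC_classifier_error")
  d <- acc_b - acc_a
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(delta = 0, t = 0, df = n - 1L, p = 1))
    return(list(delta = m, t = sign(m) * Inf, df = n - 1L, p = 0))
  }
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1L)
  list(delta = m, t = tstat, df = n - 1L, p = p)
}

#' Calibration curve from pooled held-out probabilities
#'
#' Bins predicted probabilities into `n_bins` equal-width bins over `[0, 1]`
#' and compares each bin's mean predicted probability with the observed
#' frequency of the positive ("high") class.
#'
#' @param prob Predicted probabilities of the positive class, in `[0, 1]`.
#' @param labels Factor with levels `c("low", "high")` (or character).
#' @param n_bins Number of bins (>= 2, default 10).
#' @return Data.frame: `bin`, `lo`, `hi`, `n`, `mean_pred`, `obs_freq`,
#'   `empty`. Empty bins have `NA` means and `empty = TRUE`.
#' @examples
#' p <- runif(500); yl <- ifelse(runif(500) < p, "high", "low")
#' calibrationCurve(p, yl)
#' @export
calibrationCurve <- function(prob, labels, n_bins = 10L) {
  if (n_bins < 2L)
    stop2("n_bins must be at least 2", "recallFC_classifier_error")
  if (any(prob < 0 | prob > 1))
    stop2("probabilities must lie in [0, 1]", "recallFC_classifier_error")
  labels <- as_label_factor(labels)
  stopifnot(length(prob) == length(labels))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(prob, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  out <- data.frame(
    bin = seq_len(n_bins), lo = edges[-(n_bins + 1L)], hi = edges[-1L]
  )
  out$n <- vapply(out$bin, function(b) sum(bin == b), 1L)
  out$mean_pred <- vapply(out$bin, function(b) {
    if (any(bin == b)) mean(prob[bin == b]) else NA_real_
  }, 1)
  out$obs_freq <- vapply(out$bin, function(b) {
    if (any(bin == b)) mean(labels[bin == b] == "high") else NA_real_
  }, 1)
  out$empty <- out$n == 0L
  out
}
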