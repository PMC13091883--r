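#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full analysis run over a
#' study directory laid out as written by [simulateStudy()] /
#' [writeStudy()]: `annotations/` (JSON per story and annotator),
#' `recall.csv`, `timeseries/<subject>.tsv`, `roi_manifest.csv`,
#' `timing.yaml`.
#'
#' @param study_dir Input study directory.
#' @param out_dir Output directory (created on run).
#' @param networks Network names from the ROI manifest to analyze.
#' @param variants Feature variants to classify: subset of
#'   `c("fc", "low_rank", "sparse")`.
#' @param classifiers Classifier families: subset of
#'   `c("logistic", "random_forest", "svm")`.
#' @param cv_unit LOOCV unit: `"sample"` or `"subject"`.
#' @param label_rule,theta,q Label binarization (see [binarizeLabels()]).
#' @param bounds Scene duration policy ([durationBounds()]).
#' @param min_support Minimum annotators per consensus scene.
#' @param rpca_tol,rpca_max_iter,rpca_lambda RPCA solver settings
#'   (`NULL` lambda = default scaling).
#' @param n_shuffles Label shuffles per (network, variant) for the null
#'   (0 disables). The null is computed once per (network, variant) with the
#'   ridge-logistic classifier and shared across classifier reports.
#' @param fisher_z Apply Fisher z before stacking FC features.
#' @param write_tensors Write tensors and decomposition binaries (default
#'   TRUE).
#' @param seed Seed for stochastic components.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(study_dir, out_dir,
                           networks = c("DMN", "Auditory"),
                           variants = c("fc", "low_rank", "sparse"),
                           classifiers = c("logistic", "random_forest",
                                           "svm"),
                           cv_unit = c("sample", "subject"),
                           label_rule = c("threshold", "quantile"),
                           theta = 0.5, q = 0.25,
                           bounds = durationBounds(), min_support = 2L,
                           rpca_tol = 1e-7, rpca_max_iter = 500L,
                           rpca_lambda = NULL, n_shuffles = 0L,
                           fisher_z = FALSE, write_tensors = TRUE,
                           seed = 7L) {
  cfg <- list(
    study_dir = study_dir, out_dir = out_dir, networks = networks,
    variants = match.arg(variants, c("fc", "low_rank", "sparse"),
                         several.ok = TRUE),
    classifiers = match.arg(classifiers,
                            c("logistic", "random_forest", "svm"),
                            several.ok = TRUE),
    cv_unit = match.arg(cv_unit), label_rule = match.arg(label_rule),
    theta = theta, q = q, bounds = bounds,
    min_support = as.integer(min_support), rpca_tol = rpca_tol,
    rpca_max_iter = as.integer(rpca_max_iter), rpca_lambda = rpca_lambda,
    n_shuffles = as.integer(n_shuffles), fisher_z = isTRUE(fisher_z),
    write_tensors = isTRUE(write_tensors), seed = as.integer(seed)
  )
  structure(cfg, class = "PipelineConfig")
}

config_hash <- function(cfg) {
  plain <- cfg
  # hash the scientific configuration only: where inputs/outputs live must
  # not change the provenance identity of a result
  plain$study_dir <- NULL
  plain$out_dir <- NULL
  plain$bounds <- unclass(plain$bounds)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(plain), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

pipeline_inputs <- function(cfg) {
  list(
    annotations = file.path(cfg$study_dir, "annotations"),
    recall = file.path(cfg$study_dir, "recall.csv"),
    timeseries = file.path(cfg$study_dir, "timeseries"),
    manifest = file.path(cfg$study_dir, "roi_manifest.csv"),
    timing = file.path(cfg$study_dir, "timing.yaml")
  )
}

#' Run the full scene-to-classification pipeline
#'
#' Executes, per story: consensus segmentation from the annotator JSONs,
#' scene-to-TR window mapping, per-scene/subject Pearson FC, per-scene
#' robust-PCA decomposition; then builds scene-level recall labels and runs
#' LOOCV classification for every requested network x feature-variant x
#' classifier combination, optionally with a within-story label-shuffling
#' null. All inputs are validated before any computation; any stage error
#' aborts with the stage name, retaining partial outputs under
#' `<out_dir>/failed/`. Every artifact gets a JSON provenance sidecar
#' (config hash, seed, package version), so identical config + seed
#' reproduces identical reports.
#'
#' @param cfg A [pipelineConfig()].
#' @param quiet Suppress stage progress messages (default FALSE).
#' @return (Invisibly) list with `scenes`, `labels`, `reports` (named list of
#'   [ClassificationReport-class]) and `out_dir`.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  paths <- pipeline_inputs(cfg)
  missing <- !vapply(paths, file.exists, TRUE)
  if (any(missing))
    stop2(sprintf("missing input path(s): %s",
                  paste(unlist(paths[missing]), collapse = ", ")),
          "recallFC_config_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      keep <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                      file.path(cfg$out_dir, "failed"))
      if (length(keep)) {
        faildir <- file.path(cfg$out_dir, "failed")
        dir.create(faildir, showWarnings = FALSE)
        file.copy(keep, faildir, recursive = TRUE)
        unlink(keep, recursive = TRUE)
      }
      stop2(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), "recallFC_pipeline_error")
    })
    say("stage %-12s done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  provenance <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                     package = "recallFC",
                     version = as.character(utils::packageVersion("recallFC")))

  timing_blocks <- stage("timing", readTimingConfig(paths$timing))
  manifest <- stage("manifest", readROIManifest(paths$manifest))
  bad_net <- setdiff(cfg$networks, unique(manifest$network))
  if (length(bad_net))
    stop2(sprintf("network(s) not in manifest: %s",
                  paste(bad_net, collapse = ", ")), "recallFC_config_error")

  # --- consensus segmentation per story -------------------------------------
  scenes <- stage("consensus", {
    files <- list.files(paths$annotations, pattern = "\\.json$",
                        full.names = TRUE)
    segs <- lapply(files, readAnnotatorSegmentation)
    story_of <- vapply(segs, function(s) {
      st <- attr(s, "story")
      if (is.null(st)) "" else st
    }, character(1))
    out <- lapply(names(timing_blocks), function(sn) {
      mine <- segs[story_of == sn]
      if (length(mine) < 2L)
        stop2(sprintf("story '%s': fewer than two annotation files", sn),
              "recallFC_config_error")
      sc <- suppressWarnings(consensusScenes(
        mine, bounds = cfg$bounds, min_support = cfg$min_support
      ))
      writeConsensusScenes(sc, file.path(cfg$out_dir,
                                         sprintf("scenes_%s.json", sn)))
      sc
    })
    names(out) <- names(timing_blocks)
    out
  })

  # --- labels ---------------------------------------------------------------
  labels <- stage("labels", {
    records <- readRecallCSV(paths$recall)
    per_story <- lapply(names(scenes), function(sn) {
      df <- sceneRecallScores(records, scenes[[sn]],
                              subjects = timing_blocks[[sn]]$subjects)
      df$story <- sn
      df
    })
    lab <- do.call(rbind, per_story)
    lab <- binarizeLabels(lab, rule = cfg$label_rule, theta = cfg$theta,
                          q = cfg$q)
    write.csv(lab[, c("story", "scene", "subject", "mean_score", "class")],
              file.path(cfg$out_dir, "labels.csv"), row.names = FALSE,
              quote = FALSE)
    lab
  })

  # --- time series ----------------------------------------------------------
  ts_by_story <- stage("timeseries", {
    lapply(names(timing_blocks), function(sn) {
      subjects <- timing_blocks[[sn]]$subjects
      ts <- lapply(subjects, function(subj) {
        f <- file.path(paths$timeseries, paste0(subj, ".tsv"))
        if (!file.exists(f))
          stop2(sprintf("time series file missing for subject '%s' (%s)",
                        subj, f), "recallFC_config_error")
        readROITimeSeries(f)
      })
      names(ts) <- subjects
      ts
    })
  })
  names(ts_by_story) <- names(timing_blocks)

  # --- per-network FC, decomposition, classification ------------------------
  reports <- list()
  combined <- list()
  for (net in cfg$networks) {
    rois <- manifest$roi[manifest$network == net]
    tensors <- stage(paste0("fc_", net), {
      out <- lapply(names(scenes), function(sn) {
        wins <- scenesToTRWindows(scenes[[sn]], timing_blocks[[sn]]$timing)
        tn <- sceneFCTensor(ts_by_story[[sn]], wins, rois = rois,
                            scene_ids = scenes[[sn]]$scene, story = sn,
                            fisher_z = cfg$fisher_z)
        if (cfg$write_tensors)
          writeFeatureTensor(tn, file.path(cfg$out_dir,
                                           sprintf("tensor_%s_%s", net, sn)))
        tn
      })
      names(out) <- names(scenes)
      out
    })

    decomps <- stage(paste0("rpca_", net), {
      out <- lapply(names(tensors), function(sn) {
        ds <- decomposeAllScenes(tensors[[sn]], lambda = cfg$rpca_lambda,
                                 tol = cfg$rpca_tol,
                                 max_iter = cfg$rpca_max_iter)
        summary <- lapply(ds, function(d) list(
          scene = d@scene, lambda = d@lambda, iterations = d@iterations,
          residual = d@residual, converged = d@converged
        ))
        jsonlite::write_json(
          summary, file.path(cfg$out_dir,
                             sprintf("decomp_%s_%s.json", net, sn)),
          auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
        if (cfg$write_tensors) {
          for (d in ds)
            writeDecomposition(d, file.path(
              cfg$out_dir, sprintf("decomp_%s_%s_scene%02d", net, sn, d@scene)
            ))
        }
        ds
      })
      names(out) <- names(tensors)
      out
    })

    variant_xy <- stage(paste0("features_", net), {
      flat_of <- function(tns) flattenFeatureTensor(unname(tns))
      base_flat <- flat_of(tensors)
      key <- function(map) paste(map$story, map$scene, map$subject, sep = ".")
      lab_key <- paste(labels$story, labels$scene, labels$subject, sep = ".")
      y <- labels$class[match(key(base_flat$map), lab_key)]
      if (anyNA(y))
        stop2("labels missing for some scene-subject samples",
              "recallFC_pipeline_error")
      xs <- list(fc = base_flat$x)
      for (v in setdiff(cfg$variants, "fc")) {
        comp <- if (v == "low_rank") "low_rank" else "sparse"
        vt <- lapply(names(tensors), function(sn) {
          componentTensor(tensors[[sn]], decomps[[sn]], component = comp)
        })
        xs[[v]] <- flat_of(vt)$x
      }
      list(xs = xs, y = y, map = base_flat$map)
    })

    for (v in cfg$variants) {
      x <- variant_xy$xs[[v]]
      y <- variant_xy$y
      map <- variant_xy$map
      null_sum <- NULL
      if (cfg$n_shuffles > 0L) {
        null_sum <- stage(sprintf("null_%s_%s", net, v), {
          shuffleNull(x, y, classifierSpec("logistic", seed = cfg$seed),
                      unit = cfg$cv_unit, map = map,
                      n_shuffles = cfg$n_shuffles, seed = cfg$seed)
        })
      }
      for (clf in cfg$classifiers) {
        id <- sprintf("%s_%s_%s", net, v, clf)
        rep <- stage(paste0("clf_", id), {
          r <- runLOOCV(x, y, classifierSpec(clf, seed = cfg$seed),
                        unit = cfg$cv_unit, map = map, seed = cfg$seed,
                        variant = v)
          if (!is.null(null_sum)) {
            obs <- unname(reportMetrics(r)[["accuracy"]])
            ns <- null_sum
            ns$observed <- obs
            ns$percentile <- if (ns$n_shuffles >= 20L)
              mean(ns$null_accuracy < obs) else NA_real_
            r@shuffle <- ns
          }
          r
        })
        reports[[id]] <- rep
        report_json <- list(
          network = net, variant = v, classifier = clf, unit = rep@unit,
          n_samples = nrow(rep@folds),
          metrics = as.list(rep@metrics), ci95 = rep@ci95,
          shuffle = if (length(rep@shuffle))
            rep@shuffle[c("null_mean", "null_sd", "n_shuffles", "observed",
                          "percentile")] else NULL,
          calibration = rep@calibration,
          provenance = provenance
        )
        jsonlite::write_json(report_json,
                             file.path(cfg$out_dir,
                                       sprintf("report_%s.json", id)),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        combined[[id]] <- data.frame(
          network = net, variant = v, classifier = clf,
          accuracy = rep@metrics[["accuracy"]],
          balanced_accuracy = rep@metrics[["balanced_accuracy"]],
          auc = rep@metrics[["auc"]], ci_lo = rep@ci95[1],
          ci_hi = rep@ci95[2],
          shuffle_mean = if (length(rep@shuffle)) rep@shuffle$null_mean
                         else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  write.csv(do.call(rbind, unname(combined)),
            file.path(cfg$out_dir, "reports.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scenes = scenes, labels = labels, reports = reports,
                 out_dir = cfg$out_dir))
}

#' Build classification features from an in-memory simulated study
#'
#' Convenience path mirroring [runPipeline()] without disk round-trips:
#' consensus scenes (or the generator's true scenes), TR windows, per-scene
#' FC tensors for one network, scene-level labels, and the flattened design
#' matrix with its sample map.
#'
#' @param study Study object from [simulateStudy()].
#' @param network Network name from the study's ROI manifest.
#' @param label_rule,theta,q Binarization settings (see [binarizeLabels()]).
#' @param use_true_scenes Use the generator's true partition instead of the
#'   annotator consensus (default FALSE).
#' @param bounds,min_support Consensus settings (see [consensusScenes()]).
#' @return List: `x` (samples x edges), `y` (factor low/high), `map`
#'   (story/scene/subject per row), `tensors` (per-story
#'   [FeatureTensor-class]), `scenes` (per-story scene tables), `labels`.
#' @export
studyFeatures <- function(study, network = "DMN",
                          label_rule = c("threshold", "quantile"),
                          theta = 0.5, q = 0.25, use_true_scenes = FALSE,
                          bounds = durationBounds(), min_support = 2L) {
  label_rule <- match.arg(label_rule)
  manifest <- study$stories[[1]]$manifest
  rois <- manifest$roi[manifest$network == network]
  if (!length(rois))
    stop2(sprintf("no ROIs tagged '%s' in the manifest", network),
          "recallFC_config_error")
  scenes <- lapply(names(study$stories), function(sn) {
    st <- study$stories[[sn]]
    if (use_true_scenes) st$scenes
    else suppressWarnings(consensusScenes(st$annotations, bounds = bounds,
                                          min_support = min_support))
  })
  names(scenes) <- names(study$stories)
  tensors <- lapply(names(study$stories), function(sn) {
    st <- study$stories[[sn]]
    wins <- scenesToTRWindows(scenes[[sn]], st$timing)
    sceneFCTensor(st$timeseries, wins, rois = rois,
                  scene_ids = scenes[[sn]]$scene, story = sn)
  })
  names(tensors) <- names(study$stories)
  labels <- do.call(rbind, lapply(names(study$stories), function(sn) {
    st <- study$stories[[sn]]
    df <- sceneRecallScores(st$records, scenes[[sn]],
                            subjects = names(st$timeseries))
    df$story <- sn
    df
  }))
  labels <- binarizeLabels(labels, rule = label_rule, theta = theta, q = q)
  flat <- flattenFeatureTensor(unname(tensors))
  key <- paste(flat$map$story, flat$map$scene, flat$map$subject, sep = ".")
  lkey <- paste(labels$story, labels$scene, labels$subject, sep = ".")
  y <- labels$class[match(key, lkey)]
  if (anyNA(y))
    stop2("labels missing for some scene-subject samples",
          "recallFC_pipeline_error")
  list(x = flat$x, y = y, map = flat$map, tensors = tensors,
       scenes = scenes, labels = labels)
}
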