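# recallFC

Scene-level memory recall classification from narrative fMRI functional
connectivity.

## What this package is for

In naturalistic listening experiments, subjects hear an audio story in the
scanner and afterwards answer recall questions. Analyzing such data scene by
scene requires three things that this package implements end to end:

1. **Consensus scene segmentation.** Several independent annotators propose
   scene windows (onset/offset in narrative seconds), each anchored to the
   recall questions that probe it. Proposals are validated against a 45–120 s
   duration rule, matched across annotators by shared recall questions
   (connected components of the question-sharing graph, keeping groups
   supported by at least two annotators), boundary-averaged, and repaired to
   an exact partition of the narrative.
2. **Scene-windowed connectivity and its decomposition.** Scene times are
   mapped to acquisition frames (TR = 1.5 s, 8 lead-in TRs, half-open
   0-based windows), per-scene/per-subject Pearson FC matrices are computed
   over ROI time series and vectorized (strictly lower triangle,
   r = (R² − R)/2 edges). Each scene's stacked subjects × edges matrix
   `Z_t` is split by robust PCA into

   `Z_t = L_t + S_t,  t = 1, …, T`

   where `L_t` is low-rank (shared, stimulus-driven connectivity) and `S_t`
   sparse (idiosyncratic, subject-specific), solved by inexact
   augmented-Lagrangian iteration with singular-value and soft
   thresholding (`min ‖L‖* + λ‖S‖₁ s.t. Z = L + S`, λ = 1/√max(M, r)).
3. **Recall classification.** Scene-level labels (mean recall score per
   scene and subject, binarized high/low) are classified from the raw FC,
   low-rank, and sparse feature variants with ridge logistic regression,
   random forest, and linear SVM under leave-one-out cross-validation
   (sample- or subject-grouped), with bootstrap CIs, within-story
   label-shuffling nulls, paired accuracy comparisons, and calibration
   curves.

A fully seeded synthetic-study generator (4 stories × 45 subjects,
{8, 10, 8, 6} scenes, 1440 scene-subject samples, planted low-rank +
sparse connectivity structure and recall coupling) makes every stage
testable without fMRI data. See the methods vignette
(`vignettes/recall-connectivity-methods.Rmd`) for the model, parameter
choices, and limitations.

## Worked example

```r
library(recallFC)

# simulate a small two-story study with a strong planted recall effect
cfg <- syntheticConfig(
  stories = data.frame(
    story = c("s1", "s2"), narrative_duration_s = c(312, 234),
    n_scenes = c(4L, 3L), n_questions = c(12L, 10L),
    clip_story_onset_s = c(9, 12)
  ),
  subjects_per_story = 8L, n_rois = 10L, n_dmn = 6L, effect_size = 5
)
study <- simulateStudy(cfg, seed = 3)

# consensus scenes for story s1
s1 <- study$stories$s1
consensusScenes(s1$annotations)[, 1:4]
#>   scene   onset_s  offset_s n_support
#> 1     1   0.00000  57.64425         5
#> 2     2  57.64425 164.91260         4
#> 3     3 164.91260 240.94079         4
#> 4     4 240.94079 312.00000         5

# DMN features, per-scene decomposition, and a cross-validated report
f <- studyFeatures(study, network = "DMN")
decomp <- decomposeAllScenes(f$tensors$s1)
decomp[[1]]
#> SceneDecomposition (scene 1): 8 x 15, rank(L) = 4, 72.5% of S nonzero,
#>   residual 4.65e-08 after 68 iterations (converged)

report <- runLOOCV(f$x, f$y, classifierSpec("logistic"), map = f$map)
report
#> ClassificationReport [fc | logistic | sample-level LOOCV]
#>   accuracy 0.786 (95% CI 0.679-0.893), balanced 0.621, AUC 0.816, 56 held-out samples
```

The consensus table shows the averaged, contiguity-repaired scene windows
with their annotator support. The decomposition report confirms the
`Z = L + S` contract (relative residual below the 1e-7 tolerance) and shows
the split: a rank-4 shared component plus an entrywise-sparse remainder.
The classification report pools the 56 held-out predictions: with the
strong planted effect the classifier beats the 75% majority baseline, with
an AUC of 0.82. At this toy scale the CI is wide; at the default
1440-sample scale the same pipeline reaches ~0.82 accuracy against a ~0.76
shuffle null (see below).

A file-based run of the complete pipeline:

```r
simulateStudy(cfg, seed = 3, dir = "study")
pc <- pipelineConfig("study", "out", n_shuffles = 100, seed = 7)
res <- runPipeline(pc)   # 2 networks x 3 variants x 3 classifiers = 18 reports
read.csv("out/reports.csv")
```

There is also a thin command-line front end:

```sh
Rscript inst/cli/recallseg.R simulate --out study --seed 7 --effect-size 5
Rscript inst/cli/recallseg.R run --study study --out results --shuffles 100
```

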