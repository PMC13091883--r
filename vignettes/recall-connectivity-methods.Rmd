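---
title: "Methods: from narrative scenes to recall classification"
author: "recallFC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from narrative scenes to recall classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallFC)
```

## The problem

Listeners who hear the same audio narrative segment it into the same coarse
units — scenes — and remember some scenes better than others. recallFC
implements a pipeline that connects three layers of such an experiment:

1. **Narrative structure.** Several independent annotators propose scene
   windows for a story, each window anchored to the recall questions that
   probe it. The package merges these proposals into consensus scenes.
2. **Brain dynamics.** For every scene and every listener, a functional
   connectivity (FC) matrix — pairwise Pearson correlations between ROI time
   series over the scene's acquisition frames — summarizes network state.
   Stacked across listeners, each scene's FC matrix is split into a shared
   low-rank component (stimulus-driven, common across listeners) and a
   sparse component (idiosyncratic, listener-specific) by robust PCA.
3. **Behaviour.** Per-question recall scores are averaged within each scene
   to produce a scene-level memory label (high/low), and classifiers are
   evaluated on how well each FC representation predicts that label, with a
   leakage-aware cross-validation and a label-shuffling null.

A seeded synthetic-study generator produces all three layers with planted
ground truth, so every stage is testable without access to fMRI data.

## Consensus scene segmentation

Each annotator supplies contiguous scene proposals with onset/offset in
narrative seconds and a non-empty set of recall-question IDs. Scene durations
are constrained to 45–120 s — long enough for a stable correlation estimate
(30–80 frames at TR = 1.5 s), short enough not to straddle distinct events.
Validation is hard: proposals with out-of-range durations or gaps/overlaps
beyond an `epsilon_s = 0.5` s tolerance are dropped (with a warning) before
matching, because they cannot anchor a reliable window.

Proposals from different annotators are matched when their question sets
intersect; groups are the **connected components** of that sharing graph.
Transitive closure was chosen over pairwise-only matching because it is
deterministic and invariant to annotator order; its price is that a proposal
spanning two events (an annotator who merged adjacent scenes) can bridge two
groups into one. In practice such merged proposals usually exceed the 120 s
duration bound and are dropped by validation first. A proposal can never
belong to two consensus scenes.

Each group supported by at least `min_support = 2` annotators becomes one
consensus scene: onset and offset are the arithmetic means over the matched
members (averaging over the matched members only — not all annotators — is
the package's reading of the "average over selected scenes" step, exposed
through the grouping itself). Averaging can leave small gaps or overlaps
between adjacent consensus scenes, and no published rule restores
contiguity, so the package replaces every internal boundary by the midpoint
of the neighbouring offset/onset pair and clamps the ends to `[0, D]`. The
output exactly partitions the narrative; scenes whose averaged duration
drifted outside the bounds are flagged rather than dropped (dropping would
re-open gaps). Ties in ordering are broken by (onset, offset, smallest
question ID).

## Timing: seconds to acquisition frames

Runs start with 8 lead-in TRs (12 s) before the audio clip, and the story
starts a few further seconds into the clip. Narrative-relative scene times
are therefore shifted by `lead_in_trs * tr_s + clip_story_onset_s` and
converted to 0-based, half-open TR windows with
`[floor(onset/tr), ceiling(offset/tr))`. Durations convert to frame counts
by the ceiling rule, which reproduces both printed anchor pairs
(400 s → 267 TRs, 536 s → 358 TRs at TR = 1.5 s); counts convert back by
exact multiplication (294 TRs → 441 s, 390 TRs → 585 s). When two adjacent
windows would share a boundary frame, the frame goes to the later scene. No
hemodynamic-delay shift is applied — none is specified for this design, and
a constant shift would cancel in within-window correlations anyway.

## Connectivity features

Within each scene window, FC is the Pearson correlation matrix of the ROI
time series (a constant series in a window is an error naming the ROI — it
indicates broken extraction, not data). The strictly lower triangle is
vectorized in row-major order, giving `r = (R^2 - R)/2` edge features;
networks (e.g. DMN, auditory) are analyzed separately via the ROI manifest.
No Fisher z-transform is applied by default (an option exists); no
within-window detrending is done beyond Pearson's implicit centering.
Features for one story form a `(W scenes, M subjects, r edges)` tensor.

## Low-rank plus sparse decomposition

For each scene `t`, the subjects-by-edges matrix `Z_t` is decomposed as
`Z_t = L_t + S_t`, with `L_t` low-rank (shared, stimulus-driven structure)
and `S_t` sparse (idiosyncratic deviations), by principal component pursuit:

`min ||L||_* + lambda ||S||_1  subject to  Z = L + S`

solved with inexact augmented-Lagrangian iteration alternating singular
value thresholding (for `L`) and elementwise soft thresholding (for `S`).
Choices that matter:

- `lambda = 1 / sqrt(max(M, r))`, the standard robust-PCA scaling; nothing
  in the study design suggests another weight.
- Convergence at relative residual `||Z - L - S||_F / max(||Z||_F, 1)
  <= 1e-7` (default), tight enough that the additivity contract is
  meaningful and cheap at these matrix sizes; `max_iter = 500` with a
  `converged` flag on the result.
- The dual variable starts at zero and the penalty at `1.25 / ||Z||_2`
  growing by 1.2 per iteration (gentle growth keeps the final L/S split accurate, not just the sum). With this schedule the iterate sequence is
  exactly scale-equivariant (`cZ` gives `cL, cS`), which is also how the
  solver is tested.
- SVD signs are fixed (largest-magnitude entry of each left singular vector
  made positive) so outputs are bit-stable.

The subjects-by-edges layout is the default because the low-rank component
should capture **across-subject** shared structure; a block layout that
stacks the square per-subject FC matrices vertically is available behind
`layout = "stacked_matrices"` for comparison, since the stacking convention
is a genuinely open choice.

## Labels and classification

Scene-level recall is the arithmetic mean of a subject's scores over the
scene's questions; a missing answer is an error by default (subjects without
recall data should be excluded upstream), with an opt-in mean-over-available
policy. Binarization offers two rules because published class balances are
reported without the cut point: a fixed threshold (`score >= 0.5` is high,
the default) and a quantile rule labelling the lowest 25% low, which
reproduces a roughly 1:3 low:high balance. Ties at the boundary go to high.

Classifiers are ridge (ell-2) logistic regression, a random forest, and a
linear SVM with ell-2 cost — deliberately simple models over all
`r` edges with no feature selection. Evaluation is leave-one-out
cross-validation. The default unit holds out one scene-subject sample
(matching the stacked-sample framing of the design); `unit = "subject"`
holds out all of a subject's samples together and is the recommended,
leakage-safe mode — with sample-level LOOCV, other scenes from the same
subject remain in training, so subject identity can leak into the estimate.
Pooled held-out predictions give accuracy, balanced accuracy and AUC; the
95% CI is a seeded percentile bootstrap (1000 resamples) over per-fold
outcomes. Folds whose training labels would leave a class with fewer than
two members are skipped and recorded.

The label-shuffling null permutes labels **within story**, preserving each
story's class balance, and reruns the full LOOCV per permutation. For
imbalanced labels this null centres near the majority-class proportion —
substantially above 50% — so observed accuracies should be read against the
null distribution, not against coin-flipping. The pipeline computes one null
per network and feature variant using the ridge-logistic classifier and
shares it across classifier reports: the null validates the label/scene
alignment of the data, which does not depend on the classifier family, and
this keeps a 100-shuffle full pipeline tractable on one CPU. Paired
comparisons between variants across repeated runs use a paired t test with
explicit zero-variance handling; calibration curves bin pooled held-out
probabilities into equal-width bins (imbalanced data typically shows poor
calibration — reported, not corrected).

## The synthetic-study generator

The generator emulates the scale of a four-story naturalistic listening
study: stories of 624, 780, 624 and 468 s with 8, 10, 8 and 6 scenes
(45–120 s each, mean 78 s), 30/30/25/25 recall questions, 45 listeners per
story — 1440 scene-subject samples — at TR = 1.5 s with 8 lead-in TRs and
in-clip story onsets of 9–15 s.

Per scene, `planted_rank = 3` latent stimulus time courses are **shared by
all subjects** (the stimulus drives the same temporal structure in
everyone); subject `m` expresses factor `j` in scene `t` with variance
`1 + w[t, m] * 0.5^(j - 1)`, where `w = coupling_strength * aptitude_m *
salience_t` with aptitude ~ U(0.3, 1.7) and salience ~ U(0.8, 1.2). The
variance-share construction matters: correlation matrices are scale-free, so
a pure amplitude modulation would vanish from FC; modulating the share of
one factor relative to the others changes the correlation pattern itself,
monotonically in `w`, even with zero observation noise. The default
`coupling_strength = 3` makes the stimulus-driven variance share range from
roughly 1.2x to 8x the intrinsic variance — a deliberately strong planted
signal, chosen once so that the generator's "large effect" condition is
genuinely detectable at study scale. Idiosyncratic structure adds private
couplings on a random 2% of ROI pairs per subject and scene; white noise
(`noise_sd = 1`) tops off the signal, and non-story frames contain
unit-variance scanner noise.

Recall behaviour couples to the same signal through a logistic link:
`P(correct) = plogis(alpha + effect_size * z[t, m])` with `z` the
standardized `w`, and `alpha` calibrated numerically so the expected
fraction of scene-subject samples with mean score below 0.5 matches the
25% low-class target. A scalar per-subject aptitude thus drives both the
expressed connectivity signal and recall, giving variance across subjects
and scenes with a single interpretable effect-size knob. Annotator
disagreement is emulated by clipped-Gaussian boundary jitter (sd 2 s,
clipped at 40% of the shorter neighbouring scene so ordering is preserved
by construction) and by merging adjacent scenes with probability 0.05.

What the generator does **not** emulate: hemodynamic convolution,
autocorrelated noise, motion artefacts, spatial structure within ROIs, or
annotators who split scenes. Passing tests therefore demonstrate the
pipeline's contracts and statistical behaviour under a known model — not
performance on real fMRI data.

Because the logistic link never saturates completely at finite effect size,
"perfect separability" is checked in the saturating limit
(`effect_size = 1000`, zero jitter, zero noise, no sparse couplings): there
the consensus recovers the true boundaries exactly, every scene contains a
single FC edge that threshold-separates low from high, and labels are an
exact threshold on the planted signal.

## Numerical choices and degenerate inputs

- Seconds-to-TR uses `ceiling(x - 1e-9)` (and floor with the mirrored
  guard) so exact TR multiples are not pushed over by floating-point error.
- Correlation matrices are symmetrized (`(C + t(C))/2`) before
  vectorization; asymmetry beyond 1e-9 is an error.
- `Z = 0` decomposes to `L = S = 0` without iteration; non-convergence
  returns the iterate with `converged = FALSE` and a warning rather than
  failing.
- Quantile binarization on an all-identical score vector is a degenerate
  distribution and errors; threshold binarization does not.
- All stochastic components (simulation, RF, bootstrap, shuffles,
  subsampling) take explicit seeds and restore the caller's RNG state.

## Problem sizes used in the shipped checks

The package's own test and acceptance runs use the default study scale
(1440 samples, 20 ROIs with a 12-ROI DMN and 8-ROI auditory split, giving
66 and 28 edges) for the headline end-to-end checks, 100-shuffle nulls on
story-stratified subsamples of 60 samples per story, a 45 x 496 planted
matrix (rank 3, 2% spikes) for decomposition recovery, and a two-story
miniature (8 subjects, 10 ROIs) for pipeline plumbing. These sizes were
chosen as the smallest that exercise each claim convincingly.

## Known limitations

- Consensus assumes annotators share the recall-question inventory;
  question-free proposals cannot be matched.
- The shuffle null and CIs quantify within-study uncertainty only; nothing
  here licenses generalization across stories or populations.
- Sample-level LOOCV (the default, mirroring the stacked-sample framing)
  is optimistic relative to subject-level grouping; both are provided.
- The RPCA model treats edges independently within `S`; spatially
  structured idiosyncrasy will partially load on `L`.
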