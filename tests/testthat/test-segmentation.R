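test_that("validation flags duration and continuity violations", {
  b <- durationBounds()

  short <- seg_of("a", 0, 30, list("q1"), 30)
  rep <- validateSegmentation(short, b)
  expect_false(rep$valid[1])
  expect_match(rep$reasons[1], "duration < 45")

  ok <- seg_of("a", c(0, 60), c(60, 150), list("q1", "q2"), 150)
  expect_true(all(validateSegmentation(ok, b)$valid))

  gap <- seg_of("a", c(0, 65), c(60, 120), list("q1", "q2"), 120)
  rep <- validateSegmentation(gap, b)
  expect_false(all(rep$continuity_ok))
  disc <- attr(rep, "discontinuities")
  expect_equal(disc$after_proposal, 1L)
  expect_equal(disc$gap_s, 5)
})

test_that("segmentation constructor sorts unsorted input with a warning", {
  expect_warning(
    seg <- seg_of("a", c(60, 0), c(120, 60), list("q2", "q1"), 120),
    "unsorted"
  )
  expect_equal(proposals(seg)$onset_s, c(0, 60))
})

test_that("empty proposal lists are rejected as structured errors", {
  seg <- seg_of("a", 0, 60, list("q1"), 60)
  seg@proposals <- seg@proposals[0, ]
  expect_error(validateSegmentation(seg), class = "recallFC_empty_segmentation")
})

test_that("proposals group by shared questions, transitively", {
  a <- seg_of("A", 0, 60, list(c("q1", "q2")), 60)
  b <- seg_of("B", 5, 58, list(c("q2", "q3")), 58)
  m <- matchProposals(list(a, b))
  expect_length(m$groups, 1L)
  expect_equal(nrow(m$groups[[1]]), 2L)

  # no shared questions: both unsupported
  a2 <- seg_of("A", 0, 60, list("q1"), 60)
  b2 <- seg_of("B", 0, 60, list("q7"), 60)
  m2 <- matchProposals(list(a2, b2))
  expect_length(m2$groups, 0L)
  expect_length(m2$unsupported, 2L)

  # transitive sharing links three annotators
  a3 <- seg_of("A", 0, 60, list("q1"), 60)
  b3 <- seg_of("B", 0, 60, list(c("q1", "q2")), 60)
  c3 <- seg_of("C", 0, 60, list("q2"), 60)
  m3 <- matchProposals(list(a3, b3, c3))
  expect_length(m3$groups, 1L)
  expect_equal(sort(unique(m3$groups[[1]]$annotator)), c("A", "B", "C"))
})

test_that("duplicate annotator ids are rejected", {
  a <- seg_of("A", 0, 60, list("q1"), 60)
  expect_error(matchProposals(list(a, a)), class = "recallFC_match_error")
})

test_that("grouping matches the brute-force enumeration oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n_ann <- sample(2:5, 1)
    n_sc <- sample(2:6, 1)
    dur <- n_sc * 60
    qpool <- paste0("q", 1:(2 * n_sc))
    segs <- lapply(seq_len(n_ann), function(a) {
      bnd <- seq(0, dur, length.out = n_sc + 1)
      qs <- lapply(seq_len(n_sc), function(i)
        sample(qpool, sample(1:3, 1)))
      seg_of(paste0("ann", a), bnd[-(n_sc + 1)], bnd[-1], qs, dur)
    })
    m <- matchProposals(segs, min_support = 1L)
    got <- match_groups_signature(m)
    want <- grouping_oracle(segs)
    expect_setequal(
      vapply(got, paste, character(1), collapse = " / "),
      vapply(want, paste, character(1), collapse = " / ")
    )
  }
})

test_that("consensus scenes average member boundaries and pool questions", {
  a <- seg_of("A", 100, 160, list(c("q1", "q2")), 624)
  b <- seg_of("B", 110, 170, list("q1"), 624)
  m <- matchProposals(list(a, b))
  sc <- buildConsensusScenes(m$groups, durationBounds(), 624)
  expect_equal(sc$onset_s, 105)
  expect_equal(sc$offset_s, 165)
  expect_equal(sc$questions[[1]], c("q1", "q2"))
  expect_equal(sc$n_support, 2L)

  # five identical proposals reproduce themselves
  segs <- lapply(paste0("ann", 1:5), seg_of,
                 onsets = 50, offsets = 120, questions = list("q1"),
                 duration = 170)
  m5 <- matchProposals(segs)
  sc5 <- buildConsensusScenes(m5$groups, durationBounds(), 170)
  expect_equal(sc5$onset_s, 50)
  expect_equal(sc5$offset_s, 120)

  # single-annotator groups are excluded upstream
  expect_length(m$unsupported, 0L)
  expect_error(buildConsensusScenes(list(), durationBounds(), 624),
               class = "recallFC_no_consensus")
})

test_that("continuity repair uses boundary midpoints and clamps the ends", {
  sc <- data.frame(scene = 1:2, onset_s = c(0, 62), offset_s = c(58, 120))
  out <- repairContinuity(sc, 120)
  expect_equal(out$offset_s[1], 60)
  expect_equal(out$onset_s[2], 60)

  ovl <- data.frame(scene = 1:2, onset_s = c(0, 55), offset_s = c(60, 120))
  out2 <- repairContinuity(ovl, 120)
  expect_equal(out2$offset_s[1], 57.5)
  expect_equal(out2$onset_s[2], 57.5)

  contig <- data.frame(scene = 1:2, onset_s = c(0, 60), offset_s = c(60, 120))
  expect_equal(repairContinuity(contig, 120)[, c("onset_s", "offset_s")],
               contig[, c("onset_s", "offset_s")])

  # inversion: second scene entirely before the end of the first
  inv <- data.frame(scene = 1:3, onset_s = c(0, 10, 11),
                    offset_s = c(100, 12, 120))
  expect_error(repairContinuity(inv, 120), class = "recallFC_repair_error")
})

test_that("consensus output exactly partitions the narrative", {
  set.seed(7)
  cfg <- one_story_cfg()
  for (rep in 1:5) {
    scenes <- generateTrueScenes(cfg, 1)
    segs <- generateAnnotatorProposals(scenes, cfg)
    sc <- suppressWarnings(consensusScenes(segs))
    D <- cfg$stories$narrative_duration_s[1]
    expect_equal(sum(sc$offset_s - sc$onset_s), D, tolerance = 1e-12)
    expect_equal(sc$onset_s[1], 0)
    expect_equal(sc$offset_s[nrow(sc)], D)
    expect_equal(sc$onset_s[-1], sc$offset_s[-nrow(sc)])
    expect_true(all(sc$n_support >= 2L))
  }
})

test_that("consensus is invariant to annotator order", {
  set.seed(11)
  cfg <- one_story_cfg()
  scenes <- generateTrueScenes(cfg, 1)
  segs <- generateAnnotatorProposals(scenes, cfg)
  ref <- suppressWarnings(consensusScenes(segs))
  for (rep in 1:3) {
    perm <- sample(length(segs))
    got <- suppressWarnings(consensusScenes(segs[perm]))
    expect_equal(got, ref)
  }
})
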