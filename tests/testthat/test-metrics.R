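test_that("confusion counts come from one-vs-rest pixel counting", {
  t <- matrix(0L, 20, 20); t[5:14, 5:14] <- 1L
  expect_equal(confusionCounts(t, t, 1L), list(TP = 100L, FP = 0L, FN = 0L))

  empty <- matrix(0L, 20, 20)
  t40 <- matrix(0L, 20, 20); t40[1:8, 1:5] <- 1L
  expect_equal(confusionCounts(empty, t40, 1L), list(TP = 0L, FP = 0L, FN = 40L))

  # 1-px shifted square vs brute-force overlap
  p <- matrix(0L, 20, 20); p[6:15, 5:14] <- 1L
  cc <- confusionCounts(p, t, 1L)
  expect_equal(cc$TP, 90L)   # 9 x 10 overlap
  expect_equal(cc$FP, 10L)
  expect_equal(cc$FN, 10L)
  # count identities
  expect_equal(cc$TP + cc$FN, sum(t == 1L))
  expect_equal(cc$TP + cc$FP, sum(p == 1L))

  expect_error(confusionCounts(matrix(0L, 3, 3), t, 1L), "mismatch")
})

test_that("precision, recall and F1 follow their definitions", {
  expect_equal(precisionScore(list(TP = 9, FP = 1)), 0.9)
  expect_equal(recallScore(list(TP = 9, FN = 1)), 0.9)
  expect_equal(precisionScore(list(TP = 0, FP = 0)), 0)
  expect_equal(recallScore(list(TP = 0, FN = 0)), 0)
  expect_equal(f1Score(1, 1), 1)
  expect_equal(f1Score(0.7, 0), 0)
  expect_equal(f1Score(0, 0), 0)
  # symmetry and betweenness
  set.seed(3)
  for (i in 1:10) {
    p <- runif(1, 0.05, 1); r <- runif(1, 0.05, 1)
    expect_equal(f1Score(p, r), f1Score(r, p))
    expect_gte(f1Score(p, r), min(p, r) - 1e-12)
    expect_lte(f1Score(p, r), max(p, r) + 1e-12)
  }
})

test_that("the published periderm benchmark rows are consistent with F1", {
  # printed (precision, recall, F1) triples, before and after postprocessing
  rows <- rbind(
    c(0.854, 0.869, 0.861), c(0.904, 0.865, 0.884),
    c(0.863, 0.861, 0.862), c(0.885, 0.820, 0.851),
    c(0.875, 0.861, 0.868), c(0.917, 0.823, 0.867))
  for (i in seq_len(nrow(rows))) {
    expect_lt(abs(f1Score(rows[i, 1], rows[i, 2]) - rows[i, 3]), 0.0005)
    expect_equal(round(f1Score(rows[i, 1], rows[i, 2]), 3), rows[i, 3])
  }
})

test_that("slide benchmarking equals a hand-computed table on planted confusions", {
  # three small slides with planted, hand-countable confusions
  t1 <- matrix(0L, 30, 30); t1[1:10, 1:10] <- 1L; t1[20:29, 1:10] <- 2L
  p1 <- t1
  p1[1:10, 9:10] <- 2L       # 20 periderm px -> endoderm (FN for periderm)
  p1[15, 1:10] <- 1L         # 10 background px -> periderm (FP)
  # periderm: TP 80, FP 10, FN 20 -> P = 80/90, R = 80/100

  t2 <- matrix(0L, 30, 30); t2[5:24, 5:8] <- 1L
  p2 <- t2                   # perfect slide

  t3 <- matrix(0L, 30, 30); t3[1:20, 1:5] <- 1L
  p3 <- matrix(0L, 30, 30)   # total miss: P = 0, R = 0

  rep <- benchmarkSlides(list(LabelMask(p1), LabelMask(p2), LabelMask(p3)),
                         list(LabelMask(t1), LabelMask(t2), LabelMask(t3)))
  peri <- rep[rep$class == "periderm" & rep$slide != "average", ]
  expect_equal(peri$precision, c(80 / 90, 1, 0))
  expect_equal(peri$recall, c(80 / 100, 1, 0))
  expect_equal(peri$f1, f1Score(peri$precision, peri$recall))
  avg <- rep[rep$class == "periderm" & rep$slide == "average", ]
  expect_equal(avg$precision, mean(c(80 / 90, 1, 0)))

  # identical masks everywhere -> all metrics 1
  repPerfect <- benchmarkSlides(list(LabelMask(t1)), list(LabelMask(t1)))
  peri1 <- repPerfect[repPerfect$class == "periderm", ]
  expect_true(all(peri1[, c("precision", "recall", "f1")] == 1))

  # unpaired slide lists are rejected
  expect_error(benchmarkSlides(list(LabelMask(t1)),
                               list(LabelMask(t1), LabelMask(t2))), "unpaired")

  # metrics invariant under identical class-code relabeling of pred & truth
  sw <- function(m) { x <- maskLabels(m); y <- x
    y[x == 1L] <- 2L; y[x == 2L] <- 1L; LabelMask(y) }
  repSw <- benchmarkSlides(list(sw(LabelMask(p1))), list(sw(LabelMask(t1))))
  b1 <- benchmarkSlides(list(LabelMask(p1)), list(LabelMask(t1)))
  expect_equal(repSw[repSw$class == "endoderm", c("precision", "recall", "f1")],
               b1[b1$class == "periderm", c("precision", "recall", "f1")],
               ignore_attr = TRUE)
})

test_that("before/after stages are reported side by side", {
  t1 <- matrix(0L, 20, 20); t1[1:10, 1:10] <- 1L
  before <- t1; before[1:10, 9:10] <- 2L
  after <- t1
  rep <- benchmarkSlides(list(LabelMask(before)), list(LabelMask(t1)),
                         predAfter = list(LabelMask(after)))
  peri <- rep[rep$class == "periderm" & rep$slide != "average", ]
  expect_equal(sort(unique(peri$stage)), c("after", "before"))
  expect_lt(peri$f1[peri$stage == "before"], peri$f1[peri$stage == "after"])
  lines <- renderMetricsTable(rep)
  expect_true(any(grepl("Before postprocessing", lines)))
  expect_true(any(grepl("After postprocessing", lines)))
})
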