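test_that("root instances are extracted, numbered left to right, and debris filtered", {
  specs <- lapply(c(0.4, 0.5, 0.45, 0.55, 0.5, 0.6), testRootSpec)
  sl <- generateSlide(6, specs, seed = 12, canvas = c(704, 512))
  roots <- extractRootInstances(sl$mask, minArea = 500, slideId = "s")
  expect_length(roots, 6)
  expect_equal(vapply(roots, function(r) r@rootId, integer(1)), 1:6)
  # left-to-right ordering of hypocotyl ends
  hx <- vapply(roots, function(r) r@centerline[1, 2], numeric(1))
  expect_true(all(diff(hx) > 0))
  # hypocotyl (top) end first on every centerline
  for (r in roots)
    expect_lt(r@centerline[1, 1], r@centerline[nrow(r@centerline), 1])

  # empty mask -> empty list
  expect_length(extractRootInstances(LabelMask(matrix(0L, 50, 50))), 0)

  # two roots plus a small speck: the speck falls below the area floor
  lab <- matrix(0L, 120, 80)
  lab[10:110, 10:20] <- 1L
  lab[10:110, 50:60] <- 2L
  lab[60:62, 35:36] <- 1L   # 6-px debris
  roots2 <- extractRootInstances(LabelMask(lab), minArea = 100)
  expect_length(roots2, 2)
})

test_that("periderm runs project onto the centerline as maximal segments", {
  fix <- longRootFixture(frac = 1, seed = 5)
  segs <- projectSegments(fix$root, fix$mask)
  m <- nrow(fix$root@centerline)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 1)
  expect_equal(segs$end, m)

  # no periderm at all -> zero segments
  lab <- maskLabels(fix$mask)
  lab[lab == 1L] <- 2L
  segs0 <- projectSegments(fix$root, LabelMask(lab))
  expect_equal(nrow(segs0), 0)

  # planted gap splits the run in two with the planted spacing
  cor <- corruptMask(fix$mask, fix$root, gaps = list(c(500, 100)))
  segs2 <- projectSegments(fix$root, cor)
  expect_equal(nrow(segs2), 2)
  expect_equal(segs2$start[2] - segs2$end[1] - 1, 100)
})

test_that("gaps bridge at or below 150 px and larger gaps relabel distal periderm", {
  fix <- longRootFixture(frac = 0.9, seed = 6)
  root <- fix$root

  # 100-px gap (< 150): bridged back into one run covering the gap
  cor <- corruptMask(fix$mask, root, gaps = list(c(500, 100)))
  segs <- projectSegments(root, cor)
  res <- bridgeAndRelabel(root, segs, cor, postprocessConfig())
  expect_equal(res$bridged, 1L)
  expect_equal(res$relabeled, 0L)
  after <- projectSegments(root, res$mask)
  expect_equal(nrow(after), 1)
  expect_equal(after$start, segs$start[1])
  expect_equal(after$end, segs$end[nrow(segs)])

  # 300-px gap (> 150): distal segment relabeled endodermis
  cor2 <- corruptMask(fix$mask, root, gaps = list(c(500, 300)))
  segs2 <- projectSegments(root, cor2)
  res2 <- bridgeAndRelabel(root, segs2, cor2, postprocessConfig())
  expect_equal(res2$relabeled, 1L)
  after2 <- projectSegments(root, res2$mask)
  expect_equal(nrow(after2), 1)
  expect_equal(after2$end, segs2$end[1])
  # the relabeled pixels became endodermis, not background
  expect_equal(sum(maskLabels(res2$mask) != 0), sum(maskLabels(cor2) != 0))

  # gap of exactly 150 px is bridged (boundary convention)
  cor3 <- corruptMask(fix$mask, root, gaps = list(c(500, 150)))
  res3 <- bridgeAndRelabel(root, projectSegments(root, cor3), cor3,
                           postprocessConfig())
  expect_equal(res3$bridged, 1L)
  expect_equal(nrow(projectSegments(root, res3$mask)), 1)

  # single segment passes through unchanged
  segs1 <- projectSegments(root, fix$mask)
  res4 <- bridgeAndRelabel(root, segs1, fix$mask, postprocessConfig())
  expect_identical(maskLabels(res4$mask), maskLabels(fix$mask))
})

test_that("bridge_and_relabel is idempotent and matches an interval-merging oracle", {
  fix <- longRootFixture(frac = 0.95, seed = 7)
  root <- fix$root
  m <- nrow(root@centerline)

  # brute-force oracle on the segment table
  oracle <- function(segs, thr) {
    if (nrow(segs) == 0) return(segs)
    start <- segs$start[1]; end <- segs$end[1]
    for (i in seq_len(nrow(segs))[-1]) {
      if (segs$start[i] - end - 1 <= thr) end <- segs$end[i] else break
    }
    data.frame(start = start, end = end)
  }

  set.seed(17)
  for (rep in 1:8) {
    # random gap pattern planted into the truth mask
    pos <- 60
    gaps <- list()
    while (length(gaps) < 6 && pos < m * 0.8) {
      gl <- sample(c(5, 40, 100, 160, 200, 300), 1)
      gaps[[length(gaps) + 1]] <- c(pos, gl)
      pos <- pos + gl + sample(60:200, 1)
    }
    ok <- vapply(gaps, function(g) g[1] + g[2] <= m * 0.9, logical(1))
    cor <- corruptMask(fix$mask, root, gaps = gaps[ok])
    segs <- projectSegments(root, cor)
    res <- bridgeAndRelabel(root, segs, cor, postprocessConfig())
    after <- projectSegments(root, res$mask)
    exp <- oracle(segs, 150)
    expect_equal(after$start, exp$start)
    expect_equal(after$end, exp$end)
    # idempotence: a second application changes nothing
    res2 <- bridgeAndRelabel(root, after, res$mask, postprocessConfig())
    expect_identical(maskLabels(res2$mask), maskLabels(res$mask))
    # non-background pixel count conserved by relabeling
    expect_equal(sum(maskLabels(res$mask) != 0), sum(maskLabels(cor) != 0))
  }
})

test_that("holes below 20 px close and larger holes survive", {
  fix <- longRootFixture(frac = 0.9, seed = 8)
  root <- fix$root

  cor <- corruptMask(fix$mask, root, holes = list(c(400, 10), c(800, 50)))
  expect_equal(sum(maskLabels(cor) == 0L) - sum(maskLabels(fix$mask) == 0L), 60)
  res <- closeSmallHoles(cor, root, holeMax = 20)
  expect_equal(res$filled, 1L)
  # the 10-px hole is gone, the 50-px hole remains
  expect_equal(sum(maskLabels(res$mask) == 0L) -
               sum(maskLabels(fix$mask) == 0L), 50)
  # periderm count never decreases
  expect_gte(sum(maskLabels(res$mask) == 1L), sum(maskLabels(cor) == 1L))

  # a hole of exactly 20 px is kept
  cor20 <- corruptMask(fix$mask, root, holes = list(c(400, 20)))
  res20 <- closeSmallHoles(cor20, root, holeMax = 20)
  expect_equal(res20$filled, 0L)

  # hole-free mask: idempotence
  res0 <- closeSmallHoles(fix$mask, root, holeMax = 20)
  expect_identical(maskLabels(res0$mask), maskLabels(fix$mask))
})

test_that("full postprocessing yields one hypocotyl-anchored run per root", {
  fix <- longRootFixture(frac = 0.9, seed = 9)
  cor <- corruptMask(fix$mask, fix$root,
                     gaps = list(c(300, 80), c(700, 250)),
                     holes = list(c(150, 12)))
  res <- postprocessMask(cor, postprocessConfig(150, 20, 500), "top", "fix")
  expect_equal(unname(res$stats["roots"]), 1L)
  root <- res$roots[[1]]
  segs <- projectSegments(root, res$mask)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 1)
})
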