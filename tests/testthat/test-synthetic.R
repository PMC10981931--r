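test_that("generated roots honor the periderm fraction by construction", {
  # fraction 0: no periderm pixels at all
  g0 <- generateRoot(testRootSpec(frac = 0, lateral = 0L), seed = 3)
  expect_equal(sum(maskLabels(g0$mask) == 1L), 0)
  expect_equal(g0$truth$periderm_px, 0)

  # fraction 1: truth periderm length equals truth whole length
  g1 <- generateRoot(testRootSpec(frac = 1, lateral = 0L), seed = 3)
  expect_equal(g1$truth$periderm_px, g1$truth$whole_px)
  expect_equal(sum(maskLabels(g1$mask) == 2L), 0)

  # arbitrary fraction: periderm truth = fraction x analytic arc length,
  # and the arc length matches an independent numeric integration of the
  # generating curve
  spec <- testRootSpec(frac = 0.4)
  g <- generateRoot(spec, seed = 9)
  expect_equal(g$truth$periderm_px, 0.4 * g$truth$whole_px)
  cl <- g$truth$centerline
  expect_equal(g$truth$whole_px,
               sum(sqrt(rowSums(diff(cl)^2))), tolerance = 1e-9)
  # arc length >= straight length, and close to it for gentle curvature
  expect_gte(g$truth$whole_px, spec@totalLength)
  expect_lt(g$truth$whole_px, spec@totalLength * 1.05)
})

test_that("the image side carries texture while the mask stays exact", {
  g <- generateRoot(testRootSpec(frac = 0.5), seed = 4)
  expect_equal(sort(unique(as.vector(maskLabels(g$mask)))),
               c(0L, 1L, 2L, 3L))
  img <- g$image
  expect_true(all(img >= 0 & img <= 1))
  # green-dominant fluorescence palette inside the root
  on <- maskLabels(g$mask) != 0L
  expect_gt(mean(img[, , 2][on]), mean(img[, , 1][on]))
  expect_gt(mean(img[, , 1][on]), mean(img[, , 3][on]))
  # root clearly brighter than background
  expect_gt(mean(img[, , 2][on]), 4 * mean(img[, , 2][!on]))
})

test_that("slides pack up to six reproducible, ordered roots", {
  specs <- lapply(c(0.35, 0.5, 0.6, 0.45, 0.55, 0.4), testRootSpec)
  sl <- generateSlide(6, specs, seed = 5, canvas = c(704, 512))
  expect_equal(nrow(sl$truth), 6)
  expect_equal(sl$truth$root_index, 1:6)
  # left-to-right layout matches the centerline columns
  firstCols <- vapply(sl$centerlines, function(cl) cl[1, 2], numeric(1))
  expect_true(all(diff(firstCols) > 0))

  # single-root slide
  sl1 <- generateSlide(1, testRootSpec(), seed = 5, canvas = c(704, 256))
  expect_equal(nrow(sl1$truth), 1)

  # determinism: same seed gives bit-identical image and mask
  sl2 <- generateSlide(6, specs, seed = 5, canvas = c(704, 512))
  expect_identical(sl2$image, sl$image)
  expect_identical(maskLabels(sl2$mask), maskLabels(sl$mask))

  # infeasible packing is rejected
  expect_error(generateSlide(6, testRootSpec(), seed = 1, canvas = c(704, 120)),
               "packing")
  wide <- syntheticRootSpec(totalLength = 900, width = 14,
                            curvatureAmplitude = 18, curvaturePeriod = 400)
  expect_error(generateSlide(1, wide, seed = 1, canvas = c(500, 256)),
               "length exceeds")
})

test_that("planted defects respect their preconditions", {
  fix <- longRootFixture(frac = 0.5, seed = 13)
  m <- nrow(fix$root@centerline)
  # span outside the periderm region errors
  expect_error(corruptMask(fix$mask, fix$root,
                           gaps = list(c(round(m * 0.9), 50))),
               "periderm")
  expect_error(corruptMask(fix$mask, fix$root, gaps = list(c(m, 50))),
               "centerline")
  # a planted gap removes exactly its cross-section from the periderm
  cor <- corruptMask(fix$mask, fix$root, gaps = list(c(200, 60)))
  expect_gt(sum(maskLabels(fix$mask) == 1L), sum(maskLabels(cor) == 1L))
  expect_equal(sum(maskLabels(cor) != 0L), sum(maskLabels(fix$mask) != 0L))
})

test_that("labelme-style annotations derived from a mask rasterize back", {
  # generator masks can be exported as polygon annotations for the
  # annotation-I/O path (downsampled root keeps the test fast)
  lab <- matrix(0L, 60, 40)
  lab[5:50, 10:20] <- 1L
  lab[51:58, 10:20] <- 2L
  doc <- boundaryPolygons(LabelMask(lab))
  expect_equal(vapply(doc@polygons, function(p) p$label, ""),
               c("periderm", "endoderm"))
  back <- rasterizeAnnotations(doc)
  expect_identical(maskLabels(back), lab)
})
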