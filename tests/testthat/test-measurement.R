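test_that("polyline length sums unit and diagonal steps", {
  expect_equal(polylineLength(cbind(1:101, 1)), 100)
  expect_equal(polylineLength(cbind(1:11, 1:11)), 10 * sqrt(2))
  # L-shaped path: 10 axial + 10 diagonal steps
  path <- rbind(cbind(1:11, 1), cbind(11 + 1:10, 1 + 1:10))
  expect_equal(polylineLength(path), 10 + 10 * sqrt(2))
  expect_equal(polylineLength(cbind(1, 1)), 0)
  expect_equal(polylineLength(matrix(numeric(0), 0, 2)), 0)
  # chord resampling keeps endpoints: straight lines are measured exactly
  expect_equal(polylineLength(cbind(1:101, 1), step = 9), 100)
})

test_that("micrometer conversion uses the slide calibration", {
  expect_equal(toMicrometers(5299, scaleConfig()), 10000)
  expect_equal(toMicrometers(0, scaleConfig()), 0)
  expect_equal(toMicrometers(123.4, scaleConfig(1, 1)), 123.4)
  # additivity
  expect_equal(toMicrometers(100, scaleConfig()) + toMicrometers(23, scaleConfig()),
               toMicrometers(123, scaleConfig()))
  expect_error(scaleConfig(-1, 1))
  expect_error(scaleConfig(1, 1, pixelAspectRatio = 2), "not supported")
})

test_that("centerlines follow ribbons and prune side branches", {
  # axis-aligned ribbon: path runs along the middle
  bin <- matrix(FALSE, 120, 30)
  bin[10:110, 11:19] <- TRUE
  cl <- computeCenterline(bin)
  expect_gt(nrow(cl), 85)
  expect_true(all(abs(cl[, 2] - 15) <= 2))
  expect_lt(cl[1, 1], cl[nrow(cl), 1])  # hypocotyl (top) end first
  len <- polylineLength(cl)
  expect_gt(len, 90); expect_lt(len, 105)

  # plus-shaped region: the short arm is pruned
  plus <- matrix(FALSE, 60, 60)
  plus[5:55, 28:32] <- TRUE     # long vertical arm
  plus[28:32, 20:40] <- TRUE    # short horizontal arm
  clp <- computeCenterline(plus)
  expect_gt(polylineLength(clp), 40)
  expect_true(all(abs(clp[, 2] - 30) <= 3))  # stays on the vertical arm

  # 2x2 block: degenerate single-point centerline
  blk <- matrix(FALSE, 6, 6); blk[3:4, 3:4] <- TRUE
  expect_equal(nrow(computeCenterline(blk)), 1)
})

test_that("measured lengths recover the generator's analytic truth within 2%", {
  for (s in 1:4) {
    spec <- testRootSpec(frac = c(0.3, 0.45, 0.6, 0.5)[s])
    gen <- generateRoot(spec, seed = s)
    roots <- extractRootInstances(gen$mask, minArea = 500)
    expect_length(roots, 1)
    m <- measureRoot(roots[[1]], gen$mask, scaleConfig(1, 1))
    expect_lt(abs(m$whole_root_length_px - gen$truth$whole_px) /
              gen$truth$whole_px, 0.02)
    expect_lt(abs(m$periderm_length_px - gen$truth$periderm_px) /
              gen$truth$periderm_px, 0.02)
    # unit consistency
    expect_equal(m$periderm_length_um,
                 toMicrometers(m$periderm_length_px, scaleConfig(1, 1)))
  }
})

test_that("degenerate periderm coverage gives the boundary cases", {
  # fully periderm root: periderm length = whole-root length
  fix1 <- longRootFixture(frac = 1, seed = 11)
  m1 <- measureRoot(fix1$root, fix1$mask, scaleConfig(1, 1))
  expect_equal(m1$periderm_length_px, m1$whole_root_length_px)

  # zero periderm: lengths 0 but whole root > 0
  lab <- maskLabels(fix1$mask)
  lab[lab == 1L] <- 2L
  m0 <- measureRoot(fix1$root, LabelMask(lab), scaleConfig(1, 1))
  expect_equal(m0$periderm_length_px, 0)
  expect_equal(m0$periderm_length_um, 0)
  expect_gt(m0$whole_root_length_px, 0)
})

test_that("measurement is rotation-robust and monotone in the run", {
  spec <- testRootSpec(frac = 0.5, lateral = 0L)
  gen <- generateRoot(spec, seed = 21)
  roots <- extractRootInstances(gen$mask, minArea = 500)
  m <- measureRoot(roots[[1]], gen$mask, scaleConfig(1, 1))

  # 90-degree rotated copy agrees within 1%
  H <- nrow(maskLabels(gen$mask)); W <- ncol(maskLabels(gen$mask))
  side <- max(H, W)
  pad <- matrix(0L, side, side)
  pad[seq_len(H), seq_len(W)] <- maskLabels(gen$mask)
  rot <- augmentPatch(LabelMask(pad), "rot90")
  rroots <- extractRootInstances(rot, minArea = 500, hypocotylEdge = "right")
  mr <- measureRoot(rroots[[1]], rot, scaleConfig(1, 1))
  expect_lt(abs(mr$whole_root_length_px - m$whole_root_length_px) /
            m$whole_root_length_px, 0.01)
  expect_lt(abs(mr$periderm_length_px - m$periderm_length_px) /
            m$periderm_length_px, 0.01)

  # extending the periderm run never decreases periderm length, and a
  # bridged gap counts toward the length
  fix <- longRootFixture(frac = 0.9, seed = 6)
  base <- measureRoot(fix$root, fix$mask, scaleConfig(1, 1))
  cor <- corruptMask(fix$mask, fix$root, gaps = list(c(500, 100)))
  res <- bridgeAndRelabel(fix$root, projectSegments(fix$root, cor), cor,
                          postprocessConfig())
  bridged <- measureRoot(fix$root, res$mask, scaleConfig(1, 1))
  expect_equal(bridged$periderm_length_px, base$periderm_length_px,
               tolerance = 0.02)
  gapped <- measureRoot(fix$root, cor, scaleConfig(1, 1))
  expect_lt(gapped$periderm_length_px, bridged$periderm_length_px)
})
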