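test_that("tiling covers the slide with ceiling arithmetic and padding", {
  # 14000 x 10800 @ 1024 -> 14 x 11 = 154 patches (offsets only, no pixels)
  cfg <- tilingConfig(1024)
  stride <- cfg@patchSize - cfg@overlap
  expect_equal(ceiling(14000 / stride) * ceiling(10800 / stride), 154)

  # exact-fit image -> one identical patch
  m <- matrix(sample(0:3, 64 * 64, replace = TRUE), 64, 64)
  tl <- tileImage(m, tilingConfig(64))
  expect_equal(tl$grid@nRows * tl$grid@nCols, 1)
  expect_identical(tl$patches[[1]], m)

  # one extra row -> 2 patches, second has 63 padded rows
  m2 <- matrix(7, 65, 64)
  tl2 <- tileImage(m2, tilingConfig(64, padValue = 0))
  expect_equal(length(tl2$patches), 2)
  expect_true(all(tl2$patches[[2]][2:64, ] == 0))
  expect_true(all(tl2$patches[[2]][1, ] == 7))

  # patch larger than the image -> single padded patch, not an error
  tl3 <- tileImage(matrix(1, 10, 10), tilingConfig(32))
  expect_equal(length(tl3$patches), 1)
  expect_equal(dim(tl3$patches[[1]]), c(32, 32))
})

test_that("stitch(tile(mask)) is the identity and conserves class counts", {
  set.seed(31)
  for (dims in list(c(100, 80), c(64, 64), c(130, 257))) {
    lab <- matrix(sample(0:3, prod(dims), replace = TRUE,
                         prob = c(0.7, 0.1, 0.15, 0.05)), dims[1], dims[2])
    mask <- LabelMask(lab)
    tl <- tileImage(mask, tilingConfig(64))
    # coverage: patch pixel counts (minus padding) equal the slide area
    expect_equal(tl$grid@nRows, ceiling(dims[1] / 64))
    expect_equal(tl$grid@nCols, ceiling(dims[2] / 64))
    back <- stitchMasks(tl$grid, tl$patches)
    expect_identical(maskLabels(back), lab)
    expect_identical(classCounts(back), classCounts(mask))
  }
})

test_that("stitching rejects mismatched patch counts and rebuilds mosaics", {
  tl <- tileImage(matrix(0L, 128, 128), tilingConfig(64))
  expect_error(stitchMasks(tl$grid, tl$patches[1:3]), "expected 4, received 3")

  # 2x2 grid of distinct constant patches -> block-constant mosaic
  patches <- lapply(0:3, function(k) matrix(k, 64, 64))
  mos <- stitchMasks(tl$grid, patches)
  expect_true(all(mos[1:64, 1:64] == 0))
  expect_true(all(mos[1:64, 65:128] == 1))
  expect_true(all(mos[65:128, 1:64] == 2))
  expect_true(all(mos[65:128, 65:128] == 3))
})

test_that("dihedral augmentation behaves as the symmetry group of the square", {
  set.seed(41)
  p <- matrix(runif(32 * 32), 32, 32)
  # rot90 applied 4x and hflip twice are the identity
  r <- p
  for (i in 1:4) r <- augmentPatch(r, "rot90")
  expect_identical(r, p)
  expect_identical(augmentPatch(augmentPatch(p, "hflip"), "hflip"), p)

  # index mapping oracle: (0,0) -> (0, N-1) under rot90 (clockwise)
  N <- 8
  m <- matrix(0, N, N); m[1, 1] <- 1
  expect_equal(which(augmentPatch(m, "rot90") == 1, arr.ind = TRUE),
               cbind(row = 1L, col = N), ignore_attr = TRUE)

  # every mode preserves per-class pixel counts exactly, and image+mask
  # stay aligned when transformed identically
  lab <- matrix(sample(0:3, 32 * 32, replace = TRUE), 32, 32)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  img[, , 1] <- lab  # encode the mask into a channel to check alignment
  for (mode in c("identity", "rot90", "rot180", "rot270", "hflip", "vflip",
                 "transpose", "antitranspose")) {
    tl <- augmentPatch(lab, mode)
    ti <- augmentPatch(img, mode)
    expect_identical(classCounts(LabelMask(tl)), classCounts(LabelMask(lab)))
    expect_identical(matrix(ti[, , 1], 32, 32), matrix(as.numeric(tl), 32, 32))
  }

  expect_error(augmentPatch(matrix(0, 4, 6), "rot90"), "square")
})
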