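test_that("patch splitting reproduces the 60/20/20 arithmetic", {
  s <- splitPatches(1471, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(s), c(train = 883L, val = 294L, test = 294L))
  expect_equal(lengths(splitPatches(10, c(0.6, 0.2, 0.2), seed = 2)),
               c(train = 6L, val = 2L, test = 2L))

  # disjoint, union = input, determinism in the seed
  s2 <- splitPatches(1471, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(s, s2)
  expect_equal(sort(c(s$train, s$val, s$test)), 1:1471)
  expect_equal(length(intersect(s$train, s$val)), 0)
  s3 <- splitPatches(1471, c(0.6, 0.2, 0.2), seed = 99)
  expect_false(identical(s, s3))
  expect_equal(lengths(s3), lengths(s))

  expect_error(splitPatches(2, c(0.6, 0.2, 0.2)), "at least 3")
  expect_error(splitPatches(10, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("composite loss matches closed forms", {
  # uniform logits over 4 classes: cross-entropy = ln 4 per pixel
  H <- 6; W <- 5
  logits <- array(0, dim = c(H, W, 4))
  target <- matrix(sample(0:3, H * W, replace = TRUE), H, W)
  l <- compositeLoss(logits, target)
  expect_equal(l$ce, log(4), tolerance = 1e-12)

  # probability ~1 on the true class everywhere: loss -> 0
  big <- array(0, dim = c(H, W, 4))
  for (k in 0:3) big[, , k + 1] <- 50 * (target == k)
  l2 <- compositeLoss(big, target)
  expect_lt(l2$loss, 1e-6)

  # swapped classes on a 2-class toy: Dice term = 1 for the affected
  # classes (soft Dice ~0 when prediction mass sits on the wrong class)
  tswap <- matrix(rep(c(1L, 2L), each = 10), 4, 5)
  pswap <- matrix(rep(c(2L, 1L), each = 10), 4, 5)
  lsw <- array(0, dim = c(4, 5, 4))
  for (k in 0:3) lsw[, , k + 1] <- 50 * (pswap == k)
  l3 <- compositeLoss(lsw, tswap)
  expect_equal(l3$dice, 1, tolerance = 1e-6)

  expect_gte(compositeLoss(array(rnorm(120), c(6, 5, 4)), target)$loss, 0)
  expect_error(compositeLoss(logits, matrix(7L, H, W)), "class codes")
})

test_that("IoU follows the empty-class conventions", {
  a <- matrix(0L, 10, 10); a[3:6, 3:6] <- 1L
  expect_equal(iouScore(a, a), 1)

  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  a2 <- matrix(0L, 10, 10); a2[1:3, 1:3] <- 1L
  expect_equal(iouScore(a2, b), 0)

  # half coverage, no false positives: 50/100
  t <- matrix(0L, 20, 20); t[1:10, 1:10] <- 1L
  p <- matrix(0L, 20, 20); p[1:5, 1:10] <- 1L
  expect_equal(iouScore(p, t), 0.5)

  # symmetric whenever both masks carry the same class sets
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    y <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    expect_equal(iouScore(x, y), iouScore(y, x))
  }
  expect_true(is.na(iouScore(matrix(0L, 4, 4), matrix(0L, 4, 4))))
})

test_that("a tiny network overfits 8 synthetic patches", {
  # 8 single-tissue patches from one synthetic root, ordered so the
  # validation split samples both tissue zones
  spec <- testRootSpec(lateral = 0L)
  g <- generateRoot(spec, seed = 2)
  tl <- tileImage(g$image, tilingConfig(64))
  lab <- lapply(tileImage(g$mask, tilingConfig(64))$patches, maskLabels)
  peri <- which(vapply(lab, function(p) mean(p == 1) > 0.15 && !any(p == 2),
                       logical(1)))
  endo <- which(vapply(lab, function(p) mean(p == 2) > 0.15 && !any(p == 1),
                       logical(1)))
  ord <- c(peri[1], endo[1], endo[2], peri[2], peri[3], endo[3], peri[4],
           endo[4])
  imgs <- tl$patches[ord]
  msks <- lab[ord]
  model <- trainSegmenter(imgs, msks, modelConfig(8, 4, 64),
                          trainConfig(1e-3, 120, c(0.6, 0.2, 0.2), 4,
                                      seed = 3, augment = FALSE),
                          logEvery = 0, restoreBest = FALSE)
  split <- splitPatches(8, c(0.6, 0.2, 0.2), 3)
  ious <- vapply(split$train, function(i)
    iouScore(maskLabels(predictPatch(model, imgs[[i]])), msks[[i]]),
    numeric(1))
  expect_gte(mean(ious), 0.90)

  # training loss decreases over the run
  h <- trainHistory(model)
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
})

test_that("single-epoch histories and seed determinism behave", {
  spec <- testRootSpec(lateral = 0L)
  g <- generateRoot(spec, seed = 2)
  # the root tile is two patch-columns wide; odd patch indices hold the root
  idx <- seq(1, 11, by = 2)
  imgs <- tileImage(g$image, tilingConfig(64))$patches[idx]
  msks <- lapply(tileImage(g$mask, tilingConfig(64))$patches[idx], maskLabels)

  m1 <- trainSegmenter(imgs, msks, modelConfig(4, 4, 64),
                       trainConfig(1e-3, 1, c(0.6, 0.2, 0.2), 2, seed = 5),
                       logEvery = 0)
  expect_equal(nrow(trainHistory(m1)), 1)
  expect_equal(bestEpoch(m1), 1)

  m2 <- trainSegmenter(imgs, msks, modelConfig(4, 4, 64),
                       trainConfig(1e-3, 3, c(0.6, 0.2, 0.2), 2, seed = 5),
                       logEvery = 0)
  m3 <- trainSegmenter(imgs, msks, modelConfig(4, 4, 64),
                       trainConfig(1e-3, 3, c(0.6, 0.2, 0.2), 2, seed = 5),
                       logEvery = 0)
  expect_identical(trainHistory(m2), trainHistory(m3))
  expect_identical(peridermR:::.net_get_params(m2@ptr),
                   peridermR:::.net_get_params(m3@ptr))
})

test_that("composite loss strictly decreases on a one-patch overfit run", {
  spec <- testRootSpec(lateral = 0L)
  g <- generateRoot(spec, seed = 2)
  img <- tileImage(g$image, tilingConfig(64))$patches[[1]]
  msk <- maskLabels(tileImage(g$mask, tilingConfig(64))$patches[[1]])
  model <- newSegModel(modelConfig(8, 4, 64), seed = 5)
  losses <- vapply(1:12, function(k)
    peridermR:::.net_train_batch(model@ptr, list(img), list(msk), 1e-3)$loss,
    numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("checkpoints round-trip through save and load", {
  dir <- withr::local_tempdir()
  model <- newSegModel(modelConfig(4, 4, 64), seed = 8)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  before <- maskLabels(predictPatch(model, img))
  path <- file.path(dir, "ckpt.rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(maskLabels(predictPatch(back, img)), before)
  expect_equal(back@config@baseChannels, 4L)
})
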