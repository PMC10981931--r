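# Shared fixtures. Synthetic geometry is deliberately small (desk-scale):
# roots ~650 px long, 14 px wide, 64-px patches, so the whole suite runs on
# one CPU in minutes. The generator parameters mirror the tissue-geometry
# contrast of FY-stained roots: small irregular periderm cells vs long
# rectangular endodermis cells.

testRootSpec <- function(frac = 0.45, len = 620, lateral = 1L) {
  syntheticRootSpec(totalLength = len, width = 14, peridermFraction = frac,
                    curvatureAmplitude = 18, curvaturePeriod = 400,
                    peridermCellSize = 8, endodermCellLength = 40,
                    endodermCellWidth = 9, lateralRootCount = lateral,
                    blurSigma = 1, noiseSd = 0.02)
}

# A long straight-ish root mask for the postprocess rule tests: centerline
# ~1400 px so that 300-px gaps fit well inside the periderm run.
longRootFixture <- function(frac = 0.8, seed = 5) {
  spec <- syntheticRootSpec(totalLength = 1400, width = 14,
                            peridermFraction = frac, curvatureAmplitude = 10,
                            curvaturePeriod = 900, peridermCellSize = 8,
                            endodermCellLength = 40, endodermCellWidth = 9,
                            lateralRootCount = 0L, blurSigma = 0, noiseSd = 0)
  gen <- generateRoot(spec, seed = seed)
  roots <- extractRootInstances(gen$mask, minArea = 500, slideId = "fix")
  list(gen = gen, root = roots[[1]], mask = gen$mask)
}

# Training patches from synthetic slides, cached per session.
.fixtureEnv <- new.env(parent = emptyenv())

fixturePatches <- function() {
  if (!is.null(.fixtureEnv$patches)) return(.fixtureEnv$patches)
  imgs <- list(); msks <- list()
  for (s in 1:4) {
    specs <- lapply(c(0.35, 0.5, 0.6, 0.45, 0.55, 0.4), testRootSpec)
    sl <- generateSlide(6, specs, seed = 100 + s, canvas = c(704, 512))
    imgs <- c(imgs, tileImage(sl$image, tilingConfig(64))$patches)
    msks <- c(msks, lapply(tileImage(sl$mask, tilingConfig(64))$patches,
                           maskLabels))
  }
  .fixtureEnv$patches <- list(images = imgs, masks = msks)
  .fixtureEnv$patches
}

# One model trained on the fixture patches, shared by the model-level and
# end-to-end tests (training it once keeps the suite fast).
fixtureModel <- function() {
  if (!is.null(.fixtureEnv$model)) return(.fixtureEnv$model)
  px <- fixturePatches()
  .fixtureEnv$model <- trainSegmenter(
    px$images, px$masks, modelConfig(baseChannels = 8, patchSize = 64),
    trainConfig(learningRate = 1e-3, epochs = 16, batchSize = 4, seed = 11),
    logEvery = 0)
  .fixtureEnv$model
}

evalSlide <- function(seed = 999) {
  specs <- lapply(c(0.3, 0.42, 0.5, 0.58, 0.46, 0.62),
                  function(f) testRootSpec(f, len = 680))
  generateSlide(6, specs, seed = seed, canvas = c(768, 512))
}

# Brute-force even-odd point-in-polygon (ray casting per pixel), the
# independent oracle for the scanline rasterizer.
bruteRasterize <- function(vertices, height, width) {
  eps <- 1e-7
  out <- matrix(FALSE, height, width)
  n <- nrow(vertices)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      x <- c - 1 + eps; y <- r - 1 + eps
      cross <- 0
      for (i in seq_len(n)) {
        j <- if (i == n) 1 else i + 1
        y1 <- vertices[i, 2]; y2 <- vertices[j, 2]
        if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
          xc <- vertices[i, 1] + (y - y1) * (vertices[j, 1] - vertices[i, 1]) / (y2 - y1)
          if (xc < x) cross <- cross + 1
        }
      }
      out[r, c] <- cross %% 2 == 1
    }
  }
  out
}
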