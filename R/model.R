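#' Split patches into train / validation / test sets
#'
#' Sizes are `round(f1 * n)`, `round(f2 * n)` and the remainder; the
#' permutation is driven solely by `seed`. With 1,471 patches and the
#' default 60/20/20 fractions this yields 883 / 294 / 294.
#'
#' @param x a list of patches, or a single integer n (indices are split).
#' @param fractions three positive fractions summing to 1.
#' @param seed integer RNG seed.
#' @return `list(train =, val =, test =)` of disjoint subsets (or index
#'   vectors when `x` is an integer).
#' @export
#' @examples
#' lengths(splitPatches(1471, c(0.6, 0.2, 0.2), seed = 1))
splitPatches <- function(x, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive numbers summing to 1")
  asIndex <- is.numeric(x) && length(x) == 1
  n <- if (asIndex) as.integer(x) else length(x)
  if (n < 3) stop("need at least 3 patches to populate all three splits")
  perm <- withSeed(seed, sample.int(n))
  n1 <- round(fractions[1] * n)
  n2 <- round(fractions[2] * n)
  if (n1 + n2 >= n) stop("fractions leave an empty test split for n = ", n)
  idx <- list(train = sort(perm[seq_len(n1)]),
              val = sort(perm[n1 + seq_len(n2)]),
              test = sort(perm[(n1 + n2 + 1):n]))
  if (asIndex) idx else lapply(idx, function(i) x[i])
}

#' Summed cross-entropy + soft-Dice segmentation loss
#'
#' The "logits" term is per-pixel multiclass cross-entropy computed from raw
#' logits; the Dice term is `1 - mean(soft Dice)` over the non-background
#' classes present in the target. The two terms are summed with equal
#' weight and also returned separately.
#'
#' @param logits H x W x K numeric array of class scores.
#' @param target [LabelMask-class] or integer matrix of class codes 0..K-1.
#' @return `list(ce =, dice =, loss =)`, all `>= 0`.
#' @export
compositeLoss <- function(logits, target) {
  lab <- maskLabels(target)
  d <- dim(logits)
  if (length(d) != 3 || d[1] != nrow(lab) || d[2] != ncol(lab))
    stop("logits and target shapes do not agree")
  K <- d[3]
  if (any(lab < 0) || any(lab >= K))
    stop("target contains class codes outside 0..", K - 1)
  flat <- matrix(logits, d[1] * d[2], K)
  mx <- apply(flat, 1, max)
  ex <- exp(flat - mx)
  p <- ex / rowSums(ex)
  ti <- as.vector(lab) + 1L
  n <- length(ti)
  ce <- -mean(log(pmax(p[cbind(seq_len(n), ti)], 1e-12)))
  dice <- 0
  present <- setdiff(sort(unique(ti)), 1L)
  if (length(present) > 0) {
    dsum <- 0
    for (k in present) {
      t <- as.numeric(ti == k)
      inter <- sum(p[, k] * t)
      dsum <- dsum + 2 * inter / (sum(p[, k]) + sum(t))
    }
    dice <- 1 - dsum / length(present)
  }
  list(ce = ce, dice = dice, loss = ce + dice)
}

#' Mean intersection-over-union between two label masks
#'
#' Averaged over the non-background classes present in the target: a class
#' present in the target but missed entirely by the prediction scores 0;
#' classes absent from the target are skipped.
#'
#' @param pred,target [LabelMask-class] objects or integer matrices.
#' @return scalar in [0, 1] (NA when the target has no non-background
#'   class).
#' @export
iouScore <- function(pred, target) {
  p <- maskLabels(pred); t <- maskLabels(target)
  if (!all(dim(p) == dim(t))) stop("pred and target shapes do not agree")
  classes <- setdiff(unique(as.vector(t)), 0L)
  if (length(classes) == 0) return(NA_real_)
  mean(vapply(classes, function(k) {
    inter <- sum(p == k & t == k)
    uni <- sum(p == k | t == k)
    if (uni == 0) 0 else inter / uni
  }, numeric(1)))
}

#' Create an untrained segmentation model
#'
#' @param config a [ModelConfig-class].
#' @param classMap class vocabulary; its length must equal `nClasses`.
#' @param seed seed for weight initialization.
#' @return A [SegModel-class].
#' @export
newSegModel <- function(config = modelConfig(), classMap = peridermClasses(),
                        seed = 1L) {
  if (length(classMap) != config@nClasses)
    stop("classMap length must equal nClasses")
  ptr <- .net_create(config@baseChannels, config@nClasses, 3L)
  withSeed(seed, .net_init(ptr))
  new("SegModel", ptr = ptr, config = config, classMap = classMap,
      history = data.frame(), trained = FALSE)
}

# image patch (H x W x 3, [0,1]) -> logits H x W x K
.forwardLogits <- function(model, patch) {
  .net_forward(model@ptr, patch)
}

#' Predict the class mask of a single patch
#'
#' @param model a trained [SegModel-class].
#' @param patch H x W x 3 array, H and W multiples of 4.
#' @return A [LabelMask-class] (per-pixel argmax class).
#' @export
predictPatch <- function(model, patch) {
  if (length(dim(patch)) != 3 || dim(patch)[3] != 3)
    stop("patch must be an H x W x 3 array")
  logits <- .forwardLogits(model, patch)
  d <- dim(logits)
  lab <- max.col(matrix(logits, d[1] * d[2], d[3]), ties.method = "first") - 1L
  LabelMask(matrix(lab, d[1], d[2]), model@classMap)
}

#' Segment a whole slide image
#'
#' Tiles the slide, predicts each patch, and stitches the argmax class
#' masks back to slide scale. The output has the slide's dimensions.
#'
#' @param model a trained [SegModel-class].
#' @param image H x W x 3 array in [0, 1].
#' @param tiling a [TilingConfig-class]; its patch size should match the
#'   patch size the model was trained with.
#' @return A [LabelMask-class].
#' @export
predictSlide <- function(model, image, tiling = tilingConfig(
                           patchSize = model@config@patchSize)) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an H x W x 3 array")
  tl <- tileImage(image, tiling)
  masks <- lapply(tl$patches, function(p) predictPatch(model, p))
  stitchMasks(tl$grid, masks)
}

#' Train the segmentation network
#'
#' Splits the patches 60/20/20 (configurable) at patch level, optimizes the
#' summed cross-entropy + soft-Dice loss with Adam, evaluates mean IoU on
#' the validation split after every epoch, and restores the weights of the
#' best-validation-IoU epoch at the end. All randomness (split, shuffling,
#' weight init, augmentation) is driven by `trainCfg@seed`.
#'
#' @param images list of H x W x 3 arrays in [0, 1].
#' @param masks list of [LabelMask-class] / integer matrices, aligned with
#'   `images`.
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param classMap class vocabulary.
#' @param logEvery print a progress line every this many epochs (0 = quiet).
#' @param restoreBest restore the weights of the best-validation-IoU epoch
#'   at the end (default). With very small validation splits the IoU
#'   estimate is noisy; set FALSE to keep the final-epoch weights.
#' @return A trained [SegModel-class]; `trainHistory()` holds per-epoch
#'   train loss, validation loss and validation IoU, and
#'   `attr(, "testIndex")` the held-out test split indices.
#' @export
trainSegmenter <- function(images, masks, modelCfg = modelConfig(),
                           trainCfg = trainConfig(), classMap = peridermClasses(),
                           logEvery = 5L, restoreBest = TRUE) {
  n <- length(images)
  if (n != length(masks)) stop("images and masks differ in length")
  split <- splitPatches(n, trainCfg@splitFractions, trainCfg@seed)
  if (min(lengths(split)) < 1) stop("every split needs at least one patch")
  # patches from one slide can land in different splits (patch-level split)
  .msg(sprintf("training on %d patches (val %d, test %d); patch-level split",
               length(split$train), length(split$val), length(split$test)))
  masks <- lapply(masks, function(m) {
    lab <- maskLabels(m)
    storage.mode(lab) <- "integer"
    lab
  })
  model <- newSegModel(modelCfg, classMap, seed = trainCfg@seed)
  modes <- c("identity", "rot90", "rot180", "rot270", "hflip", "vflip",
             "transpose", "antitranspose")
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_iou = numeric(0))
  bestIoU <- -Inf
  bestParams <- NULL
  withSeed(trainCfg@seed + 1L, {
    for (ep in seq_len(trainCfg@epochs)) {
      ord <- split$train[sample.int(length(split$train))]
      epLoss <- 0; nb <- 0
      for (b in split(ord, ceiling(seq_along(ord) / trainCfg@batchSize))) {
        if (trainCfg@augment) {
          mode <- sample(modes, length(b), replace = TRUE)
          imgs <- mapply(function(i, m) augmentPatch(images[[i]], m),
                         b, mode, SIMPLIFY = FALSE)
          msks <- mapply(function(i, m) augmentPatch(masks[[i]], m),
                         b, mode, SIMPLIFY = FALSE)
        } else {
          imgs <- images[b]
          msks <- masks[b]
        }
        res <- .net_train_batch(model@ptr, imgs, msks, trainCfg@learningRate)
        epLoss <- epLoss + res$loss; nb <- nb + 1
      }
      val <- vapply(split$val, function(i) {
        l <- .net_eval_loss(model@ptr, images[[i]], masks[[i]])
        iou <- iouScore(maskLabels(predictPatch(model, images[[i]])), masks[[i]])
        c(l$loss, iou)
      }, numeric(2))
      valLoss <- mean(val[1, ])
      valIoU <- mean(val[2, ], na.rm = TRUE)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = epLoss / nb,
                                     val_loss = valLoss, val_iou = valIoU))
      if (is.finite(valIoU) && valIoU > bestIoU) {
        bestIoU <- valIoU
        bestParams <- .net_get_params(model@ptr)
      }
      if (logEvery > 0 && (ep %% logEvery == 0 || ep == trainCfg@epochs))
        .msg(sprintf("epoch %d/%d train %.4f val %.4f IoU %.3f",
                     ep, trainCfg@epochs, epLoss / nb, valLoss, valIoU))
    }
  })
  if (restoreBest && !is.null(bestParams)) .net_set_params(model@ptr, bestParams)
  model@history <- hist
  model@trained <- TRUE
  attr(model, "testIndex") <- split$test
  model
}

#' Best epoch of a training history
#' @param model a trained [SegModel-class].
#' @return the (first) epoch attaining the maximum validation IoU.
#' @export
bestEpoch <- function(model) {
  h <- trainHistory(model)
  if (nrow(h) == 0) stop("model has no training history")
  if (all(!is.finite(h$val_iou))) return(1L)
  which.max(h$val_iou)
}

#' Save a model checkpoint
#'
#' The checkpoint embeds the architecture configuration, class map, weights
#' and training history, so [loadModel()] restores a working model.
#'
#' @param model a [SegModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(baseChannels = model@config@baseChannels,
               nClasses = model@config@nClasses,
               patchSize = model@config@patchSize,
               classMap = model@classMap,
               params = .net_get_params(model@ptr),
               history = model@history,
               trained = model@trained),
          path)
  invisible(path)
}

#' Load a model checkpoint written by [saveModel()]
#' @param path checkpoint file.
#' @return A [SegModel-class].
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  cfg <- modelConfig(ck$baseChannels, ck$nClasses, ck$patchSize)
  model <- newSegModel(cfg, ck$classMap, seed = 1L)
  .net_set_params(model@ptr, ck$params)
  model@history <- ck$history
  model@trained <- isTRUE(ck$trained)
  model
}
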