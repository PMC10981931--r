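#' Class codes for root tissue segmentation
#'
#' The fixed class vocabulary used throughout the pipeline: background (0),
#' periderm (1), endodermis (2) and lateral root (3).
#'
#' @return Named integer vector mapping class names to codes.
#' @export
#' @examples
#' peridermClasses()
peridermClasses <- function() {
  c(background = 0L, periderm = 1L, endoderm = 2L, lateral_root = 3L)
}

#' LabelMask: per-pixel tissue class map
#'
#' An integer matrix of class codes at image resolution together with the
#' class map. Values must all be listed in the class map.
#'
#' @slot labels integer matrix (rows = image rows).
#' @slot classMap named integer vector, see [peridermClasses()].
#' @export
setClass("LabelMask",
  representation(labels = "matrix", classMap = "integer"),
  validity = function(object) {
    if (!is.numeric(object@labels)) return("labels must be a numeric matrix")
    if (length(object@classMap) < 1 || is.null(names(object@classMap)))
      return("classMap must be a named integer vector")
    bad <- setdiff(unique(as.vector(object@labels)), object@classMap)
    if (length(bad) > 0)
      return(paste0("labels contain codes outside the class map: ",
                    paste(bad, collapse = ", ")))
    TRUE
  }
)

#' Construct a LabelMask
#'
#' @param labels integer matrix of class codes.
#' @param classMap named integer vector of accepted codes.
#' @return A [LabelMask-class] object.
#' @export
#' @examples
#' m <- LabelMask(matrix(0L, 4, 6))
#' dim(m)
LabelMask <- function(labels, classMap = peridermClasses()) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, classMap = classMap)
}

#' @describeIn LabelMask-class dimensions of the label matrix
#' @param x a LabelMask
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

setMethod("show", "LabelMask", function(object) {
  cnt <- classCounts(object)
  cat(sprintf("LabelMask %d x %d\n", nrow(object@labels), ncol(object@labels)))
  cat("  pixels per class:", paste(names(cnt), cnt, sep = "=", collapse = " "), "\n")
})

#' Access the label matrix of a LabelMask
#' @param x a [LabelMask-class] (a plain matrix is passed through).
#' @return Integer matrix of class codes.
#' @export
maskLabels <- function(x) {
  if (is(x, "LabelMask")) x@labels else x
}

#' Access the class map of a LabelMask
#' @param x a [LabelMask-class]
#' @return Named integer vector.
#' @export
classMap <- function(x) {
  if (is(x, "LabelMask")) x@classMap else peridermClasses()
}

#' Pixel counts per class
#' @param x a [LabelMask-class] or label matrix.
#' @return Named integer vector of pixel counts, one entry per mapped class.
#' @export
classCounts <- function(x) {
  lab <- maskLabels(x)
  cm <- classMap(x)
  vapply(cm, function(code) sum(lab == code), integer(1))
}

#' ScaleConfig: pixel-to-micrometer calibration
#'
#' Calibration as set on the microscope export: `pixelDistance` pixels
#' correspond to `knownDistance` micrometers. The default (0.5299 px per
#' 1.00 um) matches the 4x objective calibration used for slide scans.
#' Non-square pixels are rejected.
#'
#' @slot pixelDistance pixels per `knownDistance`.
#' @slot knownDistance micrometers.
#' @slot pixelAspectRatio must be 1.
#' @export
setClass("ScaleConfig",
  representation(pixelDistance = "numeric", knownDistance = "numeric",
                 pixelAspectRatio = "numeric"),
  prototype(pixelDistance = 0.5299, knownDistance = 1.0, pixelAspectRatio = 1.0),
  validity = function(object) {
    if (object@pixelDistance <= 0) return("pixelDistance must be > 0")
    if (object@knownDistance <= 0) return("knownDistance must be > 0")
    if (object@pixelAspectRatio != 1)
      return("pixelAspectRatio != 1 is not supported")
    TRUE
  }
)

#' @rdname ScaleConfig-class
#' @param pixelDistance,knownDistance,pixelAspectRatio see slots.
#' @return A ScaleConfig.
#' @export
#' @examples
#' scaleConfig()            # 1 px = 1/0.5299 um
scaleConfig <- function(pixelDistance = 0.5299, knownDistance = 1.0,
                        pixelAspectRatio = 1.0) {
  new("ScaleConfig", pixelDistance = pixelDistance,
      knownDistance = knownDistance, pixelAspectRatio = pixelAspectRatio)
}

#' Micrometers per pixel implied by a ScaleConfig
#' @param scale a [ScaleConfig-class]
#' @return micrometers spanned by one pixel.
#' @export
micrometersPerPixel <- function(scale) {
  stopifnot(is(scale, "ScaleConfig"))
  scale@knownDistance / scale@pixelDistance
}

setMethod("show", "ScaleConfig", function(object) {
  cat(sprintf("ScaleConfig: %.4f px = %.2f um (%.4f um/px)\n",
              object@pixelDistance, object@knownDistance,
              micrometersPerPixel(object)))
})

#' TilingConfig: patch extraction parameters
#'
#' @slot patchSize side of the square patches in pixels (default 1024).
#' @slot padValue intensity used to pad right/bottom edge patches.
#' @slot overlap overlap between adjacent patches in pixels (default 0).
#' @export
setClass("TilingConfig",
  representation(patchSize = "integer", padValue = "numeric", overlap = "integer"),
  prototype(patchSize = 1024L, padValue = 0, overlap = 0L),
  validity = function(object) {
    if (object@patchSize < 32) return("patchSize must be >= 32")
    if (object@overlap < 0 || object@overlap >= object@patchSize)
      return("overlap must satisfy 0 <= overlap < patchSize")
    TRUE
  }
)

#' @rdname TilingConfig-class
#' @param patchSize,padValue,overlap see slots.
#' @return A TilingConfig.
#' @export
tilingConfig <- function(patchSize = 1024L, padValue = 0, overlap = 0L) {
  new("TilingConfig", patchSize = as.integer(patchSize), padValue = padValue,
      overlap = as.integer(overlap))
}

#' PatchGrid: layout of patches over a slide
#'
#' @slot nRows,nCols patch grid dimensions.
#' @slot offsets integer matrix (nRows*nCols x 2) of 1-based (row, col)
#'   origins in row-major patch order.
#' @slot height,width original slide dimensions.
#' @slot patchSize,overlap tiling parameters used.
#' @export
setClass("PatchGrid",
  representation(nRows = "integer", nCols = "integer", offsets = "matrix",
                 height = "integer", width = "integer",
                 patchSize = "integer", overlap = "integer"))

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d x %d patches of %d px over %d x %d image\n",
              object@nRows, object@nCols, object@patchSize,
              object@height, object@width))
})

#' AnnotationDocument: polygonal tissue annotations for one slide
#'
#' Mirrors the labelme JSON dialect: an ordered list of polygons, each a
#' class label plus an n x 2 matrix of (x, y) vertices in 0-based pixel
#' coordinates. Later polygons overwrite earlier ones when rasterized.
#'
#' @slot polygons list of `list(label =, points =)` entries.
#' @slot imageHeight,imageWidth canvas size in pixels.
#' @export
setClass("AnnotationDocument",
  representation(polygons = "list", imageHeight = "integer", imageWidth = "integer"),
  validity = function(object) {
    ok <- c("periderm", "endoderm", "lateral_root")
    for (p in object@polygons) {
      if (!is.list(p) || is.null(p$label) || is.null(p$points))
        return("each polygon needs $label and $points")
      if (!p$label %in% ok)
        return(paste0("unknown class label '", p$label,
                      "'; accepted labels: ", paste(ok, collapse = ", ")))
      if (nrow(p$points) < 3) return("each polygon needs >= 3 vertices")
    }
    TRUE
  }
)

#' @rdname AnnotationDocument-class
#' @param polygons,imageHeight,imageWidth see slots.
#' @return An AnnotationDocument.
#' @export
annotationDocument <- function(polygons, imageHeight, imageWidth) {
  polygons <- lapply(polygons, function(p) {
    p$points <- as.matrix(p$points)
    p
  })
  new("AnnotationDocument", polygons = polygons,
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth))
}

setMethod("show", "AnnotationDocument", function(object) {
  cat(sprintf("AnnotationDocument: %d polygons on %d x %d canvas\n",
              length(object@polygons), object@imageHeight, object@imageWidth))
})

#' PostprocessConfig: mask-cleaning thresholds
#'
#' `bridgeMaxGap` is the longest run of non-periderm centerline positions
#' (in pixels) that is still bridged into the periderm; beyond it all distal
#' periderm is relabeled endodermis. `holeMax` is the largest interior hole
#' (in pixels of area) that is closed. `minRootArea` discards connected
#' components smaller than this as staining debris.
#'
#' @slot bridgeMaxGap pixels, default 150.
#' @slot holeMax pixels of area, default 20.
#' @slot minRootArea pixels of area, default 5000.
#' @export
setClass("PostprocessConfig",
  representation(bridgeMaxGap = "numeric", holeMax = "numeric",
                 minRootArea = "numeric"),
  prototype(bridgeMaxGap = 150, holeMax = 20, minRootArea = 5000),
  validity = function(object) {
    if (!(object@bridgeMaxGap > object@holeMax && object@holeMax > 0))
      return("must satisfy bridgeMaxGap > holeMax > 0")
    if (object@minRootArea < 0) return("minRootArea must be >= 0")
    TRUE
  }
)

#' @rdname PostprocessConfig-class
#' @param bridgeMaxGap,holeMax,minRootArea see slots.
#' @return A PostprocessConfig.
#' @export
postprocessConfig <- function(bridgeMaxGap = 150, holeMax = 20,
                              minRootArea = 5000) {
  new("PostprocessConfig", bridgeMaxGap = bridgeMaxGap, holeMax = holeMax,
      minRootArea = minRootArea)
}

#' RootInstance: one connected root on a slide
#'
#' @slot rootId 1-based id, ordered by hypocotyl position left to right.
#' @slot slideId slide identifier.
#' @slot pixels n x 2 integer matrix of (row, col), 1-based.
#' @slot centerline m x 2 integer matrix, ordered from the hypocotyl end.
#' @slot centerlineAssign integer vector (length n): index of the centerline
#'   position geodesically nearest to each root pixel.
#' @export
setClass("RootInstance",
  representation(rootId = "integer", slideId = "character", pixels = "matrix",
                 centerline = "matrix", centerlineAssign = "integer"))

setMethod("show", "RootInstance", function(object) {
  cat(sprintf("RootInstance %d (slide %s): %d px, centerline %d points\n",
              object@rootId, object@slideId, nrow(object@pixels),
              nrow(object@centerline)))
})

#' ModelConfig: segmentation network architecture
#'
#' A nested-skip (UNet++-style, two pooling levels) fully convolutional
#' network with residual encoder blocks. `baseChannels` sets the width of
#' the first level; deeper levels double it.
#'
#' @slot baseChannels channels at the first level (default 8).
#' @slot nClasses number of output classes (must match the class map).
#' @slot patchSize side of training/inference patches (multiple of 4).
#' @export
setClass("ModelConfig",
  representation(baseChannels = "integer", nClasses = "integer",
                 patchSize = "integer"),
  prototype(baseChannels = 8L, nClasses = 4L, patchSize = 1024L),
  validity = function(object) {
    if (object@baseChannels < 2) return("baseChannels must be >= 2")
    if (object@patchSize %% 4 != 0) return("patchSize must be a multiple of 4")
    TRUE
  }
)

#' @rdname ModelConfig-class
#' @param baseChannels,nClasses,patchSize see slots.
#' @return A ModelConfig.
#' @export
modelConfig <- function(baseChannels = 8L, nClasses = 4L, patchSize = 1024L) {
  new("ModelConfig", baseChannels = as.integer(baseChannels),
      nClasses = as.integer(nClasses), patchSize = as.integer(patchSize))
}

#' TrainConfig: optimization settings
#'
#' Defaults follow the published schedule for full-scale slides: Adam with
#' initial learning rate 1e-4, 40 epochs, patch-level 60/20/20
#' train/validation/test split.
#'
#' @slot learningRate Adam step size.
#' @slot epochs number of passes over the training split.
#' @slot splitFractions train/val/test fractions summing to 1.
#' @slot batchSize patches per optimizer step.
#' @slot seed integer driving shuffling, initialization and augmentation.
#' @slot augment apply random dihedral augmentation during training.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", epochs = "integer",
                 splitFractions = "numeric", batchSize = "integer",
                 seed = "integer", augment = "logical"),
  prototype(learningRate = 1e-4, epochs = 40L,
            splitFractions = c(0.6, 0.2, 0.2), batchSize = 4L, seed = 1L,
            augment = TRUE),
  validity = function(object) {
    f <- object@splitFractions
    if (length(f) != 3 || any(f <= 0) || abs(sum(f) - 1) > 1e-8)
      return("splitFractions must be three positive numbers summing to 1")
    if (object@epochs < 1) return("epochs must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    TRUE
  }
)

#' @rdname TrainConfig-class
#' @param learningRate,epochs,splitFractions,batchSize,seed,augment see slots.
#' @return A TrainConfig.
#' @export
trainConfig <- function(learningRate = 1e-4, epochs = 40L,
                        splitFractions = c(0.6, 0.2, 0.2), batchSize = 4L,
                        seed = 1L, augment = TRUE) {
  new("TrainConfig", learningRate = learningRate, epochs = as.integer(epochs),
      splitFractions = splitFractions, batchSize = as.integer(batchSize),
      seed = as.integer(seed), augment = augment)
}

#' SegModel: a (possibly trained) segmentation network
#'
#' Holds the native network state plus its configuration, class map and
#' training history. Use [trainSegmenter()] to fit, [predictSlide()] /
#' [predictPatch()] to apply, and [saveModel()] / [loadModel()] to persist.
#'
#' @slot ptr external pointer to the native network.
#' @slot config a [ModelConfig-class].
#' @slot classMap named integer class vocabulary.
#' @slot history per-epoch data.frame (train_loss, val_loss, val_iou).
#' @slot trained logical.
#' @export
setClass("SegModel",
  representation(ptr = "externalptr", config = "ModelConfig",
                 classMap = "integer", history = "data.frame",
                 trained = "logical"))

setMethod("show", "SegModel", function(object) {
  cat(sprintf("SegModel: nested-skip CNN, base %d channels, %d classes (%s)\n",
              object@config@baseChannels, object@config@nClasses,
              if (object@trained) "trained" else "untrained"))
  if (nrow(object@history) > 0) {
    best <- which.max(object@history$val_iou)
    cat(sprintf("  %d epochs, best val IoU %.3f at epoch %d\n",
                nrow(object@history), object@history$val_iou[best], best))
  }
})

#' Training history of a SegModel
#' @param model a [SegModel-class]
#' @return data.frame with one row per epoch.
#' @export
trainHistory <- function(model) {
  stopifnot(is(model, "SegModel"))
  model@history
}
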