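#' Assemble a pipeline configuration
#'
#' One list drives the eight batch steps (load, preprocess, segment,
#' postprocess, qc, phenotype, visualize, save). It round-trips losslessly
#' through a YAML file via [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param inputDir directory of slide images (TIFF/PNG).
#' @param outputDir working/output directory.
#' @param checkpoint path of a model checkpoint from [saveModel()].
#' @param patchSize,overlap tiling parameters (see [tilingConfig()]).
#' @param bridgeMaxGap,holeMax,minRootArea postprocessing thresholds (see
#'   [postprocessConfig()]).
#' @param pixelDistance,knownDistance scale calibration (see
#'   [scaleConfig()]).
#' @param hypocotylEdge slide edge the hypocotyls point to.
#' @param qcMargin QC crop half-window in pixels (default 1500).
#' @param chordStep centerline resampling interval for length measurement.
#' @param saveDir final bundle directory for the save step.
#' @param seed integer seed.
#' @return a validated pipeline configuration (named list).
#' @export
pipelineConfig <- function(inputDir, outputDir, checkpoint = NULL,
                           patchSize = 1024L, overlap = 0L,
                           bridgeMaxGap = 150, holeMax = 20,
                           minRootArea = 5000, pixelDistance = 0.5299,
                           knownDistance = 1.0, hypocotylEdge = "top",
                           qcMargin = 1500, chordStep = 9L, saveDir = NULL,
                           seed = 1L) {
  cfg <- list(inputDir = inputDir, outputDir = outputDir,
              checkpoint = checkpoint, patchSize = as.integer(patchSize),
              overlap = as.integer(overlap), bridgeMaxGap = bridgeMaxGap,
              holeMax = holeMax, minRootArea = minRootArea,
              pixelDistance = pixelDistance, knownDistance = knownDistance,
              hypocotylEdge = hypocotylEdge, qcMargin = qcMargin,
              chordStep = as.integer(chordStep), saveDir = saveDir,
              seed = as.integer(seed))
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks threshold ordering and nested-config validity before any work is
#' done; called by every step.
#'
#' @param cfg configuration list from [pipelineConfig()].
#' @return `cfg`, invisibly; errors on invalid settings.
#' @export
validatePipelineConfig <- function(cfg) {
  need <- c("inputDir", "outputDir", "patchSize", "bridgeMaxGap", "holeMax")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop("pipeline config is missing fields: ", paste(miss, collapse = ", "))
  # these constructors carry the validity rules
  tilingConfig(cfg$patchSize, 0, cfg$overlap %||% 0L)
  postprocessConfig(cfg$bridgeMaxGap, cfg$holeMax, cfg$minRootArea %||% 5000)
  scaleConfig(cfg$pixelDistance %||% 0.5299, cfg$knownDistance %||% 1.0)
  if (!(cfg$hypocotylEdge %||% "top") %in% c("top", "bottom", "left", "right"))
    stop("hypocotylEdge must be one of top/bottom/left/right")
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline configuration to YAML
#' @param cfg configuration list.
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ints <- c("patchSize", "overlap", "chordStep", "seed")
  for (f in intersect(ints, names(cfg))) cfg[[f]] <- as.integer(cfg[[f]])
  validatePipelineConfig(cfg)
  cfg
}

.stepDirs <- function(cfg) {
  list(pre = file.path(cfg$outputDir, "preprocessed"),
       masks = file.path(cfg$outputDir, "masks"),
       post = file.path(cfg$outputDir, "postprocessed"),
       qc = file.path(cfg$outputDir, "qc"),
       pheno = file.path(cfg$outputDir, "phenotype"),
       plots = file.path(cfg$outputDir, "plots"))
}

.slideList <- function(cfg) {
  manifest <- file.path(cfg$outputDir, "slides.csv")
  if (!file.exists(manifest))
    stop("missing slide manifest; run the 'load' step first")
  utils::read.csv(manifest, stringsAsFactors = FALSE)
}

#' Run one pipeline step
#'
#' The eight steps mirror the batch workflow: `load` lists and validates
#' the input images; `preprocess` converts them to 8-bit PNG; `segment`
#' applies the model checkpoint and writes per-slide masks; `postprocess`
#' applies the gap-bridging rules; `qc` writes per-root transition-zone
#' inspection images (and later passes consume a `selected_roots.txt`);
#' `phenotype` writes the four measurement CSVs (plus two after-QC CSVs if
#' a selection exists); `visualize` writes a per-slide boxplot; `save`
#' bundles the outputs. Steps check their prerequisites and name the step
#' to run first when one is missing.
#'
#' @param step one of load, preprocess, segment, postprocess, qc,
#'   phenotype, visualize, save.
#' @param cfg configuration from [pipelineConfig()].
#' @return step-specific artifact summary (invisible list).
#' @export
runStep <- function(step = c("load", "preprocess", "segment", "postprocess",
                             "qc", "phenotype", "visualize", "save"), cfg) {
  step <- match.arg(step)
  validatePipelineConfig(cfg)
  dirs <- .stepDirs(cfg)
  if (!dir.exists(cfg$outputDir)) dir.create(cfg$outputDir, recursive = TRUE)
  switch(step,
    load = .stepLoad(cfg),
    preprocess = .stepPreprocess(cfg, dirs),
    segment = .stepSegment(cfg, dirs),
    postprocess = .stepPostprocess(cfg, dirs),
    qc = .stepQC(cfg, dirs),
    phenotype = .stepPhenotype(cfg, dirs),
    visualize = .stepVisualize(cfg, dirs),
    save = .stepSave(cfg, dirs))
}

.stepLoad <- function(cfg) {
  if (!dir.exists(cfg$inputDir)) stop("input dir not found: ", cfg$inputDir)
  files <- list.files(cfg$inputDir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no TIFF/PNG images in ", cfg$inputDir)
  ok <- vapply(files, function(f)
    !inherits(try(readSlideImage(f), silent = TRUE), "try-error"), logical(1))
  if (any(!ok)) stop("unreadable image(s): ",
                     paste(basename(files[!ok]), collapse = ", "))
  manifest <- data.frame(slide_id = tools::file_path_sans_ext(basename(files)),
                         path = files, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(cfg$outputDir, "slides.csv"),
                   row.names = FALSE)
  .msg("loaded ", nrow(manifest), " slide(s)")
  invisible(list(slides = manifest))
}

.stepPreprocess <- function(cfg, dirs) {
  slides <- .slideList(cfg)
  dir.create(dirs$pre, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(slides$path, convertToPNG, "", outDir = dirs$pre)
  .msg("preprocessed ", length(paths), " slide(s) to PNG")
  invisible(list(png = unname(paths)))
}

.stepSegment <- function(cfg, dirs) {
  slides <- .slideList(cfg)
  if (!dir.exists(dirs$pre)) stop("no preprocessed images; run 'preprocess' first")
  if (is.null(cfg$checkpoint) || !file.exists(cfg$checkpoint))
    stop("model checkpoint not found; train a model or point 'checkpoint' at one")
  model <- loadModel(cfg$checkpoint)
  dir.create(dirs$masks, showWarnings = FALSE, recursive = TRUE)
  tiling <- tilingConfig(cfg$patchSize, 0, cfg$overlap %||% 0L)
  for (i in seq_len(nrow(slides))) {
    img <- readSlideImage(file.path(dirs$pre, paste0(slides$slide_id[i], ".png")))
    mask <- predictSlide(model, img, tiling)
    writeMaskPNG(mask, file.path(dirs$masks, paste0(slides$slide_id[i], ".png")))
  }
  .msg("segmented ", nrow(slides), " slide(s)")
  invisible(list(masks = dirs$masks))
}

.stepPostprocess <- function(cfg, dirs) {
  slides <- .slideList(cfg)
  if (!dir.exists(dirs$masks)) stop("no masks; run 'segment' first")
  dir.create(dirs$post, showWarnings = FALSE, recursive = TRUE)
  pp <- postprocessConfig(cfg$bridgeMaxGap, cfg$holeMax,
                          cfg$minRootArea %||% 5000)
  totals <- c(roots = 0L, bridged = 0L, relabeled = 0L, filled = 0L)
  for (i in seq_len(nrow(slides))) {
    sid <- slides$slide_id[i]
    mask <- readMaskPNG(file.path(dirs$masks, paste0(sid, ".png")))
    res <- postprocessMask(mask, pp, cfg$hypocotylEdge %||% "top", sid)
    writeMaskPNG(res$mask, file.path(dirs$post, paste0(sid, ".png")))
    saveRDS(res$roots, file.path(dirs$post, paste0(sid, "_roots.rds")))
    totals <- totals + res$stats
  }
  .msg(sprintf("postprocessed: %d roots, %d gaps bridged, %d distal runs relabeled, %d holes filled",
               totals["roots"], totals["bridged"], totals["relabeled"],
               totals["filled"]))
  invisible(as.list(totals))
}

.loadRoots <- function(cfg, dirs, sid) {
  f <- file.path(dirs$post, paste0(sid, "_roots.rds"))
  if (!file.exists(f)) stop("no postprocessed roots; run 'postprocess' first")
  readRDS(f)
}

.stepQC <- function(cfg, dirs) {
  slides <- .slideList(cfg)
  dir.create(dirs$qc, showWarnings = FALSE, recursive = TRUE)
  nImg <- 0L
  for (i in seq_len(nrow(slides))) {
    sid <- slides$slide_id[i]
    roots <- .loadRoots(cfg, dirs, sid)
    mask <- readMaskPNG(file.path(dirs$post, paste0(sid, ".png")))
    img <- readSlideImage(file.path(dirs$pre, paste0(sid, ".png")))
    overlay <- maskOverlay(img, mask)
    for (root in roots) {
      tp <- findTransition(root, mask)
      if (is.null(tp)) next
      makeQCImage(img, overlay, tp, cfg$qcMargin %||% 1500,
                  file.path(dirs$qc, sprintf("%s_root%d_qc.png", sid,
                                             root@rootId)))
      nImg <- nImg + 1L
    }
  }
  .msg("wrote ", nImg, " QC image(s) to ", dirs$qc)
  invisible(list(images = nImg))
}

.stepPhenotype <- function(cfg, dirs) {
  slides <- .slideList(cfg)
  dir.create(dirs$pheno, showWarnings = FALSE, recursive = TRUE)
  scale <- scaleConfig(cfg$pixelDistance %||% 0.5299, cfg$knownDistance %||% 1.0)
  meas <- do.call(rbind, lapply(seq_len(nrow(slides)), function(i) {
    sid <- slides$slide_id[i]
    roots <- .loadRoots(cfg, dirs, sid)
    mask <- readMaskPNG(file.path(dirs$post, paste0(sid, ".png")))
    measureSlide(roots, mask, scale, sid, cfg$chordStep %||% 9L)
  }))
  written <- character(0)
  for (q in c("periderm_length", "whole_root_length")) {
    for (u in c("micrometers", "pixels")) {
      written <- c(written, writeMeasurementsCSV(
        measurementTable(meas, q, u), dirs$pheno, q, u))
    }
  }
  selFile <- file.path(cfg$outputDir, "selected_roots.txt")
  if (file.exists(selFile)) {
    sel <- readSelectionList(selFile)
    kept <- applySelection(meas, sel)
    for (u in c("micrometers", "pixels")) {
      written <- c(written, writeMeasurementsCSV(
        measurementTable(kept, "periderm_length", u), dirs$pheno,
        "periderm_length", u, afterQC = TRUE))
    }
  }
  utils::write.csv(meas, file.path(dirs$pheno, "measurements_full.csv"),
                   row.names = FALSE)
  .msg("phenotype: measured ", nrow(meas), " root(s); wrote ",
       length(written), " CSV file(s)")
  invisible(list(measurements = meas, files = written))
}

.stepVisualize <- function(cfg, dirs) {
  f <- file.path(dirs$pheno, "periderm_length_micrometers.csv")
  if (!file.exists(f)) stop("no measurements; run 'phenotype' first")
  tab <- readMeasurementsCSV(f)
  dir.create(dirs$plots, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(dirs$plots, "periderm_length_boxplot.png")
  grDevices::png(out, width = 800, height = 600)
  graphics::boxplot(value ~ slide_id, data = tab,
                    xlab = "slide", ylab = "periderm length (um)",
                    main = "Periderm length per slide", col = "palegreen3")
  grDevices::dev.off()
  .msg("wrote ", out)
  invisible(list(plot = out))
}

.stepSave <- function(cfg, dirs) {
  dest <- cfg$saveDir %||% file.path(cfg$outputDir, "bundle")
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  for (d in dirs[c("post", "pheno", "plots", "qc")]) {
    if (dir.exists(d))
      file.copy(d, dest, recursive = TRUE)
  }
  .msg("bundled outputs into ", dest)
  invisible(list(dir = dest))
}

#' Run the full pipeline
#'
#' Executes the eight steps in order. The QC selection pass is skipped when
#' no `selected_roots.txt` exists in the output directory. A summary of
#' roots found and measured is returned; any step failure aborts with the
#' step's name.
#'
#' @param cfg configuration from [pipelineConfig()].
#' @return invisible summary list.
#' @export
runAll <- function(cfg) {
  validatePipelineConfig(cfg)
  summary <- list()
  for (step in c("load", "preprocess", "segment", "postprocess", "qc",
                 "phenotype", "visualize", "save")) {
    res <- tryCatch(runStep(step, cfg),
                    error = function(e) stop("pipeline step '", step,
                                             "' failed: ", conditionMessage(e),
                                             call. = FALSE))
    summary[[step]] <- res
  }
  n <- nrow(summary$phenotype$measurements)
  .msg("pipeline complete: ", n, " root(s) measured")
  invisible(summary)
}
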