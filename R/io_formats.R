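#' Read a slide image as an H x W x 3 array
#'
#' Reads TIFF, PNG or JPEG-free workflows (TIFF/PNG are the formats written
#' by the slide scanner and the preprocess step). Grayscale images are
#' replicated to 3 channels; an alpha channel, if present, is dropped.
#' Intensities are returned in [0, 1].
#'
#' @param path image file path.
#' @return numeric array H x W x 3.
#' @export
readSlideImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path),
      png = png::readPNG(path),
      stop("unsupported image format '", ext, "' for ", path)),
    error = function(e) stop("failed to decode ", path, ": ", conditionMessage(e)))
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (length(dim(img)) != 3) stop("unexpected image layout in ", path)
  if (dim(img)[3] == 1) img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an H x W x 3 array as 8-bit PNG
#'
#' @param img numeric array in [0, 1] (or a matrix, replicated to RGB).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Convert a slide image to lossless 8-bit RGB PNG
#'
#' Already-8-bit inputs keep their pixel values exactly. 16-bit TIFF inputs
#' are rescaled to 8 bits by a linear min-max stretch with a warning. An
#' already-PNG input is copied unchanged.
#'
#' @param srcPath input image (TIFF or PNG).
#' @param outDir output directory (default: alongside the input).
#' @return path of the written PNG.
#' @export
convertToPNG <- function(srcPath, outDir = dirname(srcPath)) {
  if (!file.exists(srcPath)) stop("cannot convert: file not found: ", srcPath)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  base <- tools::file_path_sans_ext(basename(srcPath))
  dst <- file.path(outDir, paste0(base, ".png"))
  ext <- tolower(tools::file_ext(srcPath))
  if (ext == "png") {
    if (normalizePath(srcPath) != normalizePath(dst, mustWork = FALSE))
      file.copy(srcPath, dst, overwrite = TRUE)
    return(dst)
  }
  if (!ext %in% c("tif", "tiff"))
    stop("unsupported input format '", ext, "' for ", srcPath)
  raw <- tryCatch(tiff::readTIFF(srcPath, as.is = TRUE),
                  error = function(e) stop("failed to decode ", srcPath, ": ",
                                           conditionMessage(e)))
  if (is.matrix(raw)) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1) raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  if (is.double(raw)) {
    # 8-bit samples come back already normalized to [0, 1]: lossless
    png::writePNG(raw, dst)
    return(dst)
  }
  if (max(raw) > 255) {
    # 16-bit export: linear min-max stretch to 8 bits
    warning("16-bit input ", basename(srcPath),
            " rescaled to 8 bits by linear min-max stretch")
    rng <- range(raw)
    if (rng[2] > rng[1]) {
      raw <- round((raw - rng[1]) / (rng[2] - rng[1]) * 255)
    } else {
      raw[] <- 0
    }
  }
  png::writePNG(raw / 255, dst)
  dst
}

#' Read a labelme-dialect annotation JSON
#'
#' Expects the "shapes" list written by polygonal annotation tools: each
#' shape has a "label", a "points" list of (x, y) vertices and
#' `shape_type = "polygon"`. Image dimensions come from "imageHeight" /
#' "imageWidth".
#'
#' @param path JSON file path.
#' @return An [AnnotationDocument-class].
#' @export
readAnnotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(doc$shapes)) stop("no 'shapes' entry in ", path)
  polys <- lapply(doc$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(p)))
    list(label = s$label, points = pts)
  })
  annotationDocument(polys, doc$imageHeight, doc$imageWidth)
}

#' Write an AnnotationDocument as labelme-dialect JSON
#'
#' @param doc an [AnnotationDocument-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(doc, path) {
  shapes <- lapply(doc@polygons, function(p) {
    list(label = p$label,
         points = lapply(seq_len(nrow(p$points)),
                         function(i) as.numeric(p$points[i, ])),
         shape_type = "polygon")
  })
  out <- list(shapes = shapes, imageHeight = doc@imageHeight,
              imageWidth = doc@imageWidth)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Rasterize polygonal annotations to a LabelMask
#'
#' Each polygon fills the pixels whose centers fall inside it (even-odd
#' rule); polygons are applied in document order so that later polygons
#' overwrite earlier ones, matching interactive annotation. All remaining
#' pixels are background.
#'
#' @param doc an [AnnotationDocument-class]; vertices are 0-based (x, y).
#' @return A [LabelMask-class] of the document's dimensions.
#' @export
rasterizeAnnotations <- function(doc) {
  stopifnot(is(doc, "AnnotationDocument"))
  cm <- peridermClasses()
  lab <- matrix(0L, doc@imageHeight, doc@imageWidth)
  for (p in doc@polygons) {
    inside <- .rasterize_polygon_cpp(p$points, doc@imageHeight, doc@imageWidth)
    lab[inside] <- cm[[p$label]]
  }
  LabelMask(lab)
}

#' Trace boundary polygons of a LabelMask
#'
#' Inverse companion of [rasterizeAnnotations()] for simply-connected
#' regions: each connected single-class region is traced along its pixel
#' boundary (polygon vertices on the half-integer corner grid), so that
#' rasterizing the result reproduces the region exactly.
#'
#' @param mask a [LabelMask-class].
#' @return An [AnnotationDocument-class].
#' @export
boundaryPolygons <- function(mask) {
  lab <- maskLabels(mask)
  cm <- classMap(mask)
  cm <- cm[cm != 0]
  polys <- list()
  for (nm in names(cm)) {
    comp <- .label_components_cpp(lab == cm[[nm]], 8L)
    for (k in seq_len(max(comp))) {
      poly <- .traceRegion(comp == k)
      polys[[length(polys) + 1]] <- list(label = nm, points = poly)
    }
  }
  annotationDocument(polys, nrow(lab), ncol(lab))
}

# Trace the outer boundary of a binary region as a closed polygon on the
# pixel-corner grid. Collects the unit edges between inside and outside
# pixels and chains them counter-clockwise. Holes are ignored (regions are
# assumed simply connected).
.traceRegion <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  idx <- which(bin, arr.ind = TRUE)
  # directed edges (corner -> corner) with inside on the left, corners keyed
  # as (x, y) in 0-based pixel coordinates offset by +-0.5
  edges <- list()
  push <- function(x1, y1, x2, y2) {
    edges[[length(edges) + 1]] <<- c(x1, y1, x2, y2)
  }
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    x0 <- c - 1 - 0.5; x1 <- c - 1 + 0.5  # 0-based pixel center c-1
    y0 <- r - 1 - 0.5; y1 <- r - 1 + 0.5
    if (r == 1 || !bin[r - 1, c]) push(x0, y0, x1, y0)      # top edge, east
    if (c == W || !bin[r, c + 1]) push(x1, y0, x1, y1)      # right edge, south
    if (r == H || !bin[r + 1, c]) push(x1, y1, x0, y1)      # bottom edge, west
    if (c == 1 || !bin[r, c - 1]) push(x0, y1, x0, y0)      # left edge, north
  }
  if (length(edges) == 0) return(matrix(numeric(0), 0, 2))
  em <- do.call(rbind, edges)
  key <- function(x, y) paste(x, y, sep = ",")
  # map start corner -> edge rows (a corner can start up to 2 edges at
  # diagonal touches; pick the unused one, preferring a turn that keeps the
  # region on the left, i.e. any consistent deterministic choice)
  starts <- split(seq_len(nrow(em)), key(em[, 1], em[, 2]))
  used <- rep(FALSE, nrow(em))
  loop <- integer(0)
  cur <- 1L
  repeat {
    used[cur] <- TRUE
    loop <- c(loop, cur)
    nxt <- starts[[key(em[cur, 3], em[cur, 4])]]
    nxt <- nxt[!used[nxt]]
    if (length(nxt) == 0) break
    cur <- nxt[1]
  }
  pts <- em[loop, c(1, 2), drop = FALSE]
  colnames(pts) <- NULL
  pts
}

#' Write a measurement table as a pipeline CSV
#'
#' File names encode quantity, unit and QC status exactly as the pipeline's
#' consumers expect: `periderm_length_micrometers.csv`,
#' `periderm_length_pixels.csv`, `whole_root_length_micrometers.csv`,
#' `whole_root_length_pixels.csv`, and after QC
#' `periderm_length_after_QC_micrometers.csv` /
#' `periderm_length_after_QC_pixels.csv`. Values are printed with full
#' precision so a write-read round trip is exact.
#'
#' @param table data.frame with columns slide_id, root_index, value.
#' @param outDir output directory.
#' @param quantity "periderm_length" or "whole_root_length".
#' @param unit "micrometers" or "pixels".
#' @param afterQC logical; insert the after_QC tag.
#' @return the written file path.
#' @export
writeMeasurementsCSV <- function(table, outDir,
                                 quantity = c("periderm_length", "whole_root_length"),
                                 unit = c("micrometers", "pixels"),
                                 afterQC = FALSE) {
  quantity <- match.arg(quantity)
  unit <- match.arg(unit)
  stopifnot(all(c("slide_id", "root_index", "value") %in% names(table)))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fname <- paste0(quantity, if (afterQC) "_after_QC" else "", "_", unit, ".csv")
  path <- file.path(outDir, fname)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("slide_id,root_index,value", con)
  if (nrow(table) > 0) {
    lines <- sprintf("%s,%d,%s", table$slide_id, as.integer(table$root_index),
                     formatC(table$value, digits = 17, format = "g"))
    writeLines(lines, con)
  }
  path
}

#' Read a pipeline measurement CSV
#' @param path CSV written by [writeMeasurementsCSV()].
#' @return data.frame with columns slide_id, root_index, value.
#' @export
readMeasurementsCSV <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer", "numeric"))
  names(df) <- c("slide_id", "root_index", "value")
  df
}

#' Write a LabelMask as an 8-bit grayscale PNG (class codes as pixel values)
#' @param mask a [LabelMask-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  lab <- maskLabels(mask)
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Read a LabelMask written by [writeMaskPNG()]
#' @param path PNG path.
#' @return A [LabelMask-class].
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  LabelMask(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)))
}
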