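#' Locate the periderm-to-endodermis transition of a root
#'
#' The transition point is the distal endpoint of the (single,
#' hypocotyl-anchored) periderm run after postprocessing; distally of it no
#' periderm remains. Roots without any periderm are flagged and return NULL.
#'
#' @param root a [RootInstance-class].
#' @param mask the post-processed [LabelMask-class].
#' @return `list(rootId =, index =, coord = c(row, col))` or NULL.
#' @export
findTransition <- function(root, mask) {
  segs <- projectSegments(root, mask)
  if (nrow(segs) == 0) {
    .msg(sprintf("root %d: no periderm run, flagged for QC", root@rootId))
    return(NULL)
  }
  idx <- segs$end[nrow(segs)]
  list(rootId = root@rootId, index = idx,
       coord = as.integer(root@centerline[idx, ]))
}

#' Colorize a label mask over the original image
#'
#' Periderm light blue, endodermis dark blue, lateral roots green, blended
#' over a dimmed copy of the original for visual inspection.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param mask a [LabelMask-class] of the same dimensions.
#' @return H x W x 3 array.
#' @export
maskOverlay <- function(image, mask) {
  lab <- maskLabels(mask)
  out <- image * 0.35
  colors <- list(`1` = c(0.4, 0.8, 1.0), `2` = c(0.1, 0.2, 0.8),
                 `3` = c(0.2, 0.9, 0.2))
  for (k in names(colors)) {
    sel <- lab == as.integer(k)
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[sel] <- 0.4 * pl[sel] + 0.6 * colors[[k]][ch]
      out[, , ch] <- pl
    }
  }
  out
}

#' Build (and optionally write) the QC inspection image for one root
#'
#' Crops a window of `margin` pixels on either side of the transition point
#' along both slide axes (clipped at the image borders) from the original
#' image and from the segmentation overlay, and stacks the two crops
#' vertically, original on top.
#'
#' @param original H x W x 3 slide image.
#' @param segmented H x W x 3 overlay (see [maskOverlay()]).
#' @param point transition point from [findTransition()].
#' @param margin half-window in pixels (default 1500).
#' @param outPath optional PNG path (`<slide>_root<k>_qc.png` convention).
#' @return the stacked array, invisibly if written.
#' @export
makeQCImage <- function(original, segmented, point, margin = 1500,
                        outPath = NULL) {
  H <- dim(original)[1]; W <- dim(original)[2]
  r <- point$coord[1]; c <- point$coord[2]
  rows <- max(1, r - margin):min(H, r + margin)
  cols <- max(1, c - margin):min(W, c + margin)
  top <- original[rows, cols, , drop = FALSE]
  bottom <- segmented[rows, cols, , drop = FALSE]
  out <- array(0, dim = c(2 * length(rows), length(cols), 3))
  out[seq_along(rows), , ] <- top
  out[length(rows) + seq_along(rows), , ] <- bottom
  if (!is.null(outPath)) {
    writeImagePNG(out, outPath)
    return(invisible(out))
  }
  out
}

#' Read a QC selection list
#'
#' One retained root per line, `slide_id,root_index`.
#'
#' @param path text file path.
#' @return data.frame (slide_id, root_index).
#' @export
readSelectionList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(slide_id = character(0), root_index = integer(0)))
  parts <- strsplit(lines, ",")
  data.frame(slide_id = trimws(vapply(parts, `[`, "", 1)),
             root_index = as.integer(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Write a QC selection list
#' @param selection data.frame (slide_id, root_index).
#' @param path output text file (conventionally `selected_roots.txt`).
#' @return `path`, invisibly.
#' @export
writeSelectionList <- function(selection, path) {
  writeLines(sprintf("%s,%d", selection$slide_id,
                     as.integer(selection$root_index)), path)
  invisible(path)
}

#' Filter a measurement table by a QC selection
#'
#' Keeps only the (slide_id, root_index) pairs named in the selection;
#' values of retained rows are untouched. Selection pairs that do not occur
#' in the table are reported and ignored.
#'
#' @param measurements data.frame with slide_id and root_index columns.
#' @param selection data.frame from [readSelectionList()].
#' @return the filtered data.frame.
#' @export
applySelection <- function(measurements, selection) {
  mkey <- paste(measurements$slide_id, measurements$root_index)
  skey <- paste(selection$slide_id, selection$root_index)
  unknown <- setdiff(skey, mkey)
  if (length(unknown) > 0)
    warning("selection pairs not present in the measurement table: ",
            paste(unknown, collapse = "; "))
  measurements[mkey %in% skey, , drop = FALSE]
}
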