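#' Compute the centerline of a connected region
#'
#' The region is thinned to a 1-px skeleton (Zhang-Suen), the skeleton is
#' turned into a graph whose 8-neighbor edges are weighted 1 (axial) or
#' sqrt(2) (diagonal), and the longest geodesic between any two skeleton
#' endpoints is returned as the centerline; side branches (lateral-root
#' stubs, skeleton spurs) are pruned implicitly by taking the single longest
#' path. The path is ordered so that its first point is the endpoint nearest
#' the configured hypocotyl edge of the slide.
#'
#' @param pixels n x 2 integer matrix of (row, col), 1-based, 8-connected;
#'   or a logical matrix.
#' @param hypocotylEdge which slide edge the hypocotyls point to; the
#'   centerline starts at the endpoint closest to it.
#' @return m x 2 integer matrix of ordered (row, col) centerline points
#'   (a single point for degenerate regions).
#' @export
computeCenterline <- function(pixels, hypocotylEdge = c("top", "bottom",
                                                        "left", "right")) {
  hypocotylEdge <- match.arg(hypocotylEdge)
  if (is.logical(pixels)) {
    bin <- pixels
    idx <- which(bin, arr.ind = TRUE)
  } else {
    idx <- pixels
    bin <- matrix(FALSE, max(idx[, 1]), max(idx[, 2]))
    bin[idx] <- TRUE
  }
  if (nrow(idx) < 2) {
    return(matrix(as.integer(idx), ncol = 2))
  }
  skel <- .thin_cpp(bin)
  sk <- which(skel, arr.ind = TRUE)
  if (nrow(sk) == 0) {
    # thinner than 1 px after skeletonization: degenerate single point
    return(matrix(as.integer(idx[1, ]), 1, 2))
  }
  if (nrow(sk) == 1) return(matrix(as.integer(sk), 1, 2))
  path <- .longestSkeletonPath(skel, sk)
  .orientToEdge(path, hypocotylEdge)
}

# Longest geodesic between skeleton endpoints (double-BFS on the weighted
# 8-neighbor graph via igraph).
.longestSkeletonPath <- function(skel, sk) {
  H <- nrow(skel)
  key <- (sk[, 2] - 1L) * H + sk[, 1]
  id <- seq_len(nrow(sk))
  lookup <- integer(max(key))
  lookup[key] <- id
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nb <- cbind(sk[, 1] + d[1], sk[, 2] + d[2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= ncol(skel)
    ok[ok] <- skel[nb[ok, , drop = FALSE]]
    nbkey <- (nb[ok, 2] - 1L) * H + nb[ok, 1]
    from <- c(from, id[ok]); to <- c(to, lookup[nbkey])
    w <- c(w, rep(if (all(d != 0)) sqrt(2) else 1, sum(ok)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = id))
  deg <- igraph::degree(g)
  ends <- which(deg <= 1)
  if (length(ends) < 2) ends <- seq_len(nrow(sk))  # loop-only skeleton
  dm <- igraph::distances(g, v = ends, to = ends)
  dm[!is.finite(dm)] <- -1
  best <- arrayInd(which.max(dm), dim(dm))
  vpath <- igraph::shortest_paths(g, from = ends[best[1]],
                                  to = ends[best[2]])$vpath[[1]]
  ord <- as.integer(igraph::as_ids(vpath))
  matrix(as.integer(sk[ord, , drop = FALSE]), ncol = 2)
}

.orientToEdge <- function(path, edge) {
  a <- path[1, ]; b <- path[nrow(path), ]
  flip <- switch(edge,
    top = a[1] > b[1], bottom = a[1] < b[1],
    left = a[2] > b[2], right = a[2] < b[2])
  if (isTRUE(flip)) path[rev(seq_len(nrow(path))), , drop = FALSE] else path
}

#' Euclidean length of an ordered pixel path
#'
#' Sums the Euclidean distances between consecutive points: 1 for axial and
#' sqrt(2) for diagonal moves on an 8-connected path. With `step > 1` the
#' path is resampled every `step` points (endpoints always kept) and chord
#' lengths are summed instead, which removes the orientation-dependent
#' overestimation inherent to unit/sqrt(2) stepping on smooth curves.
#'
#' @param line m x 2 matrix of ordered (row, col) points.
#' @param step chord subsampling interval in points (default 1 = raw steps).
#' @return length in pixels (0 for fewer than 2 points).
#' @export
#' @examples
#' polylineLength(cbind(1:101, 1))        # 100
#' polylineLength(cbind(1:11, 1:11))      # 10 * sqrt(2)
polylineLength <- function(line, step = 1L) {
  m <- nrow(line)
  if (is.null(m) || m < 2) return(0)
  if (step > 1) {
    keep <- unique(c(seq(1L, m, by = as.integer(step)), m))
    line <- line[keep, , drop = FALSE]
    m <- nrow(line)
    if (m < 2) return(0)
  }
  d <- diff(line)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Convert a pixel length to micrometers
#'
#' micrometers = pixels * knownDistance / pixelDistance.
#'
#' @param lengthPx length in pixels.
#' @param scale a [ScaleConfig-class].
#' @return length in micrometers.
#' @export
#' @examples
#' toMicrometers(5299, scaleConfig())     # 10000
toMicrometers <- function(lengthPx, scale = scaleConfig()) {
  stopifnot(is(scale, "ScaleConfig"))
  lengthPx * scale@knownDistance / scale@pixelDistance
}

#' Measure periderm and whole-root length of one root
#'
#' Whole-root length is the arc length of the full centerline; periderm
#' length is the arc length of the centerline sub-path covered by the
#' (single, hypocotyl-anchored) periderm run in the post-processed mask.
#' Both are converted to micrometers with `scale`. Lengths are measured on
#' the centerline resampled at `chordStep`-point chords to suppress
#' digitization bias (set `chordStep = 1` for raw 8-connected stepping).
#'
#' @param root a [RootInstance-class] (post-processing completed).
#' @param mask the post-processed [LabelMask-class].
#' @param scale a [ScaleConfig-class].
#' @param slideId slide identifier for the output row.
#' @param chordStep chord resampling interval (default 9 points).
#' @return one-row data.frame: slide_id, root_index, periderm_length_px,
#'   whole_root_length_px, periderm_length_um, whole_root_length_um.
#' @export
measureRoot <- function(root, mask, scale = scaleConfig(),
                        slideId = root@slideId, chordStep = 9L) {
  cl <- root@centerline
  m <- nrow(cl)
  ext <- .tipExtensions(root)
  whole <- polylineLength(cl, step = chordStep) + ext[1] + ext[2]
  segs <- projectSegments(root, mask)
  if (nrow(segs) == 0) {
    .msg(sprintf("root %d: no periderm run; periderm length 0", root@rootId))
    peri <- 0
  } else {
    if (nrow(segs) > 1)
      .msg(sprintf("root %d: %d periderm runs present; measuring the proximal run (postprocess first for a single run)",
                   root@rootId, nrow(segs)))
    s0 <- segs$start[1]; e0 <- segs$end[1]
    sub <- cl[s0:e0, , drop = FALSE]
    peri <- polylineLength(sub, step = chordStep)
    # sub-position boundary refinement: where the tissue cut crosses the
    # centerline obliquely, the cross-section periderm fraction ramps from
    # 1 to 0 over a few positions; adding the partial fractions just
    # outside the run (and subtracting the deficits just inside it) puts
    # the boundary at the area-weighted midpoint instead of the majority
    # flip, which is unbiased
    frac <- .peridermFractionByPosition(root, mask)
    step <- if (e0 > s0) peri / (e0 - s0) else 1
    win <- 12L
    outHi <- seq(e0 + 1L, min(m, e0 + win))
    inHi <- seq(max(s0, e0 - win + 1L), e0)
    adj <- 0
    if (e0 < m) adj <- adj + sum(frac[outHi]) * step
    adj <- adj - sum(1 - frac[inHi]) * step
    if (s0 > 1) {
      outLo <- seq(max(1L, s0 - win), s0 - 1L)
      inLo <- seq(s0, min(e0, s0 + win - 1L))
      adj <- adj + sum(frac[outLo]) * step - sum(1 - frac[inLo]) * step
    }
    peri <- peri + adj
    # tip corrections apply where the run reaches a centerline end
    if (s0 <= 3) peri <- peri + ext[1]
    if (e0 >= m - 2) peri <- peri + ext[2]
    peri <- max(0, min(peri, whole))
  }
  umpp <- micrometersPerPixel(scale)
  data.frame(slide_id = slideId, root_index = root@rootId,
             periderm_length_px = peri, whole_root_length_px = whole,
             periderm_length_um = peri * umpp, whole_root_length_um = whole * umpp,
             stringsAsFactors = FALSE)
}

# Tip correction at both centerline ends. Thinning stops a few pixels short
# of the region tip, and the swept region itself ends in a rounded cap of
# roughly the local half-width beyond the generating-curve endpoint, so the
# centerline is extended by (axial distance to the region boundary) minus
# (local half-width), clamped at 0. Returns c(proximal, distal) in pixels.
.tipExtensions <- function(root) {
  cl <- root@centerline
  m <- nrow(cl)
  if (m < 8) return(c(0, 0))
  pix <- root@pixels
  r0 <- min(pix[, 1]); c0 <- min(pix[, 2])
  H <- max(pix[, 1]) - r0 + 1L; W <- max(pix[, 2]) - c0 + 1L
  member <- matrix(FALSE, H, W)
  member[cbind(pix[, 1] - r0 + 1L, pix[, 2] - c0 + 1L)] <- TRUE
  inside <- function(p) {
    rr <- round(p[1]) - r0 + 1; cc <- round(p[2]) - c0 + 1
    rr >= 1 && rr <= H && cc >= 1 && cc <= W && member[rr, cc]
  }
  one <- function(endIdx, refIdx) {
    e <- cl[endIdx, ]
    dir <- e - cl[refIdx, ]
    nd <- sqrt(sum(dir^2))
    if (nd == 0) return(0)
    dir <- dir / nd
    # axial distance from the endpoint to the region boundary
    ax <- 0
    for (st in seq(0.5, 60, by = 0.5)) {
      if (!inside(e + dir * st)) break
      ax <- st
    }
    # local half-width: nearest non-member pixel around the endpoint
    win <- 30L
    rr <- max(1, e[1] - r0 + 1 - win):min(H, e[1] - r0 + 1 + win)
    cc <- max(1, e[2] - c0 + 1 - win):min(W, e[2] - c0 + 1 + win)
    sub <- member[rr, cc, drop = FALSE]
    out <- which(!sub, arr.ind = TRUE)
    hw <- if (nrow(out) == 0) win else
      sqrt(min((out[, 1] - (e[1] - r0 + 1 - rr[1] + 1))^2 +
               (out[, 2] - (e[2] - c0 + 1 - cc[1] + 1))^2)) - 1
    max(0, ax - max(0, hw))
  }
  k <- min(6L, m - 1L)
  c(one(1L, 1L + k), one(m, m - k))
}

#' Measure every root on a slide
#'
#' @param roots list of [RootInstance-class] from [extractRootInstances()]
#'   (after postprocessing).
#' @param mask post-processed [LabelMask-class].
#' @param scale a [ScaleConfig-class].
#' @param slideId slide identifier.
#' @param chordStep see [measureRoot()].
#' @return data.frame with one row per root.
#' @export
measureSlide <- function(roots, mask, scale = scaleConfig(), slideId = "slide",
                         chordStep = 9L) {
  if (length(roots) == 0)
    return(data.frame(slide_id = character(0), root_index = integer(0),
                      periderm_length_px = numeric(0),
                      whole_root_length_px = numeric(0),
                      periderm_length_um = numeric(0),
                      whole_root_length_um = numeric(0)))
  do.call(rbind, lapply(roots, measureRoot, mask = mask, scale = scale,
                        slideId = slideId, chordStep = chordStep))
}

#' Reshape slide measurements to the measurement-table format
#'
#' @param measurements data.frame from [measureSlide()].
#' @param quantity "periderm_length" or "whole_root_length".
#' @param unit "micrometers" or "pixels".
#' @return data.frame slide_id, root_index, value.
#' @export
measurementTable <- function(measurements,
                             quantity = c("periderm_length", "whole_root_length"),
                             unit = c("micrometers", "pixels")) {
  quantity <- match.arg(quantity)
  unit <- match.arg(unit)
  col <- paste0(quantity, "_", if (unit == "micrometers") "um" else "px")
  data.frame(slide_id = measurements$slide_id,
             root_index = measurements$root_index,
             value = measurements[[col]], stringsAsFactors = FALSE)
}
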