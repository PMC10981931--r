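#' Extract connected root instances from a slide mask
#'
#' Roots are the 8-connected components of the non-background pixels;
#' components smaller than `minArea` are discarded as staining debris.
#' Each root gets its skeleton centerline (ordered from the hypocotyl end)
#' and a geodesic nearest-centerline-position assignment for every root
#' pixel. Roots are numbered 1..k by the horizontal position of their
#' hypocotyl end, left to right.
#'
#' @param mask slide-scale [LabelMask-class].
#' @param minArea area floor in pixels (default from [postprocessConfig()]).
#' @param hypocotylEdge slide edge the hypocotyls point to (default "top").
#' @param slideId slide identifier carried into each instance.
#' @return list of [RootInstance-class] (possibly empty).
#' @export
extractRootInstances <- function(mask, minArea = 5000,
                                 hypocotylEdge = c("top", "bottom", "left",
                                                   "right"),
                                 slideId = "slide") {
  hypocotylEdge <- match.arg(hypocotylEdge)
  lab <- maskLabels(mask)
  comp <- .label_components_cpp(lab != 0L, 8L)
  k <- max(comp)
  if (k == 0) {
    .msg("no root components found in mask")
    return(list())
  }
  areas <- tabulate(comp[comp > 0], nbins = k)
  keep <- which(areas >= minArea)
  roots <- lapply(keep, function(ci) {
    pix <- which(comp == ci, arr.ind = TRUE)
    bin <- comp == ci
    cl <- computeCenterline(bin, hypocotylEdge)
    assign <- if (nrow(cl) >= 1) {
      am <- .assign_nearest_seed_cpp(bin, cl - 1L)
      am[pix]
    } else rep(1L, nrow(pix))
    new("RootInstance", rootId = 0L, slideId = slideId,
        pixels = matrix(as.integer(pix), ncol = 2),
        centerline = cl, centerlineAssign = as.integer(assign))
  })
  if (length(roots) == 0) return(list())
  # number by hypocotyl-end position, left to right
  hx <- vapply(roots, function(r) r@centerline[1, 2], numeric(1))
  roots <- roots[order(hx)]
  for (i in seq_along(roots)) roots[[i]]@rootId <- i
  roots
}

#' Periderm runs along a root centerline
#'
#' A centerline position is periderm if the root pixels geodesically
#' nearest to it (its local cross-section) are majority-periderm. Maximal
#' periderm runs are returned in centerline order.
#'
#' @param root a [RootInstance-class].
#' @param mask the [LabelMask-class] the root was extracted from.
#' @return data.frame with columns start, end (inclusive centerline
#'   indices) and length_px; zero rows when the root has no periderm.
#' @export
projectSegments <- function(root, mask) {
  frac <- .peridermFractionByPosition(root, mask)
  .runsFromFlags(frac > 0.5)
}

# Fraction of periderm pixels in each centerline position's cross-section
# (the root pixels geodesically nearest to that position).
.peridermFractionByPosition <- function(root, mask) {
  m <- nrow(root@centerline)
  if (m == 0) stop("degenerate root: empty centerline")
  lab <- maskLabels(mask)
  isPeri <- as.numeric(lab[root@pixels] == 1L)
  tot <- tabulate(root@centerlineAssign, nbins = m)
  peri <- as.numeric(rowsum(isPeri, root@centerlineAssign,
                            reorder = TRUE)[, 1])
  # rowsum drops empty groups; rebuild a dense per-position vector
  periDense <- numeric(m)
  periDense[sort(unique(root@centerlineAssign))] <- peri
  ifelse(tot > 0, periDense / pmax(tot, 1), 0)
}

.runsFromFlags <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             length_px = r$lengths[keep])
}

#' Bridge small periderm gaps and relabel spurious distal periderm
#'
#' Scanning along the centerline from the hypocotyl-proximal end,
#' consecutive periderm runs separated by a centerline gap of at most
#' `bridgeMaxGap` pixels are merged (the gap's cross-section pixels are
#' relabeled periderm). At the first gap exceeding the threshold, every
#' remaining distal periderm run is relabeled endodermis: a root carries a
#' single contiguous periderm anchored at the hypocotyl end, so isolated
#' distal fragments are false positives. The operation is idempotent.
#'
#' @param root a [RootInstance-class].
#' @param segments data.frame from [projectSegments()].
#' @param mask the [LabelMask-class] to relabel (the root's slide mask).
#' @param config a [PostprocessConfig-class].
#' @return `list(segments =, mask =, bridged =, relabeled =)`: the merged
#'   run (0 or 1 row), the updated mask, and counts of bridged gaps and
#'   relabeled distal runs.
#' @export
bridgeAndRelabel <- function(root, segments, mask, config = postprocessConfig()) {
  lab <- maskLabels(mask)
  nBridged <- 0L; nRelabeled <- 0L
  if (nrow(segments) == 0) {
    out <- if (is(mask, "LabelMask")) LabelMask(lab, classMap(mask)) else lab
    return(list(segments = segments, mask = out, bridged = 0L, relabeled = 0L))
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  start <- segments$start[1]
  end <- segments$end[1]
  i <- 2L
  while (i <= nrow(segments)) {
    gap <- segments$start[i] - end - 1L
    if (gap <= config@bridgeMaxGap) {
      # bridge: relabel the gap's cross-section pixels as periderm
      if (gap > 0) {
        gapPix <- root@pixels[root@centerlineAssign > end &
                              root@centerlineAssign < segments$start[i], ,
                              drop = FALSE]
        lab[gapPix] <- 1L
        nBridged <- nBridged + 1L
      }
      end <- segments$end[i]
      i <- i + 1L
    } else {
      break
    }
  }
  if (i <= nrow(segments)) {
    # large gap: everything distal is a false positive -> endodermis
    distalPix <- root@pixels[root@centerlineAssign > end, , drop = FALSE]
    sel <- lab[distalPix] == 1L
    lab[distalPix[sel, , drop = FALSE]] <- 2L
    nRelabeled <- nrow(segments) - i + 1L
  }
  out <- if (is(mask, "LabelMask")) LabelMask(lab, classMap(mask)) else lab
  list(segments = data.frame(start = start, end = end,
                             length_px = end - start + 1L),
       mask = out, bridged = nBridged, relabeled = nRelabeled)
}

#' Close tiny holes inside the periderm band
#'
#' Connected non-periderm pockets of area strictly below `holeMax` that are
#' completely surrounded by this root's periderm pixels are relabeled
#' periderm; larger holes and pockets touching other tissue or the
#' background outside the band are left untouched.
#'
#' @param mask the [LabelMask-class] to clean.
#' @param root a [RootInstance-class].
#' @param holeMax area threshold in pixels (default 20; a hole of exactly
#'   `holeMax` is kept).
#' @return `list(mask =, filled =)`: updated mask and number of holes filled.
#' @export
closeSmallHoles <- function(mask, root, holeMax = 20) {
  lab <- maskLabels(mask)
  # work in the root's bounding box, padded by 1 so border pockets stay open
  r0 <- max(1L, min(root@pixels[, 1]) - 1L)
  r1 <- min(nrow(lab), max(root@pixels[, 1]) + 1L)
  c0 <- max(1L, min(root@pixels[, 2]) - 1L)
  c1 <- min(ncol(lab), max(root@pixels[, 2]) + 1L)
  sub <- lab[r0:r1, c0:c1, drop = FALSE]
  notPeri <- sub != 1L
  comp <- .label_components_cpp(notPeri, 4L)
  nFilled <- 0L
  H <- nrow(sub); W <- ncol(sub)
  border <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  for (k in setdiff(seq_len(max(comp)), border)) {
    pix <- which(comp == k, arr.ind = TRUE)
    if (nrow(pix) >= holeMax) next
    # must be enclosed by periderm: every 8-neighbor outside the pocket is periderm
    enclosed <- TRUE
    for (i in seq_len(nrow(pix))) {
      rr <- pix[i, 1]; cc <- pix[i, 2]
      nb <- expand.grid(r = max(1, rr - 1):min(H, rr + 1),
                        c = max(1, cc - 1):min(W, cc + 1))
      nbv <- sub[as.matrix(nb)]
      nbc <- comp[as.matrix(nb)]
      if (any(nbc != k & nbv != 1L)) { enclosed <- FALSE; break }
    }
    if (enclosed) {
      sub[pix] <- 1L
      nFilled <- nFilled + 1L
    }
  }
  lab[r0:r1, c0:c1] <- sub
  out <- if (is(mask, "LabelMask")) LabelMask(lab, classMap(mask)) else lab
  list(mask = out, filled = nFilled)
}

#' Full postprocessing of a stitched slide mask
#'
#' Extracts root instances, then per root: projects periderm runs onto the
#' centerline, bridges small gaps / relabels large-gap distal fragments,
#' and closes tiny holes. Returns the cleaned mask, the root instances and
#' per-step counters.
#'
#' @param mask stitched slide [LabelMask-class].
#' @param config a [PostprocessConfig-class].
#' @param hypocotylEdge slide edge the hypocotyls point to.
#' @param slideId slide identifier.
#' @return `list(mask =, roots =, stats =)`; `stats` counts roots, bridged
#'   gaps, relabeled distal runs and filled holes.
#' @export
postprocessMask <- function(mask, config = postprocessConfig(),
                            hypocotylEdge = "top", slideId = "slide") {
  roots <- extractRootInstances(mask, config@minRootArea, hypocotylEdge,
                                slideId)
  stats <- c(roots = length(roots), bridged = 0L, relabeled = 0L, filled = 0L)
  cur <- mask
  for (root in roots) {
    segs <- projectSegments(root, cur)
    br <- bridgeAndRelabel(root, segs, cur, config)
    cur <- br$mask
    ch <- closeSmallHoles(cur, root, config@holeMax)
    cur <- ch$mask
    stats["bridged"] <- stats["bridged"] + br$bridged
    stats["relabeled"] <- stats["relabeled"] + br$relabeled
    stats["filled"] <- stats["filled"] + ch$filled
  }
  list(mask = cur, roots = roots, stats = stats)
}
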