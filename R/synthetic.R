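#' SyntheticRootSpec: parameters of one simulated root
#'
#' Describes a Fluorol-Yellow-style root: an elongated, gently curving
#' ribbon whose hypocotyl-proximal zone is textured with small irregular
#' (periderm/phellem) cells and whose distal zone carries long rectangular
#' (endodermis) cells, with bright suberized cell walls on a dark field.
#' All sizes are in pixels.
#'
#' @slot totalLength extent of the generating curve (>= 10 x width).
#' @slot width ribbon width.
#' @slot peridermFraction fraction of arc length, hypocotyl-proximal,
#'   labeled periderm.
#' @slot curvatureAmplitude,curvaturePeriod sinusoidal perturbation of the
#'   root axis.
#' @slot peridermCellSize side of the small irregular cells.
#' @slot endodermCellLength,endodermCellWidth size of the long rectangular
#'   cells.
#' @slot lateralRootCount number of short lateral-root stubs in the distal
#'   zone.
#' @slot blurSigma Gaussian optical blur (image only).
#' @slot noiseSd Gaussian sensor noise sd (image only, intensity units).
#' @export
setClass("SyntheticRootSpec",
  representation(totalLength = "numeric", width = "numeric",
                 peridermFraction = "numeric", curvatureAmplitude = "numeric",
                 curvaturePeriod = "numeric", peridermCellSize = "numeric",
                 endodermCellLength = "numeric", endodermCellWidth = "numeric",
                 lateralRootCount = "integer", blurSigma = "numeric",
                 noiseSd = "numeric"),
  prototype(totalLength = 6000, width = 40, peridermFraction = 0.5,
            curvatureAmplitude = 80, curvaturePeriod = 3000,
            peridermCellSize = 12, endodermCellLength = 60,
            endodermCellWidth = 12, lateralRootCount = 1L, blurSigma = 1.5,
            noiseSd = 0.02),
  validity = function(object) {
    if (object@totalLength < 10 * object@width)
      return("totalLength must be at least 10 x width")
    if (object@peridermFraction < 0 || object@peridermFraction > 1)
      return("peridermFraction must be in [0, 1]")
    if (object@width < 3) return("width must be >= 3 px")
    if (object@curvaturePeriod <= 0) return("curvaturePeriod must be > 0")
    TRUE
  }
)

#' @rdname SyntheticRootSpec-class
#' @param totalLength,width,peridermFraction,curvatureAmplitude,curvaturePeriod
#'   see slots.
#' @param peridermCellSize,endodermCellLength,endodermCellWidth see slots.
#' @param lateralRootCount,blurSigma,noiseSd see slots.
#' @return A SyntheticRootSpec.
#' @export
syntheticRootSpec <- function(totalLength = 6000, width = 40,
                              peridermFraction = 0.5,
                              curvatureAmplitude = 80,
                              curvaturePeriod = 3000, peridermCellSize = 12,
                              endodermCellLength = 60, endodermCellWidth = 12,
                              lateralRootCount = 1L, blurSigma = 1.5,
                              noiseSd = 0.02) {
  new("SyntheticRootSpec", totalLength = totalLength, width = width,
      peridermFraction = peridermFraction,
      curvatureAmplitude = curvatureAmplitude,
      curvaturePeriod = curvaturePeriod, peridermCellSize = peridermCellSize,
      endodermCellLength = endodermCellLength,
      endodermCellWidth = endodermCellWidth,
      lateralRootCount = as.integer(lateralRootCount), blurSigma = blurSigma,
      noiseSd = noiseSd)
}

setMethod("show", "SyntheticRootSpec", function(object) {
  cat(sprintf(paste0("SyntheticRootSpec: length %g px, width %g px, ",
                     "periderm fraction %.2f, %d lateral stub(s)\n"),
              object@totalLength, object@width, object@peridermFraction,
              object@lateralRootCount))
})

# Cell-wall texture on curvilinear coordinates (s = arc position along the
# root, d = signed lateral offset). Walls are drawn as bright lines around
# jittered cell lattices; periderm cells are small in both directions,
# endodermis cells are long along s and narrow across.
.wallTexture <- function(s, d, class, spec) {
  g <- numeric(length(s))
  nearEdge <- function(u, period, half) {
    r <- (u %% period)
    pmin(r, period - r) < half
  }
  w2 <- spec@width / 2
  outer <- abs(d) > w2 - 1.6
  peri <- class == 1L
  endo <- class == 2L
  lat <- class == 3L
  if (any(peri)) {
    cp <- spec@peridermCellSize
    js <- 0.30 * cp * sin(d[peri] * 0.41 + 1.3) + 0.18 * cp * sin(d[peri] * 0.11)
    jd <- 0.30 * cp * sin(s[peri] * 0.33 + 0.7) + 0.18 * cp * sin(s[peri] * 0.09)
    wall <- nearEdge(s[peri] + js, cp, 0.9) | nearEdge(d[peri] + jd, cp * 0.9, 0.9)
    g[peri] <- ifelse(wall, 0.95, 0.38)
  }
  if (any(endo)) {
    le <- spec@endodermCellLength; we <- spec@endodermCellWidth
    js <- 0.12 * le * sin(d[endo] * 0.23 + 0.4)
    jd <- 0.15 * we * sin(s[endo] * 0.05 + 1.1)
    wall <- nearEdge(s[endo] + js, le, 1.0) | nearEdge(d[endo] + jd, we, 0.8)
    g[endo] <- ifelse(wall, 0.85, 0.20)
  }
  if (any(lat)) {
    cl <- max(4, spec@peridermCellSize * 0.8)
    wall <- nearEdge(s[lat], cl, 0.8) | nearEdge(d[lat], cl, 0.8)
    g[lat] <- ifelse(wall, 0.55, 0.15)
  }
  g[outer & peri] <- 0.95
  g[outer & endo] <- 0.85
  g
}

# Render one root (no blur/noise) onto its own tile using the current RNG.
# Returns green-channel tile, label tile, the generating-curve polyline in
# tile coordinates (1-based), and analytic truth lengths.
.renderRootRaw <- function(spec) {
  L <- spec@totalLength
  A <- spec@curvatureAmplitude
  w <- spec@width
  margin <- ceiling(w / 2) + 3
  tileW <- as.integer(2 * ceiling(A + w / 2) + 2 * margin + 1)
  tileH <- as.integer(ceiling(L + w + 2 * margin))
  cx <- (tileW - 1) / 2
  y0 <- margin
  phase <- runif(1, 0, 2 * pi)
  t <- seq(0, L, by = 1)
  x <- cx + A * sin(2 * pi * t / spec@curvaturePeriod + phase)
  y <- y0 + t
  sArc <- c(0, cumsum(sqrt(1 + diff(x)^2)))
  S <- sArc[length(sArc)]
  periLen <- spec@peridermFraction * S

  sw <- .sweep_curve_cpp(cbind(y, x), w, tileH, tileW)
  idx <- sw$index
  on <- idx > 0
  pixS <- sArc[idx[on]]
  pixD <- sw$lateral[on]
  cls <- rep(2L, sum(on))
  if (spec@peridermFraction >= 1) {
    cls[] <- 1L
  } else if (spec@peridermFraction > 0) {
    cls[pixS <= periLen] <- 1L
  }
  lab <- matrix(0L, tileH, tileW)
  lab[on] <- cls
  green <- matrix(0, tileH, tileW)
  green[on] <- .wallTexture(pixS, pixD, cls, spec)

  # lateral-root stubs: short perpendicular protrusions in the distal zone
  if (spec@lateralRootCount > 0 && spec@peridermFraction < 1) {
    stubLen <- 2.5 * w
    stubW <- max(3, 0.35 * w)
    lo <- max(periLen + 2 * w, 0)
    hi <- S - 3 * w
    for (k in seq_len(spec@lateralRootCount)) {
      if (lo >= hi) break
      sk <- runif(1, lo, hi)
      i <- which.min(abs(sArc - sk))
      side <- sample(c(-1, 1), 1)
      # unit normal to the curve at i
      i0 <- max(1, i - 1); i1 <- min(length(t), i + 1)
      tv <- c(y[i1] - y[i0], x[i1] - x[i0])
      tv <- tv / sqrt(sum(tv^2))
      nv <- side * c(-tv[2], tv[1])
      u <- seq(0, stubLen, by = 1)
      sr <- y[i] + nv[1] * u
      sc <- x[i] + nv[2] * u
      ssw <- .sweep_curve_cpp(cbind(sr, sc), stubW, tileH, tileW)
      newpx <- ssw$index > 0 & lab == 0L
      lab[newpx] <- 3L
      green[newpx] <- .wallTexture(ssw$dist[newpx] + sk, ssw$lateral[newpx],
                                   rep(3L, sum(newpx)), spec)
    }
  }
  list(green = green, labels = lab,
       centerline = cbind(row = y + 1, col = x + 1),
       peridermPx = periLen, wholePx = S, tileH = tileH, tileW = tileW)
}

# Compose RGB from a green channel, apply blur and sensor noise.
.composeImage <- function(green, blurSigma, noiseSd) {
  if (blurSigma > 0) green <- .gaussian_blur_cpp(green, blurSigma)
  H <- nrow(green); W <- ncol(green)
  base <- 0.02
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- 0.45 * green + 0.5 * base
  img[, , 2] <- green + base
  img[, , 3] <- 0.12 * green + 0.3 * base
  if (noiseSd > 0) img <- img + array(rnorm(length(img), 0, noiseSd), dim(img))
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate one synthetic root tile with exact ground truth
#'
#' Renders a single root (see [SyntheticRootSpec-class]) onto its own tile:
#' a smooth sinusoidally perturbed curve swept with the root width, textured
#' with class-specific cell-wall lattices, blurred and noised (image only --
#' the mask is exact). The analytic truth lengths are the arc length of the
#' generating curve and its periderm fraction.
#'
#' @param spec a [SyntheticRootSpec-class].
#' @param seed integer seed; output is a pure function of (spec, seed).
#' @return `list(image, mask, truth)` where `truth` holds `periderm_px`,
#'   `whole_px` and the generating-curve `centerline` (1-based (row, col)).
#' @export
generateRoot <- function(spec = syntheticRootSpec(), seed = 1L) {
  validObject(spec)
  withSeed(seed, {
    raw <- .renderRootRaw(spec)
    img <- .composeImage(raw$green, spec@blurSigma, spec@noiseSd)
    list(image = img, mask = LabelMask(raw$labels),
         truth = list(periderm_px = raw$peridermPx, whole_px = raw$wholePx,
                      centerline = raw$centerline))
  })
}

#' Generate a synthetic slide with up to 6 roots and a truth table
#'
#' Roots are laid out left to right with hypocotyls aligned to the top
#' edge, mimicking mounted root fragments. The default canvas is a
#' half-scale slide (7000 x 5400); tests use smaller canvases.
#'
#' @param nRoots number of roots (1..6).
#' @param spec a single [SyntheticRootSpec-class] (recycled) or a list of
#'   `nRoots` specs.
#' @param seed integer seed.
#' @param canvas `c(height, width)` in pixels.
#' @return `list(image, mask, truth, centerlines)`; `truth` is a data.frame
#'   (root_index, periderm_px, whole_px) ordered left to right.
#' @export
generateSlide <- function(nRoots = 6, spec = syntheticRootSpec(), seed = 1L,
                          canvas = c(7000, 5400)) {
  if (nRoots < 1 || nRoots > 6) stop("nRoots must be between 1 and 6")
  specs <- if (is.list(spec)) spec else rep(list(spec), nRoots)
  if (length(specs) != nRoots) stop("need one spec per root")
  H <- as.integer(canvas[1]); W <- as.integer(canvas[2])
  slot <- W / nRoots
  for (sp in specs) {
    validObject(sp)
    need <- 2 * (sp@curvatureAmplitude + sp@width / 2) + 8
    if (need > slot)
      stop("infeasible packing: root needs ", ceiling(need),
           " px of width but each of the ", nRoots, " slots has only ",
           floor(slot))
    if (sp@totalLength + sp@width + 8 > H)
      stop("infeasible packing: root length exceeds canvas height")
  }
  withSeed(seed, {
    green <- matrix(0, H, W)
    lab <- matrix(0L, H, W)
    truth <- data.frame(root_index = integer(0), periderm_px = numeric(0),
                        whole_px = numeric(0))
    centerlines <- list()
    for (i in seq_len(nRoots)) {
      raw <- .renderRootRaw(specs[[i]])
      c0 <- as.integer(round((i - 0.5) * slot - raw$tileW / 2))
      c0 <- max(0L, min(W - raw$tileW, c0))
      rows <- seq_len(raw$tileH)
      cols <- c0 + seq_len(raw$tileW)
      sel <- raw$labels != 0L
      subG <- green[rows, cols]
      subL <- lab[rows, cols]
      subG[sel] <- raw$green[sel]
      subL[sel] <- raw$labels[sel]
      green[rows, cols] <- subG
      lab[rows, cols] <- subL
      truth <- rbind(truth, data.frame(root_index = i,
                                       periderm_px = raw$peridermPx,
                                       whole_px = raw$wholePx))
      cl <- raw$centerline
      cl[, 2] <- cl[, 2] + c0
      centerlines[[i]] <- cl
    }
    bs <- max(vapply(specs, function(s) s@blurSigma, numeric(1)))
    ns <- max(vapply(specs, function(s) s@noiseSd, numeric(1)))
    img <- .composeImage(green, bs, ns)
    list(image = img, mask = LabelMask(lab), truth = truth,
         centerlines = centerlines)
  })
}

#' Plant segmentation defects into a truth mask
#'
#' Fixture maker for the postprocessing rules: plants centerline gaps
#' (periderm relabeled endodermis over a span of centerline positions) and
#' interior holes (periderm set to background over a compact pocket of a
#' given area), leaving everything else untouched.
#'
#' @param mask a truth [LabelMask-class].
#' @param root the [RootInstance-class] the defects refer to.
#' @param gaps list of `c(start, length)` centerline spans (positions).
#' @param holes list of `c(center, area)`: centerline position and hole
#'   area in pixels.
#' @param seed kept for API symmetry; the operation is deterministic.
#' @return the corrupted [LabelMask-class].
#' @export
corruptMask <- function(mask, root, gaps = list(), holes = list(), seed = 1L) {
  lab <- maskLabels(mask)
  m <- nrow(root@centerline)
  for (g in gaps) {
    span <- seq(g[1], g[1] + g[2] - 1)
    if (any(span < 1 | span > m)) stop("gap span outside the centerline")
    pix <- root@pixels[root@centerlineAssign %in% span, , drop = FALSE]
    if (nrow(pix) == 0 || any(lab[pix] != 1L))
      stop("gap span must lie inside the periderm region")
    lab[pix] <- 2L
  }
  for (h in holes) {
    ci <- h[1]; area <- h[2]
    if (ci < 1 || ci > m) stop("hole center outside the centerline")
    ctr <- root@centerline[ci, ]
    if (lab[ctr[1], ctr[2]] != 1L)
      stop("hole center must lie inside the periderm region")
    # take the `area` periderm pixels nearest the center
    pperi <- root@pixels[lab[root@pixels] == 1L, , drop = FALSE]
    d2 <- (pperi[, 1] - ctr[1])^2 + (pperi[, 2] - ctr[2])^2
    sel <- pperi[order(d2)[seq_len(area)], , drop = FALSE]
    # the hole must stay strictly interior to the periderm band
    trial <- lab
    trial[sel] <- 0L
    ring <- unique(do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
      expand.grid(r = sel[i, 1] + (-1:1), c = sel[i, 2] + (-1:1))
    })))
    ring <- as.matrix(ring)
    ring <- ring[!duplicated(ring), , drop = FALSE]
    ring <- ring[ring[, 1] >= 1 & ring[, 1] <= nrow(lab) &
                 ring[, 2] >= 1 & ring[, 2] <= ncol(lab), , drop = FALSE]
    inHole <- paste(ring[, 1], ring[, 2]) %in% paste(sel[, 1], sel[, 2])
    if (any(trial[ring[!inHole, , drop = FALSE]] != 1L))
      stop("hole of area ", area, " does not fit inside the periderm band")
    lab <- trial
  }
  LabelMask(lab, classMap(mask))
}
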