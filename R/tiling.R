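#' Cut a slide image or mask into fixed-size patches
#'
#' The slide is covered by a non-overlapping (default) row-major grid of
#' `patchSize` x `patchSize` patches; right and bottom edge patches are
#' padded with `padValue` to exactly `patchSize`. With `overlap > 0`
#' adjacent patches share `overlap` pixels.
#'
#' @param x H x W x C numeric array, matrix, or [LabelMask-class].
#' @param config a [TilingConfig-class].
#' @return `list(grid = PatchGrid, patches = list)`; patches are arrays /
#'   matrices / LabelMasks matching the input kind, in row-major order.
#' @export
#' @examples
#' tl <- tileImage(matrix(0L, 100, 80), tilingConfig(patchSize = 64))
#' tl$grid
tileImage <- function(x, config = tilingConfig()) {
  isMask <- is(x, "LabelMask")
  arr <- if (isMask) maskLabels(x) else x
  d <- dim(arr)
  H <- d[1]; W <- d[2]
  if (H < 1 || W < 1) stop("cannot tile an empty image")
  ps <- config@patchSize
  stride <- ps - config@overlap
  nR <- max(1L, as.integer(ceiling((H - config@overlap) / stride)))
  nC <- max(1L, as.integer(ceiling((W - config@overlap) / stride)))
  offs <- matrix(0L, nR * nC, 2)
  patches <- vector("list", nR * nC)
  k <- 0L
  for (i in seq_len(nR)) {
    for (j in seq_len(nC)) {
      k <- k + 1L
      r0 <- (i - 1L) * stride + 1L
      c0 <- (j - 1L) * stride + 1L
      offs[k, ] <- c(r0, c0)
      r1 <- min(H, r0 + ps - 1L)
      c1 <- min(W, c0 + ps - 1L)
      if (length(d) == 3) {
        p <- array(config@padValue, dim = c(ps, ps, d[3]))
        storage.mode(p) <- storage.mode(arr)
        p[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L), ] <-
          arr[r0:r1, c0:c1, , drop = FALSE]
      } else {
        p <- matrix(config@padValue, ps, ps)
        storage.mode(p) <- storage.mode(arr)
        p[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L)] <- arr[r0:r1, c0:c1]
      }
      patches[[k]] <- if (isMask) LabelMask(p, classMap(x)) else p
    }
  }
  grid <- new("PatchGrid", nRows = nR, nCols = nC, offsets = offs,
              height = as.integer(H), width = as.integer(W),
              patchSize = ps, overlap = config@overlap)
  list(grid = grid, patches = patches)
}

#' Stitch predicted patch masks back to slide scale
#'
#' Padding introduced at the right/bottom edges is discarded. With
#' overlapping grids, the later patch in row-major order wins on shared
#' pixels, keeping the mask pipeline integer-exact.
#'
#' @param grid the [PatchGrid-class] from [tileImage()].
#' @param patchMasks list of [LabelMask-class] / matrices, row-major order.
#' @return A [LabelMask-class] (or matrix) of the original slide size.
#' @export
stitchMasks <- function(grid, patchMasks) {
  n <- grid@nRows * grid@nCols
  if (length(patchMasks) != n)
    stop("patch count mismatch: expected ", n, ", received ", length(patchMasks))
  isMask <- is(patchMasks[[1]], "LabelMask")
  out <- matrix(0L, grid@height, grid@width)
  ps <- grid@patchSize
  for (k in seq_len(n)) {
    m <- maskLabels(patchMasks[[k]])
    r0 <- grid@offsets[k, 1]; c0 <- grid@offsets[k, 2]
    r1 <- min(grid@height, r0 + ps - 1L)
    c1 <- min(grid@width, c0 + ps - 1L)
    out[r0:r1, c0:c1] <- m[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L)]
  }
  if (isMask) LabelMask(out, classMap(patchMasks[[1]])) else out
}

#' Apply one of the eight square-symmetry (dihedral) transforms to a patch
#'
#' The transform set is `identity`, `rot90` (clockwise), `rot180`, `rot270`,
#' `hflip` (mirror columns), `vflip` (mirror rows), `transpose` and
#' `antitranspose`. Applied identically to an image and its mask, the pair
#' stays aligned. Rotations by 90 degrees require square patches.
#'
#' @param x matrix, H x W x C array, or [LabelMask-class].
#' @param mode one of the eight transform names.
#' @return transformed object of the same kind.
#' @export
#' @examples
#' augmentPatch(diag(3), "rot90")
augmentPatch <- function(x, mode = c("identity", "rot90", "rot180", "rot270",
                                     "hflip", "vflip", "transpose",
                                     "antitranspose")) {
  mode <- match.arg(mode)
  if (is(x, "LabelMask"))
    return(LabelMask(augmentPatch(maskLabels(x), mode), classMap(x)))
  if (length(dim(x)) == 3) {
    slices <- lapply(seq_len(dim(x)[3]), function(k) augmentPatch(x[, , k], mode))
    return(array(unlist(slices), dim = c(dim(slices[[1]]), dim(x)[3])))
  }
  H <- nrow(x); W <- ncol(x)
  if (mode %in% c("rot90", "rot270", "transpose", "antitranspose") && H != W)
    stop("90-degree rotations and transposes require a square patch")
  switch(mode,
    identity = x,
    rot90 = t(x[H:1, , drop = FALSE]),            # (r,c) -> (c, N-1-r)
    rot180 = x[H:1, W:1, drop = FALSE],
    rot270 = t(x)[W:1, , drop = FALSE],
    hflip = x[, W:1, drop = FALSE],
    vflip = x[H:1, , drop = FALSE],
    transpose = t(x),
    antitranspose = t(x[H:1, W:1, drop = FALSE]))
}
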