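# Seeded Chan-Vese segmentation, contour extraction, size filtering and the
# crude whole-image threshold variant.

#' Seed specification for region growing
#'
#' @param point numeric (x, y) seed position in pixels (x = column,
#'   y = row).
#' @param coreHalfwidth half-width in pixels of the initial core rectangle
#'   expanded around the seed (5-15 px).
#' @return a named list (class \code{"SeedSpec"}).
#' @export
seedSpec <- function(point, coreHalfwidth = 5L) {
  if (coreHalfwidth < 5L || coreHalfwidth > 15L)
    stop("coreHalfwidth must be in [5, 15] pixels")
  s <- list(point = as.numeric(point), coreHalfwidth = as.integer(coreHalfwidth))
  class(s) <- "SeedSpec"
  s
}

# replicate-pad neighbour shifts
.shiftUp    <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
.shiftDown  <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
.shiftLeft  <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
.shiftRight <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

# mean curvature of the level-set function, central differences
.curvature <- function(phi) {
  px <- (.shiftRight(phi) - .shiftLeft(phi)) / 2
  py <- (.shiftDown(phi) - .shiftUp(phi)) / 2
  pxx <- .shiftRight(phi) - 2 * phi + .shiftLeft(phi)
  pyy <- .shiftDown(phi) - 2 * phi + .shiftUp(phi)
  pxy <- (.shiftDown(.shiftRight(phi)) - .shiftDown(.shiftLeft(phi)) -
            .shiftUp(.shiftRight(phi)) + .shiftUp(.shiftLeft(phi))) / 4
  num <- pxx * py^2 - 2 * px * py * pxy + pyy * px^2
  den <- (px^2 + py^2)^1.5 + 1e-8
  num / den
}

#' Grow a cell surface mask from a seed (Chan-Vese active contour)
#'
#' Evolves a two-phase Chan-Vese active contour from a rectangular core
#' expanded \code{coreHalfwidth} pixels around a manually supplied seed
#' point until it reaches the cell boundary. The image is range-normalized
#' before evolution, so the result is invariant to uniform intensity
#' scaling. The connected region containing the seed is returned with
#' interior holes filled, as a surface mask.
#'
#' @param image numeric intensity matrix (rows x cols).
#' @param seed a [seedSpec()].
#' @param maxIterations maximum level-set iterations (default 200).
#' @param mu curvature (smoothness) weight.
#' @param convergeIter evolution stops when the binary mask is unchanged
#'   over this many consecutive iterations (default 5).
#' @param pixelSize micrometres per pixel, stored in the returned mask.
#' @param cellId,frame identifiers stored in the returned mask.
#' @return a [CellMask-class] of kind \code{"surface"}.
#' @examples
#' ph <- renderCellImage(scenePhantomParams(vesicularFraction = 0, seed = 3))
#' ctr <- dim(ph$image) / 2
#' m <- growCell(ph$image, seedSpec(c(ctr[2], ctr[1]), 6))
#' areaPx(m)
#' @export
growCell <- function(image, seed, maxIterations = 200L, mu = 0.2,
                     convergeIter = 5L, pixelSize = 1, cellId = "cell",
                     frame = 1L) {
  stopifnot(inherits(seed, "SeedSpec"))
  nr <- nrow(image); nc <- ncol(image)
  sx <- round(seed$point[1]); sy <- round(seed$point[2])
  if (sx < 1 || sx > nc || sy < 1 || sy > nr)
    stop("parameter error: seed outside image")
  hw <- seed$coreHalfwidth
  if (sx - hw < 1 || sx + hw > nc || sy - hw < 1 || sy + hw > nr)
    stop("parameter error: seed core rectangle not fully inside image")
  rng <- range(image)
  if (diff(rng) == 0)
    stop("segmentation failure: constant image has no boundary")
  I <- (image - rng[1]) / diff(rng)

  phi <- matrix(-1, nr, nc)
  phi[(sy - hw):(sy + hw), (sx - hw):(sx + hw)] <- 1
  eps <- 1
  stable <- 0L
  prevMask <- phi > 0
  for (it in seq_len(maxIterations)) {
    inside <- phi > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(I[inside]); c2 <- mean(I[!inside])
    delta <- eps / (pi * (phi^2 + eps^2))
    force <- delta * (mu * .curvature(phi) - (I - c1)^2 + (I - c2)^2)
    # normalized explicit step: typical strongly-driven pixels move 0.5
    # level units per iteration (quantile scaling resists hot pixels), so
    # boundary pixels flip within a few iterations
    sc <- 0.5 / (stats::quantile(abs(force), 0.95, names = FALSE) + 1e-12)
    phi <- phi + pmin(pmax(sc * force, -1), 1)
    phi <- pmin(pmax(phi, -3), 3)
    mask <- phi > 0
    if (identical(mask, prevMask)) {
      stable <- stable + 1L
      if (stable >= convergeIter) break
    } else stable <- 0L
    prevMask <- mask
  }
  mask <- phi > 0
  if (!any(mask))
    stop("segmentation failure: evolution collapsed to the empty set")
  lab <- EBImage::bwlabel(mask * 1L)
  seedLab <- lab[sy, sx]
  if (seedLab == 0) {
    # seed ended up outside the evolved region; take the nearest component
    ij <- which(lab > 0, arr.ind = TRUE)
    d2 <- (ij[, 1] - sy)^2 + (ij[, 2] - sx)^2
    seedLab <- lab[ij[which.min(d2), , drop = FALSE]]
  }
  comp <- lab == seedLab
  comp <- EBImage::fillHull(comp * 1L) > 0
  cellMask(comp, cellId = cellId, frame = frame, kind = "surface",
           pixelSize = pixelSize)
}

# box erosion by t pixels; outside-image counts as background
.erodeBox <- function(m, t) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (di in -t:t) for (dj in -t:t) {
    if (di == 0 && dj == 0) next
    sh <- matrix(FALSE, nr, nc)
    ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
    okR <- ri >= 1 & ri <= nr; okC <- ci >= 1 & ci <= nc
    sh[okR, okC] <- m[ri[okR], ci[okC]]
    out <- out & sh
  }
  out
}

#' Extract the contour band of a surface mask
#'
#' Returns the boundary band of a surface mask: the surface minus its
#' erosion by \code{thicknessPx} (box structuring element), i.e. the pixels
#' comprising the cell outline.
#'
#' @param surface a [CellMask-class] of kind \code{"surface"}.
#' @param thicknessPx band thickness in pixels (default 1).
#' @return a [CellMask-class] of kind \code{"contour"}.
#' @examples
#' sq <- matrix(FALSE, 7, 7); sq[2:6, 2:6] <- TRUE
#' areaPx(contourOf(cellMask(sq)))  # 16 boundary pixels of a 5x5 square
#' @export
contourOf <- function(surface, thicknessPx = 1L) {
  stopifnot(is(surface, "CellMask"))
  if (maskKind(surface) != "surface") stop("'surface' mask required")
  m <- maskPixels(surface)
  if (!any(m)) stop("surface mask is empty")
  er <- .erodeBox(m, as.integer(thicknessPx))
  if (!any(er))
    stop("degenerate-contour error: thickness >= mask inradius")
  cellMask(m & !er, cellId = surface@cellId, frame = surface@frame,
           kind = "contour", pixelSize = surface@pixelSize)
}

#' Remove small objects from a mask list
#'
#' Drops masks whose pixel area is strictly below \code{minAreaPx}
#' (objects exactly at the threshold are retained); order is preserved and
#' every exclusion is logged with its reason.
#'
#' @param masks list of [CellMask-class] objects.
#' @param minAreaPx minimum retained area in pixels (default 50, the size
#'   filter used to eliminate small false detections).
#' @return the filtered list.
#' @export
filterSmall <- function(masks, minAreaPx = 50L) {
  if (length(masks) == 0L) return(masks)
  keep <- vapply(masks, function(m) areaPx(m) >= minAreaPx, logical(1))
  for (m in masks[!keep])
    .logExclusion("filterSmall", m@cellId,
                  sprintf("area %d px < %d px", areaPx(m), minAreaPx))
  if (!any(keep)) warning("all objects below the size threshold")
  masks[keep]
}

#' Threshold-based whole-image segmentation
#'
#' Crude segmentation for dense time-lapse data: thresholds the whole
#' image, labels connected components (which may be multi-cell clusters),
#' fills holes and applies the small-object filter.
#'
#' @param image numeric intensity matrix.
#' @param threshold intensity threshold; pixels with intensity >= threshold
#'   are foreground.
#' @param minAreaPx small-object filter in pixels (default 50).
#' @param pixelSize micrometres per pixel.
#' @param frame frame index stored in the masks.
#' @return list of [CellMask-class] surface masks (possibly empty, with a
#'   warning when nothing exceeds the threshold).
#' @export
thresholdSegment <- function(image, threshold, minAreaPx = 50L,
                             pixelSize = 1, frame = 1L) {
  bw <- image >= threshold
  if (!any(bw)) {
    warning("threshold yields zero components")
    return(list())
  }
  lab <- EBImage::bwlabel(bw * 1L)
  nComp <- max(lab)
  if (nComp == 0) {
    warning("threshold yields zero components")
    return(list())
  }
  areas <- tabulate(lab[lab > 0], nbins = nComp)
  nSmall <- sum(areas < minAreaPx)
  if (nSmall > 0L)
    message(sprintf("[thresholdSegment] excluded %d component(s): area < %d px",
                    nSmall, minAreaPx))
  ids <- which(areas >= minAreaPx)
  if (length(ids) == 0L) {
    warning("all objects below the size threshold")
    return(list())
  }
  lapply(ids, function(i) {
    comp <- EBImage::fillHull((lab == i) * 1L) > 0
    cellMask(comp, cellId = as.character(i), frame = frame,
             kind = "surface", pixelSize = pixelSize)
  })
}

#' Centroid of a mask in physical units
#'
#' @param mask a [CellMask-class].
#' @return numeric (x, y) centroid in micrometres (pixel-centre convention).
#' @export
maskCentroid <- function(mask) {
  ij <- which(maskPixels(mask), arr.ind = TRUE)
  c(x = (mean(ij[, 2]) - 0.5) * mask@pixelSize,
    y = (mean(ij[, 1]) - 0.5) * mask@pixelSize)
}
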