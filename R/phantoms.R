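# Synthetic fluorescence scene generator: single-cell phantoms with a
# tunable membrane/vesicular split and multi-cell wound-gradient scenes.
#
# The phantom emulates a 2D maximum-intensity projection of a confocal
# stack: a cell with membrane-localized receptor projects to a smoothly
# shaded disk (projection passes through the membrane cap everywhere) with
# a modest rim enhancement, whereas internalized receptor appears as
# discrete endosomal puncta. Total integrated cell fluorescence is exactly
# conserved across the membrane/vesicular split, so downstream texture
# comparisons are not intensity artifacts.
#
# Image convention: matrices indexed [row, col]; physical x runs along
# columns, y along rows; pixel (r, c) has centre ((c-0.5), (r-0.5)) * pixelSize.

#' Parameters for a single-cell fluorescence phantom
#'
#' Defines a circular cell whose total integrated fluorescence is split
#' between a projected-membrane component (smoothly shaded disk with a rim
#' band) and a set of endosomal Gaussian puncta according to
#' \code{vesicularFraction}. Puncta have fixed per-punctum brightness and
#' their number grows with the vesicular fraction (the last punctum takes
#' the fractional remainder), so the texture response is close to linear in
#' the fraction while flux is conserved exactly. A constant
#' \code{diffuseFraction} of the flux is a smooth cytosolic pool shared by
#' both phenotypes. Intensities emulate a 16-bit microscopy image (clipped
#' at 65535).
#'
#' @param imageShape integer (rows, cols) of the rendered frame.
#' @param pixelSize micrometres per pixel.
#' @param cellRadius cell radius in micrometres.
#' @param membraneThickness thickness of the membrane rim band in
#'   micrometres.
#' @param vesicleCount maximum number of punctum sites (the number active
#'   scales with \code{vesicularFraction}).
#' @param vesicleSigma standard deviation of each punctum in micrometres
#'   (PSF-sized).
#' @param vesicleMinDist minimum centre-to-centre punctum spacing in
#'   micrometres (endosomes are spatially dispersed, not stacked).
#' @param vesicularFraction fraction of the trafficking receptor pool in
#'   puncta, in [0, 1]; 0 = fully membranous, 1 = fully vesicular.
#' @param diffuseFraction fraction of total flux in the smooth cytosolic
#'   pool, identical across phenotypes.
#' @param domeAmplitude amplitude of the central projection dome relative
#'   to the plateau (projection is brightest over the cell centre).
#' @param domeSigmaFrac dome width as a fraction of the cell radius.
#' @param rimBoost rim-band enhancement relative to the plateau.
#' @param edgeOffset distance (micrometres) beyond \code{cellRadius} at
#'   which the blurred cell edge sits; the nominal surface mask is
#'   conservative with respect to the fluorescent footprint.
#' @param edgeWidth logistic width of the blurred edge in micrometres.
#' @param backgroundLevel additive background intensity (counts).
#' @param totalFlux total integrated cell fluorescence (counts).
#' @param noiseModel one of \code{"gaussian"}, \code{"none"},
#'   \code{"poisson"}.
#' @param noiseSigmaFrac for gaussian noise, sigma as a fraction of the
#'   noise-free image maximum.
#' @param poissonScale for poisson noise, counts are drawn as
#'   \code{rpois(intensity / scale) * scale}.
#' @param seed integer RNG seed; identical seeds give bit-identical images.
#' @return a named list of validated parameters (class
#'   \code{"ScenePhantomParams"}).
#' @export
scenePhantomParams <- function(imageShape = c(64L, 64L), pixelSize = 0.5,
                               cellRadius = 10, membraneThickness = 1,
                               vesicleCount = 50L, vesicleSigma = 0.5,
                               vesicleMinDist = 1.8,
                               vesicularFraction = 0, diffuseFraction = 0.4,
                               domeAmplitude = 2, domeSigmaFrac = 0.6,
                               rimBoost = 0.3, edgeOffset = 0.75,
                               edgeWidth = 0.35, backgroundLevel = 100,
                               totalFlux = 2e5,
                               noiseModel = c("gaussian", "none", "poisson"),
                               noiseSigmaFrac = 0.005, poissonScale = 1,
                               seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  if (vesicularFraction < 0 || vesicularFraction > 1)
    stop("vesicularFraction must be in [0, 1]")
  if (diffuseFraction < 0 || diffuseFraction >= 1)
    stop("diffuseFraction must be in [0, 1)")
  if (cellRadius <= 0 || membraneThickness <= 0 || vesicleSigma <= 0)
    stop("cellRadius, membraneThickness and vesicleSigma must be positive")
  if (vesicularFraction > 0 && vesicleCount < 1L)
    stop("vesicularFraction > 0 requires vesicleCount >= 1")
  p <- list(imageShape = as.integer(imageShape), pixelSize = pixelSize,
            cellRadius = cellRadius, membraneThickness = membraneThickness,
            vesicleCount = as.integer(vesicleCount),
            vesicleSigma = vesicleSigma, vesicleMinDist = vesicleMinDist,
            vesicularFraction = vesicularFraction,
            diffuseFraction = diffuseFraction,
            domeAmplitude = domeAmplitude, domeSigmaFrac = domeSigmaFrac,
            rimBoost = rimBoost, edgeOffset = edgeOffset,
            edgeWidth = edgeWidth, backgroundLevel = backgroundLevel,
            totalFlux = totalFlux, noiseModel = noiseModel,
            noiseSigmaFrac = noiseSigmaFrac, poissonScale = poissonScale,
            seed = as.integer(seed))
  class(p) <- "ScenePhantomParams"
  p
}

# pixel-centre coordinate grids in micrometres
.pixelGrid <- function(shape, pixelSize) {
  rows <- shape[1]; cols <- shape[2]
  xs <- (seq_len(cols) - 0.5) * pixelSize
  ys <- (seq_len(rows) - 0.5) * pixelSize
  list(x = matrix(xs, rows, cols, byrow = TRUE),
       y = matrix(ys, rows, cols, byrow = FALSE))
}

# Poisson-disk punctum sites inside the eroded interior; draws from the
# current RNG stream; may return fewer than n sites at tight packings
.poissonDiskSites <- function(n, cx, cy, rMax, minDist, maxTries = 4000L) {
  px <- py <- numeric(0)
  tries <- 0L
  while (length(px) < n && tries < maxTries) {
    tries <- tries + 1L
    u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
    rad <- rMax * sqrt(u)
    qx <- cx + rad * cos(th); qy <- cy + rad * sin(th)
    if (!length(px) || all((px - qx)^2 + (py - qy)^2 >= minDist^2)) {
      px <- c(px, qx); py <- c(py, qy)
    }
  }
  cbind(px, py)
}

# noise-free cell fluorescence centred at (cx, cy) um, plus truth masks.
# Punctum sites are drawn from the current RNG stream.
.renderCellComponent <- function(grid, params, cx, cy) {
  r <- params$cellRadius; mt <- params$membraneThickness
  d <- sqrt((grid$x - cx)^2 + (grid$y - cy)^2)
  S <- 1 / (1 + exp((d - (r + params$edgeOffset)) / params$edgeWidth))
  mem <- S * (1 +
    params$domeAmplitude *
      exp(-d^2 / (2 * (params$domeSigmaFrac * r)^2)) +
    params$rimBoost *
      exp(-(d - (r - mt / 2))^2 / (2 * (mt / 2)^2)))
  if (sum(mem) <= 0) stop("cell does not fit in frame")
  mem <- mem / sum(mem)
  vf <- params$vesicularFraction
  ves <- 0 * d
  nSites <- 0L
  if (params$vesicleCount > 0L) {
    rMax <- max(r - 2 * mt, 0.1 * r)
    sites <- .poissonDiskSites(params$vesicleCount, cx, cy, rMax,
                               params$vesicleMinDist)
    nSites <- nrow(sites)
    # active-site weights: fixed-brightness puncta, count grows with vf,
    # the last active site takes the fractional remainder
    w <- pmin(pmax(vf * nSites - (seq_len(nSites) - 1L), 0), 1)
    for (k in which(w > 0)) {
      g <- exp(-((grid$x - sites[k, 1])^2 + (grid$y - sites[k, 2])^2) /
                 (2 * params$vesicleSigma^2))
      ves <- ves + w[k] * g / sum(g)
    }
    if (nSites > 0L) ves <- ves / nSites
  }
  dF <- params$diffuseFraction
  img <- params$totalFlux *
    (dF * mem + (1 - dF) * ((1 - vf) * mem + ves))
  surface <- d <= r
  contour <- d <= r & d >= r - mt
  list(image = img, surface = surface, contour = contour)
}

.applyNoiseAndQuantize <- function(img, params, nrow_) {
  if (params$noiseModel == "gaussian") {
    img <- img + stats::rnorm(length(img), 0,
                              params$noiseSigmaFrac * max(img))
  } else if (params$noiseModel == "poisson") {
    img <- stats::rpois(length(img), pmax(img, 0) / params$poissonScale) *
      params$poissonScale
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535  # 16-bit saturation: clip
  matrix(img, nrow = nrow_)
}

#' Render a single-cell fluorescence phantom
#'
#' Renders one cell centred in the frame with its fluorescence split
#' between a projected-membrane component and endosomal puncta, plus
#' ground-truth surface and contour masks. Total cell flux is independent
#' of \code{vesicularFraction} (exactly, before noise and integer
#' rounding), so the co-occurrence contrast of the vesicular phenotype can
#' be compared with the membranous phenotype at matched intensity.
#'
#' @param params a [scenePhantomParams()] list.
#' @return a list with elements \code{image} (numeric matrix, integer
#'   counts in 0..65535), \code{surfaceMask} and \code{contourMask}
#'   ([CellMask-class]), and \code{noiseFree} (the matrix before noise and
#'   quantization).
#' @examples
#' ph <- renderCellImage(scenePhantomParams(vesicularFraction = 1, seed = 7))
#' range(ph$image)
#' @export
renderCellImage <- function(params) {
  stopifnot(inherits(params, "ScenePhantomParams"))
  shape <- params$imageShape
  extent <- shape * params$pixelSize  # (rows, cols) -> (y, x)
  need <- 2 * (params$cellRadius + params$edgeOffset +
                 params$membraneThickness)
  if (need > extent[1] || need > extent[2])
    stop("cell does not fit in frame: increase imageShape or pixelSize")
  .withSeed(params$seed, {
    grid <- .pixelGrid(shape, params$pixelSize)
    cx <- extent[2] / 2; cy <- extent[1] / 2
    comp <- .renderCellComponent(grid, params, cx, cy)
    noiseFree <- comp$image + params$backgroundLevel
    img <- .applyNoiseAndQuantize(noiseFree, params, shape[1])
    list(image = img,
         surfaceMask = cellMask(comp$surface, cellId = "phantom",
                                kind = "surface",
                                pixelSize = params$pixelSize),
         contourMask = cellMask(comp$contour, cellId = "phantom",
                                kind = "contour",
                                pixelSize = params$pixelSize),
         noiseFree = noiseFree)
  })
}

#' Parameters for a wound-gradient scene
#'
#' Defines a multi-cell scene in which each cell's true vesicular fraction
#' decays exponentially with its distance from a wound-margin polyline:
#' \eqn{f_i = \exp(-d_i / \lambda)} with decay length \eqn{\lambda} (default
#' 200 micrometres, the spatial range over which receptor internalization
#' falls off from the wound). Cells are placed out to \code{maxDistance}
#' (default 500 micrometres, 2.5 decay lengths, enough span to identify
#' the decay length from the profile).
#'
#' @param woundMargin 2-column matrix of polyline vertices in micrometres;
#'   default a straight vertical margin at x = 0.
#' @param decayLength gradient decay length in micrometres (> 0).
#' @param nCells number of cells to place (>= 1).
#' @param maxDistance maximum cell distance from the margin in micrometres.
#' @param marginLength extent of the scene along the margin in micrometres.
#' @param minSeparation minimum centre-to-centre separation as a multiple
#'   of the cell diameter.
#' @param seed integer RNG seed.
#' @return a named list (class \code{"GradientSceneParams"}).
#' @export
gradientSceneParams <- function(woundMargin = NULL, decayLength = 200,
                                nCells = 40L, maxDistance = 500,
                                marginLength = 400, minSeparation = 1.05,
                                seed = 1L) {
  if (decayLength <= 0) stop("decayLength must be > 0")
  if (nCells < 1L) stop("nCells must be >= 1")
  if (is.null(woundMargin))
    woundMargin <- cbind(c(0, 0), c(0, marginLength))
  p <- list(woundMargin = as.matrix(woundMargin), decayLength = decayLength,
            nCells = as.integer(nCells), maxDistance = maxDistance,
            marginLength = marginLength, minSeparation = minSeparation,
            seed = as.integer(seed))
  class(p) <- "GradientSceneParams"
  p
}

#' Render a wound-gradient scene
#'
#' Places \code{nCells} non-overlapping cells at distances sampled
#' uniformly in \code{[0, maxDistance]} from the wound margin and renders
#' each with true vesicular fraction \eqn{\exp(-d/\lambda)}. Returns the
#' composite image, a label mask and the per-cell ground truth.
#'
#' @param params a [gradientSceneParams()] list.
#' @param phantom a [scenePhantomParams()] list giving the per-cell
#'   rendering parameters (its \code{vesicularFraction} and \code{seed}
#'   are overridden per cell).
#' @return list with \code{image} (counts matrix), \code{labels} (integer
#'   label matrix of true surface masks), \code{cells} (data.frame:
#'   \code{cell_id, x_um, y_um, distance_um, vesicular_fraction}),
#'   \code{pixelSize}, and \code{woundMargin} (in scene coordinates).
#' @export
renderGradientScene <- function(params, phantom = scenePhantomParams()) {
  stopifnot(inherits(params, "GradientSceneParams"),
            inherits(phantom, "ScenePhantomParams"))
  px <- phantom$pixelSize
  r <- phantom$cellRadius
  pad <- r + phantom$edgeOffset + phantom$membraneThickness + 2 * px
  width <- params$maxDistance + 2 * pad
  height <- params$marginLength
  shape <- c(ceiling(height / px), ceiling(width / px))
  margin <- cbind(params$woundMargin[, 1] + pad, params$woundMargin[, 2])
  .withSeed(params$seed, {
    minSep <- params$minSeparation * 2 * r
    xs <- ys <- ds <- numeric(0)
    for (i in seq_len(params$nCells)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        dTarget <- stats::runif(1, 0, params$maxDistance)
        yy <- stats::runif(1, pad, height - pad)
        xx <- dTarget + pad
        if (all(sqrt((xs - xx)^2 + (ys - yy)^2) >= minSep)) {
          dTrue <- distanceToPolyline(xx, yy, margin)
          xs <- c(xs, xx); ys <- c(ys, yy); ds <- c(ds, dTrue)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement error: cannot place ", params$nCells,
             " non-overlapping cells; reduce nCells or enlarge the scene")
    }
    vf <- exp(-ds / params$decayLength)
    img <- matrix(0, shape[1], shape[2])
    labels <- matrix(0L, shape[1], shape[2])
    # render each cell into a local tile for speed
    hwPx <- ceiling((r + phantom$edgeOffset + phantom$membraneThickness +
                       3 * phantom$edgeWidth) / px) + 2L
    for (i in seq_along(xs)) {
      pc <- phantom
      pc$vesicularFraction <- vf[i]
      cPx <- ceiling(xs[i] / px); rPx <- ceiling(ys[i] / px)
      rows <- max(1L, rPx - hwPx):min(shape[1], rPx + hwPx)
      cols <- max(1L, cPx - hwPx):min(shape[2], cPx + hwPx)
      tile <- list(
        x = matrix((cols - 0.5) * px, length(rows), length(cols),
                   byrow = TRUE),
        y = matrix((rows - 0.5) * px, length(rows), length(cols)))
      comp <- .renderCellComponent(tile, pc, xs[i], ys[i])
      img[rows, cols] <- img[rows, cols] + comp$image
      lab <- labels[rows, cols]
      lab[comp$surface] <- i
      labels[rows, cols] <- lab
    }
    noiseFree <- img + phantom$backgroundLevel
    out <- .applyNoiseAndQuantize(noiseFree, phantom, shape[1])
    list(image = out, labels = labels,
         cells = data.frame(cell_id = seq_along(xs), x_um = xs, y_um = ys,
                            distance_um = ds, vesicular_fraction = vf),
         pixelSize = px,
         woundMargin = margin)
  })
}
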