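# Receptor-internalization scoring: gray-level co-occurrence contrast over
# surface-segmented cells, reference normalizations, spatial gradient
# profiling, and the ratio metrics (membrane GFP/CFP, chemokine uptake).

#' Gray-level co-occurrence matrix over a masked cell region
#'
#' Linearly quantizes the intensities inside the mask to \code{nLevels}
#' gray levels over \code{quantRange} (default: the mask's own min..max,
#' which makes the downstream contrast invariant to affine intensity
#' transforms) and accumulates pair counts at the given pixel offset.
#' By default only pairs with \emph{both} pixels inside the mask
#' contribute, so the metric reflects intracellular heterogeneity rather
#' than the cell/background edge; \code{zeroFill = TRUE} instead treats
#' out-of-mask pixels as zero intensity and includes edge pairs, for
#' sensitivity analysis.
#'
#' @param image numeric intensity matrix.
#' @param mask a [CellMask-class] (surface) or logical matrix of the same
#'   dimensions as \code{image}.
#' @param nLevels number of gray levels N (default 8).
#' @param offset integer (dy, dx) displacement of the second pixel of each
#'   pair (default \code{c(0, 1)}: right neighbour).
#' @param symmetric if TRUE, pairs are accumulated in both directions.
#' @param quantRange intensity range used for quantization; default the
#'   min..max of the masked pixels. A constant region (min == max) maps
#'   entirely to level 0.
#' @param zeroFill include pairs crossing the mask edge, with out-of-mask
#'   intensities set to zero (default FALSE).
#' @return a [CoocMatrix-class].
#' @examples
#' img <- matrix(c(0, 0, 1, 1), 2, 2)      # two columns, two levels
#' coocProb(coocMatrix(img, matrix(TRUE, 2, 2), nLevels = 2))
#' @export
coocMatrix <- function(image, mask, nLevels = 8L, offset = c(0L, 1L),
                       symmetric = FALSE, quantRange = NULL,
                       zeroFill = FALSE) {
  m <- if (is(mask, "CellMask")) maskPixels(mask) else mask
  stopifnot(identical(dim(image), dim(m)))
  N <- as.integer(nLevels)
  if (sum(m) < 2L) stop("no-pair error: mask has < 2 pixels")
  # crop to the mask bounding box (plus the offset reach) for efficiency;
  # pair semantics are unchanged
  ij <- which(m, arr.ind = TRUE)
  mar <- max(abs(offset)) + 1L
  rr <- max(1L, min(ij[, 1]) - mar):min(nrow(m), max(ij[, 1]) + mar)
  cc <- max(1L, min(ij[, 2]) - mar):min(ncol(m), max(ij[, 2]) + mar)
  image <- image[rr, cc, drop = FALSE]
  m <- m[rr, cc, drop = FALSE]
  sel <- which(m)
  lo <- if (is.null(quantRange)) min(image[sel]) else quantRange[1]
  hi <- if (is.null(quantRange)) max(image[sel]) else quantRange[2]
  if (hi > lo) {
    q <- floor((image - lo) / (hi - lo) * N)
    q[q < 0] <- 0; q[q > N - 1L] <- N - 1L
  } else {
    q <- array(0, dim(image))  # constant region: everything at level 0
  }
  nr <- nrow(image); nc <- ncol(image)
  dy <- offset[1]; dx <- offset[2]
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rep(rows, times = nc); c1 <- rep(cols, each = nr)
  r2 <- r1 + dy; c2 <- c1 + dx
  ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
  i1 <- (c1 - 1L) * nr + r1
  i2 <- (c2 - 1L) * nr + r2
  i1 <- i1[ok]; i2 <- i2[ok]
  inPair <- if (zeroFill) m[i1] | m[i2] else m[i1] & m[i2]
  i1 <- i1[inPair]; i2 <- i2[inPair]
  if (length(i1) == 0L)
    stop("no-pair error: no valid in-mask pair at this offset")
  qv <- as.vector(q)
  if (zeroFill) {
    qz <- qv; qz[!as.vector(m)] <- 0
    g1 <- qz[i1]; g2 <- qz[i2]
  } else {
    g1 <- qv[i1]; g2 <- qv[i2]
  }
  counts <- matrix(tabulate(g1 * N + g2 + 1L, nbins = N * N), N, N,
                   byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  new("CoocMatrix", p = counts / sum(counts), nLevels = N,
      offset = as.integer(offset), symmetric = symmetric,
      quantRange = c(lo, hi))
}

#' Per-cell contrast with quality gates
#'
#' Scores a set of segmented cells on one image: builds the co-occurrence
#' matrix over each surface mask and computes the contrast. Cells failing
#' the configurable quality gates (too many saturated pixels, or dynamic
#' range narrower than a minimum number of quantization levels: the
#' "overly dim or overly bright" exclusions) are dropped and logged.
#'
#' @param image numeric intensity matrix.
#' @param masks list of [CellMask-class] surface masks.
#' @param maxSaturatedFrac reject a cell if more than this fraction of its
#'   pixels is at \code{saturation} (default 1\%).
#' @param saturation saturation intensity (default 65535, 16-bit).
#' @param minDynamicLevels reject a cell whose masked intensity range spans
#'   fewer than this many quantization levels of the full image range
#'   (default 4 of \code{nLevels}).
#' @param ... passed to [coocMatrix()].
#' @return data.frame with columns \code{cell_id, frame, raw_contrast}.
#' @export
contrastPerCell <- function(image, masks, maxSaturatedFrac = 0.01,
                            saturation = 65535, minDynamicLevels = 4L,
                            ...) {
  args <- list(...)
  nLevels <- if (is.null(args$nLevels)) 8L else args$nLevels
  rows <- lapply(masks, function(m) {
    px <- image[maskPixels(m)]
    if (mean(px >= saturation) > maxSaturatedFrac) {
      .logExclusion("contrast", m@cellId, "saturated (> 1% pixels at max)")
      return(NULL)
    }
    unsat <- image[image < saturation]
    fullRange <- if (length(unsat)) diff(range(unsat)) else 0
    if (fullRange > 0 &&
        diff(range(px)) < (minDynamicLevels / nLevels) * fullRange) {
      .logExclusion("contrast", m@cellId,
                    "dynamic range below minimum quantization span")
      return(NULL)
    }
    cm <- coocMatrix(image, m, ...)
    data.frame(cell_id = m@cellId, frame = m@frame,
               raw_contrast = glcmContrast(cm))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(), frame = integer(),
                      raw_contrast = numeric())
  out
}

#' Normalize contrast values
#'
#' Applies one of the two study normalizations: division by the mean
#' contrast of reference (non-mobilized, CHT) cells, or division by the
#' maximum contrast of the movie.
#'
#' @param values data.frame with a \code{raw_contrast} column (e.g. from
#'   [contrastPerCell()]).
#' @param mode \code{"cht_mean"}, \code{"movie_max"} or \code{"none"}.
#' @param referenceValues numeric vector of reference-cell raw contrasts
#'   (required for \code{cht_mean}).
#' @return the input data.frame with added columns
#'   \code{normalization_mode, reference_value, normalized_contrast}.
#' @examples
#' df <- data.frame(raw_contrast = c(2, 4))
#' normalizeContrast(df, "cht_mean", referenceValues = c(1, 3))
#' @export
normalizeContrast <- function(values,
                              mode = c("cht_mean", "movie_max", "none"),
                              referenceValues = NULL) {
  mode <- match.arg(mode)
  ref <- switch(mode,
    cht_mean = {
      if (is.null(referenceValues) || length(referenceValues) < 1L)
        stop("cht_mean normalization requires >= 1 reference cell")
      mean(referenceValues)
    },
    movie_max = {
      mx <- max(values$raw_contrast)
      if (!is.finite(mx) || mx <= 0)
        stop("movie_max normalization requires >= 1 positive value")
      mx
    },
    none = 1
  )
  if (ref == 0) stop("normalization error: zero divisor")
  values$normalization_mode <- mode
  values$reference_value <- ref
  values$normalized_contrast <- values$raw_contrast / ref
  values
}

#' Contrast-vs-distance gradient profile
#'
#' Assigns each cell its minimum Euclidean distance from the wound-margin
#' polyline and bins the normalized contrast by distance, reporting the
#' per-bin mean, SEM across cells, and n.
#'
#' @param centroids 2-column matrix or data.frame of cell centroids (x, y)
#'   in micrometres.
#' @param contrast numeric vector of (normalized) contrast values, one per
#'   centroid.
#' @param woundMargin 2-column matrix of margin polyline vertices.
#' @param binWidthUm distance bin width in micrometres (default 25).
#' @param maxDistanceUm upper edge of the last bin; default covers the data.
#' @return data.frame \code{bin_lo, bin_hi, mean, sem, n} (class
#'   \code{"GradientProfile"}); cells beyond the last bin edge are dropped.
#' @export
gradientProfile <- function(centroids, contrast, woundMargin,
                            binWidthUm = 25, maxDistanceUm = NULL) {
  cen <- as.matrix(centroids)
  if (nrow(cen) < 1L) stop("need >= 1 cell")
  d <- distanceToPolyline(cen[, 1], cen[, 2], woundMargin)
  if (is.null(maxDistanceUm))
    maxDistanceUm <- binWidthUm * ceiling(max(d) / binWidthUm + 1e-12)
  edges <- seq(0, maxDistanceUm, by = binWidthUm)
  if (edges[length(edges)] < maxDistanceUm)
    edges <- c(edges, maxDistanceUm)
  bin <- findInterval(d, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  keep <- bin >= 1 & bin <= length(edges) - 1
  prof <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    v <- contrast[keep & bin == b]
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               mean = if (length(v)) mean(v) else NA_real_,
               sem = .sem(v), n = length(v))
  }))
  attr(prof, "distances") <- d
  class(prof) <- c("GradientProfile", class(prof))
  prof
}

#' Fit an exponential decay length to a contrast-distance relation
#'
#' Fits \eqn{y = A \exp(-d/L) + B} by Levenberg-Marquardt least squares and
#' returns the decay length L in micrometres.
#'
#' @param distance numeric distances (micrometres).
#' @param value numeric response (e.g. normalized contrast).
#' @param startL starting value for L (default: half the distance range).
#' @return fitted decay length L (micrometres).
#' @export
fitDecayLength <- function(distance, value, startL = NULL) {
  ok <- is.finite(distance) & is.finite(value)
  d <- distance[ok]; y <- value[ok]
  if (length(d) < 4L) stop("need >= 4 points to fit a decay length")
  if (is.null(startL)) startL <- diff(range(d)) / 2
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-d / L) + B,
    start = list(A = max(y) - min(y), L = startL, B = min(y)),
    lower = c(A = 0, L = 1e-3, B = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  unname(stats::coef(fit)["L"])
}

#' Membrane GFP/CFP ratio, expression-normalized
#'
#' Ratio of mean receptor-GFP to mean control membrane-CFP over the contour
#' mask, divided by the same ratio over the whole image. The whole-image
#' normalization cancels expression-level differences between embryos, so a
#' value below 1 indicates selective loss of the receptor from the
#' membrane (internalization).
#'
#' @param gfpImage,cfpImage numeric intensity matrices of equal dimensions.
#' @param contour a [CellMask-class] of kind \code{"contour"} (or a logical
#'   matrix).
#' @return numeric normalized ratio.
#' @export
membraneRatio <- function(gfpImage, cfpImage, contour) {
  m <- if (is(contour, "CellMask")) maskPixels(contour) else contour
  if (!any(m)) stop("contour mask is empty")
  cfpIn <- mean(cfpImage[m]); cfpAll <- mean(cfpImage)
  if (cfpIn == 0 || cfpAll == 0 || mean(gfpImage) == 0)
    stop("ratio error: zero denominator")
  (mean(gfpImage[m]) / cfpIn) / (mean(gfpImage) / cfpAll)
}

#' Chemokine uptake score
#'
#' Mean ligand (mCherry) intensity inside the cell's GFP surface mask,
#' normalized by the mean intensity of a reference window on the
#' ligand-secreting transplant (150 x 150 px by convention), which cancels
#' expression differences between transplants.
#'
#' @param gfpMask a [CellMask-class] surface mask (or logical matrix).
#' @param mcherryImage numeric ligand-channel intensity matrix.
#' @param transplantRoi logical matrix of the reference window, or a list
#'   \code{list(row, col, size)} giving its top-left corner and side length
#'   in pixels (default size 150).
#' @return numeric normalized uptake.
#' @export
uptakeScore <- function(gfpMask, mcherryImage, transplantRoi) {
  m <- if (is(gfpMask, "CellMask")) maskPixels(gfpMask) else gfpMask
  if (!any(m)) stop("mask is empty")
  roi <- if (is.list(transplantRoi)) {
    sz <- if (is.null(transplantRoi$size)) 150L else transplantRoi$size
    r0 <- transplantRoi$row; c0 <- transplantRoi$col
    rr <- matrix(FALSE, nrow(mcherryImage), ncol(mcherryImage))
    rr[r0:min(r0 + sz - 1L, nrow(rr)), c0:min(c0 + sz - 1L, ncol(rr))] <- TRUE
    rr
  } else transplantRoi
  if (!any(roi)) stop("ROI is empty")
  ref <- mean(mcherryImage[roi])
  if (ref == 0) stop("uptake error: ROI mean is zero")
  mean(mcherryImage[m]) / ref
}
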