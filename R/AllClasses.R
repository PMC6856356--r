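#' @import methods
NULL

#' CellMask: a binary pixel mask for one segmented cell
#'
#' A \code{CellMask} holds the binary pixel mask of a single segmented cell
#' (or cell cluster), either as a \emph{surface} mask (all pixels inside the
#' cell outline, holes filled) or as a \emph{contour} mask (the boundary band
#' of the surface). Physical areas are derived from the pixel size.
#'
#' @slot cellId character, identifier of the cell or component.
#' @slot frame integer, time index of the frame the mask was derived from.
#' @slot pixels logical matrix, \code{TRUE} for mask pixels.
#' @slot kind character, either \code{"surface"} or \code{"contour"}.
#' @slot pixelSize numeric, physical pixel size in micrometres per pixel.
#'
#' @seealso [growCell()], [contourOf()], [thresholdSegment()], [areaPx()],
#'   [areaUm2()]
#' @exportClass CellMask
setClass("CellMask",
  representation(
    cellId    = "character",
    frame     = "integer",
    pixels    = "matrix",
    kind      = "character",
    pixelSize = "numeric"
  ),
  prototype(
    cellId = "cell", frame = 1L, kind = "surface", pixelSize = 1
  )
)

setValidity("CellMask", function(object) {
  msg <- character()
  if (!is.logical(object@pixels))
    msg <- c(msg, "'pixels' must be a logical matrix")
  if (!object@kind %in% c("surface", "contour"))
    msg <- c(msg, "'kind' must be \"surface\" or \"contour\"")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' CoocMatrix: a normalized gray-level co-occurrence matrix
#'
#' Holds the pair-frequency matrix \eqn{p(i,j)} of quantized intensities over
#' a masked cell region at a fixed pixel offset, together with the
#' quantization metadata. Row/column indices correspond to gray levels
#' \eqn{0 \ldots N-1}.
#'
#' @slot p numeric N x N matrix of pair frequencies summing to one.
#' @slot nLevels integer, number of gray levels N.
#' @slot offset integer length-2 vector \code{(dy, dx)}, the pixel
#'   displacement of the second pixel of each pair.
#' @slot symmetric logical, whether pairs were accumulated in both directions.
#' @slot quantRange numeric length-2 vector, the intensity range used for
#'   linear quantization.
#'
#' @seealso [coocMatrix()], [glcmContrast()]
#' @exportClass CoocMatrix
setClass("CoocMatrix",
  representation(
    p          = "matrix",
    nLevels    = "integer",
    offset     = "integer",
    symmetric  = "logical",
    quantRange = "numeric"
  )
)

setValidity("CoocMatrix", function(object) {
  msg <- character()
  N <- object@nLevels
  if (!identical(dim(object@p), c(as.integer(N), as.integer(N))))
    msg <- c(msg, "'p' must be an N x N matrix")
  if (any(object@p < 0))
    msg <- c(msg, "'p' must be non-negative")
  if (abs(sum(object@p) - 1) > 1e-9)
    msg <- c(msg, "'p' must sum to 1 (within 1e-9)")
  if (length(object@offset) != 2L)
    msg <- c(msg, "'offset' must be a length-2 integer vector (dy, dx)")
  if (length(msg)) msg else TRUE
})

#' OwaPolygon: the occupied wound area polygon
#'
#' A simple closed polygon, in micrometres, delimiting the area of the wound
#' occupied by the neutrophil cluster (owa). It is the geometric reference
#' for track classification, distance-to-wound and approach-angle metrics.
#' Points exactly on the boundary count as inside (closed polygon).
#'
#' @slot vertices numeric matrix with two columns (x, y) in micrometres,
#'   listing the polygon vertices in order; the polygon is implicitly closed.
#'
#' @seealso [owaPolygon()], [classifyTracks()], [stepRecords()]
#' @exportClass OwaPolygon
setClass("OwaPolygon",
  representation(vertices = "matrix")
)

.polygonArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

.segmentsIntersect <- function(p1, p2, p3, p4) {
  # proper intersection test for non-adjacent polygon edges
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.polygonSimple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (sharing a vertex) and the wrap pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segmentsIntersect(v[i, ], v[idx(i + 1L), ],
                             v[j, ], v[idx(j + 1L), ]))
        return(FALSE)
    }
  }
  TRUE
}

setValidity("OwaPolygon", function(object) {
  v <- object@vertices
  msg <- character()
  if (ncol(v) != 2L || nrow(v) < 3L)
    msg <- c(msg, "'vertices' must be a matrix with >= 3 rows and 2 columns")
  else {
    if (!all(is.finite(v)))
      msg <- c(msg, "vertices must be finite")
    else {
      if (.polygonArea(v) <= 0)
        msg <- c(msg, "polygon area must be > 0")
      if (!.polygonSimple(v))
        msg <- c(msg, "polygon must be simple (non-self-intersecting)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OwaPolygon
#'
#' @param vertices numeric matrix or data.frame with columns (x, y) in
#'   micrometres; vertices in order, polygon implicitly closed.
#' @return an [OwaPolygon-class] object.
#' @examples
#' owa <- owaPolygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' owaVertices(owa)
#' @export
owaPolygon <- function(vertices) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  new("OwaPolygon", vertices = v)
}

#' Construct a CellMask
#'
#' @param pixels logical matrix, \code{TRUE} for mask pixels.
#' @param cellId identifier for the cell.
#' @param frame integer time index.
#' @param kind \code{"surface"} or \code{"contour"}.
#' @param pixelSize micrometres per pixel.
#' @return a [CellMask-class] object.
#' @export
cellMask <- function(pixels, cellId = "cell", frame = 1L,
                     kind = c("surface", "contour"), pixelSize = 1) {
  kind <- match.arg(kind)
  new("CellMask", cellId = as.character(cellId), frame = as.integer(frame),
      pixels = pixels, kind = kind, pixelSize = pixelSize)
}
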