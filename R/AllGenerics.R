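#' Mask area in pixels
#'
#' @param object a [CellMask-class]
#' @return integer count of mask pixels.
#' @export
setGeneric("areaPx", function(object) standardGeneric("areaPx"))

#' Mask area in square micrometres
#'
#' @param object a [CellMask-class]
#' @return numeric area, \code{areaPx * pixelSize^2}.
#' @export
setGeneric("areaUm2", function(object) standardGeneric("areaUm2"))

#' Mask kind accessor
#'
#' @param object a [CellMask-class]
#' @return \code{"surface"} or \code{"contour"}.
#' @export
setGeneric("maskKind", function(object) standardGeneric("maskKind"))

#' Mask pixel matrix accessor
#'
#' @param object a [CellMask-class]
#' @return the logical pixel matrix.
#' @export
setGeneric("maskPixels", function(object) standardGeneric("maskPixels"))

#' Polygon vertex accessor
#'
#' @param object an [OwaPolygon-class]
#' @return numeric matrix of (x, y) vertices in micrometres.
#' @export
setGeneric("owaVertices", function(object) standardGeneric("owaVertices"))

#' Co-occurrence probability matrix accessor
#'
#' @param object a [CoocMatrix-class]
#' @return the N x N pair-frequency matrix.
#' @export
setGeneric("coocProb", function(object) standardGeneric("coocProb"))

#' GLCM contrast
#'
#' Computes the texture contrast \eqn{C = \sum_{i,j} |i-j|^2 p(i,j)} of a
#' gray-level co-occurrence matrix. Contrast is zero for spatially uniform
#' (all mass on the diagonal) intensity patterns and grows with the
#' punctate, vesicular intensity heterogeneity that accompanies receptor
#' internalization; its maximum for N levels is \eqn{(N-1)^2}.
#'
#' @param object a [CoocMatrix-class]
#' @return non-negative numeric scalar.
#' @examples
#' img <- matrix(rep(c(0, 1), each = 2), 2, 2)  # alternating columns
#' m <- coocMatrix(img, matrix(TRUE, 2, 2), nLevels = 2)
#' glcmContrast(m)  # 1
#' @export
setGeneric("glcmContrast", function(object) standardGeneric("glcmContrast"))

#' @rdname areaPx
setMethod("areaPx", "CellMask", function(object) sum(object@pixels))

#' @rdname areaUm2
setMethod("areaUm2", "CellMask",
          function(object) sum(object@pixels) * object@pixelSize^2)

#' @rdname maskKind
setMethod("maskKind", "CellMask", function(object) object@kind)

#' @rdname maskPixels
setMethod("maskPixels", "CellMask", function(object) object@pixels)

#' @rdname owaVertices
setMethod("owaVertices", "OwaPolygon", function(object) object@vertices)

#' @rdname coocProb
setMethod("coocProb", "CoocMatrix", function(object) object@p)

#' @rdname glcmContrast
setMethod("glcmContrast", "CoocMatrix", function(object) {
  N <- object@nLevels
  ij <- 0:(N - 1L)
  d2 <- outer(ij, ij, function(i, j) (i - j)^2)
  sum(d2 * object@p)
})

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask '%s' (frame %d, %s)\n", object@cellId, object@frame,
              object@kind))
  cat(sprintf("  %d x %d px, area %d px = %.2f um^2 (pixel size %g um)\n",
              nrow(object@pixels), ncol(object@pixels), areaPx(object),
              areaUm2(object), object@pixelSize))
})

setMethod("show", "CoocMatrix", function(object) {
  cat(sprintf("CoocMatrix: %d gray levels, offset (%d,%d), %s\n",
              object@nLevels, object@offset[1], object@offset[2],
              if (object@symmetric) "symmetric" else "non-symmetric"))
  cat(sprintf("  quantization range [%g, %g], contrast %.4f\n",
              object@quantRange[1], object@quantRange[2],
              glcmContrast(object)))
})

setMethod("show", "OwaPolygon", function(object) {
  v <- object@vertices
  cat(sprintf("OwaPolygon: %d vertices, area %.1f um^2\n",
              nrow(v), .polygonArea(v)))
})
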