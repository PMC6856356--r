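# Planar geometry against the owa polygon and wound-margin polylines.
# All routines are vectorized over query points; coordinates in micrometres.

#' Test points for inclusion in a polygon
#'
#' Ray-casting point-in-polygon test with closed-boundary semantics: points
#' lying exactly on an edge or vertex count as inside. This convention makes
#' owa entry/exit detection deterministic.
#'
#' @param x,y numeric vectors of query coordinates.
#' @param polygon an [OwaPolygon-class] or a 2-column vertex matrix.
#' @param eps absolute tolerance for the on-boundary test.
#' @return logical vector.
#' @export
pointInPolygon <- function(x, y, polygon, eps = 1e-9) {
  v <- if (is(polygon, "OwaPolygon")) polygon@vertices else as.matrix(polygon)
  n <- nrow(v)
  vx <- v[, 1]; vy <- v[, 2]
  vx2 <- c(vx[-1], vx[1]); vy2 <- c(vy[-1], vy[1])
  inside <- rep(FALSE, length(x))
  onb <- rep(FALSE, length(x))
  for (j in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx2[j]; y2 <- vy2[j]
    # on-segment: zero cross product and within bounding box
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    onb <- onb | (abs(cr) <= eps * max(len, 1) &
                    x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
                    y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps)
    # crossing-number toggle
    cross <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    cross[is.na(cross)] <- FALSE
    inside <- xor(inside, cross)
  }
  inside | onb
}

# distance and nearest point from (x, y) to each closed-polygon or open
# polyline edge set; returns list(dist, nx, ny)
.nearestOnSegments <- function(x, y, v, closed) {
  n <- nrow(v)
  vx <- v[, 1]; vy <- v[, 2]
  if (closed) {
    ax <- vx; ay <- vy; bx <- c(vx[-1], vx[1]); by <- c(vy[-1], vy[1])
  } else {
    ax <- vx[-n]; ay <- vy[-n]; bx <- vx[-1]; by <- vy[-1]
  }
  m <- length(ax)
  best <- rep(Inf, length(x)); nx <- x * 0; ny <- y * 0
  for (j in seq_len(m)) {
    dx <- bx[j] - ax[j]; dy <- by[j] - ay[j]
    l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) ((x - ax[j]) * dx + (y - ay[j]) * dy) / l2 else 0
    tt <- pmin(1, pmax(0, tt))
    px <- ax[j] + tt * dx; py <- ay[j] + tt * dy
    d2 <- (x - px)^2 + (y - py)^2
    take <- d2 < best
    best[take] <- d2[take]; nx[take] <- px[take]; ny[take] <- py[take]
  }
  list(dist = sqrt(best), nx = nx, ny = ny)
}

#' Nearest point on the owa perimeter
#'
#' For each query point, finds the exact nearest point on the polygon
#' perimeter (point-to-segment minimum over all edges) and the Euclidean
#' distance to it. The perimeter point is defined for interior points too,
#' although the distance-to-owa convention reported by [stepRecords()] is
#' zero inside.
#'
#' @param x,y numeric vectors of query coordinates (micrometres).
#' @param owa an [OwaPolygon-class].
#' @return a data.frame with columns \code{dist}, \code{nx}, \code{ny}.
#' @export
nearestPerimeterPoint <- function(x, y, owa) {
  v <- if (is(owa, "OwaPolygon")) owa@vertices else as.matrix(owa)
  r <- .nearestOnSegments(x, y, v, closed = TRUE)
  data.frame(dist = r$dist, nx = r$nx, ny = r$ny)
}

#' Distance from points to the owa
#'
#' Euclidean distance to the nearest owa-perimeter point, zero for points
#' inside or on the polygon (the convention used for distance binning and
#' zone membership).
#'
#' @inheritParams nearestPerimeterPoint
#' @return numeric vector of distances in micrometres.
#' @export
distanceToOwa <- function(x, y, owa) {
  d <- nearestPerimeterPoint(x, y, owa)$dist
  d[pointInPolygon(x, y, owa)] <- 0
  d
}

#' Distance from points to an open polyline
#'
#' Minimum point-to-segment distance to a polyline such as a wound margin.
#'
#' @param x,y numeric vectors of query coordinates (micrometres).
#' @param polyline 2-column matrix of polyline vertices (micrometres).
#' @return numeric vector of distances in micrometres.
#' @export
distanceToPolyline <- function(x, y, polyline) {
  v <- as.matrix(polyline)
  if (nrow(v) < 2L) stop("polyline needs >= 2 vertices")
  .nearestOnSegments(x, y, v, closed = FALSE)$dist
}
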