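# Biased persistent random walk generator for wound-recruitment movies.
# Walkers head toward the nearest owa-perimeter point with a von Mises
# concentration while within the bias range, dwell after entering the owa,
# and a fraction subsequently disperses. Ground-truth labels are emitted
# with every track.

#' Parameters for simulated wound-recruitment tracks
#'
#' @param nTracks number of walkers.
#' @param nFrames number of recorded time points per track (movie length).
#' @param dt acquisition interval in seconds (default 30, the standard
#'   confocal time-lapse interval for these movies).
#' @param meanSpeed mean instantaneous speed in micrometres/minute.
#' @param speedSd per-step speed standard deviation (micrometres/minute).
#' @param persistence directional correlation of the unbiased walk in
#'   [0, 1): the expected cosine of the turning angle between steps.
#' @param biasStrength von Mises concentration kappa (>= 0) of the heading
#'   toward the nearest owa-perimeter point while within \code{biasRange}.
#' @param biasRange range of the directional bias in micrometres (default
#'   200, matching the spatial range of the wound signalling gradient).
#' @param dwellFrames frames a walker dwells after entering the owa.
#' @param pReverse probability that a walker that entered the owa later
#'   leaves and performs an unbiased walk (dispersal), in [0, 1].
#' @param finPolygon [OwaPolygon-class] or vertex matrix; walkers are
#'   confined to this region (reflecting boundary).
#' @param speedCoupling optional orientation coupling \code{a} so that the
#'   step speed is \code{v0 * (1 + a * cos(theta))} with theta the angle to
#'   the nearest owa-perimeter point; default 0 (no coupling).
#' @param startDistance if non-NULL, walkers start at approximately this
#'   distance (micrometres) from the owa perimeter; otherwise uniformly in
#'   the fin outside the owa.
#' @param seed integer RNG seed; identical seeds give identical track sets.
#' @return a named list (class \code{"WalkerParams"}).
#' @export
walkerParams <- function(nTracks = 100L, nFrames = 240L, dt = 30,
                         meanSpeed = 8, speedSd = 2, persistence = 0.6,
                         biasStrength = 4, biasRange = 200,
                         dwellFrames = 10L, pReverse = 0.3,
                         finPolygon = NULL, speedCoupling = 0,
                         startDistance = NULL, seed = 1L) {
  if (biasStrength < 0) stop("biasStrength (kappa) must be >= 0")
  if (pReverse < 0 || pReverse > 1) stop("pReverse must be in [0, 1]")
  if (meanSpeed < 0 || speedSd < 0) stop("speeds must be >= 0")
  if (persistence < 0 || persistence >= 1)
    stop("persistence must be in [0, 1)")
  p <- list(nTracks = as.integer(nTracks), nFrames = as.integer(nFrames),
            dt = dt, meanSpeed = meanSpeed, speedSd = speedSd,
            persistence = persistence, biasStrength = biasStrength,
            biasRange = biasRange, dwellFrames = as.integer(dwellFrames),
            pReverse = pReverse, finPolygon = finPolygon,
            speedCoupling = speedCoupling, startDistance = startDistance,
            seed = as.integer(seed))
  class(p) <- "WalkerParams"
  p
}

# uniform sample inside polygon bounding box, rejected into the polygon
.samplePointsInPolygon <- function(n, poly, reject = NULL) {
  v <- if (is(poly, "OwaPolygon")) poly@vertices else as.matrix(poly)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- ys <- numeric(0)
  guard <- 0L
  while (length(xs) < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot sample points inside polygon")
    m <- 4L * (n - length(xs)) + 16L
    cx <- stats::runif(m, xr[1], xr[2]); cy <- stats::runif(m, yr[1], yr[2])
    ok <- pointInPolygon(cx, cy, v)
    if (!is.null(reject)) ok <- ok & !reject(cx, cy)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

#' Simulate labelled wound-recruitment tracks
#'
#' Each walker performs a persistent random walk confined to the fin
#' polygon; within \code{biasRange} of the owa its heading is drawn with
#' von Mises concentration \code{biasStrength} toward the nearest
#' owa-perimeter point. On entering the owa the walker dwells
#' \code{dwellFrames} frames, then with probability \code{pReverse} leaves
#' (initial heading pointing away from the owa centroid, then an unbiased
#' persistent walk that does not re-enter) or otherwise remains inside the
#' cluster. Ground-truth labels are recorded at generation time from the
#' realized geometry: \code{forward_intersecting},
#' \code{forward_then_reverse}, \code{nonintersecting_toward},
#' \code{nonintersecting_away}.
#'
#' @param params a [walkerParams()] list.
#' @param owa an [OwaPolygon-class]; must lie inside the fin polygon.
#' @return a data.frame with columns
#'   \code{track_id, t_s, x_um, y_um, label}.
#' @examples
#' fin <- owaPolygon(cbind(c(-200, 200, 200, -200), c(-200, -200, 200, 200)))
#' owa <- owaPolygon(cbind(c(-15, 15, 15, -15), c(-15, -15, 15, 15)))
#' tr <- simulateTracks(walkerParams(nTracks = 5, nFrames = 60, seed = 2,
#'                                   finPolygon = fin), owa)
#' table(tr$label[!duplicated(tr$track_id)])
#' @export
simulateTracks <- function(params, owa) {
  stopifnot(inherits(params, "WalkerParams"), is(owa, "OwaPolygon"))
  fin <- params$finPolygon
  if (is.null(fin)) stop("finPolygon is required")
  finV <- if (is(fin, "OwaPolygon")) fin@vertices else as.matrix(fin)
  if (!all(pointInPolygon(owa@vertices[, 1], owa@vertices[, 2], finV)))
    stop("owa must lie inside the fin polygon")
  n <- params$nTracks
  if (n == 0L)
    return(data.frame(track_id = integer(), t_s = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      label = character()))
  nf <- params$nFrames
  kp <- .kappaFromPersistence(params$persistence)
  dtMin <- params$dt / 60
  owaC <- colMeans(owa@vertices)

  .withSeed(params$seed, {
    if (is.null(params$startDistance)) {
      start <- .samplePointsInPolygon(n, finV,
        reject = function(px, py) pointInPolygon(px, py, owa))
    } else {
      sd0 <- params$startDistance
      start <- .samplePointsInPolygon(n, finV,
        reject = function(px, py) {
          d <- distanceToOwa(px, py, owa)
          d < 0.9 * sd0 | d > 1.1 * sd0
        })
    }
    x <- start[, 1]; y <- start[, 2]
    heading <- stats::runif(n, -pi, pi)
    # 0 approach, 1 dwell, 2 stay inside, 3 reverse
    state <- integer(n)
    dwellLeft <- integer(n)
    entered <- exited <- logical(n)
    revDesignated <- logical(n)
    X <- matrix(NA_real_, nf, n); Y <- matrix(NA_real_, nf, n)
    X[1, ] <- x; Y[1, ] <- y

    for (f in 2:nf) {
      npp <- nearestPerimeterPoint(x, y, owa)
      targetDir <- atan2(npp$ny - y, npp$nx - x)
      newHeading <- heading
      app <- state == 0L
      if (any(app)) {
        biased <- app & params$biasStrength > 0 & npp$dist <= params$biasRange
        if (any(biased))
          newHeading[biased] <- .rvonmises(sum(biased),
                                           0, params$biasStrength) +
            targetDir[biased]
        free <- app & !biased
        if (any(free))
          newHeading[free] <- heading[free] + .rvonmises(sum(free), 0, kp)
      }
      rev <- state == 3L
      if (any(rev))
        newHeading[rev] <- heading[rev] + .rvonmises(sum(rev), 0, kp)
      ins <- state == 2L
      if (any(ins))
        newHeading[ins] <- stats::runif(sum(ins), -pi, pi)

      v <- pmax(stats::rnorm(n, params$meanSpeed, params$speedSd), 0)
      if (params$speedCoupling != 0) {
        cosT <- cos(newHeading - targetDir)
        coupled <- state == 0L
        v[coupled] <- pmax(v[coupled] *
                             (1 + params$speedCoupling * cosT[coupled]), 0)
      }
      stepLen <- v * dtMin
      stepLen[state == 1L] <- 0  # dwelling walkers hold position

      nx <- x + stepLen * cos(newHeading)
      ny <- y + stepLen * sin(newHeading)

      # reflecting fin boundary: resample heading for offenders, else stay
      bad <- !pointInPolygon(nx, ny, finV)
      # dispersing and clustered walkers also respect the owa boundary
      bad <- bad | (state == 3L & pointInPolygon(nx, ny, owa)) |
        (state == 2L & !pointInPolygon(nx, ny, owa))
      tries <- 0L
      while (any(bad) && tries < 12L) {
        tries <- tries + 1L
        h2 <- stats::runif(sum(bad), -pi, pi)
        px <- x[bad] + stepLen[bad] * cos(h2)
        py <- y[bad] + stepLen[bad] * sin(h2)
        ok <- pointInPolygon(px, py, finV)
        okOwa <- rep(TRUE, sum(bad))
        sb <- state[bad]
        okOwa[sb == 3L] <- !pointInPolygon(px[sb == 3L], py[sb == 3L], owa)
        okOwa[sb == 2L] <- pointInPolygon(px[sb == 2L], py[sb == 2L], owa)
        acc <- ok & okOwa
        idx <- which(bad)[acc]
        nx[idx] <- px[acc]; ny[idx] <- py[acc]
        newHeading[idx] <- h2[acc]
        bad[idx] <- FALSE
      }
      nx[bad] <- x[bad]; ny[bad] <- y[bad]

      x <- nx; y <- ny; heading <- newHeading
      X[f, ] <- x; Y[f, ] <- y

      # state transitions
      nowIn <- pointInPolygon(x, y, owa)
      enterNow <- state == 0L & nowIn
      if (any(enterNow)) {
        entered[enterNow] <- TRUE
        state[enterNow] <- 1L
        dwellLeft[enterNow] <- params$dwellFrames
        revDesignated[enterNow] <- stats::runif(sum(enterNow)) < params$pReverse
      }
      dw <- state == 1L
      dwellLeft[dw] <- dwellLeft[dw] - 1L
      done <- dw & dwellLeft <= 0L
      if (any(done)) {
        toRev <- done & revDesignated
        state[done & !revDesignated] <- 2L
        if (any(toRev)) {
          state[toRev] <- 3L
          # dispersal kick: initial heading away from the owa centroid
          heading[toRev] <- atan2(y[toRev] - owaC[2], x[toRev] - owaC[1])
        }
      }
      exited[state == 3L & !nowIn] <- TRUE
    }

    # realized ground-truth labels
    label <- character(n)
    for (i in seq_len(n)) {
      if (!entered[i]) {
        d0 <- distanceToOwa(X[1, i], Y[1, i], owa)
        d1 <- distanceToOwa(X[nf, i], Y[nf, i], owa)
        label[i] <- if (d1 < d0) "nonintersecting_toward" else
          "nonintersecting_away"
      } else if (exited[i]) {
        label[i] <- "forward_then_reverse"
      } else {
        label[i] <- "forward_intersecting"
      }
    }
    data.frame(track_id = rep(seq_len(n), each = nf),
               t_s = rep((seq_len(nf) - 1) * params$dt, times = n),
               x_um = as.vector(X), y_um = as.vector(Y),
               label = rep(label, each = nf))
  })
}
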