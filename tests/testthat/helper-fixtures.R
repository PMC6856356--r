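# shared fixtures: tiny geometric images, polygons and a brute-force
# co-occurrence oracle, all built in code

# filled disk image on a flat background, plus its truth mask
makeDiskImage <- function(shape = c(80L, 80L), r = 10, px = 0.5,
                          lvl = 1000, bg = 100) {
  xs <- (seq_len(shape[2]) - 0.5) * px
  ys <- (seq_len(shape[1]) - 0.5) * px
  X <- matrix(xs, shape[1], shape[2], byrow = TRUE)
  Y <- matrix(ys, shape[1], shape[2])
  d <- sqrt((X - max(xs) / 2)^2 + (Y - max(ys) / 2)^2)
  list(img = ifelse(d <= r, lvl, bg), truth = d <= r,
       center = c(max(xs) / 2, max(ys) / 2))
}

squarePoly <- function(x0, x1, y0, y1) {
  owaPolygon(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

unitSquareOwa <- function() squarePoly(0, 10, 0, 10)

bigFin <- function(half = 300) squarePoly(-half, half, -half, half)

# build a track data.frame from x/y vectors at a fixed dt (seconds)
makeTrack <- function(id, x, y, dt = 30, t0 = 0) {
  data.frame(track_id = id, t_s = t0 + (seq_along(x) - 1) * dt,
             x_um = x, y_um = y)
}

# brute-force all-pairs co-occurrence oracle, independent of coocMatrix:
# explicit double loop over every pixel and its offset partner
bruteForceCooc <- function(image, mask, nLevels = 8L, offset = c(0L, 1L),
                           symmetric = FALSE) {
  sel <- image[mask]
  lo <- min(sel); hi <- max(sel)
  q <- if (hi > lo) {
    qq <- floor((image - lo) / (hi - lo) * nLevels)
    qq[qq > nLevels - 1] <- nLevels - 1
    qq
  } else array(0, dim(image))
  counts <- matrix(0, nLevels, nLevels)
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      i2 <- i + offset[1]; j2 <- j + offset[2]
      if (i2 < 1 || i2 > nrow(image) || j2 < 1 || j2 > ncol(image)) next
      if (!mask[i, j] || !mask[i2, j2]) next
      a <- q[i, j] + 1; b <- q[i2, j2] + 1
      counts[a, b] <- counts[a, b] + 1
      if (symmetric) counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) stop("no pairs")
  counts / sum(counts)
}

bruteForceContrast <- function(p) {
  N <- nrow(p)
  sum(outer(0:(N - 1), 0:(N - 1), function(i, j) (i - j)^2) * p)
}
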