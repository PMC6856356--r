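test_that("recruitment counting uses a closed 200x200 um square", {
  wc <- c(500, 500)
  expect_equal(recruitmentCount(cbind(500, 500), wc), 1)
  expect_equal(recruitmentCount(cbind(600, 500), wc), 1)   # on the boundary
  expect_equal(recruitmentCount(cbind(601, 500), wc), 0)   # 101 um off-centre
  pts <- cbind(c(500, 450, 550, 700, 200), c(500, 460, 580, 500, 500))
  expect_equal(recruitmentCount(pts, wc), 3)
  # an arbitrarily large square counts every centroid
  expect_equal(recruitmentCount(pts, wc, halfWidthUm = 1e9), nrow(pts))
  perFrame <- data.frame(x = c(500, 700), y = c(500, 500), frame = c(1, 2))
  out <- recruitmentCount(perFrame, wc)
  expect_equal(out$count, c(1, 0))
})

test_that("cluster size filters then averages areas", {
  rec <- data.frame(frame = 1, area_um2 = c(50, 70, 100))
  out <- suppressMessages(clusterSize(rec))
  expect_equal(out$mean, 85)
  expect_equal(out$excluded, 1)
  two <- data.frame(frame = c(1, 2), area_um2 = c(80, 120))
  expect_equal(clusterSize(two)$mean, 100)
  # area exactly at the threshold is retained
  edge <- data.frame(frame = 1, area_um2 = c(60, 100))
  expect_equal(clusterSize(edge)$mean, 80)
  low <- data.frame(frame = 1, area_um2 = c(10, 20))
  expect_warning(miss <- suppressMessages(clusterSize(low)), "retained")
  expect_true(is.na(miss$mean))
  expect_error(clusterSize(two, window = c(10, 20)), "window")
})

test_that("cluster size is permutation-invariant over frames", {
  rec <- data.frame(frame = c(1, 2, 3), area_um2 = c(80, 120, 95))
  perm <- rec[c(3, 1, 2), ]
  expect_equal(clusterSize(rec)$mean, clusterSize(perm)$mean)
})

test_that("time projections recover a stable bright region", {
  sq <- matrix(0, 60, 60); sq[20:40, 20:40] <- 10
  frames <- list(sq, sq * 0.9 + 1, sq)
  owa <- owaFromTimeProjection(frames, threshold = 5, pixelSize = 1)
  trueArea <- 21 * 21
  got <- NeutroTrack:::.polygonArea(owaVertices(owa))
  expect_lt(abs(got - trueArea) / trueArea, 0.1)
  # projection of identical frames equals any single frame
  expect_identical(Reduce(pmax, list(sq, sq, sq)), sq)
  # a moving cell leaves no stable component above the floor
  mv <- lapply(c(5, 25, 45), function(o) {
    m <- matrix(0, 60, 60); m[o + 0:4, 10:14] <- 10; m
  })
  expect_error(owaFromTimeProjection(mv, threshold = 5, minAreaPx = 200L),
               "area floor")
})
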