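test_that("track loading applies the duration and fin filters", {
  two <- makeTrack("a", c(0, 1), c(0, 0))
  three <- makeTrack("b", c(0, 1, 2), c(0, 0, 0))
  out <- suppressMessages(loadTracks(rbind(two, three)))
  expect_equal(unique(out$track_id), "b")   # 3 points retained, 2 dropped
  expect_equal(attr(out, "excluded")$track_id, "a")
  # points outside the fin are dropped before the duration filter
  five <- makeTrack("c", c(1, 2, 3, 500, 600), c(1, 1, 1, 1, 1))
  fin <- squarePoly(0, 100, 0, 100)
  kept <- suppressMessages(loadTracks(five, finPolygon = fin))
  expect_equal(nrow(kept), 3)
  # two in-fin points only -> whole track dropped
  fourOut <- makeTrack("d", c(1, 2, 500, 600), c(1, 1, 1, 1))
  expect_equal(nrow(suppressMessages(loadTracks(fourOut, finPolygon = fin))), 0)
})

test_that("malformed track tables raise data errors", {
  bad <- makeTrack("a", c(0, 1, 2), c(0, 0, 0))
  bad$t_s <- c(0, 30, 30)
  expect_error(loadTracks(bad), "non-monotone")
  nf <- makeTrack("a", c(0, NA, 2), c(0, 0, 0))
  expect_error(loadTracks(nf), "parse error")
  expect_error(loadTracks(data.frame(x = 1)), "required columns")
})

test_that("forward and reverse segments follow the entry/exit rules", {
  owa <- unitSquareOwa()
  # enters at point 6 (index 6), never leaves
  x1 <- c(30, 25, 20, 16, 12, 5, 5, 5)
  tr1 <- makeTrack("t1", x1, rep(5, 8))
  cl1 <- classifyTracks(tr1, owa)
  expect_equal(cl1$category, "forward_intersecting")
  expect_equal(c(cl1$fwd_start, cl1$fwd_end), c(1, 5))
  expect_true(is.na(cl1$rev_start))
  # outside [1..5], inside [6..10], outside [11..16]
  x2 <- c(30, 25, 20, 16, 12, 5, 5, 5, 5, 5, 12, 16, 20, 25, 30, 35)
  tr2 <- makeTrack("t2", x2, rep(5, 16))
  cl2 <- classifyTracks(tr2, owa)
  expect_equal(cl2$category, "reverse")
  expect_equal(c(cl2$fwd_start, cl2$fwd_end), c(1, 5))
  expect_equal(c(cl2$rev_start, cl2$rev_end), c(10, 16))
  # never intersects, end closer than start
  tr3 <- makeTrack("t3", c(80, 60, 40), rep(5, 3))
  expect_equal(classifyTracks(tr3, owa)$category, "forward_nonintersecting")
  tr4 <- makeTrack("t4", c(40, 60, 80), rep(5, 3))
  expect_equal(classifyTracks(tr4, owa)$category, "away_nonintersecting")
  # forward segments contain no in-owa point
  for (cl in list(cl1, cl2)) {
    seg <- seq(cl$fwd_start, cl$fwd_end)
    tr <- if (identical(cl, cl1)) tr1 else tr2
    expect_false(any(pointInPolygon(tr$x_um[seg], tr$y_um[seg], owa)))
  }
})

test_that("step records carry exact speeds, distances and cosines", {
  owa <- unitSquareOwa()
  # 5 um step east in 30 s, starting 15 um east of the owa -> toward it
  tr <- makeTrack("t", c(25, 20, 15, 15, 20), rep(5, 5))
  st <- stepRecords(tr, owa)
  expect_equal(st$v_t, c(10, 10, 0, 10))
  expect_equal(st$d_t, c(15, 10, 5, 5))
  expect_equal(st$cos_theta, c(1, 1, NA, -1))  # zero step -> undefined
  expect_false(any(st$inside_owa))
  # perpendicular step
  tp <- makeTrack("p", c(15, 15), c(5, 10))
  expect_equal(stepRecords(tp, owa)$cos_theta, 0)
  # start inside the owa: distance 0, cosine undefined
  ti <- makeTrack("i", c(5, 8), c(5, 5))
  sti <- stepRecords(ti, owa)
  expect_equal(sti$d_t, 0)
  expect_true(sti$inside_owa)
  expect_true(is.na(sti$cos_theta))
  # non-positive time step
  bad <- makeTrack("b", c(0, 1), c(0, 0)); bad$t_s <- c(10, 10)
  expect_error(stepRecords(bad, owa), "non-monotone|data error")
})

test_that("speed profiles bin constructed steps exactly", {
  owa <- unitSquareOwa()
  steps <- data.frame(track_id = rep(c("a", "b"), each = 2),
                      t = c(0, 30, 0, 30),
                      v_t = c(12, 12, 6, 6),
                      d_t = c(10, 20, 30, 40),
                      cos_theta = c(0.9, 0.9, -0.9, -0.9),
                      inside_owa = FALSE,
                      phase = "forward")
  cl <- data.frame(track_id = c("a", "b"), category = "forward_intersecting",
                   fwd_start = 1, fwd_end = 2, rev_start = NA, rev_end = NA)
  prof <- speedVsDistance(steps, cl, binEdges = c(0, 25, 50))
  expect_equal(prof$mean, c(12, 6))
  expect_equal(prof$sem, c(0, 0))
  expect_equal(prof$n, c(2, 2))
  # flat speeds give a flat profile
  flat <- steps; flat$v_t <- 10
  pf <- speedVsDistance(flat, cl, binEdges = c(0, 25, 50))
  expect_equal(pf$mean, c(10, 10))
  # single step in the cosine zone
  one <- data.frame(track_id = "a", t = 0, v_t = 7, d_t = 10,
                    cos_theta = 1, inside_owa = FALSE, phase = "forward")
  pc <- speedVsCosine(one)
  expect_equal(pc$mean[pc$n > 0], 7)
  expect_warning(speedVsCosine(one[0, ]), "empty")
})

test_that("per-step and per-cell aggregation agree for one step per bin", {
  steps <- data.frame(track_id = c("a", "b", "a", "b"),
                      t = c(0, 0, 30, 30),
                      v_t = c(4, 8, 10, 2),
                      d_t = c(10, 12, 30, 35),
                      cos_theta = 0.5, inside_owa = FALSE, phase = "forward")
  cl <- data.frame(track_id = c("a", "b"), category = "forward_intersecting",
                   fwd_start = 1, fwd_end = 2, rev_start = NA, rev_end = NA)
  p1 <- speedVsDistance(steps, cl, binEdges = c(0, 25, 50),
                        aggregation = "per_step")
  p2 <- speedVsDistance(steps, cl, binEdges = c(0, 25, 50),
                        aggregation = "per_cell")
  expect_equal(p1$mean, p2$mean)
})

test_that("straightness matches closed-form values", {
  owa <- unitSquareOwa()
  # straight path toward the owa, all points within the zone
  straightTr <- makeTrack("s", seq(30, 12, by = -2), rep(5, 10))
  s1 <- trackStraightness(straightTr, owa)
  expect_equal(s1$straightness, 1)
  # out-and-back: zero net displacement over 24 um
  oab <- makeTrack("o", c(20, 24, 28, 32, 28, 24, 20),
                   rep(5, 7))
  s2 <- trackStraightness(oab, owa)
  expect_equal(s2$straightness, 0)
  # L-path: 10 east then 10 north
  lp <- makeTrack("l", c(15, 20, 25, 25, 25), c(5, 5, 5, 10, 15))
  s3 <- trackStraightness(lp, owa)
  expect_equal(s3$straightness, sqrt(200) / 20, tolerance = 1e-12)
  # restricted path below 10 um is excluded with a reason
  short <- makeTrack("x", c(15, 16, 17), rep(5, 3))
  s4 <- suppressMessages(trackStraightness(short, owa))
  expect_true(s4$excluded)
  expect_match(s4$reason, "below minimum")
  # fewer than two zone points
  far <- makeTrack("f", c(200, 210, 220), rep(5, 3))
  s5 <- suppressMessages(trackStraightness(far, owa))
  expect_true(s5$excluded)
})

test_that("net reverse traffic counts entrants and leavers", {
  mk <- function(id, cat, fwd, rev)
    data.frame(track_id = id, category = cat,
               fwd_start = fwd[1], fwd_end = fwd[2],
               rev_start = rev[1], rev_end = rev[2])
  cl <- rbind(mk(1, "reverse", c(1, 4), c(8, 12)),
              mk(2, "reverse", c(1, 4), c(8, 12)),
              mk(3, "forward_intersecting", c(1, 4), c(NA, NA)),
              mk(4, "forward_intersecting", c(1, 4), c(NA, NA)),
              mk(5, "forward_nonintersecting", c(NA, NA), c(NA, NA)))
  out <- netReverseTraffic(cl)
  expect_equal(out$ratio, 0.5)
  expect_equal(out$n_forward_intersecting, 4)
  stay <- cl[3:4, ]
  expect_equal(netReverseTraffic(stay)$ratio, 0)
  none <- cl[5, , drop = FALSE]
  expect_warning(miss <- netReverseTraffic(none), "undefined")
  expect_true(is.na(miss$ratio))
})

test_that("net reverse traffic is invariant to relabeling and time shifts", {
  fin <- bigFin()
  owa <- squarePoly(-20, 20, -20, 20)
  tr <- simulateTracks(walkerParams(nTracks = 60, nFrames = 120,
                                    startDistance = 80,
                                    finPolygon = fin, seed = 31), owa)
  r1 <- netReverseTraffic(classifyTracks(suppressMessages(loadTracks(tr)), owa))
  tr2 <- tr
  tr2$track_id <- match(tr2$track_id, unique(tr2$track_id)) + 1000
  tr2$t_s <- tr2$t_s + 12345
  r2 <- netReverseTraffic(classifyTracks(suppressMessages(loadTracks(tr2)), owa))
  expect_equal(r1$ratio, r2$ratio)
})

test_that("speed within the owa averages in-owa steps only", {
  steps <- data.frame(track_id = "a", t = c(0, 30, 60),
                      v_t = c(4, 4, 9), d_t = c(0, 0, 12),
                      cos_theta = NA, inside_owa = c(TRUE, TRUE, FALSE),
                      phase = "unclassified")
  out <- speedWithinOwa(steps)
  expect_equal(out$mean, 4)
  expect_equal(out$n, 2)
  # brute-force oracle: filter then mean
  expect_equal(out$mean, mean(steps$v_t[steps$inside_owa]))
  none <- steps; none$inside_owa <- FALSE
  expect_warning(miss <- speedWithinOwa(none), "no steps")
  expect_true(is.na(miss$mean))
})
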