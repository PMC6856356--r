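test_that("phantom rendering is deterministic for a fixed seed", {
  p <- scenePhantomParams(vesicularFraction = 0.5, seed = 42)
  a <- renderCellImage(p)
  b <- renderCellImage(p)
  expect_identical(a$image, b$image)
  expect_identical(maskPixels(a$surfaceMask), maskPixels(b$surfaceMask))
})

test_that("integrated cell flux is conserved across the vesicular split", {
  base <- sum(renderCellImage(scenePhantomParams(
    vesicularFraction = 0, noiseModel = "none", seed = 1))$noiseFree)
  for (vf in c(0.17, 0.5, 0.83, 1)) {
    f <- sum(renderCellImage(scenePhantomParams(
      vesicularFraction = vf, noiseModel = "none", seed = 1))$noiseFree)
    expect_lt(abs(f - base) / base, 0.001)
  }
})

test_that("a fully membranous cell has a smooth interior", {
  ph <- renderCellImage(scenePhantomParams(vesicularFraction = 0,
                                           noiseModel = "none", seed = 2))
  interior <- maskPixels(ph$surfaceMask) & !maskPixels(ph$contourMask)
  img <- ph$noiseFree
  gx <- abs(img[, -1] - img[, -ncol(img)])
  gInt <- gx[interior[, -1] & interior[, -ncol(img)]]
  # interior gradients stay below 10% of the interior dynamic range per px
  expect_lt(max(gInt), 0.1 * diff(range(img[interior])))
})

test_that("phantoms that do not fit the frame are rejected", {
  expect_error(renderCellImage(scenePhantomParams(
    imageShape = c(20L, 20L), cellRadius = 10)), "fit")
  expect_error(scenePhantomParams(vesicularFraction = 1.2))
  expect_error(scenePhantomParams(vesicularFraction = 0.5, vesicleCount = 0))
})

test_that("gradient scenes carry an exponential ground-truth fraction", {
  sc <- renderGradientScene(gradientSceneParams(nCells = 10, seed = 5,
                                                maxDistance = 300,
                                                marginLength = 250))
  expect_equal(sc$cells$vesicular_fraction,
               exp(-sc$cells$distance_um / 200))
  # the analytic anchors of the decay law
  expect_equal(exp(-0 / 200), 1.0)
  expect_equal(exp(-200 / 200), exp(-1), tolerance = 1e-12)
  # placed cells stay within the requested band
  expect_true(all(sc$cells$distance_um >= 0 &
                    sc$cells$distance_um <= 300 + 1e-6))
  # labels mark exactly the placed cells
  expect_equal(sort(unique(sc$labels[sc$labels > 0])), 1:10)
})

test_that("impossible placements raise a placement error", {
  expect_error(renderGradientScene(gradientSceneParams(
    nCells = 200, maxDistance = 40, marginLength = 60, seed = 1)),
    "placement")
})

test_that("track simulation is deterministic and labels are sound", {
  fin <- bigFin()
  owa <- squarePoly(-20, 20, -20, 20)
  wp <- walkerParams(nTracks = 40, nFrames = 100, finPolygon = fin,
                     seed = 7)
  tr1 <- simulateTracks(wp, owa)
  tr2 <- simulateTracks(wp, owa)
  expect_identical(tr1, tr2)
  for (id in unique(tr1$track_id)) {
    s <- tr1[tr1$track_id == id, ]
    hasInside <- any(pointInPolygon(s$x_um, s$y_um, owa))
    lab <- s$label[1]
    if (lab %in% c("forward_intersecting", "forward_then_reverse"))
      expect_true(hasInside)
    else
      expect_false(hasInside)
  }
})

test_that("walker parameter validation rejects bad inputs", {
  fin <- bigFin()
  owa <- squarePoly(-20, 20, -20, 20)
  expect_error(walkerParams(biasStrength = -1))
  expect_error(walkerParams(pReverse = 1.5))
  expect_error(walkerParams(persistence = 1))
  expect_error(simulateTracks(walkerParams(nTracks = 2), owa),
               "finPolygon")
  # owa outside the fin
  expect_error(simulateTracks(
    walkerParams(nTracks = 2, finPolygon = squarePoly(100, 200, 100, 200)),
    owa), "inside")
})

test_that("zero requested tracks yield an empty labelled table", {
  fin <- bigFin()
  owa <- squarePoly(-20, 20, -20, 20)
  tr <- simulateTracks(walkerParams(nTracks = 0, finPolygon = fin), owa)
  expect_equal(nrow(tr), 0)
  expect_named(tr, c("track_id", "t_s", "x_um", "y_um", "label"))
})
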