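test_that("seeded active contour recovers a disk on flat background", {
  z <- makeDiskImage()
  m <- growCell(z$img, seedSpec(c(40, 40), 6), pixelSize = 0.5)
  jac <- sum(z$truth & maskPixels(m)) / sum(z$truth | maskPixels(m))
  expect_gte(jac, 0.9)
  expect_equal(maskKind(m), "surface")
  expect_equal(areaUm2(m), areaPx(m) * 0.25)
})

test_that("active contour is invariant to affine intensity rescaling", {
  z <- makeDiskImage()
  m1 <- growCell(z$img, seedSpec(c(40, 40), 6))
  m2 <- growCell(z$img * 7.3 + 11, seedSpec(c(40, 40), 6))
  expect_identical(maskPixels(m1), maskPixels(m2))
})

test_that("the grown region excludes disjoint objects", {
  z <- makeDiskImage()
  img <- z$img
  img[10:20, 5:15] <- 1000  # a second, disjoint bright blob
  m <- growCell(img, seedSpec(c(40, 40), 6))
  expect_equal(sum(maskPixels(m)[10:20, 5:15]), 0)
})

test_that("degenerate segmentation inputs raise errors", {
  expect_error(growCell(matrix(5, 50, 50), seedSpec(c(25, 25), 6)),
               "segmentation failure")
  z <- makeDiskImage()
  expect_error(growCell(z$img, seedSpec(c(500, 40), 6)), "parameter error")
  expect_error(growCell(z$img, seedSpec(c(3, 3), 6)), "parameter error")
  expect_error(seedSpec(c(10, 10), 3))   # core halfwidth below 5 px
  expect_error(seedSpec(c(10, 10), 16))  # above 15 px
})

test_that("contour extraction matches pixel enumeration", {
  sq <- matrix(FALSE, 7, 7); sq[2:6, 2:6] <- TRUE
  ct <- contourOf(cellMask(sq))
  expect_equal(areaPx(ct), 16)  # 5x5 solid square, 1-px boundary
  expect_equal(maskKind(ct), "contour")
  # contour is a subset of the surface
  expect_true(all(!maskPixels(ct) | sq))
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(contourOf(cellMask(one)), "degenerate")
})

test_that("disk contours leave a connected interior", {
  ph <- renderCellImage(scenePhantomParams(vesicularFraction = 0, seed = 3))
  ct <- contourOf(ph$surfaceMask)
  expect_true(all(!maskPixels(ct) | maskPixels(ph$surfaceMask)))
  interior <- maskPixels(ph$surfaceMask) & !maskPixels(ct)
  lab <- EBImage::bwlabel(interior * 1L)
  expect_equal(max(lab), 1)
})

test_that("the size filter removes strictly sub-threshold objects", {
  mk <- function(n) {
    m <- matrix(FALSE, 20, 20); m[seq_len(n)] <- TRUE
    cellMask(m, cellId = as.character(n))
  }
  masks <- lapply(c(49, 50, 51), mk)
  kept <- suppressMessages(filterSmall(masks))
  expect_equal(vapply(kept, areaPx, integer(1)), c(50L, 51L))
  # idempotence
  expect_identical(suppressMessages(filterSmall(kept)), kept)
  expect_identical(filterSmall(list()), list())
  expect_warning(suppressMessages(filterSmall(list(mk(10)))), "below")
})

test_that("threshold segmentation labels supra-threshold components", {
  img <- matrix(0, 60, 60)
  img[5:15, 5:15] <- 10     # 121 px
  img[30:40, 30:40] <- 10
  img[45:55, 5:15] <- 10
  masks <- thresholdSegment(img, 5)
  expect_length(masks, 3)
  expect_warning(out <- thresholdSegment(img, 99), "zero components")
  expect_length(out, 0)
})

test_that("threshold segmentation finds every placed phantom cell", {
  sc <- renderGradientScene(gradientSceneParams(nCells = 12, seed = 8,
                                                maxDistance = 300,
                                                marginLength = 300))
  masks <- suppressMessages(
    thresholdSegment(sc$image, 125, pixelSize = sc$pixelSize))
  expect_equal(length(masks), nrow(sc$cells))
})
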