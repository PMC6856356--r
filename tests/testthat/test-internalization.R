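test_that("co-occurrence construction matches enumerable cases", {
  # constant masked region: all mass at (0,0)
  cm <- coocMatrix(matrix(10, 10, 10), matrix(TRUE, 10, 10), nLevels = 8)
  expect_equal(coocProb(cm)[1, 1], 1)
  expect_equal(sum(coocProb(cm)), 1)
  # 2x2 image with rows (0,1),(0,1): the two horizontal pairs are (0,1)
  img <- matrix(c(0, 0, 1, 1), 2, 2)
  cm2 <- coocMatrix(img, matrix(TRUE, 2, 2), nLevels = 2)
  expect_equal(coocProb(cm2)[1, 2], 1)
  expect_equal(glcmContrast(cm2), 1)
  # no valid pair at the offset
  expect_error(coocMatrix(img, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                          nLevels = 2), "no-pair")
})

test_that("co-occurrence matrices match a brute-force oracle", {
  set.seed(101)
  for (k in 1:25) {
    img <- matrix(runif(256, 0, 1000), 16, 16)
    mask <- matrix(runif(256) < 0.7, 16, 16)
    if (sum(mask) < 4) next
    sym <- k %% 2 == 0
    oracle <- try(bruteForceCooc(img, mask, symmetric = sym), silent = TRUE)
    got <- try(coocMatrix(img, mask, symmetric = sym), silent = TRUE)
    if (inherits(oracle, "try-error")) {
      expect_s3_class(got, "try-error")
      next
    }
    expect_equal(coocProb(got), oracle, tolerance = 1e-9)
    expect_equal(glcmContrast(got), bruteForceContrast(oracle),
                 tolerance = 1e-9)
  }
})

test_that("contrast analytics follow the defining equation", {
  p <- matrix(0, 8, 8); p[1, 1] <- 1
  m <- new("CoocMatrix", p = p, nLevels = 8L, offset = c(0L, 1L),
           symmetric = FALSE, quantRange = c(0, 1))
  expect_equal(glcmContrast(m), 0)
  # diagonal-only mass
  pd <- diag(8) / 8
  md <- new("CoocMatrix", p = pd, nLevels = 8L, offset = c(0L, 1L),
            symmetric = FALSE, quantRange = c(0, 1))
  expect_equal(glcmContrast(md), 0)
  # the maximum possible contrast is (N-1)^2
  pm <- matrix(0, 8, 8); pm[1, 8] <- 1
  mm <- new("CoocMatrix", p = pm, nLevels = 8L, offset = c(0L, 1L),
            symmetric = FALSE, quantRange = c(0, 1))
  expect_equal(glcmContrast(mm), 49)
})

test_that("contrast is invariant to affine intensity transforms", {
  set.seed(7)
  img <- matrix(runif(400, 0, 100), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  c0 <- glcmContrast(coocMatrix(img, mask))
  c1 <- glcmContrast(coocMatrix(3.7 * img + 55, mask))
  expect_equal(c0, c1, tolerance = 1e-12)
})

test_that("vesicular phantoms outscore membranous phantoms", {
  cm <- cv <- numeric(8)
  for (s in 1:8) {
    pm <- renderCellImage(scenePhantomParams(vesicularFraction = 0, seed = s))
    pv <- renderCellImage(scenePhantomParams(vesicularFraction = 1, seed = s))
    cm[s] <- glcmContrast(coocMatrix(pm$image, pm$surfaceMask))
    cv[s] <- glcmContrast(coocMatrix(pv$image, pv$surfaceMask))
  }
  expect_true(all(cv > cm))
})

test_that("contrast normalization applies the stated references", {
  df <- data.frame(raw_contrast = c(2, 4))
  out <- normalizeContrast(df, "cht_mean", referenceValues = c(1, 3))
  expect_equal(out$normalized_contrast, c(1, 2))
  expect_equal(out$reference_value, c(2, 2))
  mm <- normalizeContrast(data.frame(raw_contrast = c(0.2, 0.5, 1.0)),
                          "movie_max")
  expect_equal(mm$normalized_contrast, c(0.2, 0.5, 1.0))
  same <- normalizeContrast(data.frame(raw_contrast = c(3, 3)),
                            "cht_mean", referenceValues = c(3, 3))
  expect_equal(same$normalized_contrast, c(1, 1))
  expect_error(normalizeContrast(df, "cht_mean"), "reference")
  expect_error(normalizeContrast(data.frame(raw_contrast = c(0, 0)),
                                 "movie_max"))
})

test_that("gradient profiles bin cells by distance from the margin", {
  margin <- cbind(c(0, 0), c(0, 100))
  prof <- gradientProfile(cbind(c(10, 30), c(50, 50)), c(1, 2), margin,
                          binWidthUm = 25)
  expect_equal(prof$n[1:2], c(1, 1))
  expect_equal(prof$mean[1:2], c(1, 2))
  expect_true(all(is.na(prof$sem[prof$n < 2])))
  one <- gradientProfile(cbind(0, 50), 1, margin, binWidthUm = 25)
  expect_equal(one$n[1], 1)
  expect_equal(attr(one, "distances"), 0)
})

test_that("membrane ratio cancels expression level", {
  ct <- matrix(FALSE, 10, 10); ct[3:4, 3:8] <- TRUE
  g <- matrix(5, 10, 10); c <- matrix(5, 10, 10)
  expect_equal(membraneRatio(g, c, cellMask(ct, kind = "contour")), 1)
  expect_equal(membraneRatio(2 * c, c, ct), 1)
  g2 <- matrix(10, 10, 10); g2[ct] <- 5  # receptor lost from the contour
  expect_lt(membraneRatio(g2, c, ct), 1)
  expect_error(membraneRatio(g, matrix(0, 10, 10), ct), "zero")
})

test_that("uptake scores normalize to the transplant window", {
  mk <- matrix(FALSE, 200, 200); mk[10:20, 10:20] <- TRUE
  img <- matrix(4, 200, 200)
  roi <- list(row = 40L, col = 40L, size = 150L)
  expect_equal(uptakeScore(cellMask(mk), img, roi), 1)
  img2 <- img; img2[mk] <- 8
  expect_equal(uptakeScore(cellMask(mk), img2, roi), 2)
  img3 <- img; img3[mk] <- 0
  expect_equal(uptakeScore(cellMask(mk), img3, roi), 0)
  expect_error(uptakeScore(cellMask(mk), matrix(0, 200, 200), roi), "zero")
})

test_that("decay-length fitting recovers a known exponential", {
  set.seed(3)
  d <- runif(60, 0, 500)
  y <- 1.5 * exp(-d / 200) + 0.2 + rnorm(60, 0, 0.02)
  expect_equal(fitDecayLength(d, y), 200, tolerance = 0.1)
})

test_that("quality gates exclude saturated and flat cells", {
  img <- matrix(runif(400, 0, 1000), 20, 20)
  sat <- matrix(FALSE, 20, 20); sat[1:5, 1:5] <- TRUE
  img[sat] <- 65535
  ok <- matrix(FALSE, 20, 20); ok[10:18, 10:18] <- TRUE
  msgs <- capture_messages(
    out <- contrastPerCell(img, list(cellMask(sat, cellId = "sat"),
                                     cellMask(ok, cellId = "ok"))))
  expect_equal(out$cell_id, "ok")
  expect_true(any(grepl("saturated", msgs)))
})
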