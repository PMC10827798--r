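test_that("automatic reference-lumen search recovers the planted dark lumens", {
  ph <- generatePhantom(phantomSpec(seed = 21L))
  w <- extractROI(ph@image, phantomROI(ph))
  ref <- findReferenceLumens(w)
  expect_identical(nrow(ref$lumens), 3L)
  found <- cbind(row = ref$lumens$row + w@rowOffset,
                 col = w@cols[ref$lumens$col])
  planted <- ph@referenceLumens
  for (i in seq_len(nrow(planted))) {
    d <- sqrt((found[, "row"] - planted$row[i])^2 +
              (found[, "col"] - planted$col[i])^2)
    expect_lt(min(d), 3)
  }
  # floor is calibrated near the dark reference tone, far below stroma
  expect_lt(ref$combinedMean, 60)
})

test_that("manual reference lumens bypass the search", {
  ph <- generatePhantom(smallPhantomSpec(seed = 22L))
  w <- extractROI(ph@image, phantomROI(ph))
  man <- data.frame(row = c(100, 110, 120), col = c(30, 90, 150))
  ref <- findReferenceLumens(w, manual = man)
  expect_identical(ref$mode, "manual")
  expect_equal(ref$combinedMean, mean(ref$lumens$meanReflectance))
  expect_identical(nrow(ref$lumens), 3L)
})

test_that("256-gradation rescale maps the floor to 0 and the max to 255", {
  m <- matrix(rep(c(40, 90, 140), length.out = 200 * 20), 200, 20)
  w <- toyWindow(m, top = 10, bottom = 190)
  w8 <- rescaleTo256(w, floor = 40)
  px <- pixels(w8)
  chor <- px[10:189, ]
  expect_identical(min(chor), 0)
  expect_identical(max(chor), 255)
  # monotone non-decreasing in input intensity
  expect_true(all(px[m == 40] <= px[m == 90][1]))
  expect_true(all(px[m == 90] <= px[m == 140][1]))
  expect_error(rescaleTo256(w, floor = 140), "degenerate intensity range")
})

test_that("lumen pixels land near zero after floor rescale of a phantom", {
  ph <- generatePhantom(smallPhantomSpec(seed = 23L, noiseSd = 0))
  w <- extractROI(ph@image, phantomROI(ph))
  w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
  lum <- maskLabels(ph@truthMask) == 2L
  expect_lt(stats::median(pixels(w8)[lum]), 30)
})

test_that("global threshold on separable two-level data recovers truth exactly", {
  set.seed(31)
  truthLumen <- matrix(runif(200 * 40) < 0.4, 200, 40)
  m <- ifelse(truthLumen, 40, 140)
  w <- toyWindow(m, top = 20, bottom = 180)
  mask <- binarizeChoroid(w, method = "global", threshold = 90)
  lab <- maskLabels(mask)
  inRoi <- lab != 0L
  expect_identical(lab[inRoi] == 2L, truthLumen[inRoi])
  rec <- thresholdRecord(mask)
  expect_identical(rec$method, "global")
  expect_identical(rec$threshold, 90)
})

test_that("a threshold below every pixel yields an all-stroma mask and L/C 0", {
  m <- matrix(200, 100, 30)
  w <- toyWindow(m, top = 10, bottom = 90)
  mask <- binarizeChoroid(w, method = "global", threshold = 50)
  expect_identical(sum(maskLabels(mask) == 2L), 0L)
  b <- flatBoundaries(1:30, 10, 30, 50, 90)
  met <- computeMetrics(layerMasks(b, w), mask, w)
  expect_true(all(met$lc_pct == 0))
})

test_that("ties at the threshold are labeled stroma", {
  m <- matrix(c(89, 90, 91), 30, 30)
  w <- toyWindow(m, top = 1, bottom = 30)
  lab <- maskLabels(binarizeChoroid(w, method = "global", threshold = 90))
  expect_true(all(lab[m == 90 & lab != 0] == 1L))
  expect_true(all(lab[m == 89 & lab != 0] == 2L))
})

test_that("raising a global threshold never shrinks the lumen set", {
  ph <- generatePhantom(smallPhantomSpec(seed = 24L))
  w <- extractROI(ph@image, phantomROI(ph))
  w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
  lowSet <- maskLabels(binarizeChoroid(w8, method = "global", threshold = 60)) == 2L
  highSet <- maskLabels(binarizeChoroid(w8, method = "global", threshold = 120)) == 2L
  expect_true(all(highSet[lowSet]))
})

test_that("Niblack parameters are validated and recorded", {
  ph <- generatePhantom(smallPhantomSpec(seed = 25L))
  w <- extractROI(ph@image, phantomROI(ph))
  w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
  expect_error(binarizeChoroid(w8, method = "niblack", niblackWindow = 24L),
               "window must be odd")
  mask <- binarizeChoroid(w8, method = "niblack")
  rec <- thresholdRecord(mask)
  expect_identical(rec$window, 25L)
  expect_equal(rec$k, -0.05)
  lab <- maskLabels(mask)
  expect_true(all(lab %in% 0:2))
})

test_that("default binarization recovers per-layer lumen fractions within 5 points", {
  ph <- generatePhantom(phantomSpec(seed = 26L))
  w <- extractROI(ph@image, phantomROI(ph))
  w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
  mask <- binarizeChoroid(w8)
  lab <- maskLabels(mask)
  truth <- maskLabels(ph@truthMask)
  masks <- layerMasks(ph@truthBoundaries, w8)
  for (ly in c("cc", "sl", "hl")) {
    est <- sum(masks[[ly]] & lab == 2L) / sum(masks[[ly]])
    tru <- sum(masks[[ly]] & truth == 2L) / sum(masks[[ly]])
    expect_lt(abs(est - tru), 0.05)
  }
  # label partition invariant
  expect_identical(sum(lab == 1L) + sum(lab == 2L), sum(truth != 0L))
})
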