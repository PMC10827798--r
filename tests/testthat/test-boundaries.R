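test_that("depth profile equals plain row means when all spans are equal", {
  set.seed(41)
  m <- matrix(runif(120 * 40, 0, 255), 120, 40)
  w <- toyWindow(m, top = 11, bottom = 61)
  pr <- depthProfile(w, nSamples = 50L)
  expect_equal(pr$profile, rowMeans(m[11:60, ]), tolerance = 1e-12)
  expect_equal(pr$resampleFactor, 1)
})

test_that("a constant row stays constant at its resampled position", {
  m <- matrix(10, 120, 40)
  m[36, ] <- 77     # row 26 of 50 within the span [11, 61)
  w <- toyWindow(m, top = 11, bottom = 61)
  pr <- depthProfile(w, nSamples = 50L)
  expect_equal(pr$profile[26], 77)
  expect_true(all(pr$profile[-26] <= 77))
})

test_that("three-band profiles reproduce the plateau means", {
  m <- rbind(matrix(90, 30, 60), matrix(60, 40, 60), matrix(30, 50, 60))
  w <- toyWindow(m, top = 1, bottom = 121)
  pr <- depthProfile(w, nSamples = 240L)
  expect_equal(stats::median(pr$profile[10:50]), 90, tolerance = 1)
  expect_equal(stats::median(pr$profile[70:130]), 60, tolerance = 1)
  expect_equal(stats::median(pr$profile[160:230]), 30, tolerance = 1)
  expect_error(depthProfile(toyWindow(m[1:3, , drop = FALSE], 1, 2)),
               "choroid too thin")
})

test_that("second-derivative changepoints localize slope breaks and steps", {
  ramp <- c(seq(0, 50, length.out = 51), rep(50, 50))   # slope break at 51
  cand <- profileChangepoints(ramp, smoothingSigma = 0)
  expect_true(any(abs(cand - 51) <= 1))

  expect_identical(length(profileChangepoints(rep(7, 60), smoothingSigma = 0)), 0L)

  step <- c(rep(10, 40), rep(60, 40))                   # step between 40 and 41
  cand2 <- profileChangepoints(step, smoothingSigma = 0)
  expect_true(any(abs(cand2 - 40.5) <= 1))
  expect_error(profileChangepoints(c(1, 2, 3)), "profile too short")
})

test_that("columnwise changepoints find a flat high-contrast boundary", {
  set.seed(42)
  m <- rbind(matrix(140, 179, 80), matrix(40, 121, 80)) +
       matrix(rnorm(300 * 80, 0, 5), 300, 80)
  w <- toyWindow(m, top = 100, bottom = 280)            # boundary at row 180
  pts <- columnChangepoints(w, 150, 210, smoothingSigma = 2)
  expect_gte(nrow(pts), 0.9 * 80)
  expect_gte(mean(abs(pts$row - 180) <= 3), 0.9)
})

test_that("structureless bands rarely produce qualifying changepoints", {
  set.seed(43)
  m <- matrix(rnorm(300 * 100, 100, 8), 300, 100)
  w <- toyWindow(m, top = 100, bottom = 280)
  pts <- columnChangepoints(w, 150, 210, smoothingSigma = 2)
  expect_lt(nrow(pts) / 100, 0.2)
})

test_that("a single-column window yields at most one point", {
  m <- matrix(c(rep(140, 150), rep(40, 150)), 300, 1)
  w <- toyWindow(m, top = 100, bottom = 280)
  pts <- columnChangepoints(w, 120, 250, smoothingSigma = 2)
  expect_lte(nrow(pts), 1L)
})

test_that("quadratic fits interpolate exact quadratics to 1e-9", {
  cols <- seq(50, 449)
  truth <- c(0.001, -0.5, 200)
  pts <- data.frame(col = cols, row = 0.001 * cols^2 - 0.5 * cols + 200)
  fit <- fitBoundaryQuadratic(pts)
  expect_equal(fit$coef, truth, tolerance = 1e-9)
  expect_lt(max(abs(fit$fitted(cols) - pts$row)), 1e-9)

  lin <- data.frame(col = cols, row = 2 * cols + 3)
  fitl <- fitBoundaryQuadratic(lin)
  expect_lt(abs(fitl$coef[1]), 1e-10)
  expect_equal(fitl$coef[2], 2, tolerance = 1e-9)

  expect_error(fitBoundaryQuadratic(data.frame(col = c(1, 1, 2),
                                               row = c(1, 2, 3))),
               "underdetermined fit")
})

test_that("noisy quadratic fits stay within 0.5 px RMS of truth", {
  set.seed(44)
  cols <- seq_len(400)
  truthRow <- 1e-4 * cols^2 - 0.04 * cols + 150
  rms <- replicate(20, {
    pts <- data.frame(col = cols, row = truthRow + rnorm(400, 0, 2))
    fit <- fitBoundaryQuadratic(pts)
    sqrt(mean((fit$fitted(cols) - truthRow)^2))
  })
  expect_lt(mean(rms), 0.5)
})

test_that("trim-free quadratic fit equals the normal-equation oracle", {
  set.seed(45)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    pts <- data.frame(col = runif(n, 1, 500), row = runif(n, 50, 400))
    fit <- fitBoundaryQuadratic(pts, trimSd = Inf)
    X <- cbind(pts$col^2, pts$col, 1)
    oracle <- solve(crossprod(X), crossprod(X, pts$row))
    expect_lt(max(abs(fit$coef - as.numeric(oracle))), 1e-8)
  }
})

test_that("boundaries of noise-free phantoms are recovered within a pixel", {
  for (s in c(61L, 62L)) {
    ph <- generatePhantom(phantomSpec(seed = s, noiseSd = 0))
    w <- extractROI(ph@image, phantomROI(ph))
    w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
    db <- detectBoundaries(w8)
    tb <- ph@truthBoundaries
    expect_lt(mean(abs(db@ccSl - tb@ccSl)), 1)
    expect_lt(mean(abs(db@slHl - tb@slHl)), 1)
    expect_true(all(db@rpeLower <= db@ccSl & db@ccSl <= db@slHl &
                    db@slHl <= db@csi))
  }
})

test_that("detection is equivariant to a vertical shift of the scan", {
  ph <- generatePhantom(phantomSpec(seed = 63L))
  w <- extractROI(ph@image, phantomROI(ph))
  w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
  db <- detectBoundaries(w8)

  s <- 7L
  w8s <- w8
  w8s@top <- w8@top + s
  w8s@bottom <- w8@bottom + s
  w8s@pixels <- rbind(matrix(0, s, ncol(w8@pixels)), w8@pixels)
  dbs <- detectBoundaries(w8s)
  expect_equal(dbs@ccSl, db@ccSl + s, tolerance = 1e-8)
  expect_equal(dbs@slHl, db@slHl + s, tolerance = 1e-8)
})

test_that("detection is invariant to positive intensity rescaling", {
  ph <- generatePhantom(phantomSpec(seed = 64L))
  w <- extractROI(ph@image, phantomROI(ph))
  w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
  db <- detectBoundaries(w8)
  w8x <- w8
  w8x@pixels <- w8@pixels * 1.7
  dbx <- detectBoundaries(w8x)
  expect_equal(dbx@ccSl, db@ccSl, tolerance = 1e-8)
  expect_equal(dbx@slHl, db@slHl, tolerance = 1e-8)
})

test_that("a zero-thickness Sattler layer never produces crossing boundaries", {
  spec <- phantomSpec(seed = 65L,
                      layerThicknessUm = c(cc = 16.2, sl = 0, hl = 170.4))
  ph <- suppressWarnings(generatePhantom(spec))
  w <- extractROI(ph@image, phantomROI(ph))
  w8 <- rescaleTo256(w, findReferenceLumens(w)$combinedMean)
  db <- tryCatch(suppressWarnings(detectBoundaries(w8)),
                 error = function(e) NULL)
  if (!is.null(db))
    expect_true(all(db@rpeLower <= db@ccSl & db@ccSl <= db@slHl &
                    db@slHl <= db@csi))
  else succeed("degenerate layer rejected with an error")
})
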