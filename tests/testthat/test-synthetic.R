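test_that("noise-free flat-boundary phantom has exact truth boundaries", {
  spec <- smallPhantomSpec(noiseSd = 0,
                           boundaryCurvature = c(rpe = 0, ccsl = 0,
                                                 slhl = 0, csi = 0))
  ph <- generatePhantom(spec)
  b <- ph@truthBoundaries
  ax <- spec$axialScale
  base <- 1 + spec$rpeDepthUm / ax
  th <- spec$layerThicknessUm
  expect_true(all(b@rpeLower == base))
  expect_true(all(b@ccSl == base + th[["cc"]] / ax))
  expect_true(all(b@slHl == base + (th[["cc"]] + th[["sl"]]) / ax))
  expect_true(all(b@csi == base + sum(th) / ax))
})

test_that("realized lumen fraction tracks the target in a large layer", {
  spec <- smallPhantomSpec(seed = 11L,
                           layerThicknessUm = c(cc = 16.2, sl = 72.7, hl = 400))
  ph <- generatePhantom(spec)
  lab <- maskLabels(ph@truthMask)
  masks <- layerMasks(ph@truthBoundaries, extractROI(ph@image, phantomROI(ph)))
  frac <- sum(masks$hl & lab == 2L) / sum(masks$hl)
  expect_lt(abs(frac - 0.633), 0.03)
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generatePhantom(smallPhantomSpec(seed = 5L))
  b <- generatePhantom(smallPhantomSpec(seed = 5L))
  expect_identical(pixels(a@image), pixels(b@image))
  expect_identical(maskLabels(a@truthMask), maskLabels(b@truthMask))
  expect_identical(a@truthMetrics, b@truthMetrics)
  c <- generatePhantom(smallPhantomSpec(seed = 6L))
  expect_false(identical(pixels(a@image), pixels(c@image)))
})

test_that("lumen plus stroma pixels partition the choroid ROI", {
  ph <- generatePhantom(smallPhantomSpec(seed = 2L))
  lab <- maskLabels(ph@truthMask)
  w <- extractROI(ph@image, phantomROI(ph))
  spans <- floor(w@bottom) - floor(w@top)
  expect_identical(sum(lab == 1L) + sum(lab == 2L), as.integer(sum(spans)))
})

test_that("raising the target lumen fraction strictly raises truth L/C", {
  lcs <- vapply(c(0.3, 0.5, 0.7), function(f) {
    spec <- smallPhantomSpec(seed = 3L,
                             lumenFraction = c(cc = 0.79, sl = 0.676, hl = f))
    m <- generatePhantom(spec)@truthMetrics
    m$lc_pct[m$layer == "hl"]
  }, numeric(1))
  expect_true(all(diff(lcs) > 0))
})

test_that("impossible geometry is rejected with informative errors", {
  expect_error(generatePhantom(smallPhantomSpec(rpeDepthUm = 700)),
               "geometry overflow")
  expect_error(
    generatePhantom(smallPhantomSpec(
      lumenRadiusUm = list(cc = c(30, 40), sl = c(8, 18), hl = c(25, 60)))),
    "lumen too large")
  expect_error(phantomSpec(noiseSd = -1), "noiseSd")
  expect_error(phantomSpec(intensity = c(lumen = 200, stroma = 140,
                                         sclera = 120, rpe = 220,
                                         retina = 20, refLumen = 30)),
               "strictly below")
})

test_that("cohort generator returns one record per subject", {
  coh <- generateCohort(cohortSpec(nSubjects = 189, seed = 1L),
                        mode = "parametric")
  expect_identical(nrow(coh$records), 189L)
  expect_identical(anyDuplicated(coh$records$subject_id), 0L)
  expect_error(cohortSpec(nSubjects = 1), "degenerate cohort")
})

test_that("null effect coefficients yield near-zero standardized betas", {
  eff <- lapply(cohortSpec()$effects, function(e) e * 0)
  coh <- generateCohort(cohortSpec(nSubjects = 500, effects = eff, seed = 9L),
                        mode = "parametric")
  for (resp in c("cc_ca", "hl_lc")) {
    sr <- standardizedRegression(coh$records, resp)
    expect_true(all(abs(sr$table$beta) < 0.1))
  }
})

test_that("a designed negative age effect shows up as negative correlation", {
  coh <- generateCohort(cohortSpec(nSubjects = 200, seed = 4L),
                        mode = "parametric")
  expect_lt(spearmanRho(coh$records$age, coh$records$hl_ca)$rho, 0)
})

test_that("second-rater simulation honours its noise and bias settings", {
  coh <- generateCohort(cohortSpec(nSubjects = 40, seed = 12L),
                        mode = "parametric")
  r0 <- simulateSecondRater(coh$records, sd = 0)
  icc <- iccTwoWay(r0$hl_ca, r0$hl_ca_r2)
  expect_equal(icc$iccSingle, 1)
  expect_equal(icc$iccMean, 1)

  rOff <- simulateSecondRater(coh$records, sd = 0.001,
                              fixedOffset = c(hl_ca = -0.05), seed = 2L)
  ba <- blandAltman(rOff$hl_ca, rOff$hl_ca_r2)
  expect_true(ba$fixedBias$ciLow > 0)  # r1 - r2 = +0.05

  rProp <- simulateSecondRater(coh$records, sd = 0.01,
                               proportional = c(hl_ca = 0.1), seed = 3L)
  ba2 <- blandAltman(rProp$hl_ca, rProp$hl_ca_r2)
  expect_lt(ba2$proportionalBias$r, 0)  # d = -0.1 * value, grows with mean
  expect_lt(ba2$proportionalBias$p, 0.05)

  expect_error(simulateSecondRater(coh$records, sd = -1), "invalid noise")
})

test_that("imaging mode renders one phantom per subject with truth attached", {
  coh <- generateCohort(cohortSpec(nSubjects = 2, seed = 8L), mode = "imaging",
                        phantomBase = smallPhantomSpec())
  expect_length(coh$phantoms, 2L)
  expect_s4_class(coh$phantoms[[1]], "ChoroidPhantom")
  th <- coh$phantoms[[1]]@spec$layerThicknessUm
  expect_equal(unname(th[["hl"]]), coh$truth$th_hl[1])
})
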