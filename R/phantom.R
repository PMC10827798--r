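#' Specification of a synthetic EDI-OCT choroid phantom
#'
#' Defines the geometry, vascular structure and intensity model of a
#' single-B-scan phantom.  Defaults emulate a healthy foveal choroid on a
#' common SD-OCT raster: sublayer thicknesses and luminal fractions follow
#' population means for the choriocapillaris (CC), Sattler's layer (SL) and
#' Haller's layer (HL), and vessel lumen caliber grows from CC to HL.
#' Reflectivity follows the OCT convention that vessel lumina are dark and
#' stroma bright.
#'
#' @param widthPx,heightPx image size in pixels (default 768 x 496).
#' @param lateralScale,axialScale um per pixel (defaults 3.9 and 1.95).
#' @param foveaCol fovea center column.
#' @param rpeDepthUm depth of the RPE lower edge below the image top at the
#'   fovea, in um.
#' @param rpeBandUm thickness of the bright RPE band, um.
#' @param layerThicknessUm named vector \code{c(cc=, sl=, hl=)} of sublayer
#'   thicknesses in um; defaults 16.2 / 72.7 / 170.4.
#' @param boundaryCurvature named vector of quadratic coefficients (rows per
#'   squared column offset from the fovea) for \code{rpe, ccsl, slhl, csi};
#'   zero gives flat boundaries.  The default bows all four boundaries
#'   gently and in parallel, as choroid layers run roughly parallel to the
#'   RPE over a 1500-um window.
#' @param lumenFraction named vector of target luminal pixel fractions per
#'   sublayer; defaults 0.790 / 0.676 / 0.633.
#' @param lumenRadiusUm named list of \code{c(min, max)} lateral lumen radii
#'   in um per sublayer; CC < SL < HL calibers by default.
#' @param lumenAspect axial/lateral radius ratio of the elliptical lumens
#'   (vessels appear flattened in B-scans; default 0.6).
#' @param intensity named gray levels (0-255): \code{lumen, stroma, sclera,
#'   rpe, retina, refLumen}; \code{refLumen} is the darker tone of the three
#'   planted reference lumens in HL.
#' @param noiseSd additive Gaussian noise sd in gray levels (default 10).
#' @param seed integer RNG seed; identical spec + seed reproduces the
#'   phantom bit for bit.
#' @return a list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(widthPx = 768L, heightPx = 496L,
                        lateralScale = 3.9, axialScale = 1.95,
                        foveaCol = 384L, rpeDepthUm = 200, rpeBandUm = 20,
                        layerThicknessUm = c(cc = 16.2, sl = 72.7, hl = 170.4),
                        boundaryCurvature = c(rpe = 1e-4, ccsl = 1e-4,
                                              slhl = 1e-4, csi = 1e-4),
                        lumenFraction = c(cc = 0.790, sl = 0.676, hl = 0.633),
                        lumenRadiusUm = list(cc = c(4, 8), sl = c(8, 18),
                                             hl = c(25, 60)),
                        lumenAspect = 0.6,
                        intensity = c(lumen = 40, stroma = 140, sclera = 120,
                                      rpe = 220, retina = 20, refLumen = 30),
                        noiseSd = 10, seed = 20240130L) {
  spec <- list(widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
               lateralScale = lateralScale, axialScale = axialScale,
               foveaCol = as.integer(foveaCol), rpeDepthUm = rpeDepthUm,
               rpeBandUm = rpeBandUm, layerThicknessUm = layerThicknessUm,
               boundaryCurvature = boundaryCurvature,
               lumenFraction = lumenFraction, lumenRadiusUm = lumenRadiusUm,
               lumenAspect = lumenAspect, intensity = intensity,
               noiseSd = noiseSd, seed = as.integer(seed))
  .validatePhantomSpec(spec)
  structure(spec, class = "phantomSpec")
}

.validatePhantomSpec <- function(spec) {
  layers <- c("cc", "sl", "hl")
  stopifnot(all(layers %in% names(spec$layerThicknessUm)),
            all(layers %in% names(spec$lumenFraction)),
            all(layers %in% names(spec$lumenRadiusUm)))
  if (any(spec$layerThicknessUm < 0)) stop("layer thicknesses must be >= 0")
  if (any(spec$lumenFraction < 0 | spec$lumenFraction > 1))
    stop("lumen fractions must lie in [0, 1]")
  if (spec$intensity["lumen"] >= spec$intensity["stroma"])
    stop("lumen mean must be strictly below stroma mean")
  if (spec$noiseSd < 0) stop("noiseSd must be >= 0")
  if (spec$lateralScale <= 0 || spec$axialScale <= 0) stop("scales must be > 0")
  invisible(TRUE)
}

# Boundary row curves (real-valued, 1-based, full image width) for a spec.
.phantomCurves <- function(spec) {
  d2 <- (seq_len(spec$widthPx) - spec$foveaCol)^2
  ax <- spec$axialScale
  th <- spec$layerThicknessUm
  base <- 1 + spec$rpeDepthUm / ax
  list(rpe  = base + spec$boundaryCurvature["rpe"] * d2,
       ccsl = base + th[["cc"]] / ax + spec$boundaryCurvature["ccsl"] * d2,
       slhl = base + (th[["cc"]] + th[["sl"]]) / ax +
              spec$boundaryCurvature["slhl"] * d2,
       csi  = base + sum(th) / ax + spec$boundaryCurvature["csi"] * d2)
}

# Rasterize one axis-aligned ellipse, returning flat indices into an
# nrow x ncol matrix, clipped to the image.
.ellipseIdx <- function(row0, col0, radRowPx, radColPx, nrow, ncol) {
  r <- seq(max(1L, floor(row0 - radRowPx)), min(nrow, ceiling(row0 + radRowPx)))
  c <- seq(max(1L, floor(col0 - radColPx)), min(ncol, ceiling(col0 + radColPx)))
  if (!length(r) || !length(c)) return(integer())
  inside <- outer(((r - row0) / radRowPx)^2, ((c - col0) / radColPx)^2, "+") <= 1
  cbindIdx <- which(inside, arr.ind = TRUE)
  (c[cbindIdx[, 2]] - 1L) * nrow + r[cbindIdx[, 1]]
}

# Fill one sublayer with random elliptical lumens until the realized luminal
# fraction is within +/-0.01 of target, or 200 rejected proposals elapse
# (then the closest achievable configuration is kept).
.fillLayer <- function(lumen, region, upper, lower, fraction, radRangeUm,
                       aspect, latScale, axScale) {
  total <- sum(region)
  if (total == 0 || fraction <= 0) return(lumen)
  nr <- nrow(region); ncl <- ncol(region)
  count <- sum(lumen & region)
  rejected <- 0L
  proposals <- 0L
  bestOver <- NULL
  bestOverDist <- Inf
  while (count / total < fraction - 0.002 && rejected < 200L && proposals < 50000L) {
    proposals <- proposals + 1L
    col0 <- stats::runif(1, 1, ncl)
    u <- upper[ceiling(col0 - 0.5)]; l <- lower[ceiling(col0 - 0.5)]
    if (l - u < 1) next
    row0 <- stats::runif(1, u, l)
    # near the target, cap the caliber so a fresh (non-overlapping) lumen
    # cannot overshoot: keeps acceptance spatially uniform instead of
    # preferentially filling already-covered areas
    allowedPx <- (fraction + 0.01 - count / total) * total
    radCap <- sqrt(allowedPx * latScale * axScale / (pi * aspect))
    radHi <- min(radRangeUm[2], max(radRangeUm[1], radCap))
    radUm <- stats::runif(1, radRangeUm[1], radHi)
    idx <- .ellipseIdx(row0, col0, aspect * radUm / axScale, radUm / latScale,
                       nr, ncl)
    idx <- idx[region[idx]]
    gain <- sum(!lumen[idx])
    newFrac <- (count + gain) / total
    if (newFrac <= fraction + 0.01) {
      lumen[idx] <- TRUE
      count <- count + gain
    } else {
      rejected <- rejected + 1L
      if (abs(newFrac - fraction) < bestOverDist) {
        bestOver <- idx
        bestOverDist <- abs(newFrac - fraction)
      }
    }
  }
  # rejection budget exhausted: accept whichever configuration lands closest
  if (count / total < fraction - 0.002 && !is.null(bestOver) &&
      bestOverDist < abs(count / total - fraction))
    lumen[bestOver] <- TRUE
  lumen
}

#' Generate a synthetic B-scan phantom with exact ground truth
#'
#' Renders a grayscale B-scan containing a bright RPE band, three stacked
#' choroidal sublayers populated with dark elliptical vessel lumens at the
#' per-layer target luminal fraction, and sclera below; adds Gaussian noise;
#' and returns the image together with its exact ground truth (boundaries,
#' lumen mask, per-layer metrics) over the 1500-um foveal analysis window.
#' Three darker "reference" lumens are planted well apart in Haller's layer
#' as the darkest structures of the scan, mirroring the manual selection of
#' representative dark lumens that calibrates the binarization floor.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return a \code{\linkS4class{ChoroidPhantom}}.
#' @export
generatePhantom <- function(spec) {
  if (!inherits(spec, "phantomSpec")) spec <- do.call(phantomSpec, spec)
  .validatePhantomSpec(spec)
  curves <- .phantomCurves(spec)
  H <- spec$heightPx; W <- spec$widthPx
  if (max(curves$csi) >= H + 1)
    stop("geometry overflow: choroid extends below the image")
  th <- spec$layerThicknessUm
  for (ly in c("cc", "sl", "hl")) {
    if (th[[ly]] > 0 &&
        2 * spec$lumenAspect * min(spec$lumenRadiusUm[[ly]]) > th[[ly]])
      stop("lumen too large: smallest ", ly, " lumen is taller than its layer")
  }

  rows <- seq_len(H)
  fl <- lapply(curves, floor)
  geAbove <- function(b) outer(rows, b, ">=")  # row at/below boundary raster
  inRPE <- outer(rows, floor(curves$rpe - spec$rpeBandUm / spec$axialScale), ">=") &
           !geAbove(fl$rpe)
  inChoroid <- geAbove(fl$rpe) & !geAbove(fl$csi)
  inSclera <- geAbove(fl$csi)

  layerRegion <- list(
    cc = geAbove(fl$rpe) & !geAbove(fl$ccsl),
    sl = geAbove(fl$ccsl) & !geAbove(fl$slhl),
    hl = geAbove(fl$slhl) & !geAbove(fl$csi))

  out <- .withSeed(spec$seed, {
    lumen <- matrix(FALSE, H, W)
    for (ly in c("cc", "sl", "hl")) {
      up <- switch(ly, cc = curves$rpe, sl = curves$ccsl, hl = curves$slhl)
      lo <- switch(ly, cc = curves$ccsl, sl = curves$slhl, hl = curves$csi)
      lumen <- .fillLayer(lumen, layerRegion[[ly]], up, lo,
                          spec$lumenFraction[[ly]], spec$lumenRadiusUm[[ly]],
                          spec$lumenAspect, spec$lateralScale, spec$axialScale)
    }

    # plant three extra-dark reference lumens in HL, spread across the ROI
    refCols <- spec$foveaCol + round(c(-500, 0, 500) / spec$lateralScale)
    refRadUm <- mean(spec$lumenRadiusUm$hl)
    refIdx <- integer()
    refRec <- data.frame(row = numeric(3), col = refCols,
                         radiusPx = refRadUm / spec$lateralScale)
    for (i in seq_along(refCols)) {
      cc <- refCols[i]
      row0 <- (curves$slhl[cc] + curves$csi[cc]) / 2
      refRec$row[i] <- row0
      idx <- .ellipseIdx(row0, cc, spec$lumenAspect * refRadUm / spec$axialScale,
                         refRadUm / spec$lateralScale, H, W)
      refIdx <- c(refIdx, idx[layerRegion$hl[idx]])
    }
    lumen[refIdx] <- TRUE

    img <- matrix(spec$intensity[["retina"]], H, W)
    img[inSclera] <- spec$intensity[["sclera"]]
    img[inChoroid] <- spec$intensity[["stroma"]]
    img[lumen & inChoroid] <- spec$intensity[["lumen"]]
    img[refIdx] <- spec$intensity[["refLumen"]]
    img[inRPE] <- spec$intensity[["rpe"]]
    if (spec$noiseSd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec$noiseSd), H, W)
    img <- pmin(pmax(round(img), 0), 255)
    list(img = img, lumen = lumen, refRec = refRec)
  })

  bscan <- new("BScan", pixels = out$img, bitDepth = 8L,
               lateralScale = spec$lateralScale, axialScale = spec$axialScale)
  roi <- roiSpec(spec$foveaCol, top = curves$rpe, bottom = curves$csi,
                 widthUm = 1500)
  window <- extractROI(bscan, roi)

  cols <- window@cols
  d2c <- function(a, base) c(a, -2 * a * spec$foveaCol,
                             base + a * spec$foveaCol^2)
  ax <- spec$axialScale
  base0 <- 1 + spec$rpeDepthUm / ax
  truthB <- new("LayerBoundaries", cols = cols,
                rpeLower = curves$rpe[cols], ccSl = curves$ccsl[cols],
                slHl = curves$slhl[cols], csi = curves$csi[cols],
                coef = list(
                  ccSl = d2c(spec$boundaryCurvature[["ccsl"]], base0 + th[["cc"]] / ax),
                  slHl = d2c(spec$boundaryCurvature[["slhl"]],
                             base0 + (th[["cc"]] + th[["sl"]]) / ax),
                  residualSd = c(ccSl = 0, slHl = 0)))

  chor <- .choroidMask(window)
  lumenWin <- out$lumen[window@rowOffset + seq_len(nrow(window@pixels)), cols]
  labels <- matrix(0L, nrow(window@pixels), ncol(window@pixels))
  labels[chor] <- 1L
  labels[chor & lumenWin] <- 2L
  truthMask <- new("ChoroidMask", labels = labels,
                   thresholdRecord = list(method = "truth"))

  lm_ <- layerMasks(truthB, window)
  truthMetrics <- computeMetrics(lm_, truthMask, window)

  new("ChoroidPhantom", image = bscan,
      roi = list(foveaCol = spec$foveaCol, widthUm = 1500,
                 top = curves$rpe, bottom = curves$csi),
      truthBoundaries = truthB, truthMask = truthMask,
      truthMetrics = truthMetrics, referenceLumens = out$refRec,
      spec = unclass(spec))
}

#' @describeIn generatePhantom the phantom's ROI as a \code{\link{roiSpec}}.
#' @param phantom a \code{ChoroidPhantom}.
#' @export
phantomROI <- function(phantom) {
  roiSpec(phantom@roi$foveaCol, top = phantom@roi$top,
          bottom = phantom@roi$bottom, widthUm = phantom@roi$widthUm)
}
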