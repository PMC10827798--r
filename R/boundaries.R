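#' Depth brightness profile of the choroid window
#'
#' Resamples each column's choroid span (RPE lower edge to choroid-scleral
#' interface) onto a uniform depth axis by linear interpolation — placing
#' the brightness data "in a rectangle of uniform height" — and averages
#' across columns at each resampled depth.
#'
#' @param window a \code{\linkS4class{ChoroidWindow}}.
#' @param nSamples number of uniform depth samples per column (default 200).
#' @return list of class \code{brightnessProfile}: \code{profile} (numeric,
#'   length \code{nSamples}), \code{nSamples}, \code{spans} (per-column
#'   choroid depth in px), \code{resampleFactor} (nSamples / mean span).
#' @export
depthProfile <- function(window, nSamples = 200L) {
  stopifnot(is(window, "ChoroidWindow"))
  chor <- .choroidMask(window)
  spans <- colSums(chor)
  if (any(spans < 2))
    stop("choroid too thin: column with fewer than 2 choroid pixels")
  res <- matrix(NA_real_, nSamples, ncol(window@pixels))
  for (j in seq_len(ncol(window@pixels))) {
    v <- window@pixels[chor[, j], j]
    res[, j] <- stats::approx(seq(0, 1, length.out = length(v)), v,
                              xout = seq(0, 1, length.out = nSamples))$y
  }
  structure(list(profile = rowMeans(res), nSamples = as.integer(nSamples),
                 spans = spans, resampleFactor = nSamples / mean(spans)),
            class = "brightnessProfile")
}

#' Candidate boundary depths from second-order differentiation
#'
#' Smooths a depth profile, computes the discrete second derivative
#' \code{f''(r) = f(r+1) - 2 f(r) + f(r-1)}, and returns the local extrema of
#' \code{|f''|} whose magnitude exceeds \code{magnitudeFactor} times the
#' median absolute second difference (a scale-free criterion), ordered by
#' depth.  Ties between equal-magnitude candidates keep the shallower depth.
#'
#' @param profile numeric vector or a \code{brightnessProfile}.
#' @param smoothingSigma Gaussian sigma in samples (0 = none; default 2).
#' @param magnitudeFactor threshold multiplier on the median |f''|.
#' @return numeric vector of candidate depths (profile sample positions).
#' @export
profileChangepoints <- function(profile, smoothingSigma = 2,
                                magnitudeFactor = 1.5) {
  if (inherits(profile, "brightnessProfile")) profile <- profile$profile
  n <- length(profile)
  if (n < 5) stop("profile too short: need at least 5 samples")
  p <- .gaussSmooth1d(profile, smoothingSigma)
  d2 <- abs(diff(diff(p)))            # d2[i] is centered at depth i + 1
  if (all(d2 < 1e-12)) return(numeric())
  thr <- magnitudeFactor * stats::median(d2)
  thr <- max(thr, 1e-12)
  isMax <- d2 >= c(-Inf, d2[-length(d2)]) & d2 > c(d2[-1], -Inf)
  which(isMax & d2 >= thr) + 1
}

#' Per-column boundary change points
#'
#' For every column of the window, extracts the depth trace inside the
#' half-open search band \code{[upperLimit, lowerLimit)}, smooths it, takes
#' the first difference, and records the (sub-pixel) depth of maximum
#' absolute change as that column's candidate boundary point.  Columns whose
#' peak change does not stand out from the band (below
#' \code{magnitudeFactor} times the median absolute difference in their
#' band) are omitted.  An optional lateral pre-smoothing pools neighbouring
#' columns before the per-column analysis; with \code{feature =
#' "gradient"} the trace is the lateral gradient magnitude rather than raw
#' intensity, which responds to the change in vessel caliber between
#' sublayers rather than to their (nearly equal) mean brightness.
#'
#' @param window a \code{ChoroidWindow} (normally the 8-bit rescaled one).
#' @param upperLimit,lowerLimit search band in window sub-grid rows; scalars
#'   or per-column vectors.
#' @param smoothingSigma axial Gaussian sigma in px (default 2).
#' @param lateralSigma lateral pre-smoothing sigma in px (default 0).
#' @param magnitudeFactor omission threshold (default 5; within a
#'   narrow pre-localized refinement band a lower factor is appropriate).
#' @param feature \code{"intensity"} or \code{"gradient"}.
#' @param direction sign of the change to look for with increasing depth:
#'   \code{+1} rising, \code{-1} falling, \code{0} either (default).
#' @param order derivative order: 1 locates a step edge (peak of the first
#'   difference); 2 locates a ridge or trough (extremum of the second
#'   difference, e.g. the bright stromal seam between two vascular layers).
#' @return data.frame with columns \code{col} (original image column) and
#'   \code{row} (original image row, real-valued).
#' @export
columnChangepoints <- function(window, upperLimit, lowerLimit,
                               smoothingSigma = 2, lateralSigma = 0,
                               magnitudeFactor = 5,
                               feature = c("intensity", "gradient"),
                               direction = 0, order = 1) {
  stopifnot(is(window, "ChoroidWindow"))
  feature <- match.arg(feature)
  nc <- ncol(window@pixels)
  upperLimit <- rep_len(upperLimit, nc)
  lowerLimit <- rep_len(lowerLimit, nc)
  if (any(lowerLimit - upperLimit < 2))
    stop("invalid band: empty or near-empty search band")
  vals <- .featureMatrix(window, feature)
  sm <- .gaussSmooth(vals, sigmaRow = smoothingSigma, sigmaCol = lateralSigma)
  out <- vector("list", nc)
  for (j in seq_len(nc)) {
    rows <- seq(max(1L, ceiling(upperLimit[j])),
                min(nrow(sm), floor(lowerLimit[j] - 1e-9)))
    tr <- sm[rows, j]
    ok <- is.finite(tr)
    tr <- tr[ok]; rows <- rows[ok]
    if (length(tr) < 3 + (order == 2)) next
    dv <- if (order == 2) diff(diff(tr)) else diff(tr)
    d1 <- .orient(dv, direction)
    mx <- max(d1)
    med <- stats::median(abs(dv))
    if (mx < magnitudeFactor * max(med, 1e-12)) next
    peak <- .subpixelPeak(d1)
    # order 1: a d1 peak at index i* marks the edge between rows[i*] and
    # rows[i*+1], so the boundary row is rows[1] + i*.  order 2: a d2 peak
    # at i* marks a ridge centered on trace position i* + 1, i.e. the same
    # rows[1] + i* under the boundary-row convention.
    out[[j]] <- c(window@cols[j], rows[1] + peak + window@rowOffset)
  }
  pts <- do.call(rbind, out)
  if (is.null(pts)) return(data.frame(col = integer(), row = numeric()))
  data.frame(col = pts[, 1], row = pts[, 2])
}

# Feature image over the window sub-grid, NA outside the choroid.
.featureMatrix <- function(window, feature) {
  vals <- window@pixels
  attributes(vals) <- list(dim = dim(vals))
  vals[!.choroidMask(window)] <- NA
  if (feature == "gradient") {
    g <- abs(vals[, c(2:ncol(vals), ncol(vals))] - vals)
    g[, ncol(g)] <- g[, ncol(g) - 1]
    vals <- g
  }
  vals
}

#' Least-squares quadratic boundary fit
#'
#' Fits \code{row = a col^2 + b col + c} to detected change points by
#' ordinary least squares, applies one pass of residual-based trimming at
#' \code{trimSd} standard deviations, and refits.
#'
#' @param points data.frame with columns \code{col}, \code{row}.
#' @param trimSd residual trimming threshold in sds (default 2.5).
#' @return list: \code{coef} = c(a, b, c), \code{fitted} function of column,
#'   \code{residualSd}, \code{nUsed}.
#' @export
fitBoundaryQuadratic <- function(points, trimSd = 2.5) {
  if (length(unique(points$col)) < 3)
    stop("underdetermined fit: need points at >= 3 distinct columns")
  solveQuad <- function(col, row) {
    X <- cbind(col^2, col, 1)
    qr.solve(X, row)
  }
  cf <- solveQuad(points$col, points$row)
  res <- points$row - .quadEval(cf, points$col)
  s <- stats::sd(res)
  keep <- if (is.finite(s) && s > 0) abs(res) <= trimSd * s else rep(TRUE, nrow(points))
  if (sum(keep) >= 3 && length(unique(points$col[keep])) >= 3 &&
      any(!keep)) {
    cf <- solveQuad(points$col[keep], points$row[keep])
    res <- points$row[keep] - .quadEval(cf, points$col[keep])
  } else keep <- rep(TRUE, nrow(points))
  list(coef = as.numeric(cf),
       fitted = function(col) .quadEval(cf, col),
       residualSd = stats::sd(res), nUsed = sum(keep))
}

#' Configuration for sublayer boundary detection
#'
#' Each boundary is detected on the feature and change direction where its
#' anatomical signature lives.  The choriocapillaris is more luminal (hence
#' darker) than Sattler's layer, so the CC/SL boundary defaults to the
#' bright stromal seam between the two vascular beds: a ridge in the depth
#' intensity profile, located as the (negative) extremum of its second
#' derivative.  Sattler's and Haller's layers have nearly equal mean
#' brightness but very different vessel calibers, so the SL/HL boundary
#' defaults to the falling step edge of the lateral-gradient (edge density)
#' profile, which drops sharply where the small-caliber texture gives way
#' to large lumens.  Feature, derivative order and change direction are
#' configurable per boundary.
#'
#' @param ccFeature,ccDirection feature (\code{"intensity"} or
#'   \code{"gradient"}) and change sign for the CC/SL boundary
#'   (defaults "intensity", +1).
#' @param slhlFeature,slhlDirection same for the SL/HL boundary
#'   (defaults "gradient", -1).
#' @param ccBandUm depth band below the RPE lower edge searched for the
#'   CC/SL boundary, um: \code{c(start, end)}; default c(2, 60).
#' @param slhlMarginUm depth below the fitted CC/SL boundary where the SL/HL
#'   search begins (default 20 um).
#' @param axialSigma,lateralSigma Gaussian smoothing in px (defaults 2, 12).
#' @param refineHalfPx half-width of the per-column refinement band around
#'   the profile-level estimate (default 8 px).
#' @param magnitudeFactor omission threshold for per-column points
#'   (default 1.5 inside the refinement band).
#' @param maxViolationFrac maximum tolerated fraction of columns whose
#'   fitted boundary crosses the ordering chain by more than
#'   \code{violTolPx} before detection errors out (default 0.10).
#' @param violTolPx crossing depth, in px, below which a clip is treated as
#'   benign sub-pixel overshoot rather than an ordering violation (default 1).
#' @return list of class \code{boundaryConfig}.
#' @export
boundaryConfig <- function(ccFeature = c("intensity", "gradient"),
                           ccDirection = -1, ccOrder = 2,
                           slhlFeature = c("gradient", "intensity"),
                           slhlDirection = -1, slhlOrder = 1,
                           ccBandUm = c(2, 60), slhlMarginUm = 20,
                           axialSigma = 1, lateralSigma = 16,
                           refineHalfPx = 8, magnitudeFactor = 1.5,
                           maxViolationFrac = 0.10, violTolPx = 1) {
  structure(list(ccFeature = match.arg(ccFeature), ccDirection = ccDirection,
                 ccOrder = ccOrder,
                 slhlFeature = match.arg(slhlFeature),
                 slhlDirection = slhlDirection, slhlOrder = slhlOrder,
                 ccBandUm = ccBandUm,
                 slhlMarginUm = slhlMarginUm, axialSigma = axialSigma,
                 lateralSigma = lateralSigma, refineHalfPx = refineHalfPx,
                 magnitudeFactor = magnitudeFactor,
                 maxViolationFrac = maxViolationFrac, violTolPx = violTolPx),
            class = "boundaryConfig")
}

#' Detect the CC/SL and SL/HL sublayer boundaries
#'
#' Two-stage change-point detection on the RPE-aligned choroid window.
#' Stage 1 localizes each boundary depth on the column-averaged depth
#' profile of the feature image (second-order differentiation of the mean
#' trace); stage 2 re-detects the boundary per column inside a narrow band
#' around the stage-1 depth; stage 3 fits a quadratic curve through the
#' per-column points with residual trimming.  The CC/SL boundary is sought
#' within \code{ccBandUm} below the RPE lower edge; the SL/HL boundary is
#' then sought between the fitted CC/SL boundary (plus a margin) and the
#' choroid-scleral interface.  Fitted curves are clipped column-by-column to
#' the ordering chain \code{rpe <= ccSl <= slHl <= csi}; if more than
#' \code{maxViolationFrac} of columns require clipping, detection aborts.
#'
#' @param window8 a \code{ChoroidWindow}, normally the floor-rescaled 8-bit
#'   window (detection is invariant to positive rescaling of intensities).
#' @param config a \code{\link{boundaryConfig}}.
#' @return a \code{\linkS4class{LayerBoundaries}}.
#' @export
detectBoundaries <- function(window8, config = boundaryConfig()) {
  stopifnot(is(window8, "ChoroidWindow"), inherits(config, "boundaryConfig"))
  ax <- window8@axialScale
  nc <- ncol(window8@pixels)
  flTop <- floor(window8@top)
  flBot <- floor(window8@bottom)
  spans <- flBot - flTop
  D <- max(spans)
  winRow1 <- window8@rowOffset + 1L

  # RPE-aligned mean depth profile of a feature image:
  # depth d = image row - floor(top) + 1
  alignedProfile <- function(feature) {
    vals <- .featureMatrix(window8, feature)
    A <- matrix(NA_real_, D, nc)
    for (j in seq_len(nc)) {
      d <- seq_len(spans[j])
      A[d, j] <- vals[flTop[j] - winRow1 + d, j]
    }
    Asm <- .gaussSmooth(A, sigmaRow = config$axialSigma,
                        sigmaCol = config$lateralSigma)
    rowMeans(Asm, na.rm = TRUE)
  }
  profiles <- list(intensity = NULL, gradient = NULL)
  getProfile <- function(feature) {
    if (is.null(profiles[[feature]]))
      profiles[[feature]] <<- alignedProfile(feature)
    profiles[[feature]]
  }

  coarse <- function(feature, direction, order, lo, hi) {
    p <- getProfile(feature)
    lo <- max(2L, floor(lo)); hi <- min(D - 1L, ceiling(hi))
    if (hi - lo < 3) return(NULL)
    if (order == 2) {
      # d2 index i is centered on depth i + 1; ridge center = boundary row
      dv <- diff(diff(p))[(lo - 1L):(hi - 1L)]
      off <- lo - 1
    } else {
      # d1 index i sits between depths i and i + 1; boundary row = i + 1
      dv <- diff(p)[lo:(hi - 1L)]
      off <- lo
    }
    bad <- which(!is.finite(dv))
    if (length(bad)) dv <- dv[seq_len(min(bad) - 1L)]
    if (length(dv) < 3) return(NULL)
    off + .subpixelPeak(.orient(dv, direction))
  }

  # Columnwise change points shape the curve; the (far less texture-biased)
  # profile-level depth anchors it: the fitted quadratic is shifted so its
  # mean RPE-relative depth equals the profile estimate.
  refineFit <- function(feature, direction, order, center) {
    up <- pmax(flTop - winRow1 + center - config$refineHalfPx, 1)
    loLim <- pmin(flTop - winRow1 + center + config$refineHalfPx,
                  flBot - winRow1 + 1)
    pts <- columnChangepoints(window8, up, loLim,
                              smoothingSigma = config$axialSigma,
                              lateralSigma = config$lateralSigma,
                              magnitudeFactor = config$magnitudeFactor,
                              feature = feature, direction = direction,
                              order = order)
    if (nrow(pts) < 3 || length(unique(pts$col)) < 3) return(NULL)
    fit <- fitBoundaryQuadratic(pts)
    rowsFit <- fit$fitted(window8@cols)
    shift <- center - mean(rowsFit - flTop + 1)
    cf <- fit$coef + c(0, 0, shift)
    list(coef = cf, fitted = function(col) .quadEval(cf, col),
         residualSd = fit$residualSd, nUsed = fit$nUsed)
  }

  b1 <- config$ccBandUm / ax
  cCc <- coarse(config$ccFeature, config$ccDirection, config$ccOrder,
                b1[1], b1[2])
  if (is.null(cCc)) stop("boundary detection failed: no CC/SL change point")
  fitCc <- refineFit(config$ccFeature, config$ccDirection, config$ccOrder, cCc)
  if (is.null(fitCc)) stop("boundary detection failed: CC/SL fit underdetermined")
  ccSl <- fitCc$fitted(window8@cols)

  ccDepth <- mean(ccSl - flTop + 1)
  lo2 <- ccDepth + config$slhlMarginUm / ax
  if (D - lo2 < 5) {
    warning("Sattler band degenerate: SL/HL boundary set equal to CC/SL")
    slHl <- ccSl
    fitSl <- list(coef = fitCc$coef, residualSd = NA_real_, nUsed = 0L)
  } else {
    cSl <- coarse(config$slhlFeature, config$slhlDirection, config$slhlOrder,
                  lo2, D - 1)
    if (is.null(cSl)) stop("boundary detection failed: no SL/HL change point")
    fitSl <- refineFit(config$slhlFeature, config$slhlDirection,
                       config$slhlOrder, cSl)
    if (is.null(fitSl)) stop("boundary detection failed: SL/HL fit underdetermined")
    slHl <- fitSl$fitted(window8@cols)
  }

  rpe <- window8@top
  csi <- window8@bottom
  tol <- config$violTolPx
  viol <- (ccSl < rpe - tol) | (ccSl > csi + tol) |
          (slHl < ccSl - tol) | (slHl > csi + tol)
  if (mean(viol) > config$maxViolationFrac)
    stop("inconsistent boundaries: ordering violated at ",
         round(100 * mean(viol)), "% of columns")
  ccSl <- pmin(pmax(ccSl, rpe), csi)
  slHl <- pmin(pmax(slHl, ccSl), csi)

  new("LayerBoundaries", cols = window8@cols, rpeLower = rpe,
      ccSl = ccSl, slHl = slHl, csi = csi,
      coef = list(ccSl = fitCc$coef, slHl = fitSl$coef,
                  residualSd = c(ccSl = fitCc$residualSd,
                                 slHl = fitSl$residualSd)))
}
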