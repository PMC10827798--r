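#' @import methods
NULL

#' B-scan image with physical pixel scales
#'
#' Container for a single grayscale EDI-OCT B-scan.  Pixels are stored as a
#' numeric matrix in gray-level units (row 1 = top, the vitreous side), with
#' the lateral (column) and axial (row) scales in micrometres per pixel and
#' the acquisition bit depth (8 or 16).
#'
#' @slot pixels numeric matrix of gray levels, row 1 at the top.
#' @slot bitDepth integer, 8 or 16.
#' @slot lateralScale numeric, micrometres per pixel along columns.
#' @slot axialScale numeric, micrometres per pixel along rows.
#' @exportClass BScan
setClass("BScan",
  representation(pixels = "matrix", bitDepth = "integer",
                 lateralScale = "numeric", axialScale = "numeric"))

setValidity("BScan", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(object@lateralScale) != 1 || !is.finite(object@lateralScale) ||
      object@lateralScale <= 0) msg <- c(msg, "lateralScale must be > 0")
  if (length(object@axialScale) != 1 || !is.finite(object@axialScale) ||
      object@axialScale <= 0) msg <- c(msg, "axialScale must be > 0")
  maxv <- 2^object@bitDepth - 1
  if (length(object@pixels) && (min(object@pixels) < 0 || max(object@pixels) > maxv))
    msg <- c(msg, sprintf("pixel values outside [0, %d]", maxv))
  if (length(msg)) msg else TRUE
})

#' Choroid analysis window (ROI)
#'
#' The 1500-um-wide choroidal region of interest carved out of a B-scan:
#' a rectangular sub-grid in column extent whose vertical extent follows the
#' annotated RPE lower edge (top) and choroid-scleral interface (bottom).
#' Boundary rows are kept real-valued (sub-pixel); rasterization floors them
#' only when pixel masks are built, with half-open row intervals
#' \code{[floor(top), floor(bottom))} so every pixel belongs to exactly one
#' side.
#'
#' @slot pixels numeric matrix, the cropped sub-grid.
#' @slot cols integer vector, original image column indices (1-based).
#' @slot rowOffset integer, original image row of \code{pixels[1, ]} minus 1.
#' @slot top numeric vector, per-column RPE lower edge row (original frame).
#' @slot bottom numeric vector, per-column choroid-scleral interface row.
#' @slot foveaCol integer, fovea column in the original frame.
#' @slot lateralScale,axialScale numeric, um per pixel.
#' @exportClass ChoroidWindow
setClass("ChoroidWindow",
  representation(pixels = "matrix", cols = "integer", rowOffset = "integer",
                 top = "numeric", bottom = "numeric", foveaCol = "integer",
                 lateralScale = "numeric", axialScale = "numeric"))

setValidity("ChoroidWindow", function(object) {
  msg <- character()
  nc <- ncol(object@pixels)
  if (length(object@cols) != nc) msg <- c(msg, "cols length != ncol(pixels)")
  if (length(object@top) != nc || length(object@bottom) != nc)
    msg <- c(msg, "top/bottom must have one entry per ROI column")
  if (length(object@top) == nc && any(object@top >= object@bottom))
    msg <- c(msg, "top curve must lie strictly above bottom curve")
  if (length(msg)) msg else TRUE
})

#' Choroidal sublayer boundaries
#'
#' Four column-indexed depth curves over the ROI: the RPE lower edge and the
#' choroid-scleral interface (inputs), and the fitted quadratic CC/SL and
#' SL/HL boundaries.  Rows are real-valued in the original image frame and
#' satisfy \code{rpe <= ccSl <= slHl <= csi} at every column.
#'
#' @slot cols integer vector of ROI columns (original frame).
#' @slot rpeLower,ccSl,slHl,csi numeric vectors of boundary rows.
#' @slot coef list with elements \code{ccSl} and \code{slHl}, each numeric
#'   \code{c(a, b, c)} for \code{row = a*col^2 + b*col + c}, plus residual sd.
#' @exportClass LayerBoundaries
setClass("LayerBoundaries",
  representation(cols = "integer", rpeLower = "numeric", ccSl = "numeric",
                 slHl = "numeric", csi = "numeric", coef = "list"))

setValidity("LayerBoundaries", function(object) {
  n <- length(object@cols)
  msg <- character()
  for (s in c("rpeLower", "ccSl", "slHl", "csi"))
    if (length(slot(object, s)) != n) msg <- c(msg, paste(s, "length mismatch"))
  if (!length(msg)) {
    tol <- 1e-9
    ok <- object@rpeLower <= object@ccSl + tol &
          object@ccSl <= object@slHl + tol &
          object@slHl <= object@csi + tol
    if (!all(ok)) msg <- c(msg, "boundary ordering rpe <= ccSl <= slHl <= csi violated")
  }
  if (length(msg)) msg else TRUE
})

#' Lumen/stroma classification of the choroid window
#'
#' Per-pixel labels over the ROI sub-grid: 0 = outside the choroid,
#' 1 = stroma (bright), 2 = lumen (dark), together with a record of the
#' thresholding parameters that produced the mask.
#'
#' @slot labels integer matrix with values in {0, 1, 2}, same dim as the
#'   window it was computed from.
#' @slot thresholdRecord named list: method, floor, threshold and, for the
#'   local method, window size and k coefficient.
#' @exportClass ChoroidMask
setClass("ChoroidMask",
  representation(labels = "matrix", thresholdRecord = "list"))

setValidity("ChoroidMask", function(object) {
  if (!all(object@labels %in% 0:2)) return("labels must be 0 (outside), 1 (stroma) or 2 (lumen)")
  TRUE
})

#' Synthetic B-scan phantom with ground truth
#'
#' Output of \code{\link{generatePhantom}}: the rendered image, the true
#' sublayer boundaries, the true lumen mask and metrics over the analysis
#' ROI, and the three planted dark reference lumens in Haller's layer.
#'
#' @slot image a \code{BScan}.
#' @slot roi list with \code{foveaCol}, \code{widthUm}, \code{top},
#'   \code{bottom} (full-image-width curves), usable with
#'   \code{\link{extractROI}}.
#' @slot truthBoundaries a \code{LayerBoundaries} over the ROI.
#' @slot truthMask a \code{ChoroidMask} over the ROI window.
#' @slot truthMetrics data.frame of per-layer metrics (see
#'   \code{\link{computeMetrics}}).
#' @slot referenceLumens data.frame with columns row, col, radiusPx of the
#'   planted darkest Haller-layer lumens.
#' @slot spec the generating \code{phantomSpec} list.
#' @exportClass ChoroidPhantom
setClass("ChoroidPhantom",
  representation(image = "BScan", roi = "list",
                 truthBoundaries = "LayerBoundaries", truthMask = "ChoroidMask",
                 truthMetrics = "data.frame", referenceLumens = "data.frame",
                 spec = "list"))

setMethod("show", "BScan", function(object) {
  cat(sprintf("BScan: %d x %d px, %d-bit, %.3g x %.3g um/px (lateral x axial)\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              object@lateralScale, object@axialScale))
})

setMethod("show", "ChoroidWindow", function(object) {
  cat(sprintf(
    "ChoroidWindow: %d columns (%.0f um) x %d rows; choroid depth %.0f-%.0f px\n",
    ncol(object@pixels), ncol(object@pixels) * object@lateralScale,
    nrow(object@pixels), min(object@bottom - object@top),
    max(object@bottom - object@top)))
})

setMethod("show", "LayerBoundaries", function(object) {
  mid <- (length(object@cols) + 1) %/% 2
  cat(sprintf(
    "LayerBoundaries over %d columns; central rows rpe=%.1f ccSl=%.1f slHl=%.1f csi=%.1f\n",
    length(object@cols), object@rpeLower[mid], object@ccSl[mid],
    object@slHl[mid], object@csi[mid]))
})

setMethod("show", "ChoroidMask", function(object) {
  n <- tabulate(object@labels + 1L, 3L)
  cat(sprintf("ChoroidMask: %d lumen / %d stroma / %d outside px (method %s)\n",
              n[3], n[2], n[1],
              if (is.null(object@thresholdRecord$method)) "?" else object@thresholdRecord$method))
})

setMethod("show", "ChoroidPhantom", function(object) {
  cat("ChoroidPhantom\n  ")
  show(object@image)
  cat(sprintf("  truth L/C (total): %.1f%%; %d reference lumens planted\n",
              object@truthMetrics$lc_pct[object@truthMetrics$layer == "total"],
              nrow(object@referenceLumens)))
})
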