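#' Per-sublayer pixel masks from boundaries
#'
#' Rasterizes the boundary curves into disjoint per-layer pixel sets over
#' the choroid window using the half-open, floored convention:
#' CC = rows \code{[floor(rpe), floor(ccSl))}, SL = \code{[floor(ccSl),
#' floor(slHl))}, HL = \code{[floor(slHl), floor(csi))}.  Their union is
#' exactly the choroid ROI, so per-layer pixel counts always add up to the
#' total choroid pixel count.
#'
#' @param boundaries a \code{\linkS4class{LayerBoundaries}}.
#' @param window the \code{\linkS4class{ChoroidWindow}} the boundaries refer to.
#' @return list of logical matrices \code{cc}, \code{sl}, \code{hl},
#'   \code{total} over the window sub-grid.
#' @export
layerMasks <- function(boundaries, window) {
  stopifnot(is(boundaries, "LayerBoundaries"), is(window, "ChoroidWindow"))
  if (!identical(boundaries@cols, window@cols))
    stop("boundaries and window cover different columns")
  rows <- seq_len(nrow(window@pixels)) + window@rowOffset
  band <- function(upper, lower)
    outer(rows, floor(upper), ">=") & outer(rows, floor(lower), "<")
  masks <- list(cc = band(boundaries@rpeLower, boundaries@ccSl),
                sl = band(boundaries@ccSl, boundaries@slHl),
                hl = band(boundaries@slHl, boundaries@csi),
                total = band(boundaries@rpeLower, boundaries@csi))
  attr(masks, "boundaries") <- boundaries
  masks
}

#' Per-layer choroidal metrics
#'
#' Converts layer masks, a lumen/stroma mask and the pixel scales into the
#' reported metrics for the total choroid and each sublayer: choroidal area
#' CA, luminal area LA and stromal area SA in mm^2 (pixel counts times the
#' pixel area), the L/C ratio \code{100 * LA / CA} in percent, and the
#' central thickness in um (the real-valued boundary gap at the fovea
#' column, optionally averaged over \code{+/- cctBand} columns).  Additivity
#' (CA = LA + SA; sublayer CAs summing to the total) is exact in pixel
#' counts because unit conversion is applied once at the end.  Empty layers
#' yield NA metrics with a warning, never zeros.
#'
#' @param masks output of \code{\link{layerMasks}}.
#' @param mask a \code{\linkS4class{ChoroidMask}}.
#' @param window the \code{ChoroidWindow} (provides scales and fovea column).
#' @param cctBand average central thickness over \code{2*cctBand+1} columns
#'   centered on the fovea (default 0 = single column).
#' @return data.frame with columns layer, n_px, lumen_px, ca_mm2, la_mm2,
#'   sa_mm2, lc_pct, thickness_um.
#' @export
computeMetrics <- function(masks, mask, window, cctBand = 0L) {
  stopifnot(is(mask, "ChoroidMask"), is(window, "ChoroidWindow"))
  b <- attr(masks, "boundaries")
  lumen <- maskLabels(mask) == 2L
  pxArea <- window@lateralScale * window@axialScale * 1e-6  # um^2 -> mm^2
  fi <- which(window@cols == window@foveaCol)
  if (!length(fi)) fi <- (length(window@cols) + 1) %/% 2
  sel <- fi + seq(-cctBand, cctBand)
  sel <- sel[sel >= 1 & sel <= length(window@cols)]
  gap <- function(upper, lower) mean(lower[sel] - upper[sel]) * window@axialScale
  thick <- c(total = gap(b@rpeLower, b@csi), cc = gap(b@rpeLower, b@ccSl),
             sl = gap(b@ccSl, b@slHl), hl = gap(b@slHl, b@csi))
  out <- do.call(rbind, lapply(c("total", "cc", "sl", "hl"), function(ly) {
    n <- sum(masks[[ly]])
    nl <- sum(masks[[ly]] & lumen)
    if (n == 0) {
      warning("layer ", ly, " is empty; metrics reported as missing")
      return(data.frame(layer = ly, n_px = 0L, lumen_px = 0L,
                        ca_mm2 = 0, la_mm2 = 0, sa_mm2 = 0,
                        lc_pct = NA_real_, thickness_um = thick[[ly]]))
    }
    data.frame(layer = ly, n_px = n, lumen_px = nl,
               ca_mm2 = n * pxArea, la_mm2 = nl * pxArea,
               sa_mm2 = (n - nl) * pxArea, lc_pct = 100 * nl / n,
               thickness_um = thick[[ly]])
  }))
  rownames(out) <- NULL
  out
}

#' L/C ratio samples by sublayer across a cohort
#'
#' Collects the per-subject L/C ratios of the three sublayers, reports their
#' medians and median ordering, and runs the omnibus Kruskal-Wallis test
#' comparing the sublayers.  Subjects missing any sublayer L/C are excluded
#' (with a message).
#'
#' @param records cohort data.frame with columns \code{cc_lc, sl_lc, hl_lc}.
#' @return list: \code{groups} (named list of numeric vectors),
#'   \code{medians}, \code{ordering} (layer names sorted by decreasing
#'   median), \code{ties} (logical), \code{kruskal} (see
#'   \code{\link{kruskalWallisGroups}}).
#' @export
lcRatioByLayer <- function(records) {
  need <- c("cc_lc", "sl_lc", "hl_lc")
  if (!all(need %in% names(records)))
    stop("records must contain cc_lc, sl_lc and hl_lc columns")
  ok <- stats::complete.cases(records[need])
  if (any(!ok)) message(sum(!ok), " subject(s) excluded for missing sublayer L/C")
  if (sum(ok) < 2) stop("need at least 2 complete subjects")
  groups <- list(cc = records$cc_lc[ok], sl = records$sl_lc[ok],
                 hl = records$hl_lc[ok])
  med <- vapply(groups, stats::median, numeric(1))
  ordering <- names(sort(med, decreasing = TRUE))
  list(groups = groups, medians = med, ordering = ordering,
       ties = anyDuplicated(med) > 0,
       kruskal = kruskalWallisGroups(groups))
}
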