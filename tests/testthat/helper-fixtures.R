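# Shared fixtures: all synthetic, built in code at test time.

# Compact phantom for unit tests: coarser lateral sampling keeps the ROI at
# 250 columns instead of 384.
smallPhantomSpec <- function(seed = 1L, noiseSd = 10, ...) {
  phantomSpec(widthPx = 300L, heightPx = 420L, lateralScale = 6,
              foveaCol = 150L, seed = seed, noiseSd = noiseSd, ...)
}

# Minimal ChoroidWindow wrapper around a plain matrix: image rows 1..nrow,
# flat top/bottom curves unless vectors are given.
toyWindow <- function(m, top, bottom, lateralScale = 3, axialScale = 2,
                      foveaCol = NULL) {
  nc <- ncol(m)
  if (is.null(foveaCol)) foveaCol <- (nc + 1) %/% 2
  new("ChoroidWindow", pixels = m, cols = seq_len(nc), rowOffset = 0L,
      top = rep_len(top, nc), bottom = rep_len(bottom, nc),
      foveaCol = as.integer(foveaCol),
      lateralScale = lateralScale, axialScale = axialScale)
}

# Flat LayerBoundaries over a toy window.
flatBoundaries <- function(cols, rpe, ccsl, slhl, csi) {
  new("LayerBoundaries", cols = as.integer(cols),
      rpeLower = rep_len(rpe, length(cols)), ccSl = rep_len(ccsl, length(cols)),
      slHl = rep_len(slhl, length(cols)), csi = rep_len(csi, length(cols)),
      coef = list(ccSl = c(0, 0, ccsl), slHl = c(0, 0, slhl),
                  residualSd = c(ccSl = 0, slHl = 0)))
}

# End-to-end truth comparison for one phantom.
phantomRecovery <- function(seed, noiseSd) {
  ph <- generatePhantom(phantomSpec(seed = seed, noiseSd = noiseSd))
  res <- runSingle(ph@image, phantomROI(ph))
  tb <- ph@truthBoundaries
  db <- res$boundaries
  m <- merge(res$metrics, ph@truthMetrics, by = "layer",
             suffixes = c("", ".truth"))
  list(ccMae = mean(abs(db@ccSl - tb@ccSl)),
       slMae = mean(abs(db@slHl - tb@slHl)),
       lcErr = setNames(m$lc_pct - m$lc_pct.truth, m$layer),
       metrics = res$metrics, truth = ph@truthMetrics)
}
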