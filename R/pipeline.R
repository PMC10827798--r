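#' Pipeline configuration
#'
#' Bundles every tunable of the single-image pipeline: ROI width,
#' reference-lumen search, binarization method and boundary-detection
#' settings.  The configuration fingerprint is recorded in every output
#' file so results can be traced to the settings that produced them.
#'
#' @param roiWidthUm analysis width centered on the fovea (default 1500 um).
#' @param method binarization method (see \code{\link{binarizeChoroid}}).
#' @param niblackWindow,niblackK Niblack parameters.
#' @param globalThreshold threshold for \code{method = "global"}.
#' @param refK number of reference lumens (default 3).
#' @param boundary a \code{\link{boundaryConfig}}.
#' @param cctBand half-width in columns for central-thickness averaging
#'   (default 0 = the fovea column only).
#' @param seed integer seed for any stochastic step.
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(roiWidthUm = 1500,
                           method = c("otsu", "niblack", "global"),
                           niblackWindow = 25L, niblackK = -0.05,
                           globalThreshold = NULL, refK = 3L,
                           boundary = boundaryConfig(), cctBand = 0L,
                           seed = 20240130L) {
  structure(list(roiWidthUm = roiWidthUm, method = match.arg(method),
                 niblackWindow = niblackWindow, niblackK = niblackK,
                 globalThreshold = globalThreshold, refK = as.integer(refK),
                 boundary = boundary, cctBand = as.integer(cctBand),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
}

# Flatten the per-layer metrics data.frame into one named row.
.flattenMetrics <- function(metrics) {
  out <- list()
  for (i in seq_len(nrow(metrics))) {
    ly <- metrics$layer[i]
    out[[paste0(ly, "_ca")]] <- metrics$ca_mm2[i]
    out[[paste0(ly, "_la")]] <- metrics$la_mm2[i]
    out[[paste0(ly, "_sa")]] <- metrics$sa_mm2[i]
    out[[paste0(ly, "_lc")]] <- metrics$lc_pct[i]
    out[[paste0(ly, "_cct")]] <- metrics$thickness_um[i]
  }
  as.data.frame(out)
}

#' Run the full single-image stratification pipeline
#'
#' Executes, in order: ROI extraction, reference-lumen search, 256-gradation
#' floor rescale, sublayer boundary detection, lumen/stroma binarization,
#' layer-mask construction and metric computation.  Any stage error aborts
#' with the stage name in the message.
#'
#' @param image a \code{BScan}, or a path passed to \code{\link{readBScan}}
#'   (then \code{lateralScale}/\code{axialScale} are required).
#' @param roi a \code{\link{roiSpec}}, or a path to an annotation CSV.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, writes
#'   \code{results.json}, \code{boundaries.csv}, \code{mask.png} and
#'   \code{overlay.png}.
#' @param lateralScale,axialScale um/px, used only when \code{image} is a path.
#' @return list: \code{metrics} (per-layer data.frame), \code{row}
#'   (flattened one-row data.frame), \code{boundaries}, \code{mask},
#'   \code{referenceLumens}, \code{window8}, \code{configHash}.
#' @export
runSingle <- function(image, roi, config = pipelineConfig(), outDir = NULL,
                      lateralScale = NULL, axialScale = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.character(image))
    image <- .stage("load_bscan", readBScan(image, lateralScale, axialScale))
  if (is.character(roi))
    roi <- .stage("load_annotations",
                  readAnnotations(roi, nCols = ncol(pixels(image)),
                                  widthUm = config$roiWidthUm))
  window <- .stage("extract_roi", extractROI(image, roi))
  ref <- .stage("find_reference_lumens",
                findReferenceLumens(window, k = config$refK))
  window8 <- .stage("rescale_to_256", rescaleTo256(window, ref$combinedMean))
  boundaries <- .stage("detect_boundaries",
                       detectBoundaries(window8, config$boundary))
  mask <- .stage("binarize",
                 binarizeChoroid(window8, method = config$method,
                                 threshold = config$globalThreshold,
                                 niblackWindow = config$niblackWindow,
                                 niblackK = config$niblackK))
  masks <- .stage("layer_masks", layerMasks(boundaries, window8))
  metrics <- .stage("compute_metrics",
                    computeMetrics(masks, mask, window8,
                                   cctBand = config$cctBand))
  res <- list(metrics = metrics, row = .flattenMetrics(metrics),
              boundaries = boundaries, mask = mask, referenceLumens = ref,
              window8 = window8, configHash = .configHash(unclass(config)))
  if (!is.null(outDir)) .writeSingleOutputs(res, outDir)
  res
}

.writeSingleOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(boundaryRows(res$boundaries),
                   file.path(outDir, "boundaries.csv"), row.names = FALSE)
  lab <- maskLabels(res$mask)
  png::writePNG((lab == 2) * 1 + (lab == 1) * (128 / 255),
                file.path(outDir, "mask.png"))
  .writeOverlay(res, file.path(outDir, "overlay.png"))
  json <- list(schema_version = 1L, config_hash = res$configHash,
               threshold_record = thresholdRecord(res$mask),
               boundary_coefficients = res$boundaries@coef,
               metrics = res$metrics)
  jsonlite::write_json(json, file.path(outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

# QC overlay: boundaries drawn on the rescaled window as an RGB PNG.
.writeOverlay <- function(res, path) {
  w <- res$window8
  b <- res$boundaries
  g <- pmin(pmax(w@pixels / 255, 0), 1)
  rgb <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  draw <- function(rowsCurve, channel) {
    rr <- round(rowsCurve) - w@rowOffset
    ok <- rr >= 1 & rr <= nrow(g)
    for (ch in 1:3) {
      v <- as.numeric(ch == channel)
      rgb[cbind(rr[ok], which(ok), ch)] <<- v
    }
  }
  draw(b@rpeLower, 3)  # blue
  draw(b@ccSl, 1)      # red
  draw(b@slHl, 2)      # green
  draw(b@csi, 3)
  png::writePNG(rgb, path)
  invisible(path)
}

#' Run the cohort analysis workflow
#'
#' Measures every subject (imaging mode: the full single-image pipeline per
#' phantom; parametric mode: metrics are already in the records), simulates
#' the second examiner, and runs the statistical battery: per-metric
#' inter-rater reliability (ICC and Bland-Altman), standardized multiple
#' regression of each choroidal parameter on age / SE / AL, and the
#' Kruskal-Wallis comparison of the sublayer L/C ratios.
#'
#' @param cohort output of \code{\link{generateCohort}}, or a plain records
#'   data.frame with metric columns (parametric ingestion).
#' @param config a \code{\link{pipelineConfig}}.
#' @param rater2Sd second-rater noise passed to
#'   \code{\link{simulateSecondRater}}; NULL skips rater simulation (then
#'   reliability needs pre-existing \code{_r2} columns).
#' @param outDir optional directory for \code{metrics.csv},
#'   \code{reliability.csv} and \code{regression.csv}.
#' @return list: \code{records}, \code{reliability} (data.frame),
#'   \code{regression} (data.frame), \code{lcByLayer}, \code{configHash}.
#' @export
runCohort <- function(cohort, config = pipelineConfig(), rater2Sd = 0.15,
                      outDir = NULL) {
  if (is.data.frame(cohort)) cohort <- list(records = cohort, phantoms = NULL)
  records <- cohort$records
  if (nrow(records) < 2) stop("degenerate cohort: need at least 2 subjects")
  if (!is.null(cohort$phantoms)) {
    rows <- lapply(seq_along(cohort$phantoms), function(i) {
      ph <- cohort$phantoms[[i]]
      tryCatch(runSingle(ph@image, phantomROI(ph), config)$row,
               error = function(e) {
                 warning("subject ", i, " excluded: ", conditionMessage(e))
                 NULL
               })
    })
    ok <- !vapply(rows, is.null, TRUE)
    template <- rows[ok][[1]]
    rows[!ok] <- list(template[NA, , drop = FALSE][1, , drop = FALSE])
    records <- cbind(records, do.call(rbind, rows))
  }
  metricCols <- setdiff(names(records), c("subject_id", "age", "se", "al"))
  metricCols <- metricCols[!grepl("_r2$", metricCols)]
  if (!length(metricCols)) stop("no metric columns in cohort records")
  if (!is.null(rater2Sd) && !any(grepl("_r2$", names(records))))
    records <- simulateSecondRater(records, sd = rater2Sd, seed = config$seed)

  relCols <- intersect(c("cc_ca", "cc_lc", "sl_ca", "sl_lc", "hl_ca", "hl_lc"),
                       metricCols)
  reliability <- do.call(rbind, lapply(relCols, function(m) {
    r2col <- paste0(m, "_r2")
    if (!r2col %in% names(records)) return(NULL)
    icc <- iccTwoWay(records[[m]], records[[r2col]])
    ba <- blandAltman(records[[m]], records[[r2col]])
    data.frame(variable = m, icc_single = icc$iccSingle, icc_single_p = icc$p,
               icc_mean = icc$iccMean, icc_mean_p = icc$p,
               fixed_bias_low = ba$fixedBias$ciLow,
               fixed_bias_high = ba$fixedBias$ciHigh,
               fixed_bias_p = ba$fixedBias$p,
               proportional_r = ba$proportionalBias$r,
               proportional_p = ba$proportionalBias$p)
  }))

  regression <- NULL
  if (nrow(records) >= 6) {
    regression <- do.call(rbind, lapply(metricCols, function(m) {
      sr <- standardizedRegression(records, m)
      data.frame(response = m, predictor = sr$table$predictor,
                 beta = sr$table$beta, p = sr$table$p, n = sr$n)
    }))
  } else warning("fewer than 6 subjects: regression skipped")

  lcb <- if (all(c("cc_lc", "sl_lc", "hl_lc") %in% names(records)))
    lcRatioByLayer(records) else NULL

  out <- list(records = records, reliability = reliability,
              regression = regression, lcByLayer = lcb,
              configHash = .configHash(unclass(config)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, f) {
      if (is.null(df)) return()
      con <- file(file.path(outDir, f), "w")
      writeLines(paste0("# config_hash,", out$configHash), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    wcsv(records, "metrics.csv")
    wcsv(reliability, "reliability.csv")
    wcsv(regression, "regression.csv")
  }
  out
}

#' Seeded end-to-end demonstration run
#'
#' Generates a seeded imaging-mode cohort, runs the full pipeline on every
#' phantom and writes the cohort metrics, reliability and regression tables
#' to \code{outDir}.  Identical seed and settings produce byte-identical
#' CSV outputs.
#'
#' @param outDir output directory.
#' @param nSubjects cohort size (default 30).
#' @param seed integer seed.
#' @param config a \code{\link{pipelineConfig}}.
#' @return the \code{\link{runCohort}} result, invisibly.
#' @export
runDemo <- function(outDir, nSubjects = 30L, seed = 20240130L,
                    config = pipelineConfig(seed = seed)) {
  cs <- cohortSpec(nSubjects = nSubjects, seed = seed)
  cohort <- generateCohort(cs, mode = "imaging")
  invisible(runCohort(cohort, config = config, rater2Sd = cs$rater2Sd,
                      outDir = outDir))
}

#' Bland-Altman plot
#'
#' Differences against means with the fixed-bias line and 95 percent limits
#' of agreement, written as a PNG.
#'
#' @param ba a \code{\link{blandAltman}} result.
#' @param path output PNG path.
#' @param title plot title.
#' @return \code{path}, invisibly.
#' @export
plotBlandAltman <- function(ba, path, title = "Bland-Altman") {
  grDevices::png(path, width = 600, height = 480)
  on.exit(grDevices::dev.off())
  plot(ba$m, ba$d, pch = 19, col = "grey30", xlab = "Mean of raters",
       ylab = "Difference (rater1 - rater2)", main = title)
  graphics::abline(h = ba$fixedBias$mean, col = "blue", lwd = 2)
  graphics::abline(h = ba$loa, col = "red", lty = 2)
  graphics::abline(h = 0, col = "grey60")
  invisible(path)
}
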