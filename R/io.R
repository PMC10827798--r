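#' Read a grayscale B-scan image
#'
#' Loads an 8- or 16-bit grayscale TIFF or PNG B-scan and attaches the
#' per-image physical pixel scales.  RGB files are accepted only when all
#' channels are identical (scanner exports sometimes replicate the gray
#' channel); 16-bit values are preserved without rescaling.
#'
#' @param path file path, \code{.tif}/\code{.tiff} or \code{.png}.
#' @param lateralScale,axialScale micrometres per pixel (required; the device
#'   scale is per-image metadata the file format does not carry).
#' @return a \code{\linkS4class{BScan}}.
#' @export
readBScan <- function(path, lateralScale, axialScale) {
  if (missing(lateralScale) || missing(axialScale) ||
      is.null(lateralScale) || is.null(axialScale))
    stop("scale required: supply lateralScale and axialScale in um/pixel")
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    maxraw <- attr(arr, "bits.per.sample")
    bits <- if (!is.null(maxraw)) as.integer(maxraw) else if (max(arr) > 255) 16L else 8L
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    # png values come back in [0,1]; recover gray levels at the stored depth
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth) && info$bit.depth >= 16) 16L else 8L
    arr <- arr * (2^bits - 1)
  } else stop("unsupported image format: ", ext)
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    if (ch >= 3) {
      if (max(abs(arr[, , 1] - arr[, , 2])) > 1e-9 ||
          max(abs(arr[, , 1] - arr[, , 3])) > 1e-9)
        stop("color image unsupported: channels differ")
    }
    arr <- arr[, , 1]
  }
  new("BScan", pixels = round(arr), bitDepth = bits,
      lateralScale = as.numeric(lateralScale), axialScale = as.numeric(axialScale))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a B-scan (or any gray-level matrix) to TIFF or PNG
#'
#' @param image a \code{BScan} or numeric matrix of gray levels.
#' @param path output path; format chosen from the extension.
#' @param bitDepth bits per sample for plain matrices (default 8).
#' @return \code{path}, invisibly.
#' @export
writeBScan <- function(image, path, bitDepth = 8L) {
  if (is(image, "BScan")) {
    m <- image@pixels
    bitDepth <- image@bitDepth
  } else m <- image
  maxv <- 2^bitDepth - 1
  m01 <- pmin(pmax(round(m), 0), maxv) / maxv
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m01, path, bits.per.sample = as.integer(bitDepth))
  } else if (ext == "png") {
    png::writePNG(m01, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Region-of-interest specification
#'
#' Bundles the fovea column, analysis width and the two annotated curves
#' (RPE lower edge on top, choroid-scleral interface below) that delimit the
#' choroid.  Curves are real-valued rows indexed by original image column and
#' may be fractional; they are floored only when pixel masks are built.
#'
#' @param foveaCol fovea center column (1-based).
#' @param top,bottom numeric vectors of boundary rows, one per image column
#'   (NA allowed outside the annotated range).
#' @param widthUm analysis width in micrometres (default 1500).
#' @return a list of class \code{roiSpec}.
#' @export
roiSpec <- function(foveaCol, top, bottom, widthUm = 1500) {
  if (widthUm <= 0) stop("widthUm must be > 0")
  ok <- !is.na(top) & !is.na(bottom)
  if (any(top[ok] >= bottom[ok]))
    stop("invalid annotation: RPE lower edge must lie above the choroid-scleral interface")
  structure(list(foveaCol = as.integer(foveaCol), top = as.numeric(top),
                 bottom = as.numeric(bottom), widthUm = widthUm),
            class = "roiSpec")
}

#' Extract the foveal choroid analysis window
#'
#' Carves the analysis ROI out of a B-scan: columns span
#' \code{foveaCol +/- round(widthUm/2 / lateralScale)} (half-open on the
#' right, so the realized width is within one pixel of the request), and each
#' column's choroid extent is the half-open row interval
#' \code{[top, bottom)}.  Rows above/below the curves stay in the sub-grid
#' but are flagged outside the choroid by downstream masks.
#'
#' @param image a \code{BScan}.
#' @param roi a \code{\link{roiSpec}}.
#' @return a \code{\linkS4class{ChoroidWindow}}.
#' @export
extractROI <- function(image, roi) {
  stopifnot(is(image, "BScan"), inherits(roi, "roiSpec"))
  half <- round(roi$widthUm / 2 / image@lateralScale)
  cols <- seq(roi$foveaCol - half, roi$foveaCol + half - 1L)
  if (cols[1] < 1 || cols[length(cols)] > ncol(image@pixels))
    stop("ROI out of bounds: fovea +/- ", half, " px exceeds the image")
  top <- roi$top[cols]
  bottom <- roi$bottom[cols]
  if (anyNA(top) || anyNA(bottom))
    stop("invalid annotation: curves not defined over the full ROI")
  if (any(top >= bottom)) stop("invalid annotation: top/bottom curves cross")
  r1 <- max(1L, floor(min(top)))
  r2 <- min(nrow(image@pixels), ceiling(max(bottom)))
  if (floor(max(bottom)) > nrow(image@pixels))
    stop("ROI out of bounds: choroid-scleral interface below the image")
  new("ChoroidWindow",
      pixels = image@pixels[r1:r2, cols, drop = FALSE],
      cols = as.integer(cols), rowOffset = as.integer(r1 - 1L),
      top = top, bottom = bottom, foveaCol = as.integer(roi$foveaCol),
      lateralScale = image@lateralScale, axialScale = image@axialScale)
}

# Logical matrix over the window sub-grid: TRUE where the pixel row falls in
# the half-open choroid interval [floor(top), floor(bottom)).
.choroidMask <- function(window) {
  rows <- seq_len(nrow(window@pixels)) + window@rowOffset
  outer(rows, floor(window@top), ">=") & outer(rows, floor(window@bottom), "<")
}

#' Read / write choroid annotations
#'
#' The annotation file is a plain CSV holding the manually set curves: a
#' first comment line \code{# fovea_col,<n>} then columns
#' \code{column_index,rpe_row,csi_row}.  Rows may be fractional; they are
#' preserved as-is.
#'
#' @param path CSV path.
#' @param nCols image width in pixels; curves are expanded to vectors of this
#'   length (columns missing from the file become NA).  Defaults to the
#'   largest column index present.
#' @param widthUm analysis width passed through to \code{\link{roiSpec}}.
#' @return \code{readAnnotations}: a \code{\link{roiSpec}}.
#' @export
readAnnotations <- function(path, nCols = NULL, widthUm = 1500) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!grepl("^#\\s*fovea_col\\s*,", header))
    stop("bad annotation file: missing '# fovea_col,<n>' header line")
  foveaCol <- as.integer(sub("^#\\s*fovea_col\\s*,\\s*", "", header))
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("column_index", "rpe_row", "csi_row")
  if (!all(need %in% names(tab)))
    stop("bad annotation file: need columns ", paste(need, collapse = ", "))
  if (any(tab$rpe_row >= tab$csi_row))
    stop("invalid annotation: rpe_row >= csi_row at column ",
         tab$column_index[which(tab$rpe_row >= tab$csi_row)[1]])
  if (is.null(nCols)) nCols <- max(tab$column_index)
  top <- bottom <- rep(NA_real_, nCols)
  top[tab$column_index] <- tab$rpe_row
  bottom[tab$column_index] <- tab$csi_row
  roiSpec(foveaCol, top, bottom, widthUm = widthUm)
}

#' @rdname readAnnotations
#' @param roi a \code{roiSpec} to serialize.
#' @export
writeAnnotations <- function(roi, path) {
  ok <- which(!is.na(roi$top) & !is.na(roi$bottom))
  writeLines(sprintf("# fovea_col,%d", roi$foveaCol), path)
  suppressWarnings(utils::write.table(
    data.frame(column_index = ok, rpe_row = roi$top[ok], csi_row = roi$bottom[ok]),
    path, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
  invisible(path)
}
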