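#' Locate the darkest reference vessel lumens in Haller's layer
#'
#' The binarization floor is calibrated from representative dark vessel
#' lumens in Haller's layer.  This routine automates that selection: the
#' window is Gaussian-smoothed (sigma 2 px), the search is restricted to the
#' Haller region (by default the deepest half of each column's choroid
#' span, where the large dark lumens live), and the \code{k} darkest local
#' minima separated by at least \code{2 * maxRadiusPx} are returned with
#' their disc-mean reflectances.  Manually picked centers can be supplied
#' instead, in which case no search is run.
#'
#' @param window a \code{\linkS4class{ChoroidWindow}} (raw gray levels).
#' @param hlRegion optional logical matrix over the window marking Haller's
#'   layer; default = deepest 50 percent of each column's choroid span.
#' @param k number of lumens (default 3).
#' @param maxRadiusPx assumed maximum lumen radius; minima must be separated
#'   by twice this (default 16 px).
#' @param discRadiusPx radius of the disc over which each lumen's mean
#'   reflectance is taken (default 5 px).
#' @param manual optional data.frame with columns \code{row, col} (window
#'   coordinates) of manually selected lumen centers.
#' @return list of class \code{referenceLumens}: \code{lumens} data.frame
#'   (row, col, meanReflectance), \code{combinedMean}, and the parameters.
#' @export
findReferenceLumens <- function(window, hlRegion = NULL, k = 3L,
                                maxRadiusPx = 16, discRadiusPx = 5,
                                manual = NULL) {
  stopifnot(is(window, "ChoroidWindow"))
  chor <- .choroidMask(window)
  px <- window@pixels
  nr <- nrow(px); nc <- ncol(px)
  discMean <- function(row, col) {
    idx <- .ellipseIdx(row, col, discRadiusPx, discRadiusPx, nr, nc)
    idx <- idx[chor[idx]]
    if (!length(idx)) stop("reference lumen disc falls outside the choroid")
    mean(px[idx])
  }
  if (!is.null(manual)) {
    means <- mapply(discMean, manual$row, manual$col)
    lum <- data.frame(row = manual$row, col = manual$col,
                      meanReflectance = means)
    return(structure(list(lumens = lum, combinedMean = mean(means),
                          k = nrow(lum), mode = "manual",
                          discRadiusPx = discRadiusPx),
                     class = "referenceLumens"))
  }
  if (k < 1) stop("k must be >= 1")
  if (is.null(hlRegion)) {
    rows <- seq_len(nr) + window@rowOffset
    mid <- floor(window@top) + 0.5 * (floor(window@bottom) - floor(window@top))
    hlRegion <- chor & outer(rows, mid, ">=")
  }
  if (!any(hlRegion)) stop("HL too small: empty Haller search region")
  vals <- px
  vals[!chor] <- NA
  sm <- .gaussSmooth(vals, sigmaRow = 2, sigmaCol = 2)
  sm[!hlRegion] <- NA
  if (max(sm, na.rm = TRUE) - min(sm, na.rm = TRUE) < 1e-9)
    stop("no lumen contrast: Haller region has constant intensity")
  ord <- order(sm, na.last = NA)
  # inside a large flat lumen the smoothed minimum can sit anywhere; recentre
  # on the darkness-weighted centroid of the surrounding basin
  recentre <- function(row, col) {
    r <- max(1, row - maxRadiusPx):min(nr, row + maxRadiusPx)
    c <- max(1, col - maxRadiusPx):min(nc, col + maxRadiusPx)
    patch <- sm[r, c, drop = FALSE]
    wgt <- pmax(sm[row, col] + 6 - patch, 0)
    wgt[is.na(wgt)] <- 0
    if (sum(wgt) == 0) return(c(row, col))
    c(sum(row(patch) * wgt) / sum(wgt) + r[1] - 1,
      sum(col(patch) * wgt) / sum(wgt) + c[1] - 1)
  }
  centers <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    row <- (i - 1L) %% nr + 1L
    col <- (i - 1L) %/% nr + 1L
    if (nrow(centers) &&
        any((centers[, 1] - row)^2 + (centers[, 2] - col)^2 <
            (2 * maxRadiusPx)^2)) next
    centers <- rbind(centers, recentre(row, col))
    if (nrow(centers) == k) break
  }
  if (nrow(centers) < k)
    stop("HL too small: cannot place ", k, " separated reference lumens")
  means <- mapply(discMean, centers[, 1], centers[, 2])
  lum <- data.frame(row = centers[, 1], col = centers[, 2],
                    meanReflectance = means)
  structure(list(lumens = lum, combinedMean = mean(means), k = k,
                 mode = "auto", maxRadiusPx = maxRadiusPx,
                 discRadiusPx = discRadiusPx),
            class = "referenceLumens")
}

#' Convert the choroid window to 256 gradations above a brightness floor
#'
#' Linearly maps gray levels from \code{[floor, max]} to \code{[0, 255]}
#' (rounded), clipping values below the floor to 0.  The floor is normally
#' the combined mean reflectance of the reference lumens, so the darkest
#' vessel interiors land at 0 and the full dynamic range of the choroid is
#' spread over the 8-bit scale.  The map is monotone non-decreasing.
#'
#' @param window a \code{ChoroidWindow} (any bit depth).
#' @param floor gray level used as the new zero; must be below the maximum
#'   choroidal intensity.
#' @return a \code{ChoroidWindow} with 8-bit pixels; attributes
#'   \code{rescaleFloor} and \code{rescaleMax} record the map.
#' @export
rescaleTo256 <- function(window, floor) {
  stopifnot(is(window, "ChoroidWindow"))
  chor <- .choroidMask(window)
  mx <- max(window@pixels[chor])
  if (mx - floor < 1e-9)
    stop("degenerate intensity range: floor is not below the window maximum")
  m <- round((window@pixels - floor) / (mx - floor) * 255)
  m <- pmin(pmax(m, 0), 255)
  out <- window
  out@pixels <- m
  attr(out@pixels, "rescaleFloor") <- floor
  attr(out@pixels, "rescaleMax") <- mx
  out
}

# Local mean and sd over a w x w square window via integral images.
.localStats <- function(m, w) {
  half <- (w - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x) {
    # replicate-pad by half on each side
    x <- x[c(rep(1, half), seq_len(nr), rep(nr, half)), , drop = FALSE]
    x[, c(rep(1, half), seq_len(nc), rep(nc, half)), drop = FALSE]
  }
  ii <- function(x) {
    s <- apply(x, 2, cumsum)
    t(apply(s, 1, cumsum))
  }
  box <- function(x) {
    p <- pad(x)
    S <- ii(p)
    Z <- matrix(0, nrow(S) + 1, ncol(S) + 1)
    Z[-1, -1] <- S
    r1 <- seq_len(nr); c1 <- seq_len(nc)
    Z[r1 + w, c1 + w, drop = FALSE] - Z[r1, c1 + w, drop = FALSE] -
      Z[r1 + w, c1, drop = FALSE] + Z[r1, c1, drop = FALSE]
  }
  n <- w * w
  mu <- box(m) / n
  ex2 <- box(m^2) / n
  list(mean = mu, sd = sqrt(pmax(ex2 - mu^2, 0)))
}

#' Binarize the choroid window into luminal and stromal pixels
#'
#' Classifies every choroidal pixel of the (8-bit, floor-rescaled) window as
#' lumen (dark) or stroma (bright).  Three thresholding rules are offered:
#' \describe{
#'   \item{\code{"otsu"} (default)}{global threshold chosen by Otsu's
#'     criterion on the histogram of choroidal pixels (the floor-rescale has
#'     already anchored the dark end at the reference-lumen mean).}
#'   \item{\code{"niblack"}}{local threshold \code{mean + k * sd} over an
#'     odd square window (default 25 px, k = -0.05).}
#'   \item{\code{"global"}}{an explicit threshold in [0, 255].}
#' }
#' A pixel is labeled lumen iff its intensity is strictly below the
#' threshold (ties are stroma).  Labels are assigned only within the choroid
#' ROI; everything else is "outside".
#'
#' @param window8 a \code{ChoroidWindow} with 8-bit (rescaled) pixels.
#' @param method one of \code{"otsu"}, \code{"niblack"}, \code{"global"}.
#' @param threshold explicit threshold for \code{method = "global"}.
#' @param niblackWindow odd window size >= 3 for Niblack.
#' @param niblackK Niblack k coefficient.
#' @return a \code{\linkS4class{ChoroidMask}}.
#' @export
binarizeChoroid <- function(window8, method = c("otsu", "niblack", "global"),
                            threshold = NULL, niblackWindow = 25L,
                            niblackK = -0.05) {
  stopifnot(is(window8, "ChoroidWindow"))
  method <- match.arg(method)
  chor <- .choroidMask(window8)
  px <- window8@pixels
  rec <- list(method = method,
              floor = attr(px, "rescaleFloor"),
              rescaleMax = attr(px, "rescaleMax"))
  if (method == "otsu") {
    vals <- px[chor]
    if (max(vals) == min(vals)) stop("degenerate intensity range")
    th <- EBImage::otsu(EBImage::Image(matrix(vals / 255, ncol = 1)),
                        range = c(0, 1), levels = 256) * 255
    lumen <- px < th & chor
    rec$threshold <- as.numeric(th)
  } else if (method == "global") {
    if (is.null(threshold) || threshold < 0 || threshold > 255)
      stop("global method needs a threshold in [0, 255]")
    lumen <- px < threshold & chor
    rec$threshold <- threshold
  } else {
    if (niblackWindow %% 2 == 0 || niblackWindow < 3)
      stop("window must be odd and >= 3")
    st <- .localStats(px, as.integer(niblackWindow))
    lumen <- px < (st$mean + niblackK * st$sd) & chor
    rec$window <- as.integer(niblackWindow)
    rec$k <- niblackK
  }
  labels <- matrix(0L, nrow(px), ncol(px))
  labels[chor] <- 1L
  labels[lumen] <- 2L
  new("ChoroidMask", labels = labels, thresholdRecord = rec)
}
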