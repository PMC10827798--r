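#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' Computes ICC(2,1) (single measure) and ICC(2,k) (average measure, k = 2
#' raters) from the two-way ANOVA mean squares of a subjects x raters table,
#' the standard reliability index for interchangeable human raters.  With
#' between-subject mean square MSR, between-rater mean square MSC and
#' residual mean square MSE over n subjects and k raters:
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' \deqn{ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)}
#' Significance is the F test of the between-subject effect,
#' \code{F = MSR/MSE} on \code{(n-1, (n-1)(k-1))} df.  A one-way model
#' (ICC(1,1)) is available via \code{model = "oneway"}.
#'
#' @param rater1,rater2 paired numeric vectors; pairs with missing values
#'   are dropped.
#' @param model \code{"twoway"} (default) or \code{"oneway"}.
#' @return list: \code{iccSingle}, \code{iccMean}, \code{p}, \code{n}, and
#'   the mean squares \code{msr}, \code{msc}, \code{mse}.
#' @export
iccTwoWay <- function(rater1, rater2, model = c("twoway", "oneway")) {
  model <- match.arg(model)
  ok <- is.finite(rater1) & is.finite(rater2)
  x <- cbind(rater1[ok], rater2[ok])
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("insufficient pairs: need n >= 3")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 1e-14) {
    warning("zero between-subject variance; ICC reported as 0")
    return(list(iccSingle = 0, iccMean = 0, p = NA_real_, n = n,
                msr = msr, msc = msc, mse = mse))
  }
  if (model == "twoway") {
    iccS <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    iccM <- (msr - mse) / (msr + (msc - mse) / n)
    fstat <- msr / mse
    p <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else {
    msw <- (sse + ssc) / (n * (k - 1))
    iccS <- (msr - msw) / (msr + (k - 1) * msw)
    iccM <- (msr - msw) / msr
    fstat <- msr / msw
    p <- stats::pf(fstat, n - 1, n * (k - 1), lower.tail = FALSE)
  }
  list(iccSingle = iccS, iccMean = iccM, p = p, n = n,
       msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman agreement analysis
#'
#' Assesses agreement between two raters via the differences
#' \code{d = rater1 - rater2} and means \code{m = (rater1 + rater2)/2}.
#' Fixed bias is the mean difference with its t-based 95 percent CI and
#' one-sample t-test p; proportional bias is the Pearson correlation R of d
#' on m with its test p (the regression slope of d on m is also reported);
#' the 95 percent limits of agreement \code{mean(d) +/- 1.96 sd(d)} are
#' returned for plotting.
#'
#' @param rater1,rater2 paired numeric vectors (n >= 3 after dropping
#'   missing pairs).
#' @return list of class \code{blandAltman}: \code{fixedBias} (mean, ciLow,
#'   ciHigh, p), \code{proportionalBias} (r, p, slope; NA when the means
#'   have no variance), \code{loa} (low, high), \code{n}, \code{d}, \code{m}.
#' @export
blandAltman <- function(rater1, rater2) {
  ok <- is.finite(rater1) & is.finite(rater2)
  r1 <- rater1[ok]; r2 <- rater2[ok]
  n <- length(r1)
  if (n < 3) stop("insufficient pairs: need n >= 3")
  d <- r1 - r2
  m <- (r1 + r2) / 2
  if (stats::sd(d) < 1e-14) {
    fixed <- list(mean = mean(d), ciLow = mean(d), ciHigh = mean(d), p = NA_real_)
  } else {
    tt <- stats::t.test(d)
    fixed <- list(mean = unname(tt$estimate), ciLow = tt$conf.int[1],
                  ciHigh = tt$conf.int[2], p = tt$p.value)
  }
  if (stats::sd(m) < 1e-14 || stats::sd(d) < 1e-14) {
    prop <- list(r = NA_real_, p = NA_real_, slope = NA_real_)
  } else {
    ct <- stats::cor.test(d, m)
    prop <- list(r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(stats::lm(d ~ m))[2]))
  }
  sdd <- stats::sd(d)
  structure(list(fixedBias = fixed, proportionalBias = prop,
                 loa = c(low = mean(d) - 1.96 * sdd,
                         high = mean(d) + 1.96 * sdd),
                 n = n, d = d, m = m),
            class = "blandAltman")
}

#' Spearman rank correlation
#'
#' Rank-based correlation with mid-ranks for ties; p-value from the
#' t approximation (via \code{stats::cor.test}).  Constant input yields NA.
#'
#' @param x,y numeric vectors (pairs with missing values dropped; n >= 3).
#' @return list: \code{rho}, \code{p}, \code{n}.
#' @export
spearmanRho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("insufficient pairs: need n >= 3")
  if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Standardized multiple regression
#'
#' Ordinary least squares of a z-scored response on z-scored predictors
#' (age, spherical equivalent, axial length by default), the model behind a
#' table of standardized betas: each coefficient is the expected change in
#' the response (in sds) per sd of the predictor, with a two-sided t-test
#' p-value.  Rows with any missing value are listwise-deleted.
#'
#' @param data data.frame containing the response and predictor columns.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns
#'   (default \code{c("age", "se", "al")}).
#' @return list of class \code{stdRegression}: \code{table} (data.frame
#'   predictor, beta, p), \code{n}, \code{response}, \code{r2}.
#' @export
standardizedRegression <- function(data, response,
                                   predictors = c("age", "se", "al")) {
  cols <- c(response, predictors)
  if (!all(cols %in% names(data))) stop("missing columns in data")
  d <- data[stats::complete.cases(data[cols]), cols]
  n <- nrow(d)
  if (n <= 5) stop("need more than 5 complete observations")
  z <- as.data.frame(lapply(d, function(v) {
    s <- stats::sd(v)
    if (s < 1e-14) stop("singular design: constant column")
    (v - mean(v)) / s
  }))
  X <- as.matrix(cbind(1, z[predictors]))
  if (qr(X)$rank < ncol(X)) stop("singular design: predictors exactly collinear")
  fit <- stats::lm(stats::reformulate(predictors, response), data = z)
  sm <- summary(fit)$coefficients
  tab <- data.frame(predictor = predictors,
                    beta = unname(sm[predictors, 1]),
                    p = unname(sm[predictors, 4]))
  structure(list(table = tab, n = n, response = response,
                 r2 = summary(fit)$r.squared),
            class = "stdRegression")
}

#' Kruskal-Wallis rank-sum test over groups
#'
#' Omnibus comparison of two or more groups: the tie-corrected H statistic
#' with a chi-squared p on (groups - 1) df, plus group medians.  Thin,
#' structured wrapper over \code{stats::kruskal.test}.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list: \code{H}, \code{df}, \code{p}, \code{medians}.
#' @export
kruskalWallisGroups <- function(groups) {
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
       medians = vapply(groups, stats::median, numeric(1)))
}
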