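# Brute-force oracles, written from the defining formulas, independent of the
# package implementations they check.

oracleIcc <- function(x1, x2) {
  x <- cbind(x1, x2); n <- nrow(x); k <- 2
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sse <- sum((x - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  list(single = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
       mean = (msr - mse) / (msr + (msc - mse) / n))
}

oracleKruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

test_that("ICC is 1 for perfect agreement and near 0 for shuffled raters", {
  x <- c(3.1, 4.5, 2.2, 5.0, 3.3, 4.1, 2.8, 3.9)
  icc <- iccTwoWay(x, x)
  expect_equal(icc$iccSingle, 1)
  expect_equal(icc$iccMean, 1)

  set.seed(81)
  y <- rnorm(2000)
  icc0 <- iccTwoWay(y, sample(y))
  expect_lt(abs(icc0$iccSingle), 0.1)

  expect_warning(iccz <- iccTwoWay(rep(2, 5), rep(2, 5)), "zero between-subject")
  expect_identical(iccz$iccSingle, 0)
  expect_error(iccTwoWay(1:2, 2:3), "insufficient pairs")
})

test_that("ICC matches the ANOVA mean-square oracle on a hand dataset", {
  r1 <- c(9, 6, 8, 7, 10, 6)
  r2 <- c(2, 1, 4, 1, 5, 2)
  icc <- iccTwoWay(r1, r2)
  orc <- oracleIcc(r1, r2)
  expect_equal(icc$iccSingle, orc$single, tolerance = 1e-9)
  expect_equal(icc$iccMean, orc$mean, tolerance = 1e-9)
  # and on a second, well-agreeing set
  r3 <- r1 + c(0.2, -0.1, 0.3, 0, -0.2, 0.1)
  expect_equal(iccTwoWay(r1, r3)$iccSingle, oracleIcc(r1, r3)$single,
               tolerance = 1e-9)
})

test_that("ICC estimates the variance-component ratio", {
  set.seed(82)
  n <- 2000
  subj <- rnorm(n, sd = 1)
  e1 <- rnorm(n, sd = 0.6547)   # sigma_e^2 chosen for true ICC = 0.70
  e2 <- rnorm(n, sd = 0.6547)
  icc <- iccTwoWay(subj + e1, subj + e2)
  expect_lt(abs(icc$iccSingle - 0.70), 0.03)
})

test_that("Bland-Altman detects fixed and proportional bias and not their absence", {
  x <- c(10, 12, 9, 14, 11, 13, 10.5, 12.5)
  ident <- blandAltman(x, x)
  expect_equal(ident$fixedBias$mean, 0)
  expect_equal(ident$fixedBias$ciLow, 0)
  expect_equal(ident$fixedBias$ciHigh, 0)
  expect_true(is.na(ident$proportionalBias$r))

  set.seed(83)
  r1 <- rnorm(50, 10, 2)
  shift <- blandAltman(r1, r1 - 0.5 + rnorm(50, 0, 0.05))
  expect_gt(shift$fixedBias$ciLow, 0)
  expect_lt(shift$fixedBias$p, 0.001)
  # closed-form t interval on the differences
  d <- shift$d
  expect_equal(shift$fixedBias$ciLow,
               mean(d) - qt(0.975, 49) * sd(d) / sqrt(50), tolerance = 1e-9)
  expect_equal(shift$loa[["low"]], mean(d) - 1.96 * sd(d), tolerance = 1e-9)

  prop <- blandAltman(r1, 0.9 * r1)
  expect_gt(prop$proportionalBias$r, 0)
  expect_lt(prop$proportionalBias$p, 0.01)
  expect_equal(prop$proportionalBias$r,
               cor(r1 - 0.9 * r1, (r1 + 0.9 * r1) / 2), tolerance = 1e-9)
})

test_that("Spearman handles monotone, antitone and tied data", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearmanRho(x, exp(x))$rho, 1)
  expect_equal(spearmanRho(x, -x)$rho, -1)

  a <- c(1, 2, 2, 3, 4, 4, 5)
  b <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(spearmanRho(a, b)$rho, cor(rank(a), rank(b)), tolerance = 1e-9)
  expect_true(is.na(spearmanRho(rep(1, 5), 1:5)$rho))
})

test_that("standardized regression recovers designed effects", {
  set.seed(84)
  n <- 500
  d <- data.frame(age = rnorm(n), se = rnorm(n), al = rnorm(n))
  z <- function(v) (v - mean(v)) / sd(v)
  d$y <- -0.5 * z(d$age) - 0.5 * z(d$al) + rnorm(n, 0, 0.5)
  sr <- standardizedRegression(d, "y")
  tab <- sr$table
  target <- -0.5 / sqrt(0.75)   # response z-scoring rescales the betas
  expect_lt(abs(tab$beta[tab$predictor == "age"] - target), 0.08)
  expect_lt(abs(tab$beta[tab$predictor == "al"] - target), 0.08)
  expect_lt(abs(tab$beta[tab$predictor == "se"]), 0.08)
  expect_true(all(tab$p[tab$predictor %in% c("age", "al")] < 1e-10))

  d$null <- rnorm(n)
  sr0 <- standardizedRegression(d, "null")
  expect_true(all(abs(sr0$table$beta) < 0.1))
})

test_that("with orthogonal predictors each beta equals the simple correlation", {
  n <- 64
  d <- data.frame(age = rep(c(-1, 1), n / 2),
                  se = rep(c(-1, -1, 1, 1), n / 4),
                  al = rep(c(-1, 1), each = n / 2))
  set.seed(85)
  d$y <- 0.4 * d$age - 0.3 * d$al + rnorm(n)
  sr <- standardizedRegression(d, "y")
  for (p in c("age", "se", "al"))
    expect_equal(sr$table$beta[sr$table$predictor == p], cor(d$y, d[[p]]),
                 tolerance = 1e-9)
})

test_that("degenerate regression designs are rejected", {
  d <- data.frame(age = 1:10, se = 2 * (1:10), al = rnorm(10), y = rnorm(10))
  expect_error(standardizedRegression(d, "y"), "collinear")
  expect_error(standardizedRegression(d[1:5, ], "y"), "more than 5")
})

test_that("Kruskal-Wallis matches its rank-sum formula oracle", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  kw <- kruskalWallisGroups(same)
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  expect_identical(kw$df, 2L)

  set.seed(86)
  sep <- list(cc = rnorm(50, 79, 1), sl = rnorm(50, 67.6, 1),
              hl = rnorm(50, 63.3, 1))
  expect_lt(kruskalWallisGroups(sep)$p, 0.01)

  ties <- list(g1 = c(1, 2, 2, 4), g2 = c(2, 3, 3, 5), g3 = c(5, 6, 2, 2))
  expect_equal(kruskalWallisGroups(ties)$H, oracleKruskal(ties),
               tolerance = 1e-9)
  expect_error(kruskalWallisGroups(list(a = 1:3, b = numeric())), "empty group")
})
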