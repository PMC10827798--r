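#' Specification of a simulated subject cohort
#'
#' Describes a cross-sectional cohort of adult subjects (one eye each) whose
#' ocular covariates — age (years), spherical equivalent (SE, diopters) and
#' axial length (AL, mm) — exert linear effects on choroidal sublayer
#' thickness and luminal fraction.  Covariates are drawn independently from
#' Gaussians; each structural target is generated from standardized
#' coefficients plus Gaussian residual noise scaled so the marginal moments
#' match the requested means/sds.
#'
#' Default covariate moments are those of a typical adult clinic population
#' (age 59.6 +/- 14.8 y, AL 24.61 +/- 1.71 mm, SE -2.06 +/- 3.52 D); default
#' effect signs encode the established associations: older age thins every
#' sublayer and lowers L/C, longer axial length thins Sattler's and Haller's
#' layers but has little effect on the choriocapillaris.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param ageDist,alDist,seDist numeric \code{c(mean, sd)}.
#' @param effects named list, one element per structural target
#'   (\code{th_cc, th_sl, th_hl, lc_cc, lc_sl, lc_hl}), each a named vector
#'   of standardized slopes \code{c(age=, se=, al=)}.
#' @param thicknessMoments,lcMoments lists with \code{mean} and \code{sd}
#'   named vectors (um for thickness, percent for L/C).
#' @param rater2Sd second-rater measurement noise, as a fraction of each
#'   metric's between-subject sd (default 0.15).
#' @param seed integer RNG seed.
#' @return a list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 189L,
                       ageDist = c(59.6, 14.8),
                       alDist = c(24.61, 1.71),
                       seDist = c(-2.06, 3.52),
                       effects = list(
                         th_cc = c(age = -0.30, se = 0.15, al = -0.10),
                         th_sl = c(age = -0.45, se = 0.13, al = -0.38),
                         th_hl = c(age = -0.43, se = 0.07, al = -0.57),
                         lc_cc = c(age = -0.50, se = 0.25, al = -0.02),
                         lc_sl = c(age = -0.20, se = -0.09, al = -0.05),
                         lc_hl = c(age = -0.20, se = 0.06, al = -0.42)),
                       thicknessMoments = list(
                         mean = c(cc = 16.2, sl = 72.7, hl = 170.4),
                         sd = c(cc = 2.6, sl = 19.4, hl = 72.0)),
                       lcMoments = list(
                         mean = c(cc = 79.0, sl = 67.6, hl = 63.3),
                         sd = c(cc = 6.3, sl = 7.3, hl = 6.6)),
                       rater2Sd = 0.15, seed = 20240130L) {
  if (nSubjects < 2) stop("degenerate cohort: need at least 2 subjects")
  if (ageDist[2] < 0 || alDist[2] < 0 || seDist[2] < 0 || rater2Sd < 0)
    stop("all sds must be >= 0")
  structure(list(nSubjects = as.integer(nSubjects), ageDist = ageDist,
                 alDist = alDist, seDist = seDist, effects = effects,
                 thicknessMoments = thicknessMoments, lcMoments = lcMoments,
                 rater2Sd = rater2Sd, seed = as.integer(seed)),
            class = "cohortSpec")
}

# Draw one structural target from its standardized linear model.
.drawTarget <- function(z, beta, mean, sd) {
  beta <- beta[colnames(z)]
  r2 <- sum(beta^2)
  resid <- sqrt(max(0, 1 - r2))
  mean + sd * (as.numeric(z %*% beta) + stats::rnorm(nrow(z), 0, resid))
}

#' Simulate a subject cohort
#'
#' Draws covariates, maps them through the standardized effect coefficients
#' plus residual noise to per-subject structural parameters (sublayer
#' thicknesses and luminal fractions), and either emits per-layer metrics
#' directly (\code{mode = "parametric"}, areas computed for the rectangular
#' 1500-um analysis window) or renders one phantom per subject and leaves
#' metric measurement to the imaging pipeline (\code{mode = "imaging"}).
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param mode \code{"parametric"} or \code{"imaging"}.
#' @param phantomBase a \code{\link{phantomSpec}} supplying geometry and
#'   intensity settings for imaging mode; per-subject thicknesses, luminal
#'   fractions and seeds are overridden.
#' @return a list with \code{records} (data.frame, one row per subject:
#'   subject_id, age, se, al and — in parametric mode — metric columns
#'   \code{<layer>_<ca|la|sa|lc|cct>}), \code{truth} (the structural
#'   parameters) and, in imaging mode, \code{phantoms} (list of
#'   \code{ChoroidPhantom}).
#' @export
generateCohort <- function(spec, mode = c("parametric", "imaging"),
                           phantomBase = phantomSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  mode <- match.arg(mode)
  n <- spec$nSubjects

  sim <- .withSeed(spec$seed, {
    age <- stats::rnorm(n, spec$ageDist[1], spec$ageDist[2])
    se <- stats::rnorm(n, spec$seDist[1], spec$seDist[2])
    al <- stats::rnorm(n, spec$alDist[1], spec$alDist[2])
    z <- cbind(age = (age - spec$ageDist[1]) / spec$ageDist[2],
               se = (se - spec$seDist[1]) / spec$seDist[2],
               al = (al - spec$alDist[1]) / spec$alDist[2])
    tm <- spec$thicknessMoments; lm_ <- spec$lcMoments
    truth <- data.frame(subject_id = seq_len(n), age = age, se = se, al = al)
    for (ly in c("cc", "sl", "hl")) {
      th <- .drawTarget(z, spec$effects[[paste0("th_", ly)]],
                        tm$mean[[ly]], tm$sd[[ly]])
      lc <- .drawTarget(z, spec$effects[[paste0("lc_", ly)]],
                        lm_$mean[[ly]], lm_$sd[[ly]])
      truth[[paste0("th_", ly)]] <- pmax(th, phantomBase$axialScale)  # >= 1 px
      truth[[paste0("lc_", ly)]] <- pmin(pmax(lc, 2), 98)
    }
    list(truth = truth, seeds = sample.int(2147483646L, n))
  })
  truth <- sim$truth

  if (mode == "parametric") {
    half <- round(750 / phantomBase$lateralScale)
    widthUm <- 2 * half * phantomBase$lateralScale
    records <- truth[c("subject_id", "age", "se", "al")]
    for (ly in c("cc", "sl", "hl")) {
      ca <- truth[[paste0("th_", ly)]] * widthUm * 1e-6
      lc <- truth[[paste0("lc_", ly)]]
      records[[paste0(ly, "_ca")]] <- ca
      records[[paste0(ly, "_la")]] <- ca * lc / 100
      records[[paste0(ly, "_sa")]] <- ca * (1 - lc / 100)
      records[[paste0(ly, "_lc")]] <- lc
      records[[paste0(ly, "_cct")]] <- truth[[paste0("th_", ly)]]
    }
    records$total_ca <- records$cc_ca + records$sl_ca + records$hl_ca
    records$total_la <- records$cc_la + records$sl_la + records$hl_la
    records$total_sa <- records$cc_sa + records$sl_sa + records$hl_sa
    records$total_lc <- 100 * records$total_la / records$total_ca
    records$total_cct <- records$cc_cct + records$sl_cct + records$hl_cct
    return(list(records = records, truth = truth, phantoms = NULL))
  }

  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- phantomBase
    ps$layerThicknessUm <- c(cc = truth$th_cc[i], sl = truth$th_sl[i],
                             hl = truth$th_hl[i])
    ps$lumenFraction <- c(cc = truth$lc_cc[i] / 100, sl = truth$lc_sl[i] / 100,
                          hl = truth$lc_hl[i] / 100)
    # vessel caliber scales with layer size: cap radii so even the smallest
    # proposable lumen fits inside a thin subject's layer
    for (ly in c("cc", "sl", "hl")) {
      capUm <- ps$layerThicknessUm[[ly]] / (2 * ps$lumenAspect)
      r <- ps$lumenRadiusUm[[ly]]
      ps$lumenRadiusUm[[ly]] <- c(min(r[1], 0.5 * capUm), min(r[2], capUm))
    }
    ps$seed <- sim$seeds[i]
    class(ps) <- "phantomSpec"
    phantoms[[i]] <- generatePhantom(ps)
  }
  records <- truth[c("subject_id", "age", "se", "al")]
  list(records = records, truth = truth, phantoms = phantoms)
}

#' Simulate a second rater's measurements
#'
#' Adds independent Gaussian measurement noise (and, optionally, a fixed
#' offset and a proportional component for bias-injection experiments) to
#' every metric column of a cohort record table, appending \code{_r2}
#' columns.  With \code{sd = 0} and no bias terms the second rater agrees
#' perfectly and every downstream ICC is 1.
#'
#' @param records data.frame with metric columns (everything except
#'   subject_id/age/se/al is treated as a metric).
#' @param sd either a single fraction of each metric's between-subject sd,
#'   or a named vector of absolute sds per metric column.
#' @param fixedOffset named numeric, constant added to the second rater's
#'   value for the named columns.
#' @param proportional named numeric, slope of an extra term
#'   \code{proportional * value} for the named columns.
#' @param seed integer RNG seed.
#' @return \code{records} with added \code{<metric>_r2} columns.
#' @export
simulateSecondRater <- function(records, sd = 0.15, fixedOffset = NULL,
                                proportional = NULL, seed = 20240130L) {
  if (any(sd < 0)) stop("invalid noise: sd must be >= 0")
  metricCols <- setdiff(names(records),
                        c("subject_id", "age", "se", "al",
                          grep("_r2$", names(records), value = TRUE)))
  .withSeed(seed, {
    for (m in metricCols) {
      s <- if (length(sd) > 1 || !is.null(names(sd))) {
        if (!m %in% names(sd)) 0 else sd[[m]]
      } else sd * stats::sd(records[[m]], na.rm = TRUE)
      if (!is.finite(s)) s <- 0
      v <- records[[m]] + stats::rnorm(nrow(records), 0, s)
      if (!is.null(fixedOffset) && m %in% names(fixedOffset))
        v <- v + fixedOffset[[m]]
      if (!is.null(proportional) && m %in% names(proportional))
        v <- v + proportional[[m]] * records[[m]]
      records[[paste0(m, "_r2")]] <- v
    }
    records
  })
}
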