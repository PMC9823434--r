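#' Dual-waveband emission ratio
#'
#' The 730-over-685 nm baseline emission ratio,
#' \code{Fo730 / Fo685}. Cyanobacterial photosystem I chlorophyll a
#' emits near 730 nm without contributing variable fluorescence, so the
#' ratio rises with the cyanobacterial share of the community when
#' chlorophyll-a absorption is targeted (GOR excitation).
#'
#' @param fo685 baseline fluorescence at 685 nm, a.u.; must be > 0.
#' @param fo730 baseline fluorescence at 730 nm, a.u.; >= 0.
#' @return dimensionless ratio (vectorised).
#' @export
emissionRatio <- function(fo685, fo730) {
  if (any(fo685 <= 0)) stop("F_o(685) must be > 0")
  if (any(fo730 < 0)) stop("F_o(730) must be >= 0")
  fo730 / fo685
}

#' Relative group abundance
#'
#' @param counts named numeric, cells mL^-1 per group; >= 0 with a
#'   positive total.
#' @return named fractions summing to 1.
#' @export
relativeAbundance <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  tot <- sum(counts)
  if (tot <= 0) stop("total count is zero: relative abundance undefined")
  counts / tot
}

#' Simple linear regression with slope test
#'
#' Ordinary least squares of \code{y} on \code{x} with the classical
#' two-sided t-test on the slope and the adjusted coefficient of
#' determination \eqn{R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-2)}. This is
#' the per-regression statistical surface used for the field
#' correlations (no multiple-testing correction is applied, matching
#' how such per-marker regressions are conventionally reported).
#'
#' @param x,y equal-length numeric vectors, n >= 3; \code{x} must not
#'   be constant. NA pairs are dropped.
#' @param predictorName,responseName labels carried into the result.
#' @return list with \code{n, slope, intercept, slopeSE, tValue,
#'   pValue, r2, adjR2, predictorName, responseName}.
#' @export
olsRegress <- function(x, y, predictorName = deparse(substitute(x)),
                       responseName = deparse(substitute(y))) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 complete (x, y) pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant: slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adjR2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(n = n, slope = slope, intercept = intercept, slopeSE = se,
       tValue = tval, pValue = pval, r2 = r2, adjR2 = adjR2,
       predictorName = predictorName, responseName = responseName)
}

#' Emission-ratio versus abundance experiment
#'
#' The statistical core of the cyanobacteria discriminator, run on the
#' synthetic scenario: for each noise realisation, (i) simulate a
#' seasonal succession, (ii) compute the community's dark F_o at 685
#' and 730 nm under GOR excitation with multiplicative lognormal
#' measurement noise, (iii) form the 730/685 emission ratio, (iv)
#' estimate relative cyanobacterial abundance from simulated
#' Sedgewick-Rafter counts, and (v) regress ratio on relative
#' abundance.
#'
#' @param scenario a \code{\linkS4class{SuccessionScenario}}.
#' @param models group optical models.
#' @param nRealisations number of independent realisations.
#' @param measurementSdLog lognormal measurement noise sd on each
#'   F_o band (natural-log scale; default 0.05).
#' @param protocol excitation protocol for the ratio (default GOR).
#' @param seed base integer seed.
#' @return data.frame with one row per realisation: \code{slope,
#'   pValue, adjR2}.
#' @export
ratioAbundanceExperiment <- function(scenario = successionScenario(),
                                     models = defaultGroupModels(),
                                     nRealisations = 200,
                                     measurementSdLog = 0.05,
                                     protocol = "GOR", seed = 1) {
  p <- getProtocol(protocol)
  out <- vector("list", nRealisations)
  for (r in seq_len(nRealisations)) {
    states <- simulateSuccession(scenario,
                                 seed = substreamSeed(seed, "succ", r))
    nD <- nrow(states)
    fo685 <- fo730 <- numeric(nD)
    for (i in seq_len(nD)) {
      ab <- c(algae = states$algae[i],
              cyanobacteria = states$cyanobacteria[i])
      fo685[i] <- communityFluorescence(ab, models, p, 685)["fo"]
      fo730[i] <- communityFluorescence(ab, models, p, 730)["fo"]
    }
    if (measurementSdLog > 0) {
      eps <- withSeed(substreamSeed(seed, "meas", r),
                      stats::rnorm(2 * nD, 0, measurementSdLog))
      fo685 <- fo685 * exp(eps[seq_len(nD)])
      fo730 <- fo730 * exp(eps[nD + seq_len(nD)])
    }
    ratio <- emissionRatio(fo685, fo730)
    cntA <- simulateMicroscopy(states$algae,
                               seed = substreamSeed(seed, "countA", r))
    cntC <- simulateMicroscopy(states$cyanobacteria,
                               seed = substreamSeed(seed, "countC", r))
    relC <- cntC / (cntA + cntC)
    fit <- olsRegress(relC, ratio, "relative_cyanobacteria",
                      "Fo_ratio_730_685")
    out[[r]] <- data.frame(slope = fit$slope, pValue = fit$pValue,
                           adjR2 = fit$adjR2)
  }
  do.call(rbind, out)
}

#' Type-I error calibration of the slope test
#'
#' Simulates \code{nSim} null datasets (y independent of x, Gaussian)
#' at sample size \code{n} and returns the fraction of regressions
#' with p below \code{level}; a calibrated test attains the nominal
#' level.
#'
#' @param nSim number of null simulations.
#' @param n sample size per simulation.
#' @param level nominal significance level.
#' @param seed integer seed.
#' @return observed rejection fraction.
#' @export
typeIErrorRate <- function(nSim = 1000, n = 23, level = 0.05, seed = 1) {
  withSeed(seed, {
    rej <- logical(nSim)
    for (s in seq_len(nSim)) {
      x <- stats::rnorm(n)
      y <- stats::rnorm(n)
      rej[s] <- olsRegress(x, y)$pValue < level
    }
    mean(rej)
  })
}
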