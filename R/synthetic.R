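#' Default group optical models
#'
#' Synthetic optical constants for the two functional groups. The
#' values are package defaults constructed to satisfy the
#' pigment-targeting structure of the excitation protocols, not
#' measurements: the algal cross-section spectrum peaks in the blue
#' (chlorophylls a/b/c, carotenoids; 416-452 nm) and is small in the
#' green-orange, the cyanobacterial spectrum peaks at 594-622 nm
#' (phycobilipigments) and is small in the blue, and the cyanobacterial
#' PSI chlorophyll-a allocation routes a larger fraction of baseline
#' emission to 730 nm than in algae.
#'
#' @return named list of two \code{\linkS4class{GroupOpticalModel}}
#'   (\code{algae}, \code{cyanobacteria}).
#' @export
defaultGroupModels <- function() {
  wb <- instrumentWavebands()
  mk <- function(name, sig, fvfm, psi, foPerCell) {
    names(sig) <- as.character(wb)
    new("GroupOpticalModel", name = name, sigmaSpectrum = sig,
        fvfmMax = fvfm, psiFraction730 = psi, foPerCell = foPerCell)
  }
  list(
    algae = mk("algae",
               c(4.5, 5.0, 4.2, 3.2, 1.2, 0.5, 0.4),
               fvfm = 0.65, psi = 0.08, foPerCell = 2e-7),
    cyanobacteria = mk("cyanobacteria",
                       c(0.5, 0.6, 0.7, 0.9, 2.5, 4.5, 4.0),
                       fvfm = 0.45, psi = 0.35, foPerCell = 5e-8)
  )
}

# PSII emission partition between the two detection bands: fraction of
# PSII (variable-capable) emission passed by each filter. PSI
# chlorophyll-a emission adds to the 730 nm baseline only, via each
# group's psiFraction730.
.PSII_PARTITION <- c("685" = 1.0, "730" = 0.25)

# Per-group building blocks of the community signal under one protocol:
# base: abundance x foPerCell x sum_lambda(dose_lambda x sigma_g(lambda))
# sigmaEff: dose-weighted mean cross-section (sets the induction rate).
groupSignal <- function(abundance, model, protocol) {
  p <- getProtocol(protocol)
  sig <- model@sigmaSpectrum[as.character(p@wavebands)]
  doseSigma <- sum(p@intensities * sig)
  list(base = abundance * model@foPerCell * doseSigma,
       sigmaEff = if (sum(p@intensities) > 0)
         doseSigma / sum(p@intensities) else 0)
}

#' Community fluorescence forward model
#'
#' Dark-level (F_o) and saturated (F_m) fluorescence of a mixed
#' community under one protocol and emission band, as a sum of linear
#' per-group contributions: each group contributes
#' \code{abundance x foPerCell x sum(dose x sigma(lambda))} of baseline
#' PSII signal, partitioned between the 685 and 730 nm bands, plus a
#' PSI chlorophyll-a term at 730 nm (\code{psiFraction730}), plus a
#' variable component scaled by the group's maximum F_v/F_m. Linear and
#' monotone in every abundance; additive over protocols that share LED
#' settings.
#'
#' @param abundance named numeric, cells mL^-1 per group; names must
#'   match \code{names(models)}.
#' @param models list of \code{\linkS4class{GroupOpticalModel}}.
#' @param protocol protocol name or object.
#' @param emissionBand 685 or 730.
#' @return named numeric \code{c(fo = , fm = )}, a.u.
#' @export
communityFluorescence <- function(abundance, models = defaultGroupModels(),
                                  protocol = "GOR", emissionBand = 685) {
  stopifnot(emissionBand %in% c(685, 730))
  if (is.null(names(abundance)) ||
      !all(names(abundance) %in% names(models)))
    stop("'abundance' must be named by groups present in 'models'")
  if (any(abundance < 0)) stop("abundances must be >= 0")
  part <- .PSII_PARTITION[[as.character(emissionBand)]]
  foT <- 0; fmT <- 0
  for (g in names(abundance)) {
    m <- models[[g]]
    gs <- groupSignal(abundance[[g]], m, protocol)
    foG <- gs$base * (part + if (emissionBand == 730) m@psiFraction730 else 0)
    vG <- gs$base * part * m@fvfmMax / (1 - m@fvfmMax)
    foT <- foT + foG
    fmT <- fmT + foG + vG
  }
  c(fo = foT, fm = fmT)
}

#' Simulate a mixed-community ST trace
#'
#' Superposes the per-group induction curves (each group rises with its
#' own dose-weighted sigma) on a uniform time grid and adds Gaussian
#' detector noise. Under actinic background E the kinetic cross-section
#' and the variable component are quenched by
#' \eqn{q = P_q/(P_q + E)} (a simple downregulation proxy producing the
#' saturating J(E) shape the Webb fit assumes); F_o is unaffected.
#'
#' @inheritParams communityFluorescence
#' @param actinicE actinic background, umol photons m^-2 s^-1.
#' @param quenchPq half-saturation irradiance of the quenching proxy.
#' @param noiseSd additive Gaussian noise sd, a.u.
#' @param nSamples samples per trace; default 1 per us plus t = 0.
#' @param seed optional integer seed.
#' @return an \code{\linkS4class{STTrace}}.
#' @export
communitySTTrace <- function(abundance, models = defaultGroupModels(),
                             protocol = "GOR", emissionBand = 685,
                             actinicE = 0, quenchPq = 300, noiseSd = 0,
                             nSamples = NULL, seed = NULL) {
  p <- getProtocol(protocol)
  if (is.null(nSamples)) nSamples <- p@pulseLength + 1
  stopifnot(nSamples >= 8)
  tt <- seq(0, p@pulseLength, length.out = nSamples)
  part <- .PSII_PARTITION[[as.character(emissionBand)]]
  q <- quenchPq / (quenchPq + actinicE)
  flux <- umolToPhotonFlux(combinedIntensity(p))
  f <- rep(0, length(tt))
  for (g in names(abundance)) {
    m <- models[[g]]
    gs <- groupSignal(abundance[[g]], m, p)
    foG <- gs$base * (part + if (emissionBand == 730) m@psiFraction730 else 0)
    vG <- gs$base * part * m@fvfmMax / (1 - m@fvfmMax) * q
    alphaG <- gs$sigmaEff * q * flux
    f <- f + foG + vG * (1 - exp(-alphaG * tt))
  }
  if (noiseSd > 0)
    f <- withSeed(seed, f + stats::rnorm(length(f), 0, noiseSd))
  new("STTrace", time = tt, fluorescence = pmax(f, 0), protocol = p@name,
      emissionBand = emissionBand, actinicE = actinicE)
}

#' Construct a succession scenario
#'
#' Defaults emulate a temperate reservoir season sampled on 23 dates:
#' an early algal (diatom-type) pulse peaking near date 3 and decaying,
#' and a logistic cyanobacterial rise through mid-season, with
#' multiplicative lognormal date-to-date noise (sd 0.3 on the log
#' scale). Amplitudes are free synthetic parameters.
#'
#' @param nDates number of sampling dates, >= 3.
#' @param algaeBase,algaePeak,algaePeakTime,algaePeakWidth algal
#'   Gaussian-pulse parameters (cells mL^-1; date units).
#' @param cyanoMin,cyanoMax,cyanoMidpoint,cyanoRate cyanobacterial
#'   logistic parameters.
#' @param noiseSdLog lognormal noise sd, natural-log scale.
#' @return a \code{\linkS4class{SuccessionScenario}}.
#' @export
successionScenario <- function(nDates = 23,
                               algaeBase = 400, algaePeak = 8000,
                               algaePeakTime = 3, algaePeakWidth = 2.5,
                               cyanoMin = 800, cyanoMax = 60000,
                               cyanoMidpoint = 8, cyanoRate = 2.5,
                               noiseSdLog = 0.3) {
  new("SuccessionScenario", nDates = nDates, algaeBase = algaeBase,
      algaePeak = algaePeak, algaePeakTime = algaePeakTime,
      algaePeakWidth = algaePeakWidth, cyanoMin = cyanoMin,
      cyanoMax = cyanoMax, cyanoMidpoint = cyanoMidpoint,
      cyanoRate = cyanoRate, noiseSdLog = noiseSdLog)
}

#' Simulate a seasonal succession
#'
#' Evaluates the scenario's deterministic trajectories at dates
#' 1..nDates and applies independent multiplicative lognormal noise per
#' date and group. With the default scenario the community is
#' algae-dominated at the start and cyanobacteria-dominated from
#' mid-season onward.
#'
#' @param scenario a \code{\linkS4class{SuccessionScenario}}.
#' @param seed integer seed; same seed, same series.
#' @return data.frame with columns \code{date}, \code{algae},
#'   \code{cyanobacteria} (cells mL^-1).
#' @export
simulateSuccession <- function(scenario = successionScenario(),
                               seed = NULL) {
  stopifnot(is(scenario, "SuccessionScenario"))
  d <- seq_len(scenario@nDates)
  algae <- scenario@algaeBase + scenario@algaePeak *
    exp(-0.5 * ((d - scenario@algaePeakTime) / scenario@algaePeakWidth)^2)
  cyano <- scenario@cyanoMin + (scenario@cyanoMax - scenario@cyanoMin) /
    (1 + exp(-(d - scenario@cyanoMidpoint) / scenario@cyanoRate))
  if (scenario@noiseSdLog > 0) {
    noise <- withSeed(seed,
      matrix(stats::rnorm(2 * length(d), 0, scenario@noiseSdLog),
             ncol = 2))
    algae <- algae * exp(noise[, 1])
    cyano <- cyano * exp(noise[, 2])
  }
  data.frame(date = d, algae = algae, cyanobacteria = cyano)
}

#' Simulate a Sedgewick-Rafter microscopy count
#'
#' Emulates counting \code{nUnits} randomly selected units of
#' \code{unitVolumeUl} microlitres each from a 1 mL gridded chamber:
#' the total count is Poisson with mean
#' \code{trueDensity x nUnits x unitVolumeUl / 1000}, and the density
#' estimate is the count divided by the counted volume (x 10 at the
#' defaults of 100 x 1 uL). The estimator is unbiased with variance
#' \code{trueDensity x 10} at the defaults.
#'
#' @param trueDensity cells mL^-1, >= 0 (vectorised).
#' @param nUnits number of counting units (default 100).
#' @param unitVolumeUl volume per unit, uL (default 1).
#' @param seed optional integer seed.
#' @return estimated cells mL^-1, same length as \code{trueDensity}.
#' @export
simulateMicroscopy <- function(trueDensity, nUnits = 100,
                               unitVolumeUl = 1, seed = NULL) {
  stopifnot(all(trueDensity >= 0), nUnits >= 1, unitVolumeUl > 0)
  volMl <- nUnits * unitVolumeUl / 1000
  counts <- withSeed(seed,
                     stats::rpois(length(trueDensity), trueDensity * volMl))
  counts / volMl
}

#' Microscopy scale factor
#'
#' Reciprocal of the counted volume: the factor converting a raw count
#' into cells mL^-1 (10 at the default 100 x 1 uL).
#'
#' @inheritParams simulateMicroscopy
#' @return scalar factor.
#' @export
microscopyScaleFactor <- function(nUnits = 100, unitVolumeUl = 1) {
  1000 / (nUnits * unitVolumeUl)
}

#' @export
setMethod("show", "GroupOpticalModel", function(object) {
  cat("GroupOpticalModel \"", object@name, "\" (synthetic defaults)\n",
      sep = "")
  cat("  sigma spectrum (nm^2): ",
      paste(sprintf("%s=%.2g", names(object@sigmaSpectrum),
                    object@sigmaSpectrum), collapse = " "), "\n", sep = "")
  cat(sprintf("  FvFm_max = %.2f  psiFraction730 = %.2f  foPerCell = %.3g\n",
              object@fvfmMax, object@psiFraction730, object@foPerCell))
})
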