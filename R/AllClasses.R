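#' @import methods
NULL

#' Excitation protocol: a set of LEDs fired together during an ST pulse
#'
#' An \code{ExcitationProtocol} bundles the LED wavebands fired
#' simultaneously during a single-turnover (ST) saturation pulse, the
#' per-LED intensities actually set, the pulse length and the emission
#' bands recorded. The photon irradiance delivered during the pulse
#' (E_ST) is the arithmetic sum of the set LED intensities; see
#' \code{\link{combinedIntensity}}.
#'
#' @slot name protocol label, e.g. \code{"GOR"} or a custom label for
#'   single-waveband spectral pulses.
#' @slot wavebands numeric, LED centre wavelengths in nm; each must be
#'   one of the seven instrument wavebands (416, 452, 473, 495, 534,
#'   594, 622 nm). The 452 nm waveband may appear twice (two blue LEDs).
#' @slot intensities numeric, set intensity per LED in
#'   \eqn{\mu}mol photons m\eqn{^{-2}} s\eqn{^{-1}}; each must be
#'   positive and no larger than its LED's maximum.
#' @slot pulseLength pulse duration in \eqn{\mu}s, 100 or 200.
#' @slot emissionBands numeric subset of \code{c(685, 730)} nm.
#'
#' @seealso \code{\link{protocolRegistry}}, \code{\link{getProtocol}}
#' @export
setClass("ExcitationProtocol",
  representation(
    name = "character",
    wavebands = "numeric",
    intensities = "numeric",
    pulseLength = "numeric",
    emissionBands = "numeric"
  )
)

setValidity("ExcitationProtocol", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  if (length(object@wavebands) < 1L)
    msgs <- c(msgs, "protocol must contain at least one LED")
  if (length(object@wavebands) != length(object@intensities))
    msgs <- c(msgs, "'wavebands' and 'intensities' lengths differ")
  bad <- setdiff(object@wavebands, instrumentWavebands())
  if (length(bad))
    msgs <- c(msgs, paste0("unknown waveband(s): ",
                           paste(bad, collapse = ", "),
                           " (instrument wavebands are ",
                           paste(instrumentWavebands(), collapse = ", "), ")"))
  if (any(!is.finite(object@intensities)) || any(object@intensities <= 0))
    msgs <- c(msgs, "all LED intensities must be finite and > 0")
  if (length(object@wavebands) == length(object@intensities) &&
      !length(bad)) {
    mx <- ledMaxIntensity(object@wavebands)
    over <- object@intensities > mx * (1 + 1e-9)
    if (any(over))
      msgs <- c(msgs, paste0("intensity exceeds LED maximum at ",
                             paste(object@wavebands[over], collapse = ", "),
                             " nm"))
  }
  if (length(object@pulseLength) != 1L ||
      !object@pulseLength %in% c(100, 200))
    msgs <- c(msgs, "'pulseLength' must be 100 or 200 us")
  if (length(object@emissionBands) < 1L ||
      length(setdiff(object@emissionBands, c(685, 730))))
    msgs <- c(msgs, "'emissionBands' must be a non-empty subset of {685, 730}")
  if (length(msgs)) msgs else TRUE
})

#' Single-turnover fluorescence trace
#'
#' Time-resolved fluorescence recorded during one ST saturation pulse at
#' one excitation protocol, emission band and actinic background.
#'
#' @slot time numeric, \eqn{\mu}s; strictly increasing, starting at 0.
#' @slot fluorescence numeric, arbitrary units; finite and non-negative,
#'   same length as \code{time}.
#' @slot protocol name of the excitation protocol used.
#' @slot emissionBand 685 or 730 (nm).
#' @slot actinicE actinic background irradiance in
#'   \eqn{\mu}mol photons m\eqn{^{-2}} s\eqn{^{-1}} (0 = dark-adapted).
#'
#' @seealso \code{\link{simulateSTTrace}}, \code{\link{fitSTTrace}},
#'   \code{\link{readTraces}}
#' @export
setClass("STTrace",
  representation(
    time = "numeric",
    fluorescence = "numeric",
    protocol = "character",
    emissionBand = "numeric",
    actinicE = "numeric"
  )
)

setValidity("STTrace", function(object) {
  msgs <- character(0)
  if (length(object@time) != length(object@fluorescence))
    msgs <- c(msgs, "'time' and 'fluorescence' lengths differ")
  if (length(object@time) < 2L)
    msgs <- c(msgs, "a trace needs at least 2 samples")
  else {
    if (object@time[1L] != 0)
      msgs <- c(msgs, "time must start at 0")
    if (any(diff(object@time) <= 0))
      msgs <- c(msgs, "time must be strictly increasing")
  }
  if (any(!is.finite(object@fluorescence)) || any(object@fluorescence < 0))
    msgs <- c(msgs, "fluorescence must be finite and >= 0")
  if (length(object@emissionBand) != 1L ||
      !object@emissionBand %in% c(685, 730))
    msgs <- c(msgs, "'emissionBand' must be 685 or 730")
  if (length(object@actinicE) != 1L || !is.finite(object@actinicE) ||
      object@actinicE < 0)
    msgs <- c(msgs, "'actinicE' must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' Fitted parameters of a single-turnover induction curve
#'
#' Result of inverting the ST induction model on one trace: minimum and
#' maximum fluorescence yields (F_o, F_m), the functional absorption
#' cross-section of PSII photochemistry (sigma_PII, nm^2 PSII^-1), the
#' derived initial photon-use rate alpha_PII = sigma_PII x photon flux
#' (photons PSII^-1 us^-1), optional PSII connectivity rho, fit RMSE and
#' a saturation quality flag.
#'
#' @slot fo,fm minimum / maximum fluorescence, a.u.; \code{fm >= fo >= 0}.
#' @slot sigmaPII nm^2 PSII^-1.
#' @slot alphaPII photons PSII^-1 us^-1; equals
#'   \code{sigmaPII * umolToPhotonFlux(eST)}.
#' @slot rho connectivity in [0, 1); 0 when connectivity fitting is off.
#' @slot rmse root-mean-square residual of the fit, a.u.
#' @slot saturationStatus one of \code{"optimal"}, \code{"suboptimal"},
#'   \code{"unsaturated"}.
#' @slot converged logical; \code{FALSE} flags a non-converged fit
#'   (parameters are then best-effort, see \code{diagnostics}).
#' @slot eST pulse photon irradiance used, umol photons m^-2 s^-1.
#' @slot pulseLength us.
#' @slot nObs number of samples fitted.
#' @slot diagnostics character; optimiser messages for flagged fits.
#'
#' @seealso \code{\link{fitSTTrace}}, \code{\link{fvfm}}
#' @export
setClass("STFitResult",
  representation(
    fo = "numeric", fm = "numeric",
    sigmaPII = "numeric", alphaPII = "numeric",
    rho = "numeric", rmse = "numeric",
    saturationStatus = "character",
    converged = "logical",
    eST = "numeric", pulseLength = "numeric",
    nObs = "numeric", diagnostics = "character"
  )
)

setValidity("STFitResult", function(object) {
  msgs <- character(0)
  if (!(object@fm >= object@fo && object@fo >= 0))
    msgs <- c(msgs, "requires fm >= fo >= 0")
  if (object@sigmaPII < 0) msgs <- c(msgs, "sigmaPII must be >= 0")
  if (object@rho < 0 || object@rho >= 1)
    msgs <- c(msgs, "rho must lie in [0, 1)")
  aExp <- object@sigmaPII * umolToPhotonFlux(object@eST)
  if (aExp > 0 && abs(object@alphaPII - aExp) > 1e-9 * aExp)
    msgs <- c(msgs, "alphaPII inconsistent with sigmaPII * flux(eST)")
  if (!object@saturationStatus %in% c("optimal", "suboptimal", "unsaturated"))
    msgs <- c(msgs, "invalid saturationStatus")
  if (length(msgs)) msgs else TRUE
})

#' Webb exponential light-response curve fit
#'
#' Fit of \eqn{J(E) = P_{max}(1 - \exp(-\alpha_{LC} E / P_{max}))} to
#' the per-step electron transport rates of a fluorescence light curve.
#'
#' @slot modelName currently \code{"webb_exponential"}.
#' @slot pMax asymptotic light-saturated rate, electrons PSII^-1 s^-1.
#' @slot alphaLC initial slope, electrons PSII^-1 s^-1 per umol photons
#'   m^-2 s^-1.
#' @slot rmse fit RMSE.
#' @slot converged logical.
#' @slot atUpperBound logical; \code{TRUE} when \code{pMax} pegged its
#'   upper box bound, i.e. the data are effectively linear in E and the
#'   asymptote is not identified.
#' @export
setClass("PICurveFit",
  representation(
    modelName = "character", pMax = "numeric", alphaLC = "numeric",
    rmse = "numeric", converged = "logical", atUpperBound = "logical"
  )
)

#' Aggregated fluorescence light curve
#'
#' Twelve ST acquisitions across stepped actinic irradiances, reduced to
#' the aggregate photophysiology used for reporting: means of F_o,
#' F_v/F_m, alpha_PII and sigma_PII over the first five (lowest) light
#' steps, the maximum per-step electron transport rate (ETR_max) and the
#' Webb light-response fit (P_max, alpha_LC).
#'
#' @slot steps data.frame with one row per actinic step, columns
#'   \code{actinicE, fo, fm, fvfm, sigmaPII, alphaPII, jPII, converged}.
#' @slot foMean5,fvfmMean5,alphaMean5,sigmaMean5 means over the first
#'   five light steps.
#' @slot etrMax maximum \code{jPII} across steps, electrons PSII^-1 s^-1.
#' @slot piFit a \code{\linkS4class{PICurveFit}}.
#' @slot protocol excitation protocol name.
#' @slot nFailed number of steps whose ST fit failed (recorded as NA
#'   rows, not fatal).
#'
#' @seealso \code{\link{runFLC}}, \code{\link{aggregateFLC}}
#' @export
setClass("FLCResult",
  representation(
    steps = "data.frame",
    foMean5 = "numeric", fvfmMean5 = "numeric",
    alphaMean5 = "numeric", sigmaMean5 = "numeric",
    etrMax = "numeric", piFit = "PICurveFit",
    protocol = "character", nFailed = "numeric"
  )
)

#' Seven-waveband PSII excitation spectrum
#'
#' F_v and sigma_PII measured waveband-by-waveband across the seven
#' instrument LEDs under one dose-optimisation mode.
#'
#' @slot wavebands the 7 LED centres, nm.
#' @slot fv variable fluorescence per waveband, a.u. (NA = failed fit).
#' @slot sigmaPII nm^2 PSII^-1 per waveband (NA = failed fit).
#' @slot mode \code{"algae_optimised"} or \code{"cyanobacteria_optimised"}.
#' @slot dose applied pulse intensity per waveband, umol photons m^-2 s^-1.
#'
#' @seealso \code{\link{measureSpectrum}}, \code{\link{spectrumContrast}}
#' @export
setClass("ExcitationSpectrum",
  representation(
    wavebands = "numeric", fv = "numeric", sigmaPII = "numeric",
    mode = "character", dose = "numeric"
  )
)

setValidity("ExcitationSpectrum", function(object) {
  msgs <- character(0)
  n <- length(instrumentWavebands())
  if (length(object@wavebands) != n || length(object@fv) != n ||
      length(object@sigmaPII) != n || length(object@dose) != n)
    msgs <- c(msgs, sprintf("all fields must have %d entries", n))
  if (any(object@fv < 0, na.rm = TRUE))
    msgs <- c(msgs, "fv must be >= 0")
  if (any(object@sigmaPII < 0, na.rm = TRUE))
    msgs <- c(msgs, "sigmaPII must be >= 0")
  if (!object@mode %in% c("algae_optimised", "cyanobacteria_optimised"))
    msgs <- c(msgs, "invalid mode")
  if (length(msgs)) msgs else TRUE
})

#' Optical model of a phytoplankton group
#'
#' The per-group constants from which the synthetic community forward
#' model builds fluorescence: a PSII absorption cross-section spectrum
#' over the seven instrument wavebands, the dark-adapted maximum
#' F_v/F_m, the fraction of baseline (F_o-level) emission routed to the
#' 730 nm band by photosystem I chlorophyll a, and the F_o signal per
#' cell at unit dose-weighted cross-section.
#'
#' All values are synthetic package defaults chosen to satisfy the
#' pigment-targeting semantics of the instrument protocols (algae peak
#' in the blue, cyanobacteria in the green-orange, cyanobacterial PSI
#' 730 nm allocation larger); they are not measurements.
#'
#' @slot name \code{"algae"} or \code{"cyanobacteria"}.
#' @slot sigmaSpectrum named numeric, nm^2 PSII^-1 at each of the 7
#'   wavebands.
#' @slot fvfmMax dark-adapted F_v/F_m, in [0, 1).
#' @slot psiFraction730 extra 730 nm baseline emission per unit of the
#'   group's F_o-level signal, contributed by PSI chlorophyll a.
#' @slot foPerCell a.u. per (cell mL^-1) per (umol photons m^-2 s^-1
#'   x nm^2) of summed dose-weighted cross-section.
#'
#' @seealso \code{\link{defaultGroupModels}},
#'   \code{\link{communityFluorescence}}
#' @export
setClass("GroupOpticalModel",
  representation(
    name = "character", sigmaSpectrum = "numeric", fvfmMax = "numeric",
    psiFraction730 = "numeric", foPerCell = "numeric"
  )
)

setValidity("GroupOpticalModel", function(object) {
  msgs <- character(0)
  wb <- instrumentWavebands()
  if (length(object@sigmaSpectrum) != length(wb) ||
      !identical(names(object@sigmaSpectrum), as.character(wb)))
    msgs <- c(msgs, "sigmaSpectrum must be named by the 7 instrument wavebands")
  if (any(object@sigmaSpectrum < 0)) msgs <- c(msgs, "sigmaSpectrum >= 0")
  if (object@fvfmMax < 0 || object@fvfmMax >= 1)
    msgs <- c(msgs, "fvfmMax must lie in [0, 1)")
  if (object@psiFraction730 < 0) msgs <- c(msgs, "psiFraction730 >= 0")
  if (object@foPerCell < 0) msgs <- c(msgs, "foPerCell >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Seasonal succession scenario
#'
#' Parameters of the two-group synthetic succession: a spring algal
#' (diatom-type) pulse declining into summer and a logistic
#' cyanobacterial rise, sampled at \code{nDates} dates with
#' multiplicative lognormal date-to-date noise.
#'
#' @slot nDates number of sampling dates (default 23).
#' @slot algaeBase,algaePeak,algaePeakTime,algaePeakWidth Gaussian-pulse
#'   parameters of the algal trajectory, cells mL^-1 and date units.
#' @slot cyanoMin,cyanoMax,cyanoMidpoint,cyanoRate logistic parameters
#'   of the cyanobacterial trajectory.
#' @slot noiseSdLog lognormal noise sd on the natural-log scale
#'   (default 0.3).
#'
#' @seealso \code{\link{successionScenario}},
#'   \code{\link{simulateSuccession}}
#' @export
setClass("SuccessionScenario",
  representation(
    nDates = "numeric",
    algaeBase = "numeric", algaePeak = "numeric",
    algaePeakTime = "numeric", algaePeakWidth = "numeric",
    cyanoMin = "numeric", cyanoMax = "numeric",
    cyanoMidpoint = "numeric", cyanoRate = "numeric",
    noiseSdLog = "numeric"
  )
)

setValidity("SuccessionScenario", function(object) {
  msgs <- character(0)
  if (object@nDates < 3) msgs <- c(msgs, "nDates must be >= 3")
  if (object@noiseSdLog < 0) msgs <- c(msgs, "noiseSdLog must be >= 0")
  if (any(c(object@algaeBase, object@algaePeak, object@cyanoMin,
            object@cyanoMax) < 0))
    msgs <- c(msgs, "abundance parameters must be >= 0")
  if (length(msgs)) msgs else TRUE
})
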