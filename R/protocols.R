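# Unit bridge: 1 umol photons m^-2 s^-1 expressed as photons nm^-2 us^-1.
# N_A x 1e-6 (umol -> photons) / 1e18 (m^2 -> nm^2) / 1e6 (s -> us).
.AVOGADRO <- 6.02214076e23
.FLUX_PER_UMOL_US <- .AVOGADRO * 1e-6 / (1e18 * 1e6)  # 6.02214076e-7
.FLUX_PER_UMOL_S <- .AVOGADRO * 1e-6 / 1e18           # 0.602214076

#' Instrument excitation wavebands
#'
#' The seven LED centre wavelengths of the multispectral fluorometer.
#'
#' @return numeric vector c(416, 452, 473, 495, 534, 594, 622), nm.
#' @export
instrumentWavebands <- function() c(416, 452, 473, 495, 534, 594, 622)

#' LED channel table
#'
#' One row per physical LED: centre waveband, maximum intensity and
#' whether the intensity is auto-adjustable (only the two blue 452 nm
#' LEDs are). Maxima for the green (10,500), orange (2,896) and red
#' (7,594 umol photons m^-2 s^-1) LEDs and for the two blue LEDs
#' (16,819 and 16,719) are instrument constants; the 416, 473 and
#' 495 nm LEDs have no published maxima and default to the larger blue
#' maximum (overridable via \code{maxOverride}).
#'
#' @param maxOverride optional named numeric (names = waveband nm)
#'   replacing default per-waveband maxima.
#' @return data.frame with columns \code{waveband}, \code{led},
#'   \code{maxIntensity}, \code{adjustable}.
#' @export
ledChannels <- function(maxOverride = NULL) {
  tab <- data.frame(
    waveband = c(416, 452, 452, 473, 495, 534, 594, 622),
    led = c("V", "B1", "B2", "C", "T", "G", "O", "R"),
    maxIntensity = c(16819, 16819, 16719, 16819, 16819, 10500, 2896, 7594),
    adjustable = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (!is.null(maxOverride)) {
    if (is.null(names(maxOverride)))
      stop("'maxOverride' must be named by waveband (nm)")
    for (wb in names(maxOverride))
      tab$maxIntensity[tab$waveband == as.numeric(wb)] <- maxOverride[[wb]]
  }
  tab
}

# Largest admissible intensity per waveband (the 452 nm pair is checked
# against the larger of its two LED maxima).
ledMaxIntensity <- function(wavebands) {
  tab <- ledChannels()
  vapply(wavebands, function(wb) max(tab$maxIntensity[tab$waveband == wb]),
         numeric(1))
}

#' Construct an excitation protocol
#'
#' @param name protocol label.
#' @param wavebands LED centre wavelengths, nm.
#' @param intensities set intensity per LED, umol photons m^-2 s^-1.
#' @param pulseLength 100 or 200 us.
#' @param emissionBands subset of c(685, 730).
#' @return an \code{\linkS4class{ExcitationProtocol}}.
#' @export
excitationProtocol <- function(name, wavebands, intensities,
                               pulseLength = 200,
                               emissionBands = c(685, 730)) {
  if (length(wavebands) == 0L)
    stop("configuration error: protocol '", name, "' has an empty LED list")
  new("ExcitationProtocol", name = as.character(name),
      wavebands = as.numeric(wavebands),
      intensities = as.numeric(intensities),
      pulseLength = as.numeric(pulseLength),
      emissionBands = as.numeric(emissionBands))
}

#' Built-in protocol registry
#'
#' The five standard excitation protocols. Waveband composition and
#' pulse length are fixed; per-LED intensities default to the LED
#' maxima (the two blue LEDs are auto-adjusted on the instrument within
#' roughly [14,068, 16,819]; supply \code{blueIntensities} to model a
#' specific setting).
#'
#' \itemize{
#'   \item \code{B}: both 452 nm LEDs, 100 us pulse (algae: chlorophylls
#'     a/b/c, carotenoids).
#'   \item \code{GOR}: 534 + 594 + 622 nm, 200 us (cyanobacteria:
#'     phycobilipigments).
#'   \item \code{GORB}: 452 x2 + 534 + 594 + 622 nm, 200 us (whole
#'     community).
#'   \item \code{GOB}: 452 x2 + 534 + 594 nm, 200 us.
#'   \item \code{GO}: 534 + 594 nm, 200 us.
#' }
#'
#' @param blueIntensities numeric length 2, intensities of the two
#'   452 nm LEDs; default their maxima c(16819, 16719).
#' @return named list of \code{\linkS4class{ExcitationProtocol}}.
#' @export
protocolRegistry <- function(blueIntensities = c(16819, 16719)) {
  stopifnot(length(blueIntensities) == 2L)
  b <- as.numeric(blueIntensities)
  gor <- c(10500, 2896, 7594)
  list(
    B = excitationProtocol("B", c(452, 452), b, pulseLength = 100),
    GOR = excitationProtocol("GOR", c(534, 594, 622), gor,
                             pulseLength = 200),
    GORB = excitationProtocol("GORB", c(452, 452, 534, 594, 622),
                              c(b, gor), pulseLength = 200),
    GOB = excitationProtocol("GOB", c(452, 452, 534, 594),
                             c(b, gor[1:2]), pulseLength = 200),
    GO = excitationProtocol("GO", c(534, 594), gor[1:2], pulseLength = 200)
  )
}

#' Look up a protocol by name
#'
#' @param protocol an \code{ExcitationProtocol} (returned as-is) or one
#'   of the registry names "B", "GOR", "GORB", "GOB", "GO".
#' @param ... passed to \code{\link{protocolRegistry}}.
#' @return an \code{\linkS4class{ExcitationProtocol}}.
#' @export
getProtocol <- function(protocol, ...) {
  if (is(protocol, "ExcitationProtocol")) return(protocol)
  reg <- protocolRegistry(...)
  if (!protocol %in% names(reg))
    stop("unknown protocol '", protocol, "'; registry protocols are ",
         paste(names(reg), collapse = ", "))
  reg[[protocol]]
}

#' @describeIn accessors total pulse irradiance E_ST of a protocol: the
#'   arithmetic sum of its set LED intensities.
#' @export
setMethod("combinedIntensity", "ExcitationProtocol", function(object) {
  if (length(object@intensities) == 0L)
    stop("configuration error: protocol has no LEDs")
  sum(object@intensities)
})

#' @describeIn accessors pulse duration of a protocol, us.
#' @export
setMethod("pulseLength", "ExcitationProtocol",
          function(object) object@pulseLength)

#' @export
setMethod("show", "ExcitationProtocol", function(object) {
  cat("ExcitationProtocol \"", object@name, "\"\n", sep = "")
  cat("  wavebands (nm): ", paste(object@wavebands, collapse = ", "), "\n",
      sep = "")
  cat("  intensities (umol m-2 s-1): ",
      paste(format(object@intensities, big.mark = ","), collapse = ", "),
      "  [E_ST = ", format(combinedIntensity(object), big.mark = ","),
      "]\n", sep = "")
  cat("  pulse length: ", object@pulseLength, " us; emission bands: ",
      paste(object@emissionBands, collapse = ", "), " nm\n", sep = "")
})

#' Photon-flux unit bridge
#'
#' Converts a photon irradiance in umol photons m^-2 s^-1 into photons
#' nm^-2 us^-1, the scale on which sigma_PII (nm^2 PSII^-1) times flux
#' gives alpha_PII (photons PSII^-1 us^-1).
#'
#' @param E irradiance, umol photons m^-2 s^-1; must be >= 0.
#' @return photons nm^-2 us^-1 (E x 6.02214076e-7).
#' @export
umolToPhotonFlux <- function(E) {
  if (any(!is.finite(E)) || any(E < 0))
    stop("irradiance must be finite and >= 0")
  E * .FLUX_PER_UMOL_US
}

#' alpha_PII from sigma_PII and pulse irradiance
#'
#' \code{alphaFromSigma} gives the initial photon-use rate
#' alpha_PII = sigma_PII x photon flux of the pulse;
#' \code{sigmaFromAlpha} is its exact inverse for E > 0.
#'
#' @param sigma sigma_PII, nm^2 PSII^-1 (>= 0).
#' @param alpha alpha_PII, photons PSII^-1 us^-1 (>= 0).
#' @param E pulse irradiance E_ST, umol photons m^-2 s^-1 (>= 0).
#' @return alpha_PII (photons PSII^-1 us^-1) or sigma_PII (nm^2).
#' @export
alphaFromSigma <- function(sigma, E) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  sigma * umolToPhotonFlux(E)
}

#' @rdname alphaFromSigma
#' @export
sigmaFromAlpha <- function(alpha, E) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  flux <- umolToPhotonFlux(E)
  if (any(flux == 0)) stop("E must be > 0 to invert")
  alpha / flux
}

#' Expected PSII closure at pulse end
#'
#' Fraction of PSII reaction centres closed by the end of an ST pulse
#' under the no-connectivity model, \eqn{1 - e^{-\alpha L}}. Used by the
#' saturation QC: a pulse that closes too small a fraction of centres
#' leaves F_m poorly constrained by extrapolation.
#'
#' @param alpha alpha_PII, photons PSII^-1 us^-1 (>= 0).
#' @param pulseLen pulse length, us (> 0).
#' @return closure fraction in [0, 1).
#' @export
expectedClosure <- function(alpha, pulseLen) {
  stopifnot(all(alpha >= 0), all(pulseLen > 0))
  1 - exp(-alpha * pulseLen)
}

#' Saturation QC thresholds
#'
#' The default quality bands for the ST fit: alpha_PII in
#' [0.042, 0.064] photons PSII^-1 us^-1 is "optimal" (good curve fit at
#' full saturation); alpha_PII below 0.02 is "unsaturated" (the GO-type
#' low-dose regime); in addition the expected closure
#' \eqn{1-e^{-\alpha L}} must reach \code{closureMin}, otherwise F_m is
#' an extrapolation and the fit is flagged "unsaturated" regardless of
#' alpha. Everything else is "suboptimal".
#'
#' @param alphaOptimal length-2 numeric, the optimal alpha band.
#' @param alphaUnsaturated scalar, below which the fit is unsaturated.
#' @param closureMin minimum expected closure at pulse end.
#' @return list of thresholds.
#' @export
saturationThresholds <- function(alphaOptimal = c(0.042, 0.064),
                                 alphaUnsaturated = 0.02,
                                 closureMin = 0.95) {
  stopifnot(length(alphaOptimal) == 2L, alphaOptimal[1] < alphaOptimal[2],
            alphaUnsaturated >= 0, closureMin > 0, closureMin < 1)
  list(alphaOptimal = alphaOptimal, alphaUnsaturated = alphaUnsaturated,
       closureMin = closureMin)
}

#' Classify ST saturation status
#'
#' @param alpha fitted alpha_PII.
#' @param pulseLen pulse length, us.
#' @param thresholds see \code{\link{saturationThresholds}}.
#' @return "optimal", "suboptimal" or "unsaturated".
#' @export
classifySaturation <- function(alpha, pulseLen,
                               thresholds = saturationThresholds()) {
  if (alpha < thresholds$alphaUnsaturated ||
      expectedClosure(alpha, pulseLen) < thresholds$closureMin)
    return("unsaturated")
  if (alpha >= thresholds$alphaOptimal[1] &&
      alpha <= thresholds$alphaOptimal[2])
    return("optimal")
  "suboptimal"
}

#' Serialise / load the protocol registry
#'
#' Round-trips a list of protocols through a YAML config with keys
#' \code{name, wavebands, intensities, pulse_length_us, emission_bands}.
#'
#' @param protocols named list of \code{ExcitationProtocol}.
#' @param path file path.
#' @return \code{readProtocolConfig} returns a named list of
#'   \code{ExcitationProtocol}; \code{writeProtocolConfig} returns
#'   \code{path} invisibly.
#' @export
writeProtocolConfig <- function(protocols, path) {
  entries <- lapply(protocols, function(p) list(
    name = p@name, wavebands = as.list(p@wavebands),
    intensities = as.list(p@intensities),
    pulse_length_us = p@pulseLength,
    emission_bands = as.list(p@emissionBands)))
  yaml::write_yaml(list(protocols = unname(entries)), path)
  invisible(path)
}

#' @rdname writeProtocolConfig
#' @export
readProtocolConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$protocols)) stop("no 'protocols' key in ", path)
  out <- lapply(cfg$protocols, function(e)
    excitationProtocol(e$name, unlist(e$wavebands), unlist(e$intensities),
                       pulseLength = e$pulse_length_us,
                       emissionBands = unlist(e$emission_bands)))
  names(out) <- vapply(out, function(p) p@name, character(1))
  out
}
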