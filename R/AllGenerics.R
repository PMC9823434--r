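#' @title Accessor generics
#' @description Accessors for the fitted and aggregated photophysiology
#'   objects. \code{fo}, \code{fm}, \code{fv} return minimum, maximum and
#'   variable fluorescence (a.u.); \code{fvfm} the maximum PSII
#'   photochemical efficiency \eqn{F_v/F_m = (F_m - F_o)/F_m};
#'   \code{sigmaPII} the PSII absorption cross-section (nm^2);
#'   \code{alphaPII} the initial photon-use rate (photons PSII^-1 us^-1);
#'   \code{saturationStatus} the ST saturation QC flag;
#'   \code{combinedIntensity} the summed LED intensity E_ST of a protocol
#'   (umol photons m^-2 s^-1); \code{pulseLength} the ST pulse duration
#'   (us).
#' @param object an object of the relevant class.
#' @return a numeric (or character, for \code{saturationStatus}) scalar
#'   or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fo", function(object) standardGeneric("fo"))

#' @rdname accessors
#' @export
setGeneric("fm", function(object) standardGeneric("fm"))

#' @rdname accessors
#' @export
setGeneric("fv", function(object) standardGeneric("fv"))

#' @rdname accessors
#' @export
setGeneric("fvfm", function(object) standardGeneric("fvfm"))

#' @rdname accessors
#' @export
setGeneric("sigmaPII", function(object) standardGeneric("sigmaPII"))

#' @rdname accessors
#' @export
setGeneric("alphaPII", function(object) standardGeneric("alphaPII"))

#' @rdname accessors
#' @export
setGeneric("saturationStatus",
           function(object) standardGeneric("saturationStatus"))

#' @rdname accessors
#' @export
setGeneric("combinedIntensity",
           function(object) standardGeneric("combinedIntensity"))

#' @rdname accessors
#' @export
setGeneric("pulseLength", function(object) standardGeneric("pulseLength"))
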