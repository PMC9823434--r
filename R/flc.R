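#' Per-step electron transport rate
#'
#' J_PII: the photon flux through the light-adapted PSII absorption
#' cross-section, read as an electron transport rate on the assumption
#' that every photon driving PSII photochemistry translocates one
#' electron. \code{J = sigma' x E x 0.602214076}, with sigma' in nm^2
#' and E (actinic) in umol photons m^-2 s^-1, giving electrons PSII^-1
#' s^-1.
#'
#' @param sigmaPrime light-adapted sigma_PII', nm^2 (>= 0).
#' @param actinicE actinic irradiance, umol photons m^-2 s^-1 (>= 0).
#' @return electrons PSII^-1 s^-1.
#' @export
computeJPII <- function(sigmaPrime, actinicE) {
  stopifnot(all(sigmaPrime >= 0), all(actinicE >= 0))
  sigmaPrime * actinicE * .FLUX_PER_UMOL_S
}

#' Default actinic light-step grid
#'
#' Twelve actinic steps from 0 to 1200 umol photons m^-2 s^-1,
#' geometrically spaced to resolve the light-limited slope.
#'
#' @return numeric vector of length 12.
#' @export
defaultActinicGrid <- function() {
  c(0, 10, 25, 50, 90, 150, 250, 380, 550, 750, 975, 1200)
}

#' Fit a Webb exponential light-response curve
#'
#' Least-squares fit of \eqn{J(E) = P_{max}(1 - e^{-\alpha_{LC} E /
#' P_{max}})} to per-step electron transport rates. The fit profiles
#' out the amplitude: writing \eqn{w = \alpha_{LC}/P_{max}}, the model
#' is linear in \eqn{P_{max}} at fixed \eqn{w}, so the residual sum of
#' squares is minimised over \eqn{\log w} by golden-section search with
#' the amplitude solved in closed form. This is deterministic and
#' remains well-behaved in both limits: effectively linear data drive
#' \eqn{w \to 0} (asymptote beyond the measured range; flagged
#' \code{atUpperBound}, with alpha_LC still the slope) and saturated
#' data drive \eqn{w} large (\eqn{P_{max}} = the plateau).
#'
#' @param E actinic irradiances; at least 4 distinct values including 0.
#' @param J electron transport rates, same length; NA pairs dropped.
#' @return a \code{\linkS4class{PICurveFit}}; \code{atUpperBound} is
#'   set when the fitted asymptote exceeds 10 x max(J), i.e. the grid
#'   never approaches saturation and P_max is not identified.
#' @export
fitPICurve <- function(E, J) {
  keep <- is.finite(E) & is.finite(J)
  E <- E[keep]; J <- J[keep]
  if (length(unique(E)) < 4 || !any(E == 0))
    stop("need >= 4 distinct actinic levels including E = 0")
  if (all(J == 0)) stop("all-zero J: no light response to fit")
  jmax <- max(J)
  eMin <- min(E[E > 0])
  # profiled amplitude and RSS at fixed shape w = alpha_LC / P_max
  profile <- function(logw) {
    f <- 1 - exp(-exp(logw) * E)
    p <- sum(J * f) / sum(f * f)
    sum((J - p * f)^2)
  }
  # w below lo is indistinguishable from a line over the grid; above
  # hi the curve is saturated at the first positive E
  lo <- log(1e-4 / max(E))
  hi <- log(50 / eMin)
  opt <- stats::optimize(profile, c(lo, hi),
                         tol = .Machine$double.eps^0.5)
  w <- exp(opt$minimum)
  f <- 1 - exp(-w * E)
  p <- sum(J * f) / sum(f * f)
  new("PICurveFit", modelName = "webb_exponential",
      pMax = p, alphaLC = p * w,
      rmse = sqrt(mean((J - p * f)^2)),
      converged = TRUE, atUpperBound = p > 10 * jmax)
}

#' @export
setMethod("show", "PICurveFit", function(object) {
  cat("PICurveFit (", object@modelName, ")\n", sep = "")
  cat(sprintf("  P_max = %.5g  alpha_LC = %.5g  rmse = %.3g%s%s\n",
              object@pMax, object@alphaLC, object@rmse,
              if (object@atUpperBound) "  [P_max at upper bound]" else "",
              if (!object@converged) "  [NOT CONVERGED]" else ""))
})

#' Aggregate a fluorescence light curve
#'
#' Reduces per-step ST fits to the reported FLC summary: F_o, F_v/F_m,
#' alpha_PII and sigma_PII averaged over the first five (lowest-E)
#' light steps, ETR_max as the maximum per-step J_PII, and the Webb
#' light-response fit for P_max / alpha_LC. Failed steps (NA rows) are
#' excluded from the means and counted in \code{nFailed}.
#'
#' @param steps data.frame with columns \code{actinicE, fo, fm, fvfm,
#'   sigmaPII, alphaPII, jPII} (and optionally \code{converged}), one
#'   row per actinic step, sorted by \code{actinicE}; at least 5 steps.
#' @param protocol protocol name carried into the result.
#' @return an \code{\linkS4class{FLCResult}}.
#' @export
aggregateFLC <- function(steps, protocol = "") {
  need <- c("actinicE", "fo", "fm", "fvfm", "sigmaPII", "alphaPII", "jPII")
  if (!all(need %in% names(steps)))
    stop("missing step columns: ",
         paste(setdiff(need, names(steps)), collapse = ", "))
  if (nrow(steps) < 5) stop("need at least 5 light steps to aggregate")
  if (is.unsorted(steps$actinicE)) stop("steps must be sorted by actinicE")
  if (is.null(steps$converged)) steps$converged <- !is.na(steps$fo)
  first5 <- steps[seq_len(5), ]
  m5 <- function(x) mean(x, na.rm = TRUE)
  ok <- stats::complete.cases(steps[, c("actinicE", "jPII")])
  piFit <- if (sum(steps$jPII[ok] != 0) == 0)
    new("PICurveFit", modelName = "webb_exponential", pMax = NA_real_,
        alphaLC = NA_real_, rmse = NA_real_, converged = FALSE,
        atUpperBound = FALSE)
  else fitPICurve(steps$actinicE[ok], steps$jPII[ok])
  new("FLCResult", steps = steps,
      foMean5 = m5(first5$fo), fvfmMean5 = m5(first5$fvfm),
      alphaMean5 = m5(first5$alphaPII), sigmaMean5 = m5(first5$sigmaPII),
      etrMax = if (any(ok)) max(steps$jPII[ok]) else NA_real_,
      piFit = piFit, protocol = protocol,
      nFailed = sum(is.na(steps$fo)))
}

#' Run a full fluorescence light curve on a synthetic sample
#'
#' For each actinic step, builds the community's light-adapted ST trace
#' from the group optical models (sigma' quenched as
#' \eqn{\sigma' = \sigma P_q/(P_q+E)}), fits it, computes J_PII from
#' the fitted sigma', and aggregates. A failed step is recorded as an
#' NA row, not fatal; a zero-biomass sample yields an all-failed,
#' flagged result.
#'
#' @param abundance named numeric, cells mL^-1 per group (names matching
#'   \code{models}).
#' @param models list of \code{\linkS4class{GroupOpticalModel}};
#'   default \code{\link{defaultGroupModels}()}.
#' @param protocol protocol name or object.
#' @param actinicGrid 12 non-decreasing irradiances from 0 to 1200;
#'   default \code{\link{defaultActinicGrid}()}.
#' @param emissionBand 685 (default) or 730.
#' @param noiseSd additive trace noise, a.u.
#' @param quenchPq half-saturation irradiance of the sigma' quenching
#'   proxy, umol photons m^-2 s^-1 (default 300).
#' @param seed integer seed; per-step sub-streams are derived from it.
#' @return an \code{\linkS4class{FLCResult}}.
#' @export
runFLC <- function(abundance, models = defaultGroupModels(),
                   protocol = "GOR", actinicGrid = defaultActinicGrid(),
                   emissionBand = 685, noiseSd = 0.5, quenchPq = 300,
                   seed = NULL) {
  p <- getProtocol(protocol)
  if (length(actinicGrid) != 12 || is.unsorted(actinicGrid) ||
      actinicGrid[1] != 0 || max(actinicGrid) > 1200)
    stop("actinicGrid must be 12 non-decreasing values from 0 to <= 1200")
  rows <- lapply(seq_along(actinicGrid), function(i) {
    E <- actinicGrid[i]
    tr <- communitySTTrace(abundance, models, p,
                           emissionBand = emissionBand, actinicE = E,
                           quenchPq = quenchPq, noiseSd = noiseSd,
                           seed = if (is.null(seed)) NULL else
                             substreamSeed(seed, "flc", p@name,
                                           emissionBand, i))
    fit <- tryCatch(fitSTTrace(tr, protocol = p), error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(actinicE = E, fo = NA_real_, fm = NA_real_,
                        fvfm = NA_real_, sigmaPII = NA_real_,
                        alphaPII = NA_real_, jPII = NA_real_,
                        converged = FALSE))
    data.frame(actinicE = E, fo = fo(fit), fm = fm(fit),
               fvfm = if (fm(fit) > 0) fvfm(fit) else NA_real_,
               sigmaPII = sigmaPII(fit), alphaPII = alphaPII(fit),
               jPII = computeJPII(sigmaPII(fit), E),
               converged = fit@converged)
  })
  steps <- do.call(rbind, rows)
  if (all(is.na(steps$fo))) {
    empty <- new("PICurveFit", modelName = "webb_exponential",
                 pMax = NA_real_, alphaLC = NA_real_, rmse = NA_real_,
                 converged = FALSE, atUpperBound = FALSE)
    return(new("FLCResult", steps = steps, foMean5 = NA_real_,
               fvfmMean5 = NA_real_, alphaMean5 = NA_real_,
               sigmaMean5 = NA_real_, etrMax = NA_real_, piFit = empty,
               protocol = p@name, nFailed = nrow(steps)))
  }
  aggregateFLC(steps, protocol = p@name)
}

#' @describeIn accessors mean F_o over the first five FLC light steps.
#' @export
setMethod("fo", "FLCResult", function(object) object@foMean5)

#' @describeIn accessors mean F_v/F_m over the first five FLC steps.
#' @export
setMethod("fvfm", "FLCResult", function(object) object@fvfmMean5)

#' @describeIn accessors mean sigma_PII over the first five FLC steps.
#' @export
setMethod("sigmaPII", "FLCResult", function(object) object@sigmaMean5)

#' @describeIn accessors mean alpha_PII over the first five FLC steps.
#' @export
setMethod("alphaPII", "FLCResult", function(object) object@alphaMean5)

#' ETR_max of a fluorescence light curve
#'
#' @param object an \code{FLCResult}.
#' @return maximum per-step J_PII, electrons PSII^-1 s^-1.
#' @export
etrMax <- function(object) {
  stopifnot(is(object, "FLCResult"))
  object@etrMax
}

#' P_max of a fluorescence light curve
#'
#' @param object an \code{FLCResult} or \code{PICurveFit}.
#' @return Webb asymptote, electrons PSII^-1 s^-1.
#' @export
pMax <- function(object) {
  if (is(object, "FLCResult")) return(object@piFit@pMax)
  stopifnot(is(object, "PICurveFit"))
  object@pMax
}

#' @export
setMethod("show", "FLCResult", function(object) {
  cat("FLCResult [", object@protocol, "], ", nrow(object@steps),
      " steps (", object@nFailed, " failed)\n", sep = "")
  cat(sprintf("  means over first 5 steps: F_o = %.4g  F_v/F_m = %.4f  alpha_PII = %.4g  sigma_PII = %.4g\n",
              object@foMean5, object@fvfmMean5, object@alphaMean5,
              object@sigmaMean5))
  cat(sprintf("  ETR_max = %.5g  P_max = %.5g  alpha_LC = %.5g\n",
              object@etrMax, object@piFit@pMax, object@piFit@alphaLC))
})
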