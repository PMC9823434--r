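# Trace file format: one or more blocks, each
#   # protocol: GOR
#   # emission_nm: 685
#   # actinic_umol: 0
#   time_us<TAB>fluorescence
#   <rows...>
# separated by blank lines. Numbers are written with %.17g so the
# write/read round trip is bit-exact for doubles.

#' Write ST traces to a delimited text file
#'
#' @param traces an \code{STTrace} or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readTraces}}
#' @export
writeTraces <- function(traces, path) {
  if (is(traces, "STTrace")) traces <- list(traces)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    stopifnot(is(tr, "STTrace"))
    if (k > 1) writeLines("", con)
    writeLines(c(paste0("# protocol: ", tr@protocol),
                 paste0("# emission_nm: ", sprintf("%.17g", tr@emissionBand)),
                 paste0("# actinic_umol: ", sprintf("%.17g", tr@actinicE)),
                 "time_us\tfluorescence"), con)
    writeLines(sprintf("%.17g\t%.17g", tr@time, tr@fluorescence), con)
  }
  invisible(path)
}

#' Read ST traces from a delimited text file
#'
#' Parses the block format written by \code{\link{writeTraces}}.
#' Malformed rows and non-monotone time columns are reported with their
#' line numbers. An empty file yields an empty list with a warning.
#'
#' @param path input file path.
#' @return list of \code{\linkS4class{STTrace}}.
#' @export
readTraces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) {
    warning("empty trace file: ", path)
    return(list())
  }
  traces <- list()
  meta <- list()
  tvals <- fvals <- numeric(0)
  rowLines <- integer(0)
  inData <- FALSE

  flush <- function() {
    if (!length(tvals)) return()
    for (key in c("protocol", "emission_nm", "actinic_umol"))
      if (is.null(meta[[key]]))
        stop("trace block ending near line ",
             rowLines[length(rowLines)], " lacks '", key, "' metadata")
    bad <- which(diff(tvals) <= 0)
    if (length(bad))
      stop("parse error: time not strictly increasing at line ",
           rowLines[bad[1] + 1], " of ", path)
    if (tvals[1] != 0)
      stop("parse error: time must start at 0 (line ", rowLines[1], ")")
    traces[[length(traces) + 1]] <<- new("STTrace",
      time = tvals, fluorescence = fvals,
      protocol = meta$protocol,
      emissionBand = as.numeric(meta$emission_nm),
      actinicE = as.numeric(meta$actinic_umol))
    meta <<- list(); tvals <<- numeric(0); fvals <<- numeric(0)
    rowLines <<- integer(0); inData <<- FALSE
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) {
      if (inData) flush()
      kv <- sub("^#\\s*", "", ln)
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[[key]] <- val
      next
    }
    if (grepl("^time_us\t", ln)) {
      if (!identical(strsplit(ln, "\t")[[1]],
                     c("time_us", "fluorescence")))
        stop("parse error: bad column header at line ", i, " of ", path)
      inData <- TRUE
      next
    }
    if (!inData)
      stop("parse error: data row before column header at line ", i)
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) != 2)
      stop("parse error: expected 2 columns at line ", i, " of ", path)
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop("parse error: non-numeric value at line ", i, " of ", path)
    tvals <- c(tvals, vals[1]); fvals <- c(fvals, vals[2])
    rowLines <- c(rowLines, i)
  }
  flush()
  traces
}

# Tab-separated result-table writer shared by the pipeline stages;
# numeric columns at full precision so reruns are byte-comparable.
writeResultTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Tabulate an FLC result
#'
#' One row per (sample, protocol) with the aggregate photophysiology
#' and the per-step detail JSON-encoded in the final column.
#'
#' @param flc an \code{\linkS4class{FLCResult}}.
#' @param sampleId sample label.
#' @return one-row data.frame.
#' @export
flcResultRow <- function(flc, sampleId = "sample") {
  stopifnot(is(flc, "FLCResult"))
  data.frame(
    sample = sampleId, protocol = flc@protocol,
    fo_mean5 = flc@foMean5, fvfm_mean5 = flc@fvfmMean5,
    alpha_mean5 = flc@alphaMean5, sigma_mean5 = flc@sigmaMean5,
    etr_max = flc@etrMax, p_max = flc@piFit@pMax,
    alpha_lc = flc@piFit@alphaLC, n_failed = flc@nFailed,
    steps_json = as.character(jsonlite::toJSON(flc@steps, digits = NA)),
    stringsAsFactors = FALSE)
}

#' Tabulate an excitation spectrum (long format)
#'
#' @param spec an \code{\linkS4class{ExcitationSpectrum}}.
#' @param sampleId sample label.
#' @return data.frame with columns \code{sample, mode, waveband_nm,
#'   F_v, sigma_PII, dose}.
#' @export
spectrumTable <- function(spec, sampleId = "sample") {
  stopifnot(is(spec, "ExcitationSpectrum"))
  data.frame(sample = sampleId, mode = spec@mode,
             waveband_nm = spec@wavebands, F_v = spec@fv,
             sigma_PII = spec@sigmaPII, dose = spec@dose,
             stringsAsFactors = FALSE)
}

#' Tabulate a regression result
#'
#' @param fit result of \code{\link{olsRegress}}.
#' @param protocol protocol label.
#' @return one-row data.frame (p-values below 1e-15 are printed as
#'   "< 1e-15" in the \code{p_text} column; \code{p_value} keeps the
#'   raw number).
#' @export
regressionRow <- function(fit, protocol = "") {
  data.frame(predictor = fit$predictorName, response = fit$responseName,
             protocol = protocol, n = fit$n, slope = fit$slope,
             intercept = fit$intercept, p_value = fit$pValue,
             p_text = formatPValue(fit$pValue), adj_R2 = fit$adjR2,
             stringsAsFactors = FALSE)
}
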