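#' Default run configuration
#'
#' Configuration for \code{\link{runPipeline}}: the synthetic scenario
#' parameters, the protocols to run FLCs with, the spectrum mode,
#' output directory, seed and QC thresholds. Serialisable to/from YAML
#' (\code{\link{readRunConfig}}).
#'
#' @param outDir output directory.
#' @param seed non-negative integer seed.
#' @param protocols protocol names for the FLC stage (default the
#'   algae- and cyanobacteria-targeted pair \code{c("B", "GOR")}; any
#'   subset of the registry is accepted).
#' @param spectraMode \code{"auto"}, \code{"algae_optimised"} or
#'   \code{"cyanobacteria_optimised"}.
#' @param nDates number of sampling dates in the synthetic succession.
#' @param noiseSd additive ST trace noise, a.u.
#' @param measurementSdLog lognormal measurement noise on dark F_o for
#'   the emission-ratio stage.
#' @param quenchPq sigma' quenching half-saturation, umol m^-2 s^-1.
#' @param thresholds saturation QC thresholds
#'   (\code{\link{saturationThresholds}}).
#' @return a named list (class \code{"pfRunConfig"}).
#' @export
runConfig <- function(outDir = "phytofluor-run", seed = 1,
                      protocols = c("B", "GOR"), spectraMode = "auto",
                      nDates = 23, noiseSd = 0.5,
                      measurementSdLog = 0.05, quenchPq = 300,
                      thresholds = saturationThresholds()) {
  if (length(seed) != 1 || is.na(seed) || seed < 0 ||
      seed != round(seed))
    stop("'seed' must be a single non-negative integer")
  structure(list(outDir = outDir, seed = as.integer(seed),
                 protocols = protocols, spectraMode = spectraMode,
                 nDates = nDates, noiseSd = noiseSd,
                 measurementSdLog = measurementSdLog,
                 quenchPq = quenchPq, thresholds = thresholds),
            class = "pfRunConfig")
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @param config a config from \code{\link{runConfig}}.
#' @return \code{readRunConfig} returns the config list;
#'   \code{writeRunConfig} returns \code{path} invisibly.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$thresholds))
    raw$thresholds <- do.call(saturationThresholds, raw$thresholds)
  do.call(runConfig, raw)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes the complete assessment on a simulated seasonal succession:
#' (1) simulate community states and microscopy counts; (2) per date,
#' measure the seven-waveband PSII excitation spectrum (mode selected
#' from the dark F_o responses when \code{spectraMode = "auto"});
#' (3) per date and protocol, run a 12-step fluorescence light curve
#' and aggregate its photophysiology; (4) compute the 730/685 dark
#' emission ratio under GOR excitation; (5) regress the fluorescence
#' markers against (relative) group abundance. Writes four
#' tab-separated result tables plus a JSON run manifest to
#' \code{config$outDir}; identical configs reproduce identical tables.
#'
#' Protocol names are validated before any computation; per-stage
#' failures are recorded in the results, not fatal.
#'
#' @param config a \code{\link{runConfig}} list or path to its YAML
#'   serialisation.
#' @return invisibly, a list with \code{states}, \code{spectra},
#'   \code{flc}, \code{ratios}, \code{regressions}, \code{manifest}.
#' @export
runPipeline <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  reg <- names(protocolRegistry())
  bad <- setdiff(config$protocols, reg)
  if (length(bad))
    stop("validation error: unknown protocol(s) ",
         paste(bad, collapse = ", "), "; registry protocols are ",
         paste(reg, collapse = ", "))
  if (!config$spectraMode %in% c("auto", "algae_optimised",
                                 "cyanobacteria_optimised"))
    stop("validation error: bad spectraMode '", config$spectraMode, "'")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  models <- defaultGroupModels()
  t0 <- proc.time()[["elapsed"]]
  logStage <- function(stage)
    message(sprintf("[phytoFluor] %-12s %.1fs", stage,
                    proc.time()[["elapsed"]] - t0))

  scenario <- successionScenario(nDates = config$nDates)
  states <- simulateSuccession(scenario, seed = substreamSeed(seed, "succ"))
  states$algae_counted <- simulateMicroscopy(
    states$algae, seed = substreamSeed(seed, "countA"))
  states$cyanobacteria_counted <- simulateMicroscopy(
    states$cyanobacteria, seed = substreamSeed(seed, "countC"))
  logStage("simulate")

  specRows <- list()
  for (i in seq_len(nrow(states))) {
    ab <- c(algae = states$algae[i],
            cyanobacteria = states$cyanobacteria[i])
    sp <- measureSpectrum(ab, models, mode = config$spectraMode,
                          noiseSd = config$noiseSd,
                          seed = substreamSeed(seed, "spec", i))
    specRows[[i]] <- spectrumTable(sp, sampleId = paste0("date_", i))
  }
  spectra <- do.call(rbind, specRows)
  logStage("spectra")

  flcRows <- list()
  for (pn in config$protocols) {
    for (i in seq_len(nrow(states))) {
      ab <- c(algae = states$algae[i],
              cyanobacteria = states$cyanobacteria[i])
      flc <- runFLC(ab, models, protocol = pn,
                    noiseSd = config$noiseSd, quenchPq = config$quenchPq,
                    seed = substreamSeed(seed, "flc", pn, i))
      flcRows[[length(flcRows) + 1]] <-
        flcResultRow(flc, sampleId = paste0("date_", i))
    }
  }
  flcTab <- do.call(rbind, flcRows)
  logStage("flc")

  nD <- nrow(states)
  fo685 <- fo730 <- numeric(nD)
  for (i in seq_len(nD)) {
    ab <- c(algae = states$algae[i],
            cyanobacteria = states$cyanobacteria[i])
    fo685[i] <- communityFluorescence(ab, models, "GOR", 685)["fo"]
    fo730[i] <- communityFluorescence(ab, models, "GOR", 730)["fo"]
  }
  if (config$measurementSdLog > 0) {
    eps <- withSeed(substreamSeed(seed, "ratio-meas"),
                    stats::rnorm(2 * nD, 0, config$measurementSdLog))
    fo685 <- fo685 * exp(eps[seq_len(nD)])
    fo730 <- fo730 * exp(eps[nD + seq_len(nD)])
  }
  ratios <- data.frame(
    sample = paste0("date_", seq_len(nD)), protocol = "GOR",
    F_o_685 = fo685, F_o_730 = fo730,
    ratio_730_685 = emissionRatio(fo685, fo730),
    stringsAsFactors = FALSE)
  logStage("ratios")

  relC <- states$cyanobacteria_counted /
    (states$algae_counted + states$cyanobacteria_counted)
  regs <- rbind(
    regressionRow(olsRegress(relC, ratios$ratio_730_685,
                             "relative_cyanobacteria",
                             "Fo_ratio_730_685"), protocol = "GOR"),
    regressionRow(olsRegress(states$cyanobacteria_counted, fo685,
                             "cyanobacteria_cells_per_ml",
                             "Fo_GOR_685"), protocol = "GOR"))
  logStage("regress")

  manifest <- list(
    package = "phytoFluor",
    version = as.character(utils::packageVersion("phytoFluor")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = unclass(config)[setdiff(names(config), "thresholds")],
    thresholds = config$thresholds,
    tables = c("community_states.tsv", "flc_results.tsv", "spectra.tsv",
               "emission_ratios.tsv", "regressions.tsv"))
  writeResultTable(states, file.path(config$outDir,
                                     "community_states.tsv"))
  writeResultTable(flcTab, file.path(config$outDir, "flc_results.tsv"))
  writeResultTable(spectra, file.path(config$outDir, "spectra.tsv"))
  writeResultTable(ratios, file.path(config$outDir,
                                     "emission_ratios.tsv"))
  writeResultTable(regs, file.path(config$outDir, "regressions.tsv"))
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(states = states, spectra = spectra, flc = flcTab,
                 ratios = ratios, regressions = regs,
                 manifest = manifest))
}
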