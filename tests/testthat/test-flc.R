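test_that("J_PII follows the unit-conversion oracle and is linear", {
  expect_identical(computeJPII(3, 0), 0)
  expect_equal(computeJPII(3, 1200), 3 * 1200 * FLUX_S, tolerance = 1e-12)
  expect_equal(computeJPII(3, 1200), 2167.97, tolerance = 1e-5)
  expect_equal(computeJPII(6, 800), 2 * computeJPII(3, 800))
})

test_that("Webb fit recovers noiseless generating parameters", {
  E <- defaultActinicGrid()
  pm <- 500; al <- 2.0
  J <- pm * (1 - exp(-al * E / pm))
  fit <- fitPICurve(E, J)
  expect_lt(relErr(fit@pMax, pm), 1e-6)
  expect_lt(relErr(fit@alphaLC, al), 1e-6)
  expect_false(fit@atUpperBound)
  expect_true(fit@converged)
})

test_that("Webb fit limit behaviour: linear and saturated data", {
  E <- defaultActinicGrid()
  # strictly linear response: slope recovered, asymptote unidentified
  cSlope <- 0.8
  fitLin <- fitPICurve(E, cSlope * E)
  expect_true(fitLin@atUpperBound)
  expect_lt(relErr(fitLin@alphaLC, cSlope), 0.01)
  # saturated response: P_max equals the plateau
  pStar <- 321
  J <- ifelse(E > 0, pStar, 0)
  fitSat <- fitPICurve(E, J)
  expect_lt(relErr(fitSat@pMax, pStar), 0.01)
})

test_that("Webb fit input contracts are enforced", {
  E <- defaultActinicGrid()
  expect_error(fitPICurve(E, rep(0, 12)), "all-zero J")
  expect_error(fitPICurve(c(0, 100, 200), c(0, 1, 2)), ">= 4 distinct")
  expect_error(fitPICurve(c(10, 100, 200, 400), c(1, 2, 3, 4)), "E = 0")
})

test_that("FLC aggregation follows the first-five / max rules", {
  E <- defaultActinicGrid()
  mkSteps <- function(fo, j) data.frame(
    actinicE = E, fo = fo, fm = fo * 2, fvfm = 0.5,
    sigmaPII = 3, alphaPII = alphaFromSigma(3, 20990), jPII = j,
    converged = TRUE)
  st <- mkSteps(fo = c(100, 98, 96, 94, 92, 90, 88, 86, 84, 82, 80, 78),
                j = c(0, 50, 120, 200, 260, 300, 310, 290, 280, 270,
                      260, 250))
  agg <- aggregateFLC(st, "GOR")
  expect_equal(agg@foMean5, 96)
  expect_equal(etrMax(agg), 310)
  expect_true(all(st$jPII <= etrMax(agg)))
  # idempotence: identical steps give the common value everywhere
  stSame <- mkSteps(fo = rep(100, 12), j = rep(200, 12))
  stSame$jPII[1] <- 0
  aggSame <- aggregateFLC(stSame)
  expect_equal(aggSame@foMean5, 100)
  expect_equal(aggSame@fvfmMean5, 0.5)
  expect_equal(etrMax(aggSame), 200)
  expect_error(aggregateFLC(st[1:4, ]), "at least 5")
})

test_that("aggregates ignore permutations of steps 6-12", {
  E <- defaultActinicGrid()
  withr::with_seed(8, {
    fo <- sort(runif(12, 80, 120), decreasing = TRUE)
    j <- c(0, cumsum(runif(11, 0, 60)))
  })
  base <- data.frame(actinicE = E, fo = fo, fm = fo * 2, fvfm = 0.5,
                     sigmaPII = 3, alphaPII = 0.05, jPII = j,
                     converged = TRUE)
  perm <- base
  idx <- c(12, 9, 6, 11, 8, 7, 10)
  perm[6:12, c("fo", "fm", "fvfm", "sigmaPII", "alphaPII", "jPII")] <-
    base[idx, c("fo", "fm", "fvfm", "sigmaPII", "alphaPII", "jPII")]
  a1 <- aggregateFLC(base); a2 <- aggregateFLC(perm)
  expect_equal(a1@foMean5, a2@foMean5)
  expect_equal(a1@fvfmMean5, a2@fvfmMean5)
  expect_equal(a1@alphaMean5, a2@alphaMean5)
  expect_equal(a1@sigmaMean5, a2@sigmaMean5)
  expect_equal(etrMax(a1), etrMax(a2))
})

test_that("noiseless single-group FLC matches the closed-form oracle", {
  # algae-only sample: each step's trace is a single exponential, so
  # the fitted sigma' equals sigma_eff * Pq/(Pq+E) exactly and every
  # aggregate is hand-computable
  ab <- c(algae = 5000)
  models <- defaultGroupModels()["algae"]
  p <- getProtocol("GOR")
  E <- defaultActinicGrid()
  Pq <- 300
  flc <- runFLC(ab, models, "GOR", noiseSd = 0, quenchPq = Pq, seed = 1)
  m <- models$algae
  sig <- m@sigmaSpectrum[as.character(p@wavebands)]
  sigEff <- sum(p@intensities * sig) / sum(p@intensities)
  base <- 5000 * m@foPerCell * sum(p@intensities * sig)
  q5 <- Pq / (Pq + E[1:5])
  expect_lt(relErr(flc@foMean5, base), 1e-6)
  expect_lt(relErr(flc@sigmaMean5, mean(sigEff * q5)), 1e-6)
  # fvfm per step: v*q / (fo + v*q) with v = base * r/(1-r)
  v <- base * m@fvfmMax / (1 - m@fvfmMax)
  expect_lt(relErr(flc@fvfmMean5, mean(v * q5 / (base + v * q5))), 1e-6)
  jOracle <- sigEff * Pq / (Pq + E) * E * FLUX_S
  expect_lt(relErr(etrMax(flc), max(jOracle)), 1e-6)
  expect_equal(flc@nFailed, 0)
})

test_that("zero-biomass FLC fails every step and is flagged", {
  flc <- runFLC(c(algae = 0, cyanobacteria = 0), protocol = "GOR",
                noiseSd = 0, seed = 1)
  expect_equal(flc@nFailed, 12)
  expect_true(is.na(flc@foMean5))
  expect_true(is.na(etrMax(flc)))
  expect_false(flc@piFit@converged)
})

test_that("FLC runs are deterministic under a fixed seed", {
  ab <- testAbundance()
  f1 <- runFLC(ab, protocol = "GOR", noiseSd = 0.5, seed = 99)
  f2 <- runFLC(ab, protocol = "GOR", noiseSd = 0.5, seed = 99)
  expect_identical(f1@steps, f2@steps)
  expect_identical(pMax(f1), pMax(f2))
  f3 <- runFLC(ab, protocol = "GOR", noiseSd = 0.5, seed = 100)
  expect_false(identical(f1@steps$fo, f3@steps$fo))
})

test_that("actinic grid contract is enforced", {
  ab <- testAbundance()
  expect_error(runFLC(ab, actinicGrid = c(0, 100, 200)), "12")
  expect_error(runFLC(ab, actinicGrid = rev(defaultActinicGrid())),
               "non-decreasing")
})
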