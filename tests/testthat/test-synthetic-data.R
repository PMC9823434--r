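test_that("default group optics satisfy the pigment-targeting structure", {
  m <- defaultGroupModels()
  expect_named(m, c("algae", "cyanobacteria"))
  sa <- m$algae@sigmaSpectrum
  sc <- m$cyanobacteria@sigmaSpectrum
  expect_gt(sa[["452"]], sa[["594"]])
  expect_gt(sc[["594"]], sc[["452"]])
  expect_gt(m$cyanobacteria@psiFraction730, m$algae@psiFraction730)
  expect_true(m$algae@fvfmMax < 1 && m$cyanobacteria@fvfmMax < 1)
})

test_that("community fluorescence is linear and additive over protocols", {
  ab <- testAbundance()
  z <- communityFluorescence(c(algae = 0, cyanobacteria = 0))
  expect_equal(unname(z), c(0, 0))
  f1 <- communityFluorescence(ab, protocol = "GOR")
  f2 <- communityFluorescence(2 * ab, protocol = "GOR")
  expect_equal(unname(f2), 2 * unname(f1), tolerance = 1e-12)
  for (band in c(685, 730)) {
    gorb <- communityFluorescence(ab, protocol = "GORB",
                                  emissionBand = band)
    gor <- communityFluorescence(ab, protocol = "GOR",
                                 emissionBand = band)
    b <- communityFluorescence(ab, protocol = "B", emissionBand = band)
    expect_lt(max(abs(gorb - (gor + b))), 1e-10 * max(gorb))
  }
  expect_error(communityFluorescence(c(5, 5)), "named")
})

test_that("the 730/685 GOR ratio rises strictly with cyano fraction", {
  total <- 20000
  fracs <- seq(0, 1, by = 0.05)
  ratio <- vapply(fracs, function(f) {
    ab <- c(algae = (1 - f) * total, cyanobacteria = f * total)
    f685 <- communityFluorescence(ab, protocol = "GOR",
                                  emissionBand = 685)["fo"]
    f730 <- communityFluorescence(ab, protocol = "GOR",
                                  emissionBand = 730)["fo"]
    emissionRatio(f685, f730)
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("succession trajectories are reproducible and shaped", {
  sc <- successionScenario(noiseSdLog = 0)
  det <- simulateSuccession(sc, seed = 1)
  d <- det$date
  expect_equal(det$algae,
               400 + 8000 * exp(-0.5 * ((d - 3) / 2.5)^2))
  expect_equal(det$cyanobacteria,
               800 + (60000 - 800) / (1 + exp(-(d - 8) / 2.5)))
  s1 <- simulateSuccession(successionScenario(), seed = 9)
  s2 <- simulateSuccession(successionScenario(), seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 23)
  relC <- s1$cyanobacteria / (s1$algae + s1$cyanobacteria)
  expect_gt(relC[23], relC[1])
})

test_that("microscopy counting is a x10 Poisson estimator", {
  expect_equal(microscopyScaleFactor(), 10)
  expect_equal(microscopyScaleFactor(nUnits = 50, unitVolumeUl = 2), 10)
  expect_equal(microscopyScaleFactor(nUnits = 100, unitVolumeUl = 2), 5)
  expect_identical(simulateMicroscopy(0, seed = 1), 0)
  est <- simulateMicroscopy(rep(1000, 1e4), seed = 77)
  expect_true(all(est %% 10 == 0))  # estimates are counts x 10
  # unbiased: mean within 3 sd/sqrt(n)
  expect_lt(abs(mean(est) - 1000), 3 * sd(est) / sqrt(1e4))
  # Poisson scaling: var = density x 10, within chi-square MC slack
  expect_lt(abs(var(est) / (1000 * 10) - 1), 4 * sqrt(2 / 1e4))
})

test_that("sub-stream seeds are label-stable and order-independent", {
  expect_identical(substreamSeed(5, "flc", "GOR", 1),
                   substreamSeed(5, "flc", "GOR", 1))
  expect_false(substreamSeed(5, "flc", "GOR", 1) ==
                 substreamSeed(5, "flc", "B", 1))
  # draws for one label are unaffected by work done under another
  a1 <- simulateSuccession(seed = substreamSeed(3, "succ"))
  invisible(simulateMicroscopy(1:100, seed = substreamSeed(3, "other")))
  a2 <- simulateSuccession(seed = substreamSeed(3, "succ"))
  expect_identical(a1, a2)
})

test_that("end-to-end trace-level pipeline recovers the discriminator", {
  # succession -> dark GOR ST traces at both bands -> fits -> F_o
  # ratios -> regression on counted relative abundance
  states <- simulateSuccession(seed = substreamSeed(21, "succ"))
  nD <- nrow(states)
  ratio <- numeric(nD)
  for (i in seq_len(nD)) {
    ab <- c(algae = states$algae[i],
            cyanobacteria = states$cyanobacteria[i])
    f685 <- fitSTTrace(communitySTTrace(ab, protocol = "GOR",
                                        emissionBand = 685, noiseSd = 0.5,
                                        seed = substreamSeed(21, i, 685)))
    f730 <- fitSTTrace(communitySTTrace(ab, protocol = "GOR",
                                        emissionBand = 730, noiseSd = 0.5,
                                        seed = substreamSeed(21, i, 730)))
    ratio[i] <- emissionRatio(fo(f685), fo(f730))
  }
  cntA <- simulateMicroscopy(states$algae,
                             seed = substreamSeed(21, "cA"))
  cntC <- simulateMicroscopy(states$cyanobacteria,
                             seed = substreamSeed(21, "cC"))
  fit <- olsRegress(cntC / (cntA + cntC), ratio)
  expect_gt(fit$slope, 0)
  expect_lt(fit$pValue, 0.01)
})
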