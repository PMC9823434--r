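test_that("forward model hits F_o at t = 0 and F_m asymptotically", {
  expect_equal(stForward(100, 300, 4, "GOR", t = 0), 100)
  alpha <- alphaFromSigma(4, 20990)
  tBig <- 20 / alpha
  expect_equal(stForward(100, 300, 4, "GOR", t = tBig), 300,
               tolerance = 1e-8)
  # frozen closed-form value at t = 100 us
  expect_equal(stForward(100, 300, 4, "GOR", t = 100),
               100 + 200 * (1 - exp(-4 * 20990 * FLUX_US * 100)),
               tolerance = 1e-12)
  expect_equal(stForward(100, 300, 4, "GOR", t = 100), 298.73,
               tolerance = 1e-4)
  expect_error(stForward(100, 300, 4, "GOR", rho = 1, t = 10),
               "rho")
})

test_that("closed form and implicit solution agree with ODE integration", {
  times <- seq(0, 400, by = 10)
  for (alpha in c(0.005, 0.05, 0.5)) {
    closed <- 1 - exp(-alpha * times)
    ode <- odeClosedFraction(times, alpha, rho = 0)
    expect_lt(max(abs(closed[-1] - ode[-1]) / closed[-1]), 1e-8)
  }
  # connectivity branch against the same independent integrator
  for (rho in c(0.2, 0.5)) {
    impl <- phytoFluor:::stClosedFraction(times, 0.05, rho)
    ode <- odeClosedFraction(times, 0.05, rho)
    expect_lt(max(abs(impl[-1] - ode[-1]) / ode[-1]), 1e-8)
  }
})

test_that("forward model is monotone and bounded for all rho", {
  tt <- seq(0, 200, by = 2)
  for (rho in c(0, 0.3, 0.7)) {
    f <- stForward(50, 250, 3, "GOR", rho = rho, t = tt)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 50 - 1e-12 & f <= 250 + 1e-12))
  }
})

test_that("trace simulation is exact at zero noise and seed-reproducible", {
  tr0 <- simulateSTTrace(100, 300, 4, "GOR")
  expect_equal(tr0@fluorescence,
               stForward(100, 300, 4, "GOR", t = tr0@time))
  expect_equal(length(tr0@time), 201)  # 1 us grid over a 200 us pulse
  trA <- simulateSTTrace(100, 300, 4, "GOR", noiseSd = 2, seed = 11)
  trB <- simulateSTTrace(100, 300, 4, "GOR", noiseSd = 2, seed = 11)
  expect_identical(trA@fluorescence, trB@fluorescence)
  trC <- simulateSTTrace(100, 300, 4, "GOR", noiseSd = 2, seed = 12)
  expect_false(identical(trA@fluorescence, trC@fluorescence))
})

test_that("replicate noisy traces average to the noiseless curve", {
  nRep <- 1e4
  noiseSd <- 2
  tr0 <- simulateSTTrace(100, 300, 4, "GOR", nSamples = 21)
  acc <- rep(0, 21)
  for (r in seq_len(nRep)) {
    tr <- simulateSTTrace(100, 300, 4, "GOR", nSamples = 21,
                          noiseSd = noiseSd, seed = 20000 + r)
    acc <- acc + tr@fluorescence
  }
  # 3 x sd / sqrt(n) Monte Carlo band (floor at 0 never binds here)
  expect_lt(max(abs(acc / nRep - tr0@fluorescence)),
            3 * noiseSd / sqrt(nRep) * 2)
})

test_that("noiseless fits are self-inverse to 1e-6", {
  tr <- simulateSTTrace(100, 300, 4, "GOR")
  fit <- fitSTTrace(tr)
  expect_lt(relErr(fo(fit), 100), 1e-6)
  expect_lt(relErr(fm(fit), 300), 1e-6)
  expect_lt(relErr(sigmaPII(fit), 4), 1e-6)
  expect_equal(alphaPII(fit), alphaFromSigma(sigmaPII(fit), 20990))
  expect_equal(fvfm(fit), (fm(fit) - fo(fit)) / fm(fit))
  expect_equal(fv(fit), fm(fit) - fo(fit))
  expect_true(fit@converged)
  expect_equal(saturationStatus(fit), "optimal")
})

test_that("connectivity fitting recovers rho on its own forward model", {
  p <- getProtocol("GOR")
  tt <- seq(0, 200, by = 1)
  f <- stForward(100, 300, 4, p, rho = 0.4, t = tt)
  tr <- new("STTrace", time = tt, fluorescence = f, protocol = "GOR",
            emissionBand = 685, actinicE = 0)
  fit <- fitSTTrace(tr, fitRho = TRUE)
  expect_lt(relErr(fo(fit), 100), 1e-4)
  expect_lt(relErr(fm(fit), 300), 1e-4)
  expect_lt(relErr(sigmaPII(fit), 4), 1e-3)
  expect_lt(abs(fit@rho - 0.4), 1e-3)
})

test_that("flat and degenerate traces are rejected informatively", {
  tt <- seq(0, 200, by = 2)
  flat <- new("STTrace", time = tt, fluorescence = rep(50, length(tt)),
              protocol = "GOR", emissionBand = 685, actinicE = 0)
  expect_error(fitSTTrace(flat), "flat trace")
  short <- new("STTrace", time = c(0, 1, 2, 5, 10, 20, 50),
               fluorescence = c(1, 2, 3, 4, 5, 6, 7), protocol = "GOR",
               emissionBand = 685, actinicE = 0)
  expect_error(fitSTTrace(short), "at least 8 samples")
})

test_that("F_v/F_m accessor handles the stated cases", {
  mk <- function(foV, fmV) new("STFitResult", fo = foV, fm = fmV,
    sigmaPII = 4, alphaPII = alphaFromSigma(4, 20990), rho = 0,
    rmse = 0, saturationStatus = "optimal", converged = TRUE,
    eST = 20990, pulseLength = 200, nObs = 100,
    diagnostics = character(0))
  expect_equal(fvfm(mk(100, 100)), 0)
  expect_equal(fvfm(mk(100, 300)), 2 / 3, tolerance = 1e-12)
  for (fmV in c(10, 1000)) expect_equal(fvfm(mk(0.2 * fmV, fmV)), 0.8)
  expect_error(fvfm(mk(0, 0)), "F_m = 0")
})

test_that("low-dose GO acquisitions are flagged unsaturated", {
  tr <- simulateSTTrace(100, 300, 2, "GO")
  fit <- fitSTTrace(tr)
  expect_lt(alphaPII(fit), 0.02)
  expect_equal(saturationStatus(fit), "unsaturated")
})

test_that("fitted parameters are scale-equivariant", {
  k <- 3.7
  tr <- simulateSTTrace(100, 300, 4, "GOR", noiseSd = 1, seed = 5)
  trK <- new("STTrace", time = tr@time, fluorescence = k * tr@fluorescence,
             protocol = tr@protocol, emissionBand = 685, actinicE = 0)
  f1 <- fitSTTrace(tr)
  f2 <- fitSTTrace(trK)
  expect_lt(relErr(fo(f2), k * fo(f1)), 1e-9)
  expect_lt(relErr(fm(f2), k * fm(f1)), 1e-9)
  expect_lt(relErr(sigmaPII(f2), sigmaPII(f1)), 1e-9)
  expect_lt(abs(fvfm(f2) - fvfm(f1)), 1e-9)
})

test_that("fit-simulate round trip at 1% noise recovers parameters", {
  nCases <- 100
  errSig <- errFo <- errFm <- numeric(nCases)
  # draws span the dark-adapted photophysiology of the two groups:
  # F_v/F_m in [0.45, 0.65], sigma_PII in the optimal GOR band
  withr::with_seed(42, {
    fmT <- runif(nCases, 150, 500)
    fvfmT <- runif(nCases, 0.45, 0.65)
    sigT <- runif(nCases, 3, 6)
  })
  foT <- fmT * (1 - fvfmT)
  fvT <- fmT * fvfmT
  for (i in seq_len(nCases)) {
    tr <- simulateSTTrace(foT[i], foT[i] + fvT[i], sigT[i], "GOR",
                          noiseSd = 0.01 * fvT[i], seed = 500 + i)
    fit <- fitSTTrace(tr)
    errSig[i] <- relErr(sigmaPII(fit), sigT[i])
    errFo[i] <- relErr(fo(fit), foT[i])
    errFm[i] <- relErr(fm(fit), foT[i] + fvT[i])
  }
  expect_lt(median(errSig), 0.02)
  expect_lt(median(errFo), 0.005)
  expect_lt(median(errFm), 0.005)
})

test_that("truncation degrades F_m recovery only after the QC flag fires", {
  # sigma = 4 under GOR: alpha ~ 0.0506, so the closure floor (0.95)
  # trips below t_max = 3/alpha ~ 59 us; alpha*t_max = 1 is ~ 20 us
  alpha <- alphaFromSigma(4, 20990)
  for (tmax in c(20, 40, 80, 120, 200)) {
    n <- tmax + 1
    tt <- seq(0, tmax, length.out = n)
    errs <- numeric(20)
    flagged <- logical(20)
    for (r in seq_len(20)) {
      f <- stForward(100, 300, 4, "GOR", t = tt)
      f <- withr::with_seed(900 + 37 * tmax + r,
                             f + rnorm(n, 0, 0.01 * 200))
      tr <- new("STTrace", time = tt, fluorescence = pmax(f, 0),
                protocol = "GOR", emissionBand = 685, actinicE = 0)
      fit <- fitSTTrace(tr)
      errs[r] <- relErr(fm(fit), 300)
      flagged[r] <- saturationStatus(fit) == "unsaturated"
    }
    if (expectedClosure(alpha, tmax) < 0.95) {
      expect_true(all(flagged), label = paste("flag at tmax", tmax))
    } else {
      expect_false(any(flagged), label = paste("no flag at tmax", tmax))
      expect_lt(median(errs), 0.05)
    }
  }
})
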