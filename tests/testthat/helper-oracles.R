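# Independent oracles used across the suite.

# Hand unit bridge: umol photons m^-2 s^-1 -> photons nm^-2 us^-1.
FLUX_US <- 6.02214076e23 * 1e-6 / (1e18 * 1e6)
FLUX_S <- FLUX_US * 1e6

# Numerical ODE oracle for the closed-centre fraction:
# dC/dt = alpha (1 - C) / (1 - rho C), C(0) = 0, via deSolve (lsoda),
# independent of the package's closed-form / implicit-root path.
odeClosedFraction <- function(times, alpha, rho = 0, tol = 1e-12) {
  deriv <- function(t, y, parms)
    list(parms$alpha * (1 - y) / (1 - parms$rho * y))
  out <- deSolve::ode(y = c(C = 0), times = times, func = deriv,
                      parms = list(alpha = alpha, rho = rho),
                      rtol = tol, atol = tol)
  unname(out[, "C"])
}

relErr <- function(est, true) abs(est - true) / abs(true)

# A dark-adapted mixed community used by several tests.
testAbundance <- function(algae = 3000, cyano = 20000)
  c(algae = algae, cyanobacteria = cyano)
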