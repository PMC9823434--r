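---
title: "Multispectral single-turnover fluorometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral single-turnover fluorometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoFluor)
```

## The measurement and its model

A single-turnover (ST) saturating pulse is short enough (100–200 µs)
to close every photosystem II (PSII) reaction centre at most once.
During the pulse, fluorescence rises from F~o~ (all centres open) to
F~m~ (all closed), and the *rate* of the rise encodes the functional
absorption cross-section of PSII photochemistry, σ~PII~. phytoFluor
models the closed-centre fraction as

$$\frac{dC}{dt} = \alpha\,\frac{1 - C}{1 - \rho C}, \qquad C(0) = 0,
\qquad \alpha = \sigma_{PII} \cdot \phi(E_{ST}),$$

where φ(E~ST~) converts the pulse irradiance (µmol photons m^-2^
s^-1^, the instrument's scale) into photons nm^-2^ µs^-1^ so that
σ~PII~ in nm^2^ PSII^-1^ yields α~PII~ in photons PSII^-1^ µs^-1^.
The conversion is Avogadro's number scaled by the µmol, m^2^→nm^2^
and s→µs factors: φ(E) = E × 6.02214076 × 10^-7^. Fluorescence follows

$$F(t) = F_o + (F_m - F_o)\,\frac{C(1-\rho)}{1-\rho C}.$$

With connectivity ρ = 0 (the default) the closed form
C(t) = 1 − e^−αt^ is used. For ρ > 0 we invert the exact implicit
relation ρC − (1−ρ)log(1−C) = αt per time point inside the analytic
bracket $[1 - e^{-(\alpha t-\rho)/(1-\rho)},\; 1 - e^{-\alpha
t/(1-\rho)}]$; within 10^-9^ of full closure the bracket is narrower
than the rounding noise of the objective and its lower endpoint is
returned (relative error below 10^-17^). The test suite checks both
branches against independent `deSolve` integration of the ODE to
10^-8^ relative.

ρ defaults to 0 and ρ-fitting is opt-in: connectivity curves the early
rise in a way that trades off against σ~PII~, it is rarely reported
for field instruments, and fitting it on data that do not constrain it
merely inflates variance. When it *is* fitted, the optimiser is
multi-started over ρ ∈ {0, 0.2, 0.4, 0.6, 0.8} and the lowest-RSS
solution kept, because a single Levenberg–Marquardt start reliably
stalls in a ρ ≈ 0 local minimum.

The relation α~PII~ = σ~PII~ × φ(E~ST~) is this package's definition,
adopted as the only dimensionally consistent bridge between the two
parameters; commercial instruments describe the same link with
instrument-specific scale factors that are not public, and no claim of
equivalence with any instrument's internal algebra is made.

## Fitting and its numerical choices

`fitSTTrace()` inverts the forward model by Levenberg–Marquardt
(`minpack.lm::nlsLM`) with box bounds F~o~ ≥ 0, F~v~ = F~m~ − F~o~ ≥ 0
and σ~PII~ ∈ [0, 50] nm^2^. We deliberately do *not* bound F~m~ below
by the maximum observed fluorescence: under noise that bound biases
F~m~ upward. Starting values are derivative-free and deterministic:
F~o~ from the first three samples, F~m~ from the last three, and σ
from a through-origin regression of −log(1 − normalised F) on t over
the interior of the rise.

Degenerate inputs are separated from failures: a trace whose dynamic
range is below 10^-3^ of its mean carries no inversion information and
raises a flat-trace error, while optimiser non-convergence returns a
flagged result (`converged = FALSE`, diagnostics attached) so that one
bad light step never aborts a light curve.

Saturation QC follows the α~PII~ bands used in practice: [0.042,
0.064] photons PSII^-1^ µs^-1^ is *optimal*, below 0.02 is
*unsaturated* (the regime reached by low-dose green–orange pulses on
cyanobacteria-dominated water), anything else *suboptimal*. A second
guard flags fits whose expected closure 1 − e^−αL^ over the recorded
window L falls below 0.95, i.e. when ≥ 5% of the rise is extrapolated
— this catches truncated acquisitions whose α looks healthy. The 0.95
floor corresponds to αL = 3 and was fixed from that extrapolation
argument; both thresholds are arguments of `saturationThresholds()`.

## Light curves and aggregation

A fluorescence light curve (FLC) repeats the ST measurement over 12
actinic steps from 0 to 1200 µmol photons m^-2^ s^-1^. The default
grid (`defaultActinicGrid()`) is geometrically spaced to resolve the
light-limited slope; steps are treated as at steady state (acclimation
kinetics are not modelled). Because F~o~, F~v~/F~m~, α~PII~ and σ~PII~
decline along the steps, their reported FLC values are means over the
five lowest steps; electron transport is summarised by the maximum
per-step J~PII~ = σ′~PII~ × actinic flux, and by a Webb exponential
$J(E) = P_{max}(1 - e^{-\alpha_{LC} E / P_{max}})$ fitted across the
curve. "First five steps" means the five lowest actinic irradiances
including the dark step, in acquisition order.

P~max~ is reported on the J~PII~ scale (electrons PSII^-1^ s^-1^), the
Webb asymptote's natural unit; it is defined here operationally as
that asymptote. The Webb fit profiles out the amplitude — at fixed
shape w = α~LC~/P~max~ the model is linear in P~max~ — and minimises
the profiled RSS over log w with a golden-section search. This is
deterministic and exact in both limits that break a naive nonlinear
fit: effectively linear data drive w → 0, leaving α~LC~ equal to the
slope while P~max~ runs beyond the data (flagged `atUpperBound` when
it exceeds 10 × max J, i.e. the grid never approached saturation), and
plateau data drive w large with P~max~ equal to the plateau.

## Excitation spectra and the dose schedules

`measureSpectrum()` fires each of the seven wavebands alone (200 µs)
and records F~v~ and σ~PII~ at 685 nm. Two dose schedules reflect the
two community types: *algae-optimised* delivers the full blue dose at
452 nm with other wavebands targeting the same photon dose capped at
their LED maxima; *cyanobacteria-optimised* references the 594 nm LED,
whose low maximum (2896 µmol photons m^-2^ s^-1^) every LED can match,
giving a flat schedule. Instrument vendors do not publish their
scaling law; this schedule is the package's own documented choice and
is overridable. The mode is chosen automatically from the dark F~o~
responses at 452 versus 594 nm (threshold 0.5 on the blue share), a
proxy for chlorophyll *b/c* versus phycobilipigment presence; the rule
is scale-invariant by construction. The 416, 473 and 495 nm LEDs have
no published maxima and default to the larger blue maximum.

A spectrum entry is reported missing unless its fitted F~v~ exceeds
3 × the fit RMSE: below that, the trace is indistinguishable from
detector noise and the extrapolated F~v~ would be meaningless (this is
what makes a zero-biomass sample return an all-missing spectrum rather
than noise-fit artefacts).

## What the synthetic community emulates — and what it does not

The generator exists so that every statistical claim in the package is
testable end to end. Its structure:

* **Group optics.** Each group carries a σ~PII~ spectrum over the
  seven wavebands (algae peaked at 416–452 nm, cyanobacteria at
  594–622 nm), a dark F~v~/F~m~ (0.65 algae, 0.45 cyanobacteria), a
  PSI allocation term `psiFraction730` (0.08 versus 0.35) routing
  baseline emission to 730 nm, and a per-cell signal coefficient.
  These constants are *synthetic package defaults*: the scientific
  constraints they honour are orderings (blue- versus orange-peaked
  spectra, larger cyanobacterial PSI term), not measured values.
* **Community signal.** F~o~ and F~m~ are sums of per-group terms,
  linear in each abundance; mixture ST traces superpose the group
  exponentials. Linearity makes protocol additivity (GORB = GOR + B)
  exact in the simulator, which the tests assert to 10^-10^.
* **Light response.** Under actinic E, the kinetic cross-section and
  the variable component are quenched by P~q~/(P~q~ + E) with
  P~q~ = 300 µmol photons m^-2^ s^-1^ — a one-parameter downregulation
  proxy that produces the saturating J(E) the Webb fit assumes.
* **Succession.** 23 sampling dates; an algal spring pulse (Gaussian,
  peak 8000 cells mL^-1^ near date 3) decaying into a logistic
  cyanobacterial rise (to 60 000 cells mL^-1^, midpoint date 8), with
  multiplicative lognormal noise of sd 0.3 on the log scale — chosen
  to resemble the volatility of seasonal count series, without
  claiming fidelity to any particular lake. Absolute amplitudes are
  free parameters of `successionScenario()`.
* **Counting.** Sedgewick-Rafter microscopy is Poisson: 100 random
  1 µL units counted, estimate = count × 10, hence unbiased with
  variance 10 × density.

Deliberately absent: state transitions and NPQ kinetics within or
between pulses, light/nutrient history effects on the PSII:PSI ratio,
pigment packaging, species-level taxonomy, multiplicative detector
noise, and any mechanistic nutrient–growth coupling. Consequently,
passing tests demonstrate that the estimators recover the parameters
of *this* data-generating process and that the 730/685 discriminator
behaves monotonically under PSI-driven mixing — they do not establish
field accuracy on waters whose optics violate these simplifications.

## Randomness and reproducibility

One base seed drives a run; every stochastic task derives a sub-stream
seed from deterministic labels (stage, date, protocol, emission band)
via a polynomial string hash, so adding a protocol or stage to a
configuration never perturbs the draws of existing ones. Pipeline
outputs are written at full precision and reruns with an identical
config are byte-identical.

## Problem sizes used in the checks

The packaged checks run the parameter-recovery study at 100 traces
(1 µs sampling, 1% of F~v~ Gaussian noise, dark F~v~/F~m~ drawn in
[0.45, 0.65], σ~PII~ in [3, 6] nm^2^ — at 1% noise the linearised
standard error of F~o~ is 0.36–0.55%, so the sub-0.5% median criterion
is attainable exactly in this physiological band), the null
calibration of the slope test at 1000 simulations of n = 23, and the
scenario power surface at 200 succession realisations; these sizes
give Monte Carlo error comfortably below the margins being asserted
while keeping a full run in tens of seconds.

## Known limitations

* σ~PII~ recovered from *mixture* traces is an effective,
  fluorescence-weighted parameter; only single-group samples make it
  exactly interpretable.
* The emission-ratio regression is reported per predictor with no
  multiple-testing correction, matching how such per-marker
  correlations are conventionally reported; treat families of
  regressions accordingly.
* Unsaturated acquisitions (α~PII~ < 0.02, or closure < 0.95) yield
  extrapolated F~m~; the QC flag marks them but the numbers are still
  returned and should be interpreted with caution.
* p-values below 10^-15^ are printed as "< 1e-15"; smaller values are
  numerically meaningless.
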