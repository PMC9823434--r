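# phytoFluor

Analysis of multispectral single-turnover (ST) active chlorophyll
fluorescence from mixed freshwater phytoplankton communities, for
aquatic ecologists and water-quality monitoring teams who need to track
cyanobacteria against a eukaryotic-algae background from fluorometric
data alone.

Multispectral ST fluorometers fire saturating 100–200 µs pulses built
from seven excitation LEDs (416, 452, 473, 495, 534, 594, 622 nm) and
record the fluorescence rise in two emission bands (685 and 730 nm).
Blue wavebands excite chlorophyll *a/b/c* and carotenoids (algae);
green–orange wavebands excite phycobilipigments (cyanobacteria).
Because most cyanobacterial chlorophyll *a* sits in photosystem I —
which fluoresces near 730 nm without variable fluorescence — the dark
F<sub>o</sub>(730/685) emission ratio under green–orange–red (GOR)
excitation rises with the cyanobacterial share of the community.

## The model

During an ST pulse the closed fraction *C(t)* of PSII reaction centres
follows

  dC/dt = α (1 − C) / (1 − ρC),  C(0) = 0,  α = σ<sub>PII</sub> · E<sub>ST</sub>,

with σ<sub>PII</sub> the functional absorption cross-section of PSII
photochemistry (nm² PSII⁻¹), E<sub>ST</sub> the pulse photon flux
(photons nm⁻² µs⁻¹), and ρ the inter-unit connectivity (0 by default).
Fluorescence rises as

  F(t) = F<sub>o</sub> + (F<sub>m</sub> − F<sub>o</sub>) · C(1 − ρ)/(1 − ρC),

and nonlinear least squares recovers F<sub>o</sub>, F<sub>m</sub>,
σ<sub>PII</sub> (and optionally ρ) per trace. Derived quantities follow
the field's conventions: F<sub>v</sub>/F<sub>m</sub> =
(F<sub>m</sub> − F<sub>o</sub>)/F<sub>m</sub>; α<sub>PII</sub> =
σ<sub>PII</sub> × flux (photons PSII⁻¹ µs⁻¹, with [0.042, 0.064]
optimal and < 0.02 unsaturated); per-step electron transport
J<sub>PII</sub> = σ′<sub>PII</sub> × actinic flux; and a Webb
exponential J(E) = P<sub>max</sub>(1 − e^(−α<sub>LC</sub>E/P<sub>max</sub>))
fitted across the 12-step fluorescence light curve (FLC), whose
F<sub>o</sub>, F<sub>v</sub>/F<sub>m</sub>, α<sub>PII</sub> and
σ<sub>PII</sub> are reported as means over the first five light steps
and ETR as the maximum J<sub>PII</sub>.

A first-class synthetic-data module generates the study conditions:
two-group (algae / cyanobacteria) seasonal succession over 23 sampling
dates, group optical models with blue- versus orange-peaked
σ<sub>PII</sub> spectra and PSI-driven 730 nm emission, raw ST traces
at both emission bands, and Sedgewick-Rafter Poisson counting noise
(counts × 10 → cells mL⁻¹).

## Worked example

```r
library(phytoFluor)

# a noisy dark-adapted GOR trace from known parameters, then inverted
tr <- simulateSTTrace(Fo = 100, Fm = 300, sigma = 4, "GOR",
                      noiseSd = 2, seed = 7)
fitSTTrace(tr)
#> STFitResult (E_ST = 20,990 umol m-2 s-1, 200 us pulse, n = 201)
#>   F_o = 100.6  F_m = 300.2  F_v/F_m = 0.6647
#>   sigma_PII = 4.014 nm^2  alpha_PII = 0.05074  rho = 0
#>   saturation: optimal
```

F<sub>o</sub> and F<sub>m</sub> come back within 1% of truth, the
fitted cross-section (4.01 nm²) puts α<sub>PII</sub> ≈ 0.051 inside the
optimal saturation band, so the pulse fully closed PSII and the fit is
trustworthy. A full light curve on a simulated mixed community:

```r
ab <- c(algae = 3000, cyanobacteria = 20000)   # cells / mL
runFLC(ab, protocol = "GOR", seed = 3)
#> FLCResult [GOR], 12 steps (0 failed)
#>   means over first 5 steps: F_o = 81.85  F_v/F_m = 0.4345  alpha_PII = 0.02867  sigma_PII = 2.268
#>   ETR_max = 452.43  P_max = 459.95  alpha_LC = 1.2163
```

The GOR-excited mixture saturates only partially (α<sub>PII</sub> ≈
0.029, mirroring what low-intensity green–orange LEDs achieve on real
communities), and electron transport saturates near 460 electrons
PSII⁻¹ s⁻¹. The whole pipeline — excitation spectra, FLCs per
protocol, 730/685 emission ratios and the abundance regressions — runs
from one config:

```r
runPipeline(runConfig(outDir = "run1", seed = 1))
```

or from the shell via `inst/scripts/phytofluor` (subcommands
`simulate`, `fit-st`, `run-flc`, `spectra`, `ratios`, `regress`,
`pipeline`).

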