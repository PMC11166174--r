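# petkh

Kinetic modelling and hydrolysis-rate mapping for hydrolyzable covalent
PET probes.

## The problem

Covalent enzyme inhibitors labelled for PET normally behave as
irreversible tracers: activity accumulates and stays. A carbamate probe
targeting monoacylglycerol lipase (MAGL) instead shows clear late washout,
because the covalent probe–enzyme complex is itself slowly hydrolyzed,
releasing labelled CO₂ that clears rapidly from brain. Once the plasma
input has decayed away, the tissue clearance rate equals the hydrolysis
rate **K_H** of the complex — and because enzymatic hydrolysis is pH
dependent (half-maximal CO₂ production at pH 5.3), K_H is a pH-weighted
readout of the intracellular milieu. In ischaemic tissue, where anaerobic
glycolysis acidifies cells, K_H drops measurably.

`petkh` implements the full analysis chain for anyone working with such
probes:

* **Compartment model** — plasma Cp → free tissue probe C1 (K1, k2) →
  covalent complex C2 (k3) → tissue CO₂ C3 (K_H) → efflux (k5), with an
  optional plasma-CO₂ reuptake path (k4). The linear system is solved
  *exactly* by matrix exponentials with the biexponential input folded
  into the state, so the fast CO₂ efflux (k5 ≈ 1.74 min⁻¹ vs
  K_H ≈ 0.7 h⁻¹) causes no stiffness trouble.
* **K_H estimation** — mono-exponential nonlinear least squares
  `A·e^(−a t)` on the 15–90 min washout window, with `a = K_H` in h⁻¹.
* **pH response** — logistic dose–response `f(pH)` with half-max 5.3
  linking pH to fractional hydrolysis activity, and `modulatedKH()` to
  derive regional K_H from regional pH.
* **In vitro assay simulator** — closed-system brain-homogenate
  CO₂-collection assay (probe → complex → dissolved CO₂ → bubbled trap),
  conservation-exact, with a pH sweep and half-max fitting.
* **Parametric mapping** — voxel-wise relative-K_H maps from 4D dynamic
  images: (early-frame mean − late-frame mean)/early-frame mean.
* **Synthetic data** — named scenarios (healthy, three occlusion
  durations, blocked, chase, non-hydrolyzable analogue) generating
  regional TACs and 4D two-hemisphere phantoms with ground truth, so the
  entire pipeline is testable without scanner data.

## Worked example

Simulate a stroke-model study (3–4 h occlusion: contralateral
K_H = 0.62 h⁻¹, lesion K_H = 0.41 h⁻¹ with 70 % reduced delivery), fit
both sides, and compare:

```r
library(petkh)

scen <- scenarioSpec("mcao_3_4h")
sim  <- generateRegionalTacs(scen)
khC  <- khValue(fitMonoExp(sim$tacs$contralateral))
khI  <- khValue(fitMonoExp(sim$tacs$ipsilateral))
c(contralateral = khC, ipsilateral = khI)
#> contralateral   ipsilateral
#>     0.6198763     0.4099347
percentReduction(khI, khC)
#> [1] 33.86833
```

The fitted rates recover the generating values to < 0.1 % and the lesion
shows the expected ≈ 34 % reduction. A parametric map of the same
scenario as a digital phantom:

```r
ph  <- generatePhantom(phantomSpec(scenario = scen, gridDim = c(64, 64, 32)))
khm <- relativeKHMap(ph$image)            # frames 3-10 vs 11-26
mapRegionSummary(khm, ph$masks[c("ipsilateral", "contralateral")])
#>          region     n      mean sd flagged
#> 1   ipsilateral  6812 0.2114792  0   FALSE
#> 2 contralateral 19372 0.3081822  0   FALSE
```

The lesion's relative efflux fraction (0.21) sits well below healthy
tissue (0.31), the voxel-wise signature of slowed hydrolysis. The pH
side:

```r
phHalfMax(phResponseModel())       # 5.3
sw <- phSweep(inVitroParams(), seq(3.5, 7.4, by = 0.25))
fitPH50FromSweep(sw)$ph50          # 5.3 recovered from the simulated assay
```

A TAC CSV ships as
`system.file("extdata", "example_tac_synthetic.csv", package = "petkh")`
(synthetic, generated by the package itself), and
`inst/scripts/petkh` offers shell subcommands (`simulate-tac`, `fit-kh`,
`map-kh`, ...) over the same functions.

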