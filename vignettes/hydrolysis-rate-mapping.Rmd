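---
title: "Modelling and estimating the hydrolysis rate of a covalent PET probe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and estimating the hydrolysis rate of a covalent PET probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkh)
```

## The model

A covalent MAGL inhibitor labelled with carbon-11 enters brain tissue
from plasma, binds its enzyme irreversibly, and — unusually for a
covalent probe — leaves again, because the probe–enzyme complex is
slowly hydrolyzed and the labelled product (¹¹CO₂) clears rapidly. We
render this as a linear compartment chain:

$$
\begin{aligned}
\frac{dC_1}{dt} &= K_1\,C_p(t) - (k_2 + k_3)\,C_1 \\
\frac{dC_2}{dt} &= k_3\,C_1 - K_H\,C_2 \\
\frac{dC_3}{dt} &= K_H\,C_2 - k_5\,C_3 + k_4\,C_p^{CO_2}(t)
\end{aligned}
$$

with $C_1$ free probe, $C_2$ the covalent complex, $C_3$ tissue CO₂, and
total measured activity $C_1+C_2+C_3$. This is the conventional
first-order rendering of an irreversible-binding model extended with a
product-washout pool; only the compartment diagram is given by the
biology, so the equations above are the package's explicit commitment.
Assumptions worth stating:

* all exchanges are first order (tracer-dose regime, no enzyme
  saturation in vivo);
* hydrolysis is irreversible and is the only route out of $C_2$;
* the plasma curve drives $C_1$ only, except through the optional $k_4$
  reuptake path.

**Units.** All internal computation is in minutes. $K_H$ alone is stored
and reported in h⁻¹, the convention in which such rates are quoted
(healthy brain ≈ 0.66–0.75 h⁻¹); it is divided by 60 at the solver
boundary. `rateConstants()` validates non-negativity of all six rates.

**The CO₂ reuptake path.** The diagrammed $k_4$ arrow (plasma CO₂ back
into tissue) is never quantified in practice and a plasma-CO₂ curve is
rarely available, so `k4` defaults to 0 and the CO₂ plasma pool defaults
to absent. Both a shared and a separate CO₂ plasma pool are
representable — `solveCompartments(co2Input = )` accepts any second
input curve — but neither is asserted as the "true" reading of the
diagram.

## Exact integration

With a biexponential input each forcing term satisfies
$\dot u = -\lambda u$, so augmenting the state with the forcing
exponentials makes the whole system homogeneous linear:
$x(t+\Delta) = e^{M\Delta}x(t)$. The solver propagates this matrix
exponential between breakpoints (input delay, rate-switch events) and
output points. Consequences:

* the solution is **exact** for piecewise-constant rates — no step-size
  tuning, no stiffness from $k_5 \gg K_H$ (a ratio of ~150 in the
  default regime, $k_5 = 1.74$ min⁻¹ vs $K_H \approx 0.7$ h⁻¹);
* rate-switch events (a chase that sets $k_3 \to 0$ at 20 min, a
  pre-blockade scaling $k_3$ from $t=0$) are handled without any special
  casing.

The test suite cross-checks the propagator against an independently
coded stiff integrator (`deSolve::lsoda` at `rtol = 1e-12`) on 20 random
parameter sets; agreement is required to 1e-6 relative.

**Frame averaging.** PET measures frame integrals, not instantaneous
values, so model TACs are duration-normalized integrals per frame. The
generator evaluates the closed-form solution directly at 10-point
Gauss–Legendre nodes inside each frame (machine precision for
exponentials on ≤ 5-min frames). The default schedule is the 26-frame,
90-min acquisition: 4 × 1 min, 8 × 2 min, 14 × 5 min.

## The input function and the fitting window

The default plasma curve is a bolus,
$C_p(t) = 9.5\,(e^{-0.55t} - e^{-6t})$ SUV, peaking at ~0.44 min with
$C_p(15)/C_p^{peak} < 10^{-3}$. The shape is constrained only by the
requirement that the input be negligible by 15 min — the condition under
which the 15–90 min tissue washout is input-free;
`generateInputFunction()` asserts this property rather than assuming it,
and warns for parameter sets that violate it. With the input gone,
$C_1$ (decaying at $k_2+k_3 = 0.9$ min⁻¹) is exhausted well before
15 min, CO₂ is quasi-steady at $(K_H/k_5)C_2 \lesssim 1\%$ of the
complex, and the total activity decays mono-exponentially at $K_H$ to
well under 1 %.

`fitMonoExp()` therefore fits $A e^{-a t}$ by nonlinear least squares
(Levenberg–Marquardt) on frames whose midpoints fall in the window
(default 15–90 min), with $t$ in hours so $a$ is directly $K_H$ in h⁻¹.
Numerical choices:

* initialisation: $A_0$ = first in-window value, $a_0$ = log-linear
  regression slope on positive in-window values;
* bounds $a \in [0, 20]$ h⁻¹; a flat TAC degenerates cleanly to
  $a = 0$;
* frames driven negative by noise are kept in the NLS objective but
  excluded from the log-linear initializer;
* weights default to uniform; `weights = "duration"` gives
  duration-proportional weights (longer frames, lower variance) since no
  weighting convention is standard here;
* the estimate is a *clearance* rate identified with $K_H$; no $k_5$
  correction is attempted (the identification error is
  $\mathcal{O}(K_H/k_5) \approx 0.7\%$).

## pH dose–response

Enzymatic hydrolysis activity versus pH is modelled as a base-10
logistic, $f(pH) = floor + (ceiling - floor)/(1 + 10^{hill\,(pH_{50} -
pH)})$, the standard dose–response shape. The default half-max is
pH 5.3 (the measured half-max of CO₂ production in brain homogenate);
the slope defaults to `hill = 1` and is user-settable because only the
half-max point is empirically constrained — the default is *not* claimed
to reproduce the measured curve's exact shape. The in-vitro curve need
not equal the in-vivo pH→$K_H$ relation (no direct calibration exists),
so this component is configurable, not a claimed calibration.
Severe-acid loss of binding (below pH ≈ 4.8, where the enzyme denatures)
is modelled as a separate multiplier on the *binding* rate
(`deactivationRule()`, default factor 0.15 — a fixture choice), not on
$K_H$, because that loss is a loss of affinity, not of catalysis.

## The in vitro assay simulator

The homogenate CO₂-collection assay is a closed system: pools
C1 (unbound), C2 (complex), C3 (dissolved CO₂), an external bubble trap,
and a pellet/nonspecific pool, summing to 100 %ID at all times
(asserted to 1e-9). Choices where the assay description is silent:

* **nonspecific pool**: measured but kinetically uncharacterised;
  modelled as an instantaneous fixed partition at $t=0$, default 25 % —
  a fixture choice, not a claim (the reported compartment splits do not
  sum to 100 %ID, so no absolute-split target is meaningful);
* **binding**: first order, `kOn = 0.08` min⁻¹, placing the unbound pool
  below 5 %ID by 60 min as observed for the hydrolyzable probe;
* **enzyme capacity**: the observed ~35 %ID complex plateau implies a
  finite reactive-enzyme pool; available as optional `bMax` with flux
  $k_{on} C_1 (1 - C_2/B_{max})$ (hydrolyzed enzyme not regenerated —
  the conservative reading), default **off** since no enzyme
  concentration is reported. Linear mode is solved exactly by matrix
  exponential; capacity mode by `lsoda` at 1e-12 tolerance;
* **trap**: bubbling is first-order removal of dissolved CO₂ at
  1 min⁻¹ — fast, as continuous bubbling suggests;
* all %ID values are decay-corrected quantities; physical decay of raw
  counts is handled separately by `decayCorrect()`.

`phSweep()` reports, per pH, the final pool split *and* an effective
CO₂-production rate measured from the simulation output as
$(C_3 + trap)/\int C_2\,dt$ — for first-order hydrolysis this ratio *is*
the rate constant, so `fitPH50FromSweep()` (logistic least squares on
that rate, floor fixed at 0) recovers the half-max pH without the bias
that fitting cumulative trapped CO₂ would introduce (cumulative capture
is a concave function of the rate, which shifts the apparent midpoint by
≈ 0.1 pH units over a 60-min incubation).

## Parametric mapping

`relativeKHMap()` implements the four-step frame arithmetic: average an
early block (apparent maximum uptake), average a late block, subtract,
divide by the early average. Decisions:

* **frame indexing is 1-based**: early = frames 3–10, late = 11–26 on
  the 26-frame schedule. The conventional time labels ("2–15 min",
  "15–90 min") do not exactly match the schedule arithmetic (frame 10
  ends at 16 min); the indices are operational and win;
* **mask threshold**: voxels with early mean ≤ 0.2 SUV are masked out
  (NaN) and counted — at that delivery level the ratio becomes
  unreliable; configurable;
* map values are **not clipped**: a non-hydrolyzable tracer accumulates
  late and produces values ≤ 0, which should stay visible;
* no smoothing by default; optional separable Gaussian smoothing
  (FWHM in mm) before averaging for noisy data. Whether any smoothing
  belongs upstream is left to the user — the defaults here are
  declared, not inferred from practice;
* output keeps the input grid; NaN outside the validity mask.

For a noise-free mono-exponential voxel the map equals
$1 - \bar{E}_{late}/\bar{E}_{early}$, strictly increasing in $K_H$
(verified over 0.1–2 h⁻¹) and invariant to global intensity scaling.

## The synthetic-data generator

Scenarios define the study conditions once:

| scenario | regions | $K_H$ (h⁻¹) | delivery |
|---|---|---|---|
| `healthy` | 6 brain regions | 0.66–0.75 (regional means) | spread to give 1.6–1.9 SUV peaks |
| `mcao_1h` | contra / ipsi | 0.62 / 0.47 | ipsi = 30 % of contra |
| `mcao_3_4h` | contra / ipsi | 0.62 / 0.41 | ipsi = 30 % of contra |
| `mcao_6h` | contra / ipsi | 0.67 / 0.56 | ipsi = 30 % of contra |
| `blocked` | brain | 0.66 | $k_3$ at 5 % from $t=0$ |
| `chase` | brain | 0.66 | $k_3 \to 0$ at 20 min |
| `hppc_like` | brain | 0 | plateau 1.0–1.4 SUV |

$k_2 = 0.3$ and $k_3 = 0.6$ min⁻¹ are fixture choices (unreported in
vivo); they put two-thirds of delivered probe into the trapped pool with
free probe exhausted well before 15 min — the regime that makes the
mono-exponential shortcut valid. Regional $K_1$ values are calibrated
through the linearity of the system (peak SUV per unit $K_1$ ≈ 10.0
with the default input) so healthy peaks span 1.6–1.9 SUV. Regional pH
can be supplied instead of $K_H$, routed through `modulatedKH()`.

The phantom is a schematic two-hemisphere ellipsoid (default
64 × 64 × 32, 0.5 mm voxels) with an ellipsoidal lesion confined to the
ipsilateral hemisphere; every voxel carries its label's regional TAC
exactly, plus optional noise. Noise is zero-mean Gaussian with
SD = level × value / √(frame duration in min) — the standard
frame-weighted TAC approximation, declared rather than data-derived.
All stochastic output is a pure function of (spec, seed).

**What the phantom does *not* emulate:** reconstruction noise
correlations, partial-volume effects, motion, scatter/attenuation
artefacts, anatomical geometry, or input-function variability between
subjects. Passing tests on this generator demonstrate the *estimator's*
correctness and the pipeline's self-consistency under the declared
conditions, not robustness to every property of real scanner data.

## Problem sizes and test design

The suite runs the full 64 × 64 × 32 × 26 phantom once (map oracle,
region ranking, scale invariance) and uses 16 × 16 × 8 phantoms for the
100-replicate Monte-Carlo checks; K_H recovery sweeps use 100 noise
replicates per rate at the 26-frame schedule. These sizes give stable
Monte-Carlo estimates at interactive runtimes. Oracles are independent
of the code paths they check: `lsoda` for the propagator,
`stats::integrate` for frame means, direct row arithmetic for the map,
closed forms for the logistic.

## Known limitations

* $K_H$ is identified with the clearance rate; the
  $\mathcal{O}(K_H/k_5)$ bias is accepted, as is conventional.
* The pH→$K_H$ link is a configurable model, not a calibration; mapping
  relative $K_H$ to absolute pH requires external calibration data.
* The mono-exponential window (15–90 min) presumes the input-extinction
  property; tracers or species with slower plasma clearance need a
  different window, which is why the window is a parameter everywhere.
* Conflicting reported values for the 1 h and 6 h occlusion conditions
  exist (tabulated vs narrative); the tabulated values
  (0.62/0.47 and 0.67/0.56 h⁻¹) are used for the scenario defaults.
* The relative map is relative: no conversion to absolute h⁻¹ is
  attempted, by design.
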