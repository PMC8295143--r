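---
title: "Electro-thermal modeling and protocol optimization for irreversible electroporation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-thermal modeling and protocol optimization for irreversible electroporation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Irreversible electroporation (IRE) ablates tissue with trains of short
high-voltage pulses delivered through needle electrodes. The mechanism is
nominally non-thermal — lethal permeabilization of cell membranes wherever
the local field magnitude exceeds a threshold — but Joule heating is not
zero, and aggressive protocols can push tissue past the ~50 °C mark where
thermal damage to vessels, ducts and other structures near the target
becomes a real risk. Planning a protocol therefore means choosing five
coupled parameters — active electrode length, inter-electrode distance,
voltage, pulse number and pulse width — to maximize the ablated region
while keeping peak temperature below the damage cap.

`ireplan` implements that planning loop for two parallel needle electrodes
in liver tissue: a 2D coupled electric/bioheat model, response extraction
(ablation area, peak temperature, damage verdict), and a screening-design →
response-surface → desirability-optimization pipeline.

## Physical model

**Electric problem.** The pulse time scale (tens of µs) is far below any
thermal scale, and tissue charging transients are not modeled, so the field
is quasi-static: the potential solves the current-conservation equation

$$\nabla \cdot \big(\sigma(|E|)\, \nabla V\big) = 0,$$

with the applied voltage on one active electrode segment, ground on the
other, and electrical insulation on the outer tissue boundary and along the
insulated needle shafts. Tissue conductivity rises with the local field —
the signature of electroporation — between a floor of 0.0650 S/m and a
ceiling of 0.1483 S/m for bovine liver. The constant-coefficient Laplace
problem is available as `mode = "constant_sigma"`, both because it is the
textbook starting point and because the field-dependent and constant
solutions bracket what commercial solvers may have done; the field-dependent
form is the default since it is the only way the conductivity-versus-field
material curve can matter at all.

**Thermal problem.** Temperature follows the Pennes bioheat equation

$$\rho c_p \frac{\partial T}{\partial t}
  = \nabla\cdot (k(T)\nabla T) + Q_s + \rho_b c_{p,b}\,\omega_b (T_b - T) + Q_{met},$$

with no advection (ex vivo tissue, zero velocity field), blood constants
$\rho_b = 1000$ kg/m³, $c_{p,b} = 3640$ J/(kg·°C), $\omega_b = 5\times10^{-4}$ 1/s,
$T_b = 37$ °C and $Q_{met} = 0$. The perfusion sink is retained by default
because the reference model includes it even for ex vivo tissue;
`perfusion = FALSE` switches it off. The heat source is duty-cycle-averaged
Joule heating,

$$Q_s = (\text{pulse width} \times \text{frequency})\; \sigma(|E|)\, |E|^2,$$

evaluated at the converged field of the electric solve. At duty cycles of
order $10^{-4}$ (e.g. 41 µs at 1 Hz) the averaged source and an explicit
on/off pulse train differ negligibly over a 30–90 s treatment, while the
averaged form permits time steps of 0.1 s instead of sub-µs resolution.
There is no electro-thermal back-coupling: the material curves provide no
temperature dependence of $\sigma$, so the field is solved once per
protocol.

## Geometry

The model plane **contains both electrode axes** (x lateral, y downward
from the tissue surface). This choice is deliberate: the active length is a
study factor, and the temperature profile along the inter-electrode
vertical line is a reported diagnostic — neither is expressible in a cross
section perpendicular to the needles. Electrodes are rectangles of
diameter × active length ending at the tip (insertion depth 20 mm by
default), with the insulated shaft above the active segment excluded from
both conduction problems. The center measurement point is the node midway
between the axes at half the active length; the outer probe sits 3 mm
lateral of the right electrode surface at tip depth, matching the
fiber-optic probe placement used in bench validation of such models.

Defaults that the source material does not fix, chosen once and kept:

* **electrode diameter 1.0 mm** — typical 18–19 G monopolar IRE needles;
* **domain 60 × 60 mm** — the insulated boundary changes the center-point
  field by < 1% when the domain is doubled (tested);
* **grid spacing 0.25 mm, dt 0.1 s** — halving either changes the
  center-point field by < 1% and the final center temperature by < 0.1 °C
  (tested at coarser base resolutions to keep the suite fast).

## Material curves

Exact property-versus-temperature and conductivity-versus-field curves for
bovine liver are not tabulated in the source material (only the σ floor and
ceiling are), so every property is a declarative piecewise-linear knot
curve loaded from CSV, clamped outside its knot range:

* `sigma_vs_field.csv`: a symmetric smoothstep from 0.0650 S/m below
  10 kV/m to 0.1483 S/m above 70 kV/m — the transition range of published
  liver electroporation curves. Because the knot set is symmetric, the
  curve passes through the exact midpoint (0.0650 + 0.1483)/2 at 40 kV/m.
* `k_vs_temperature.csv`: constant 0.52 W/(m·°C), a standard liver value;
  add knots to model temperature dependence (the solver then refactors the
  thermal system each step).
* `epsr_vs_temperature.csv`: carried for interface completeness but unused —
  permittivity does not enter a static conduction problem. Documented as
  inert rather than silently dropped.

These defaults are calibration knobs by design; swapping the CSVs
recalibrates the model without code changes.

## Numerics

Structured node-centered finite volumes with a 5-point stencil replace an
unstructured mesher: the discretization is reproducible from a single
spacing parameter and symmetric positive definite, solved by sparse
Cholesky. The field-dependent conductivity is converged by Picard
iteration with under-relaxation 0.5 on the σ update, stopping when the
relative residual of the assembled conservation equation falls below 1e-8
(a hard error, never a silent partial result, if 100 iterations do not
suffice). Time integration is backward Euler with k lagged one step; with
the default constant k the system matrix is factored once per treatment.
Field magnitudes use central differences, falling back to one-sided stencils
next to insulated shafts and boundaries. The ablation area is a cell count
(nodes with $|E| \ge$ 800 V/cm × cell area) — monotone in both threshold
and voltage, convergent under refinement, with no sub-cell interpolation to
tune.

On the threshold's units: the source text prints both "800 V/m" and
"800 V/s" in different places. At 800 V/m essentially the entire domain
between 3000 V electrodes would count as ablated, contradicting the printed
areas of at most 375 mm²; 800 V/cm ($8\times10^4$ V/m) is the standard
liver IRE threshold scale and is the only reading numerically consistent
with the reported areas. The default is therefore 800 V/cm, configurable.

## The statistics stack

**Designs.** `full_factorial()` enumerates the 2×3×3×3×3 = 162 level
combinations; `taguchi_L18()` maps the five factors onto the first five
columns of the canonical L18(2¹3⁷) orthogonal array, which reproduces the
published 18-run screening design row for row.

**Response surface.** Both responses are fitted by OLS on coded units
(each factor mapped linearly to [−1, 1]) with intercept, five linear terms
and pure quadratic terms for the four 3-level factors. Two-factor
interactions are excluded by default: with 18 runs the full interaction set
is super-saturated, and the pure-quadratic model reproduces the reference
ANOVA p-values (distance 0.020 and voltage 0.003 for temperature, voltage
< 0.001 for area) and the reference optimum predictions to the printed
precision — strong evidence it is the model the original analysis used.
Factor significance is read from the linear-term t-test, the convention
under which those printed values are recovered.

**Desirability.** The optimization objective follows the study's stated
goal — *maximize the electric field between the electrodes while limiting
the maximum temperature to 50 °C* — as a geometric mean of three [0, 1]
scores:

1. mean inter-electrode field, proxied by voltage/distance, as a
   larger-is-better ramp over its achievable range;
2. peak temperature as a *thermal-budget* ramp, $(T-37)/(50-37)$ for
   $T \le 50$ and 0 above: protocols are rewarded for using the full
   headroom under the damage cap and disqualified for crossing it;
3. predicted ablation area as a larger-is-better ramp between the observed
   response minimum and maximum.

A pure stay-below-50 penalty (d = 1 when cool, falling to 0 at 50 °C) is
available via `desirability_spec(temp_shape = "upper_bound")`, but as a
default it drives the optimizer to the coldest corner of the box and away
from any protocol that actually exploits the allowed thermal budget, which
contradicts the planning intent.

**Optimizer.** The 2-level hardware factor is enumerated; the four
continuous factors are searched by 64-start Nelder-Mead (half the starts
seeded from a coarse grid, half uniform under a fixed seed), with
near-corner coordinates snapped to the bound and the interior coordinates
re-polished. Between the two discrete slices, the winner is chosen by
composite desirability *only when the discrete factor is significant in at
least one response model*; when it is statistically inert in both (as it is
in the reference data, p ≈ 0.36–0.45), the slice ranking would rest
entirely on noise-level coefficients, so the lower — less invasive — level
is preferred. Exact ties break toward the smallest voltage, then the
smallest pulse number. The continuous pulse-number optimum is also reported
rounded to the nearest multiple of ten, the granularity used when
protocols are delivered.

## What the synthetic generators emulate

`generate_synthetic_responses()` draws responses from a known quadratic
surface plus i.i.d. Gaussian noise; it exists to verify coefficient
recovery (exact at zero noise), sampling spread against the OLS covariance
formula, and null behavior of the ANOVA under permutation or overwhelming
noise. `two_wire_potential()` is the closed-form bipolar line-source
solution used (on a synthetic cross-sectional disk-electrode grid, on a
mid-plane band away from the conductors) to verify the field solver to
within 2%, a tolerance that acknowledges both the thin-wire approximation
and the staircase representation of a disk on a square lattice. Neither
generator models spatially correlated noise, electrode-placement error, or
tissue heterogeneity — passing tests say the solvers and statistics are
self-consistent and match their oracles, not that real livers behave like
the model.

## Problem sizes used by the test suite

The calibrated end-to-end check runs at the default 0.25 mm spacing
(241 × 241 nodes) and dt = 0.1 s. Property and invariant tests use 0.5–1 mm
spacing and dt of 0.5–1 s, where a full coupled solve takes well under a
second; refinement tests compare consecutive resolutions at those coarser
bases. The 18-run screening re-simulation for trend checks runs at 0.5 mm.

## Known limitations

* 2D: areas, not volumes; no angulated or multi-needle configurations.
* No temperature dependence of electrical conductivity, no phase change
  above 100 °C, no Arrhenius damage integral — the damage verdict is the
  50 °C threshold alone.
* The quasi-static, duty-averaged source ignores within-pulse dynamics and
  inter-pulse rest periods.
* The desirability optimum inherits the response-surface model's bias; the
  pipeline's verification step (re-simulating the optimum) quantifies it
  per study rather than assuming it away.
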