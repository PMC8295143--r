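# ireplan

Electro-thermal simulation and protocol optimization for irreversible
electroporation (IRE) with two parallel needle electrodes.

IRE ablates soft tissue (here: liver) with trains of short high-voltage
pulses: wherever the field magnitude exceeds a lethal threshold
(800 V/cm by default), cell membranes are permanently permeabilized. The
technique is nominally non-thermal, but Joule heating is not zero, and
crossing ~50 °C risks collateral thermal damage to vessels and ducts. The
planning problem is to choose the five protocol parameters — active
electrode length, inter-electrode distance, voltage, pulse number, pulse
width — that maximize the ablated area while staying below the thermal
cap. `ireplan` is aimed at researchers studying IRE treatment planning and
at anyone who wants a fully scriptable, open reimplementation of the
screening → response-surface → desirability planning loop.

## The model

* **Electric:** quasi-static current conservation
  ∇·(σ(|E|)∇V) = 0 on a 2D plane containing both electrode axes, with the
  applied voltage on one active segment, ground on the other, insulated
  outer boundary and needle shafts. σ(|E|) rises from 0.0650 to
  0.1483 S/m (bovine liver) along a configurable piecewise-linear curve;
  the nonlinearity is converged by Picard iteration. A `constant_sigma`
  mode solves the plain Laplace problem.
* **Thermal:** Pennes bioheat equation
  ρc<sub>p</sub> ∂T/∂t = ∇·(k∇T) + Q<sub>s</sub> + ρ<sub>b</sub>c<sub>p,b</sub>ω<sub>b</sub>(T<sub>b</sub> − T) + Q<sub>met</sub>,
  integrated by backward Euler from 37 °C with the duty-cycle-averaged
  Joule source Q<sub>s</sub> = (pulse width × frequency)·σ(|E|)·|E|².
* **Responses:** ablation area (cell-counted |E| ≥ 800 V/cm region), peak
  tissue temperature, and a 50 °C damage verdict.
* **Statistics:** full-factorial and Taguchi L18(2¹3⁴) designs; quadratic
  response surfaces on coded units with per-term ANOVA; composite
  desirability optimization (maximize inter-electrode field and predicted
  area, use — but never exceed — the 50 °C thermal budget) with
  verification re-simulation at the optimum.

See the methods vignette (`vignettes/ire-protocol-planning.Rmd`) for the
assumptions, defaults and design choices.

## Worked example

Fit the response surfaces to the shipped 18-run screening table and find
the desirability-optimal protocol:

```r
library(ireplan)

tab <- ire_screening_table()
models <- list(area        = fit_rsm(tab, tab, "ablation_area_mm2"),
               temperature = fit_rsm(tab, tab, "max_temperature_C"))
opt <- optimize_desirability(models, desirability_spec(), seed = 1)
round(opt$optimum, 4)
#> active_length_mm      distance_mm        voltage_V     pulse_number
#>          10.0000          10.0000        3000.0000          54.3083
#>   pulse_width_us
#>          40.0000
round(opt$predicted, 4)
#>        area temperature
#>    269.7987     50.0000
opt$pulse_number_rounded
#> [1] 50
```

The optimum sits at 10 mm active length, 10 mm spacing and 3000 V with
~54 pulses of 40 µs: the protocol that drives the strongest field between
the electrodes while the predicted peak temperature uses the entire
thermal budget (50.00 °C, i.e. no damage margin is wasted). The ANOVA
behind it flags electrode distance (p = 0.020) and voltage (p = 0.003) as
the significant drivers of temperature, and voltage alone (p < 0.001) for
area.

Simulate that protocol with the coupled solver and extract the responses:

```r
sim <- simulate_protocol(active_length = 10, distance = 10, voltage = 3000,
                         pulse_number = 50, pulse_width = 41.21,
                         config = run_config())
ablation_area(sim$field, sim$grid)   # mm^2
#> [1] 262.5
sim$max_temperature                  # degrees C
#> [1] 46.50765
thermal_damage_flag(sim)
#> [1] FALSE
```

The simulated area (262.5 mm²) and peak temperature (46.5 °C) sit a few
percent from the response-surface predictions — the RSM overestimates the
temperature, as the verification step of `run_optimization_and_verify()`
quantifies — and the protocol stays safely below 50 °C.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/ire-plan.R screen   --design l18 --out out/
Rscript inst/scripts/ire-plan.R optimize --responses out/responses.csv --out out/
Rscript inst/scripts/ire-plan.R simulate --protocol 10,10,3000,50,41.21 --out out/
```

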