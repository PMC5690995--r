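# compcomm

Commissioning tools for **brass-compensator IMRT**: a two-parameter
compensator beam model, χ²-based optimization against slab-attenuation
measurements, a from-scratch 2D gamma-index comparison of measured and
calculated dose planes, and a synthetic-data generator that lets the whole
pipeline be validated by parameter recovery.

## The problem

Solid brass compensators modulate an IMRT beam by varying the thickness of
milled brass across the field. A model-based treatment planning system
(TPS) typically models them with just two adjustable parameters — a brass
density ρ (g/cm³) and a *modified scatter factor* MSF (cm⁻¹) that
multiplies the fluence by 1 + MSF·L for path length L through the
compensator — leaving the validated open-beam model untouched. This
package implements both measurement-driven routes by which those two
parameters are commissioned:

- **Slab attenuation (ion chamber).** Central-axis transmission through
  flat brass slabs (1, 3, 5 cm) at depths 2.5/10/20 cm and field sizes
  5×5/10×10/20×20 cm², modelled as

  T(t) = (1 + MSF·t) · exp(−κρt),

  with κ a fixed mass-attenuation constant (0.037 cm²/g by default).
  Measured and predicted log ratios are compared with
  χ² = Σᵢ (pᵢ − xᵢ)²/|xᵢ|, minimized by sequential parameter sweeps: MSF
  sweeps at each density give a minimum-of-minima curve over ρ, whose
  argmin per (depth, field-size) condition is averaged into the
  commissioned density; a final MSF sweep at that density completes the
  fit.

- **Gamma analysis (diode array).** For a seven-field compensator plan,
  measured diode planes are compared with calculated planes via the gamma
  index γ(r_m) = min over r_c of √(|r_c−r_m|²/DTA² + Δ²/ΔD²), with local
  percent dose difference, a 10% low-dose threshold, and a ladder of
  criteria (3%/3mm → 1%/1mm). The commissioned (ρ, MSF) minimizes the
  total number of failing points (γ > 1) across fields; only the strict
  criteria discriminate, so they drive selection.

Because real commissioning data exist only as instrument readings, the
package generates synthetic studies from a known ground-truth model —
noisy slab tables and compensator-modulated diode planes — so every stage
is testable end to end.

## Worked example

```r
library(compcomm)

truth <- beam_model(rho = 7.8, msf = 0.1)

# a synthetic ion-chamber study: 9 conditions x {0,1,3,5} cm, 0.5% noise
meas <- generate_slab_measurements(truth, noise = noise_spec(0.005, seed = 42))
fit <- commission_slabs(meas)
print(fit)
#> <commissioning_result>
#>   conditions: 9
#>   per-condition rho optima: 7.8, 7.8, 7.7, 7.8, 7.9, 7.8, 7.8, 7.8, 7.8 g/cm^3
#>   commissioned rho (mean): 7.8 g/cm^3
#>   commissioned MSF: 0.1 cm^-1 (chi2 = 0.00225821)
```

The nine per-condition density optima scatter by one 0.1 g/cm³ grid step
around the truth under measurement noise; their mean and the final MSF
sweep recover the generating parameters exactly.

```r
# one field of a diode-array study: measured at truth, calculated at a
# mis-commissioned density (nominal brass, 8.5 g/cm^3)
plan <- plan_spec(field_size_cm = 10)
comp <- generate_compensator_map(plan, seed = 7)
measured <- sample_diode_array(simulate_dose_plane(comp, truth), 7,
                               noise_spec(0.01, seed = 8))

gamma_index(measured, simulate_dose_plane(comp, beam_model(8.5, 0.1)),
            gamma_criteria(2, 2))
#> <gamma_result> 2%/2mm: 225 evaluated, 203 failing (pass rate 9.8%)

gamma_index(measured, simulate_dose_plane(comp, truth), gamma_criteria(2, 2))
#> <gamma_result> 2%/2mm: 225 evaluated, 2 failing (pass rate 99.1%)
```

A 0.7 g/cm³ density error fails 90% of diodes at 2%/2mm; at the true
parameters only the 1% reading noise remains and the plane passes.

## The analysis workflow

The `analysis/` scripts run the full study at realistic size and leave
their tables, reports and sweep plots under `results/`:

```sh
Rscript analysis/01_simulate_study.R     # synthetic study (slabs + 7 fields)
Rscript analysis/02_commission_slabs.R   # chi-squared track
Rscript analysis/03_commission_gamma.R   # gamma-analysis track
Rscript analysis/04_noise_robustness.R   # recovery error vs noise level
```

## Documentation

The methods vignette (`vignettes/compensator-commissioning.Rmd`) explains
the model and its assumptions, the sweep and gamma algorithms, the
parameter-confounding ridge between ρ and MSF, what the synthetic
generator does and does not emulate, and all numerical conventions
(grids, tie-breaks, search radius and step, degenerate inputs).
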