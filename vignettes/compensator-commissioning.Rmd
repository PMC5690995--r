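---
title: "Commissioning a compensator beam model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Commissioning a compensator beam model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compcomm)
```

## The problem

Solid brass compensators are an alternative to MLC delivery for IMRT: a
milled block whose thickness varies over the field modulates the beam
fluence. Before a treatment planning system (TPS) can plan with them, its
compensator model must be commissioned — its adjustable parameters tuned
until calculated dose matches measurement — while leaving the open-beam
model untouched, so that fields needing no modulation still collapse to
the validated open-beam behaviour.

A model-based TPS typically exposes exactly two compensator parameters: a
brass density $\rho$ (g/cm$^3$) and a *modified scatter factor* MSF
(cm$^{-1}$), a correction for the extra scatter a metal compensator
produces relative to tissue, applied by multiplying the fluence by
$1 + \mathrm{MSF}\cdot L$ with $L$ the primary-ray path length through
the compensator. This package implements the full two-track commissioning
procedure for such a model:

1. **Slab track** — ion-chamber transmission through flat brass slabs
   (1, 3, 5 cm) at several depths and field sizes, fitted by a
   $\chi^2$ sweep procedure.
2. **Diode-array track** — planar dose measurements of a seven-field
   IMRT plan's compensators, fitted by minimizing the number of detector
   points failing a gamma-index test.

Because the real measurements behind such a commissioning exist only as
instrument readings, the package ships a synthetic-data generator that
emulates both measurement campaigns from a known ground-truth model, so
every stage can be validated by parameter recovery.

## The surrogate transmission model

The TPS's internal dose engine is out of scope; what the commissioning
needs is the central-axis transmission a given $(\rho, \mathrm{MSF})$
pair implies. We fix the surrogate

$$T(t) = (1 + \mathrm{MSF}\, t)\, e^{-\kappa \rho t},$$

where $t$ is the brass thickness (cm) and $\kappa$ is a fixed mass
attenuation coefficient (default $0.037$ cm$^2$/g, a plausible value for
brass at the effective energy of a 10 MV beam; configurable). The
product $\kappa\rho$ plays the role of the effective linear attenuation
coefficient. This form reproduces the two behaviours the commissioning
procedure relies on:

* at MSF $\approx 0$ the log attenuation $\ln T = \ln(1+\mathrm{MSF}\,t)
  - \kappa\rho t$ is (numerically) a straight line in $t$;
* at large MSF (e.g. 0.5 cm$^{-1}$) it is visibly curved, so density and
  scatter factor are separately identifiable from multi-thickness data.

Whether the fluence factor is applied before or after attenuation is
unobservable at the level of total transmission; the product form is
assumed. Depth in water and field size do not enter $T$: their effect is
represented only through separate measurement conditions that the
optimizer stratifies over (and, in the generator, an optional
per-condition perturbation of $\kappa$). No beam-hardening or divergence
correction is modelled inside $T$; we are not attempting to determine an
absolute attenuation coefficient, only to tune the two TPS parameters.

## The $\chi^2$ slab workflow

With measured log ratios $x_i = \ln(I_i/I_0)$ and model predictions
$p_i$, the misfit is

$$\chi^2 = \sum_i \frac{(p_i - x_i)^2}{|x_i|}.$$

The denominator is taken in absolute value: log ratios are negative, and
a relative-misfit objective must be non-negative. Zero-thickness
(open-field) rows are the normalization itself and are excluded from the
sum, where they would divide by zero.

The optimization mirrors what a physicist does in a TPS that offers no
optimizer — sequential one-dimensional sweeps:

1. for each density on a grid, sweep MSF and record the minimum
   $\chi^2$ (`min_chi2_curve()`);
2. the argmin of that minimum-of-minima curve is the commissioned
   density for one measurement condition;
3. per-condition optima are averaged (unweighted, overall and per depth)
   into the aggregate density (`aggregate_optimum()`);
4. a final MSF sweep at the aggregate density, pooling all conditions,
   commissions the scatter factor.

`commission_slabs()` runs all four steps; `chi2_surface()` exposes the
exhaustive 2D grid evaluation as a cross-check mode, and the test suite
asserts that the sequential reduction equals the 2D surface reduced
along the MSF axis. A simultaneous 2D search could in principle refine
the optimum further, but the sequential procedure is the primary method
here because it is what the manual workflow supports.

**Default grids.** $\rho \in [7.0, 9.0]$ in steps of 0.1 g/cm$^3$ and
$\mathrm{MSF} \in [0, 0.5]$ in steps of 0.05 cm$^{-1}$, with
$10^{-4}$ cm$^{-1}$ added as the near-zero probe value. These bracket
nominal brass (8.5 g/cm$^3$) and the physically sensible scatter-factor
range at the resolution a manual sweep would use. Grid values are
rounded (`round(seq(...), 6)`) so nominal points such as 7.8 are exactly
representable and noise-free closure can return the truth bit-exactly.
Exact argmin ties break toward the smaller parameter value —
deterministic and order-independent.

**Parameter confounding.** Over the slab range $t \in [1, 5]$ cm the
sensitivities $\partial \ln T/\partial\rho = -\kappa t$ and
$\partial \ln T/\partial\,\mathrm{MSF} = t/(1+\mathrm{MSF}\,t)$ are
nearly collinear, so the $\chi^2$ surface has a shallow ridge: an MSF
offset of 0.025 cm$^{-1}$ can be compensated by roughly 0.4–0.5
g/cm$^3$ of density. Two practical consequences, both visible in the
test suite: recovery bounds should be stated per coordinate (with the
companion parameter on-grid), and beam hardening — emulated by the
generator's quadratic log-attenuation term — masquerades as extra
density when MSF is pinned near zero. The multi-condition average and
the independent gamma track are the defences against this degeneracy.

## The gamma-index workflow

The diode-array track compares a measured dose plane $D_m$ (reference)
with a calculated plane $D_c$ through the standard gamma index

$$\gamma(r_m) = \min_{r_c}\sqrt{\frac{|r_c - r_m|^2}{\delta^2}
 + \frac{\Delta(r_m, r_c)^2}{\epsilon^2}},$$

with $\delta$ the distance-to-agreement (mm), $\epsilon$ the percent
dose-difference tolerance, and $\Delta$ the percent dose difference,
normalized **locally** to $D_m(r_m)$ by default (the global, "Van Dyk"
normalization to $\max D_m$ is implemented but off by default). Points
with $D_m$ below 10% of the plane maximum are excluded — detectors
outside the IMRT field. A point fails when $\gamma > 1$.

**Search.** The minimization scans a disc of candidate positions around
each reference point — radius $3\delta$, step $\delta/10$, always
containing the zero offset — with bilinear interpolation of the
calculated plane; candidates falling off the plane are skipped. The
truncation is exact for any $\gamma < 3$, because a candidate beyond
radius $R$ carries a distance penalty of at least $R/\delta$ alone;
the suite asserts this, and asserts that halving the step (a superset
of candidates) can only lower $\gamma$. The scan itself is a small
C++ kernel; the test suite and the acceptance script compare it
point-for-point against a plain-R exhaustive search written from the
textbook formula.

**Commissioning by failing points.** `failing_vs_parameter()` recomputes
every field's calculated plane at each grid value of one parameter
(holding the other fixed), totals failing points across the seven fields
at four stringency levels — 3%/3mm, 2%/2mm, 1.5%/1.5mm, 1%/1mm — and
reports the per-criteria argmin. The loose institutional criteria pass
nearly everything and are flat in the parameters; the strict levels
discriminate. `commission_gamma()` therefore selects the argmin at the
strictest level, sweeping density first (MSF at 0.1 cm$^{-1}$), then MSF
at the commissioned density. Flat stretches of zero failing points
resolve to the smallest grid value by the tie-break rule; this is
visible at loose criteria and is why the strict level drives selection.

## The synthetic study

`generate_slab_measurements()` emulates the ion-chamber campaign: the
full crossing of thicknesses $\{0, 1, 3, 5\}$ cm (the zero row is the
open-field normalization), depths $\{2.5, 10, 20\}$ cm and field sizes
$\{5, 10, 20\}$ cm, with multiplicative Gaussian reading noise
($x_i = \ln[T(t_i)(1+\varepsilon_i)] - c\,t_i^2$,
$\varepsilon_i \sim N(0, \sigma^2)$) and an optional hardening
coefficient $c$. The default study noise $\sigma = 0.5\%$ is a realistic
chamber repeatability. An optional per-condition $\pm 2\%$ perturbation
of $\kappa$ reproduces the spread of per-condition density optima a real
beam shows across depths and field sizes (harder beam for small fields).

`generate_compensator_map()` builds IMRT-like thickness maps: a sum of
eight random cosine modes plus three Gaussian bumps, rescaled to
[base, max] thickness and clipped at the 0.6 cm fabrication minimum,
with spatial frequency (and bump sharpness) scaling with a roughness
knob — rougher maps have steeper fluence gradients, which the suite
checks empirically. Defaults: 25 cm field, 5 mm calculation grid, 7 mm
diode pitch (a generic diode-array geometry), thickness up to 5 cm,
matching the slab range studied. `simulate_dose_plane()` applies $T$
pointwise to a flat unit open field (a smooth profile can be supplied;
beam horns are deliberately not modelled — only compensator-induced
modulation is under test), and `sample_diode_array()` measures it:
bilinear sampling at the diode pitch plus multiplicative noise. All
generators are bit-reproducible given (parameters, seed).

**What passing tests do and do not show.** The generator shares its
transmission formula with the fitted model, so noise-free closure tests
demonstrate the correctness of the optimization machinery, not the
physical fidelity of the surrogate. Real data add beam hardening,
off-axis spectral change, detector-response effects and setup error that
the generator only caricatures (the hardening term, the $\kappa$
jitter). Recovery results here therefore validate the *procedure* —
identifiability, noise robustness, the discriminating power of strict
gamma criteria — and say nothing about how well the surrogate matches a
particular accelerator.

## Numerical choices and degenerate inputs

* Natural logarithms throughout; the attenuation law is exponential in
  $e$.
* $\chi^2$ requires at least one positive-thickness record; measured
  values of exactly 0 are a domain error (exclude normalization rows).
* Dose planes must be finite, non-negative, on strictly positive
  spacing; bilinear interpolation needs at least a $2\times2$ grid and
  returns `NA` outside it (boundary positions are clamped within a
  $10^{-9}$ relative tolerance).
* Gamma evaluation errors out when the measured maximum is not positive
  or when an evaluated reference position lies outside the calculated
  plane (non-overlapping planes).
* A roughness of 0 degenerates the compensator generator to a flat slab
  at base thickness; `sample_diode_array()` refuses a pitch finer than
  the plane grid.
* Reported gamma values can be capped (`gamma_cap`); the default is
  uncapped so oracle comparisons are exact.

## Problem sizes

The shipped analysis scripts use the full study geometry (25 cm fields,
36×36 diode planes, nine-point density sweep). The test suite and the
acceptance script exercise the same code paths on smaller planes
(10 cm fields, 15×15 diode grids) and a five-point density sweep, with
100 replicate studies for the noise-robustness checks — sizes chosen to
keep the whole validation suite comfortably interactive while leaving
every algorithmic branch covered.

## Known limitations

* The surrogate is a central-axis transmission model; it does not model
  the TPS's superposition/convolution engine, scatter kernels, or
  off-axis spectra.
* No uncertainty quantification on the commissioned parameters; the
  procedure reports grid argmins and means, as the manual workflow does.
* 2D gamma only, on planes; no absolute-dose calibration, angular
  response or array-specific corrections.
* The sequential sweep is not a global optimizer; with strongly
  confounded parameters it inherits the ridge behaviour discussed above.
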