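---
title: "Ice-curve thermodynamics: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ice-curve thermodynamics: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocurve)
```

## The physical problem

Frozen desserts are two-phase systems: ice crystals embedded in an
unfrozen, solute-concentrated serum phase. How much ice exists at a
given temperature — the *ice curve* — controls hardness, melting
behaviour and sensory quality, and is set by the anti-freeze agents
(sugars, polyols, alcohols, salts) in the formulation. `cryocurve`
implements a deliberately simple equilibrium description of that curve
and the estimators needed to fit it to calorimetric data.

## Model and assumptions

Three ingredients:

1. **Colligative freezing-point depression.** For a dilute ideal
   solution, `freezing_point()` evaluates
   $\Delta T_f = K_k\, i\, \frac{m_s/M_s}{m_w[\mathrm{kg}]}$ with
   $K_k = 1.86$ K kg mol$^{-1}$. The ideality assumption is the model's
   main simplification: concentrated or strongly dissociating solutes
   (NaCl, and to a lesser degree ethanol) deviate from it. We keep the
   ideal form because it needs no system-specific calibration and
   reproduces the measured freezing points of the bundled
   non-electrolyte model systems to the printed 0.01 degC.

2. **Equilibrium mole fraction of the serum phase.** Equating chemical
   potentials of ice and serum water yields
   $x_s(T) = 1 - e^{\,a - b/T}$ with $b = \Delta H_{fus}/R = 722.8$ K
   and $a = b/T_{water}$. The serum must hold exactly this solute mole
   fraction; any surplus water freezes.

3. **Bound water.** Each solute binds an *effective hydration number*
   $h$ of water molecules (mol water / mol solute) that cannot freeze.
   $h$ is *effective*: fitted from ice-content data, it absorbs
   non-ideal concentration effects (solute clustering, altered hydrogen
   bonding), which is why it varies with both temperature and
   concentration rather than being a molecular constant.

The ice content per `basis_mass` grams of sample is then

$$\%ice = \frac{100\,MW_w}{basis}\left[n_w - \Big(\frac{1}{x_s} - 1\Big) n_s - n_s h\right]$$

implemented in `ice_content()`, with the closed-form inversion for $h$
in `hydration_number()` and the zero-ice root (the melting point) in
`melting_point()`.

**What the model ignores:** activity coefficients and multi-solute
interaction terms, glass transitions and state diagrams, ice-crystal
size and network morphology, and kinetics — it is an equilibrium
screening tool, not a process model.

## Conventions the equations force

* **Ice-content basis.** All percentages are relative to the **total
  sample mass**, not the water mass. The prefactor
  $100/(m_w + m_s)$ and the exact round trip from premix
  concentrations through measured ice contents to serum-phase
  concentrations (e.g. 11.5 % glucose at 73 % ice gives
  $11.5/(100-73) = 43\%$) are only consistent on that basis.
* **Temperature.** All interfaces take degrees Celsius; the exponential
  law is evaluated in Kelvin internally.
* **The constant $a$.** Computed as $b/T_{water} = 2.64617$ rather than
  the commonly printed rounding 2.646. `thermo_constants(use_printed_a
  = TRUE)` reproduces calculations done with the rounded value; the
  difference in $x_s$ is below 0.02 %. With the computed $a$, pure
  water's equilibrium limit falls exactly at 0 degC, which keeps the
  melting-point bracket clean.
* **Clamping vs. raw algebra.** The forward model clamps negative ice
  to 0 and flags the point `valid = FALSE` (temperature above the
  melting point, or all water bound). The inversion and the
  melting-point root-finder use the *raw* unclamped expression, so the
  algebra stays exact: inverting a forward value reproduces $h$ to
  machine precision (the suite checks $10^{-9}$ over 1,000 random
  compositions). Negative fitted $h$ is reported with a warning and a
  `"negative_h"` flag — never silently clamped, because clamping would
  bias a fitted surface. Inversions within $10^{-9}$ of zero are
  treated as round-off, not inconsistency.
* **Mixtures.** The single-solute expression extends additively: total
  solute moles in the colligative term, $\sum n_s h_s$ for bound water.
  Single-solute calls evaluate the literal one-solute formula.
* **NaCl.** The registry carries the ideal $i = 2$. Measured freezing
  points of NaCl solutions are distinctly non-ideal (about 20 % shallower);
  `fit_dissociation_degree()` provides a least-squares effective-$i$
  calibration (the four bundled observations give $i \approx 1.57$),
  but the package never substitutes the fitted value silently — the
  choice is the user's.
* **Ethanol's molecular weight.** The bundled registry uses
  46.5 g/mol. Pure ethanol is 46.07 g/mol, but 46.5 is the value under
  which the bundled model-system freezing points reproduce exactly
  (denatured food-grade ethanol is slightly heavier); the discrepancy
  is documented rather than resolved.
* **Rounding for table reproduction.** Freezing points compare at two
  decimals; serum concentrations at the nearest integer, half-up.

## Numerical choices

* `melting_point()` brackets the zero-ice root on $[-40, 0]$ degC and
  solves to $10^{-6}$ degC with a derivative-free bracketed search —
  robust and deterministic; no derivatives of the exponential law are
  needed. An error (rather than `NA`) is raised when no sign change
  exists, e.g. when all water is bound.
* DSC endotherm integration (`integrate_endotherm()`) uses a
  trapezoidal rule over time against a straight baseline joining the
  window endpoints. Sigmoidal baselines and overlapping
  solute-crystallisation peaks (the known failure mode for NaCl traces)
  are out of scope; a baseline crossing the signal more than twice
  (ignoring sub-5 %-of-peak noise) triggers a warning. Integration
  limits are a user input: published work rarely states them, so no
  default window is imposed.
* The fitted hydration table defaults to **mean-then-invert** replicate
  handling (average the replicate ice contents, invert once), matching
  the convention that reported hydration numbers are computed from
  averaged measurements. **invert-then-mean** is selectable; the modes
  agree exactly on noiseless data and differ only through noise.
* Interpolation of fitted surfaces defaults to **nearest** — reported
  hydration tables are discrete cells and smoother policies
  (`linear-in-T`, `bilinear`) are opt-in. Lookups outside the fitted
  hull error unless extrapolation is explicitly enabled; flagged cells
  never feed interpolation.

## Melting-test estimators

The five melting parameters are defined on the cumulative drip-mass and
core-temperature series logged every 10 s:

* **Lag time** — time of the first droplet. A balance only registers a
  drop once the threshold mass (default 0.5 g) has dripped, which
  happens a delay of $threshold/slope$ after melt onset; at 1 %/min on
  a 300 g sample that delay is a full logging interval. The estimator
  therefore takes the linearly interpolated threshold-crossing time and
  subtracts that delay using the fitted fast-phase slope, which debiases
  the estimate at slow drip rates.
* **Total melting time** — interpolated time at which the drip mass
  reaches $1-\varepsilon$ of its final value ($\varepsilon$ = 0.5 %;
  the "last droplet" is not machine-detectable otherwise).
* **Melting rate** — ordinary least squares of drip mass (% of initial
  mass) against time over the samples between 20 % and 80 % of the
  final dripped mass. The "fast melting phase" has no standard bounds;
  a central band is the conventional, configurable choice. Units are
  % of initial mass per minute, the scale on which reported rates
  (about 1–1.75 %/min) are quoted.
* **Onset temperature** — core temperature interpolated at the observed
  threshold-crossing time: that is when the first drop physically
  falls, and by then the core sits on the melting plateau, so the
  reading avoids the steep pre-plateau ramp.
* **Temperature-rise rate** — (temperature at the total melting time
  minus at $t=0$) divided by the total melting time.

Hardness is the stress of the *first* force peak during probe
penetration — force at the first local maximum of the 3-point-smoothed
force divided by the probe-tip area (N/mm$^2$ = MPa; 4 mm probe by
default). A monotone trace falls back to the global maximum with a
warning.

## What the synthetic generators emulate — and what they do not

The study conditions this package targets have no deposited raw data,
so every pipeline stage is validated against seeded generators:

* `generate_ice_dataset()` draws ice contents from the forward model
  under a ground-truth $h(c, T)$ surface plus Gaussian noise
  (default s.d. 1 % absolute, the magnitude of replicate standard
  deviations typically printed for such measurements; 3 replicates).
* `generate_melting_curve()` produces the lag / linear fast phase /
  plateau shape with a linear-to-plateau core-temperature profile,
  0.05 g balance noise and 0.05 degC thermocouple noise at a 10 s
  cadence. The default initial mass is 300 g so that the first 0.5 g
  drips within about one logging interval of the true lag at
  1–1.75 %/min rates — the regime in which the lag estimator's
  one-interval accuracy claim is meaningful.
* `generate_dsc_trace()` emits a 1 degC/min heating ramp carrying a
  Gaussian endotherm of analytic area $\%ice \cdot 334/100$ J/g on a
  (optionally drifting) linear baseline.

Gaussian noise everywhere is itself a modelling choice: published
tables report only $\pm$ s.d., so the error model is unconstrained.
The generators do **not** simulate instrument physics — thermal lag,
pan effects, solute crystallisation artifacts, non-linear melt fronts —
so passing recovery tests demonstrates the *estimators* are correct and
unbiased under the stated noise model, not that the model captures
every feature of real traces. Real DSC data with overlapping
crystallisation events (NaCl) remain unsupported.

Test and acceptance problem sizes — 1,000 random compositions for the
inversion grid, 100 melting curves spanning lag 5–20 min and rate
1–1.75 %/min, 18-cell hydration surfaces with 3 replicates — were
chosen to exercise the full parameter ranges of interest while keeping
the whole suite in the seconds range.

## Known limitations

* Ideal-solution colligative law: quantitative only for dilute
  non-electrolytes; NaCl requires the effective-$i$ bridge.
* The effective hydration number is a fitted, condition-specific
  quantity — values extracted here are not directly comparable to
  spectroscopic hydration numbers measured above 0 degC.
* No constraint is imposed on fitted $h(T)$ trends: non-monotonic
  temperature dependence (observed for glucose) is reported as-is.
* Whether replicate averaging happens before or after inversion is not
  standardised in the field; both modes are provided, and with noisy
  data they give slightly different surfaces.
* The CLI's configuration file is YAML (`--config`), with explicit
  flags taking precedence.
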