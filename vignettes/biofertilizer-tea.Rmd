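---
title: "Flowsheet and techno-economic model of a microalgal amino-acid biofertilizer plant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowsheet and techno-economic model of a microalgal amino-acid biofertilizer plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcatea)
```

## The process and its model

The plant converts microalgal sludge — the centrifuged by-product of a
wastewater-treatment plant operated with *Scenedesmus almeriensis* — into a
liquid biofertilizer whose value lies in free L-amino acids. Regulation
requires at least 6 % free amino acids in the product, and the flowsheet is
designed to meet that grade.

The model is a steady-state mass and energy balance over six stages, solved
in one topological pass because the flowsheet has no recycles. Each stream
is a temperature, a pressure and eleven component mass flows (kg/h). The
components and their roles:

* **water** — the continuous phase (80 % of the sludge);
* **protein, lipids, carbohydrates, ash** — the dry-biomass macromolecular
  fractions (defaults 49.5/17.5/26.0/7.0 % of dry matter);
* **enzymes, sucrose** — the solids of the liquid protease preparations
  (an endoprotease and an exoprotease dosed sequentially);
* **H₂SO₄, Ca(OH)₂, CaSO₄, amino acids** — the pH-control reagents and the
  two reaction products.

Three modelling commitments shape everything downstream:

1. **Constant-cp enthalpy.** Mixture enthalpy is `Σ mᵢ cpᵢ T`. The original
   design work delegated properties to a simulator's activity-coefficient
   models; here the cp set is explicit and config-overridable: water 4.18,
   protein and lipids 1.60, carbohydrates/sucrose/amino acids/enzymes 1.55,
   ash 0.84, the three inorganic salts 1.10 kJ kg⁻¹ K⁻¹. The organic values
   are Choi–Okos-type food-engineering estimates restricted to a 1.4–1.6
   band; with them the hydrolysis heat duty lands within 3 % of the
   reference balance (10,062 vs 10,336.5 kJ/h), which we accept as the
   price of a dependency-free, auditable enthalpy model. The hot-water loop
   carries its own cp of 4.372 kJ kg⁻¹ K⁻¹, back-calculated from the
   reference loop flow (118.20 kg/h over 85→65 °C); plain 4.18 would
   underpredict that flow by ~4 %.
2. **Mass-closed stoichiometry.** Protein converts to amino acids 1:1 by
   mass at the 55 % degree of hydrolysis (no net hydrolytic water uptake —
   the only reading consistent with the reference stream balance), and the
   dosed acid reacts completely, H₂SO₄ + Ca(OH)₂ → CaSO₄ + 2 H₂O, tracked
   as fixed mass ratios per kg of acid (74.09/98.08 lime consumed,
   136.14/98.08 gypsum, 36.03/98.08 water). Both reactions conserve total
   mass exactly, so the whole flowsheet closes its balance to numerical
   precision — a property the test suite asserts to 1e-9 relative on 100
   randomized configurations.
3. **Solubility-class centrifugation.** "35 % humidity in the solid" is
   interpreted as the entrained-mother-liquor mass fraction of the cake:
   the cake is the insoluble solids (all of them, at the default full
   recovery) plus liquor — water *and* dissolved solutes, at the liquor's
   own composition — solving `cake = S/(1 − 0.35)`. This is the only
   reading that reproduces the reference cake (21.36/61.05 = 0.350) and it
   routes enzymes with the solids, as that balance requires.

## Stage parameters

| Parameter | Default | Why |
|---|---|---|
| sludge feed | 260.42 kg/h, 7920 h/y | the 2062.5 t/y reference capacity |
| dry matter | 50.57/260.42 = 0.1942 | reference stream table verbatim; the nominal 20 % is one config edit away |
| homogenizer | 200 bar, η = 0.35 | η calibrated once so dissipated pumping work gives the ≈ 40 °C outlet |
| enzyme dose | 4 % v/w per preparation × 2, ρ 1.183 kg/L | reproduces the 4.79 kg/h preparation feed and the 37.91 t/y annual consumption |
| Ca(OH)₂ / H₂SO₄ | 0.79 / 0.19 % v/v on sludge; 70 % w/v, 98 wt%; ρ 1.396 / 1.8305 kg/L | densities back-calculated so the reagent streams match the reference balance |
| hydrolysis | 50 °C, conversion 0.55 | batch end-point of the 3 h, two-protease protocol |
| exchanger | 85/65 °C hot loop, 10 °C minimum approach | countercurrent duty only; no area rating |
| centrifuge | cake liquid fraction 0.35, solids recovery 1.0 | see above |
| solar field | 20 % loss margin, 8 h/day collection, ΔT 10 °C, 350.22 kJ h⁻¹ m⁻² °C⁻¹, 1.9 m²/collector | daily-energy sizing rule; `ceil(area/1.9)` plus one installed spare (5.6 → 6 + 1 = 7). The spare policy is ours: the reference installation reports seven units against a 5.6-unit requirement and the extra unit is read as a spare, configurable to zero |
| storage tanks | 1 day sludge, 30 days product/reagents, 1.33 oversize | volume = flow·24·days/ρ with a 75 % working-volume rule |

## Economics

CAPEX is data, not correlation: the seventeen-item equipment list and the
eight investment line items are packaged as reference tables
(`ref_equipment_costs()`, `ref_capex_breakdown()`), because the commercial
estimator behind them is proprietary. The per-item equipment cells sum to
1,085,950 EUR while the carried equipment total is 1,088,448.80 EUR; both
numbers are kept and the 2,498.80 EUR rounding gap is asserted in tests.
`scale_equipment_cost()` provides the usual 0.6-power law for what-if
scales.

OPEX is built from computed bases where the data allow and calibrated
factors where they do not:

* raw materials = consumptions × prices (sludge 0.5 EUR/kg, enzyme
  preparation 20 EUR/kg, Ca(OH)₂ 65 EUR/t, H₂SO₄ 73 EUR/t) — fully
  computed, 1.79 MEUR/y in the base case;
* utilities = 112 kW installed power × hours × 0.12 EUR/kWh + water at
  1 EUR/m³ + a 0.19 MEUR residual. The published utilities line is not
  decomposed anywhere, so the residual is an explicit calibration constant,
  not a model;
* labor = staffed hours × rates (23.41 / 26.45 EUR/h); the default staffing
  (three operator positions around the 7920 h year plus 920 h supervision)
  is likewise calibrated to the published labor line;
* maintenance (0.622 % of CAPEX), operating supplies (25.86 % of labor),
  contingencies (11.11 % of direct cash cost) and administration (40.63 %
  of labor + maintenance) — factor defaults backed out of the published
  cost structure once, then frozen;
* straight-line depreciation at 0.77 MEUR/y as published — deliberately
  *not* CAPEX/life = 0.965 MEUR/y, which contradicts the published line;
  the field is config and the discrepancy is left visible.

The cash flow is the simplest defensible convention: full investment at
t = 0, equal end-of-year flows `(R − OPEX_cash − D)(1 − t) + D`, negative
pre-tax income taxed at zero (no carry-forward), no working capital,
salvage or escalation. All of these are deliberate simplifications: the
published indicators (NPV 9.17 MEUR, IRR 18.31 %, PP 6.51 y) come from a
proprietary cash-flow engine whose conventions cannot be recovered — with
the published revenue, OPEX and CAPEX, *any* plain DCF yields ≈ 5.2 MEUR
and ≈ 15 %. The package therefore validates its DCF by its defining
properties (NPV(IRR) = 0 within 1 EUR; strict monotonicity in each price;
currency-scale invariance of IRR; discounted ≥ simple payback) rather than
by equality with those three numbers, and reports PI = NPV/CAPEX, which
does reproduce the published 0.95 when fed the published NPV/investment
pair.

IRR uses bisection refinement (`uniroot`, tol 1e-10 on the rate) on the
bracket [−0.99, 10] and is `NA` without a sign change. In scenario tables,
IRR and payback are additionally blanked whenever NPV < 0: an investment
that is never recovered has no payback, and a negative internal rate is
not a meaningful return — the convention the reference study uses for its
three loss-making scenarios.

## Sensitivity analysis

`bb_design()` hard-codes the 13-run Box–Behnken layout (12 edge runs + 1
center) in the published run order, with factors A (sludge cost), B (enzyme
cost), C (sale price) at 0.2/0.6/1.0, 10/17.5/25 and 2.5/5.0/7.5 EUR/kg.
Coding is the standard `x = (value − center)/half-range`, stated explicitly
because the source omits it. The coded columns are orthogonal with zero
sums, so the linear OLS coefficients equal the contrasts
`(Σ Y₊ − Σ Y₋)/8` — the test suite checks the identity numerically, and
the fit to the published NPV column yields a₁ = −6.0225, a₂ = −2.0500,
a₃ = +28.0275 MEUR with R² > 0.999: the sale price outweighs the sludge
cost ~4.7× and the enzyme cost ~13.7×.

Scenarios with undefined IRR/payback are dropped pairwise from the IRR and
payback fits (the source's handling of its blanks is unstated; dropped
counts are reported in the fit object). No hierarchical term pruning is
applied by default — the full 10-term model is fitted and the source's
smooth surfaces are consistent with either choice.

## The scenario generator

`scenario_sampler()`/`sample_configs()` draw randomized configurations so
every pipeline stage is property-testable without external data: dry-biomass
composition uniform on the simplex with protein constrained to [0.3, 0.6]
(the plausible band for protein-rich microalgae), dry matter U[0.15, 0.25],
conversion U[0.3, 0.8], feed scale ±50 % of base, and the three prices
uniform on the sensitivity ranges. Sampling is uniform because only ranges
are known; the simplex draw uses the ordered-uniform-gaps construction.
Draws are deterministic given the seed (the previous RNG state is
restored).

What the generator does *not* emulate: correlated compositions (real
harvests co-vary protein and ash), seasonality of feed rate and solar
yield, measurement noise, or off-spec excursions of the hydrolysis
end-point. Passing property tests therefore demonstrate internal
consistency of the balances and economics over the stated ranges — not
calibration to any real plant's variability.

## Numerical choices and degenerate inputs

* Balance tolerances: mixing and reactions are exact arithmetic; closure
  asserted to 1e-9 relative.
* A tiny negative lime residue from floating-point subtraction in the
  reactor is clamped to zero; an actual stoichiometric deficit (beyond
  1e-9 kg/h) raises an error naming the shortfall.
* Zero-flow streams: mixing with one is the identity; mass fractions on
  one raise an error rather than returning 0/0.
* Zero duty sizes a zero-area field with only the installed spare.
* Centrifuging a solids-free feed returns the feed as centrate and an
  empty cake; insufficient liquor for the requested cake humidity errors.
* Approach-temperature violations in the exchanger error rather than warn.

## Problem sizes

The full pipeline — flowsheet, TEA, 13 scenarios and the RSM fit — runs in
well under a second; the test suite's heaviest blocks are the two
100-configuration closure sweeps, chosen to give the conservation
properties real coverage while keeping the suite in seconds.

## Known limitations

* No hydrolysis kinetics: the 3 h batch is represented only by its 55 %
  end-point; pH dynamics and the two-enzyme sequencing are out of scope.
* No vapor–liquid equilibrium, activity models or ionic speciation; heat
  duties inherit the few-percent bias of the constant-cp model.
* The exchanger is duty-only (no area rating), and equipment costs are
  packaged data, so costing new flowsheet structures requires new cost
  inputs, not just new balances.
* Absolute NPV/IRR/payback are convention-dependent; use them
  comparatively (across scenarios) rather than as bankable point
  estimates.
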