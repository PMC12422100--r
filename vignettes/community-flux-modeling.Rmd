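---
title: "Stoichiometric flux and cross-feeding analysis of synthetic anaerobic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric flux and cross-feeding analysis of synthetic anaerobic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntroflux)
```

## The system and the model

`syntroflux` analyzes defined anaerobic co-cultures in which a cellulolytic
fermenter (*Ruminiclostridium cellulolyticum*, Rc) converts
glucose-equivalents from cellulose into lactate, acetate, ethanol, H~2~ and
CO~2~, and up to three partners consume those intermediates: the
acetoclastic methanogen *Methanosaeta concilii* (Mc), the hydrogenotrophic
methanogen *Methanospirillum hungatei* (Mh), and the sulfate-reducing
bacterium *Desulfovibrio vulgaris* (Dv), which in the absence of sulfate
acts as a syntrophic lactate oxidizer. Eight assemblies are supported by
default: the Rc mono-culture, three bi-cultures, three tri-cultures and the
quad-culture.

Community metabolism is summarized by six species-attributed overall
reactions (per mol glucose-equivalent for Rc):

| reaction | species | stoichiometry | ATP | ΔG°′ (kJ/mol) |
|---|---|---|---|---|
| lactate fermentation | Rc | glucose → 2 lactate | 2 | −198 |
| hydrogenic acetogenesis | Rc | glucose → 2 acetate + 2 CO~2~ + 4 H~2~ | 4 | −206 |
| mixed-acid fermentation | Rc | glucose → ethanol + acetate + 2 CO~2~ + 2 H~2~ | 3 | −220 |
| hydrogenic lactate oxidation | Dv | lactate → acetate + CO~2~ + 2 H~2~ | 1 | −4.2 |
| hydrogenotrophic methanogenesis | Mh | 4 H~2~ + CO~2~ → CH~4~ | 0.5 | −131 |
| acetoclastic methanogenesis | Mc | acetate → CH~4~ + CO~2~ | 0.25 | −36 |

Water and protons are implicit (the pH-7 transformed-energy convention
absorbs them), so every reaction must balance carbon and degree-of-reduction
electrons (γ = 4C + H − 2O) exactly over the explicit CHO species — an
invariant the catalogue loader enforces. Cellulose enters as
glucose-equivalent (anhydroglucose, 162 g/mol); hydrolysis is a substrate
supply, not a fitted reaction. ATP yields follow standard anaerobic
bioenergetics (4 ATP when all glycolytic reducing equivalents leave as H~2~,
2 for homolactic fermentation, 3 for the mixed-acid route, 1 for lactate
oxidation via substrate-level phosphorylation, fractional yields for the
methanogens' chemiosmotic ATP). ΔG°′ values are standard-literature numbers
at pH 7 and 25 °C. All of this lives in a YAML config
(`default_catalogue_path()`) and can be replaced wholesale; biomass can be
coupled as an explicit product at `Y_ATP × atp_yield` (default
10.5 g/mol ATP) with `add_biomass()`.

## Fed-batch bookkeeping

Cultures run 7 days in 160 ml bottles with 20 ml liquid. Each day 2 ml of
liquid is sampled and replaced with analyte-free medium and 5 ml of
headspace gas is withdrawn. Net cumulative production therefore has to
credit back everything previously removed:

$$\mathrm{cum}_d = V C_d + \sum_{k<d} v\,C_k - V C_0,$$

with the analogous ideal-gas form ($n = PV/RT$) for headspace gases.
Gas bookkeeping uses the incubation temperature (307.15 K); thermodynamics
uses 298.15 K, matching the reference state of the ΔG°′ values. Whether
sampled gas should be credited back is not observable from the data itself;
we credit it, symmetrically with the liquid handling. Replicates are kept
separate through fitting and summarized as mean ± SD.

## Extent fitting

Writing $S$ for the stoichiometric matrix over the measured products
(lactate, acetate, ethanol, H~2~, CO~2~, CH~4~) and $y$ for a replicate's
cumulative production, extents are estimated by

$$\hat\xi = \arg\min_{\xi \ge 0} \lVert W(S\xi - y)\rVert^2
  + \lambda \lVert \xi - a \rVert^2,$$

solved with the deterministic Lawson–Hanson active-set algorithm
(`pracma::lsqnonneg`); ties in degenerate fits are resolved by its active-set
order, which is stable across runs. $W$ weights each analyte by the inverse
of its observed range so that the large-mmol gases do not dominate the small
fermentation products; the same scaling defines the fit metrics, with
$R^2$ and NRMSE pooled over range-normalized observations. The default fit
target is the day-7 cumulative vector (`mode = "endpoint"`), because the
quantity of interest is the run-total extent; when endpoint extents are
compared with the daily series for reporting $R^2$, they are assumed to
accrue uniformly over the run, which matches the generator and is a
reasonable description of a daily-fed culture. `mode = "trajectory"` instead
stacks days 1–7 with nonnegative per-day extents.

### Structural unidentifiability and the proteomics prior

Over the measured product set, the lactate-oxidation column satisfies

$$\text{lactate oxidation} = \tfrac12(\text{hydrogenic acetogenesis}
  - \text{lactate fermentation}),$$

because fermenting glucose to lactate and then oxidizing that lactate is
chemically identical to direct hydrogenic acetogenesis. The ATP yields
(2, 4, 1) obey the same relation, so a biomass row cannot break the
collinearity, and neither can adding glucose consumption as an observation.
Any assembly containing both Rc and Dv is therefore rank-deficient: the
data constrain only the sum of the fermentation routes, not the split. The
fit flags this (`rank_deficient`) rather than failing, and the remedy is
exactly why proteomics enters the model: marker-protein abundances give a
prior activity per reaction, and a small ridge ($\lambda > 0$) selects the
solution nearest that prior within the optimal set. The methanogenesis
extents lie outside the null space and are unaffected by the choice.

`proteomics_prior()` averages marker abundances per reaction, optionally
scales by ATP yield, and rescales the priors to a configurable total. The
direction of the ATP scaling is genuinely ambiguous — whether abundance
times or divided by ATP yield best proxies turnover depends on how the
abundances were produced — so `atp_scaling` exposes `"multiply"` (default),
`"divide"` and `"none"`. For data from the package's own generator the
correct pairing is `"none"`, because the generator makes marker abundance
directly proportional to extent. A real limitation survives either way:
per-species proteome normalization (each species' proteins summing to 1)
destroys cross-species abundance comparability, so priors can be biased
along the null space even when within-species ratios are exact. In
practice this means lactate-route splits recovered through the prior are
semi-quantitative; we report them as such and keep all hard conclusions on
the identifiable combinations.

## Exchange networks

From fitted extents, each species' net production and net intake of every
metabolite is computed (a species consuming its own product is netted out
first, so edges are strictly interspecies), and each receiver's intake is
allocated to donors in proportion to their production shares. Two edge
conventions exist because the literature is not consistent about units:
`"consumer_extent"` (default) reports the receiving reaction's extent
attributed to the donor — in a bi-culture with a single −1-coefficient
consumer both conventions coincide with that reaction's extent — and
`"metabolite_total"` reports summed mmol of the transferred metabolites.
`compare_exchanges()` contrasts two networks edge by edge and flags edges
present in only one of them as `"emergent"` or `"lost"`.

## Thermodynamics

For each reaction, $Q = \prod a_i^{\nu_i}$ with aqueous activities in
mol/L, gas activities in atm, and unit activity for solids and biomass;
$\Delta G' = \Delta G°' + RT \ln Q$ with $R = 8.314$ J/mol·K and
$T = 298.15$ K. No Henry's-law conversion or ionic-strength correction is
applied; gases always enter as partial pressures. A ten-fold activity shift
of a single ±1 participant moves $\Delta G'$ by exactly
$RT\ln 10 = 5.708$ kJ/mol, and lowering pH~2~ from 1 to $10^{-4}$ atm
raises the hydrogenotrophic-methanogenesis $\Delta G'$ by
$4RT\ln 10^4 = 91.3$ kJ/mol — the quantitative heart of interspecies
hydrogen transfer. In the pipeline, analytes measured as zero on the final
day are floored at a detection-limit activity of $10^{-6}$ (mol/L or atm)
so quotients stay finite; `delta_g_prime()` itself is strict and rejects
non-positive quotients.

## Element accounting

Carbon and electron ledgers multiply final cumulative amounts by the
catalogue carbon count and degree of reduction. Because the catalogue is
exactly balanced, any fitted solution conserves carbon and electrons from
glucose-equivalents to products, and the CH~4~ electron ledger is always
exactly 8× its carbon ledger.

## The synthetic-data generator

`simulate_culture()` inverts the fed-batch bookkeeping: per-day increments
$S\,\xi_d$ (extents spread uniformly over 7 days) update in-vessel amounts,
readings are taken as concentrations/pressures with multiplicative Gaussian
noise (default CV 5%, truncated at zero — the study design uses technical
duplicates but states no error model, so the CV is a configurable choice),
and daily sampling removes proportional shares. The headspace starts with
3% H~2~. Default per-assembly extent presets mirror the study regimes
(mono-culture glucose-equivalent consumption ≈ 1.14 mmol ≈ 184 mg
cellulose; Rc&Mc acetoclastic extent 0.32 mmol; Rc&Dv lactate oxidation
0.18 mmol; Rc&Mh hydrogenotrophic methanogenesis 0.42 mmol; mixed-acid
fermentation absent when Mh and Dv co-occur; quad-culture routing
≈ 1.36 mmol carbon to CH~4~), chosen once subject to every daily in-vessel
amount staying nonnegative — which caps the quad hydrogenotrophic extent at
0.55 mmol given its H~2~ supply. `simulate_proteins()` emits marker
abundances proportional to extents plus uncorrelated background proteins,
normalized per species. All randomness flows from the single config seed.

What the generator does *not* emulate: growth kinetics (extents are
uniform in time), thermodynamic feedback of product accumulation on rates,
pH drift, sulfate treatments, and cross-species normalization artifacts of
real TMT proteomics beyond the per-species sum-to-one convention. Passing
round-trip tests therefore demonstrates correctness of the bookkeeping,
solver and inference machinery — not that real cultures satisfy the
six-reaction model.

## Numerical choices and problem sizes

Default tolerances and sizes used by the test-suite checks: noise-free
round trips must recover extents to ≤ 10⁻⁶ relative error on
full-column-rank assemblies; at 5% CV the median relative error over 100
seeded single-replicate trials stays below 10%; solver results are compared
against an exhaustive/refined grid-search oracle at 10⁻³ extent resolution
on 20 random targets per small assembly (objective comparison where the
stoichiometry is rank-deficient, since extents are then non-unique);
zero-range analytes are floored at 1% of the largest analyte range before
weighting. Bootstrap uncertainty resamples replicates with replacement
(deterministic per seed). These sizes keep the whole suite desk-scale
(well under a minute for the core checks).

## Known limitations

* The fermentation-route split in Rc+Dv assemblies is identified only
  through the proteomics prior, with the normalization caveat above.
* Exchange-edge magnitudes depend on the convention; where multiple donors
  supply a metabolite the proportional-share allocation is an assumption,
  not an observation.
* ΔG′ uses concentrations as activities; ionic strength, pH excursions and
  dissolved-gas supersaturation are ignored.
* Endpoint fitting assumes time-uniform extent accrual when scored against
  daily series; strongly lag-phased cultures should use trajectory mode.
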