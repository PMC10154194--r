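---
title: "Circular food-system optimization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular food-system optimization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circfood)
```

# The problem

A food system that recycles its residual streams — crop by-products, food
waste, manure and human excreta — as animal feed or fertilizer can feed a
population from far less land than one that discards them. `circfood`
formalizes this as a linear program over a *food-system instance*: a
parameterization of climate-soil zones with land areas, crops with
zone-specific yields and rotation limits, livestock and aquaculture systems
with full-lifecycle feed requirements, capture fisheries capped at maximum
sustainable yield (MSY), residual-stream conversion parameters, and a
population with its dietary requirements. The solver chooses cultivated
areas, grassland use, herd sizes, feed rations, trade flows, and fertilizer
applications that minimize agricultural land (or maximize the population
fed) subject to the biophysical couplings between those choices, then
computes a tier-1/tier-2 greenhouse-gas inventory for the solution.

# The optimization model

## Decision variables

All variables are continuous and nonnegative, in fixed units: areas in ha,
biomass in t fresh matter (grass in t dry matter), fertilizer in kg of
nutrient, diets in g per capita per day.

* `area[crop, zone]` — cultivated area per suitable crop-zone pair;
* `gha[zone]` — grassland in use;
* `units[system, country]` — producing units; one unit is the herd slice
  (producing animal plus its share of parent and reproduction stock) that
  delivers one tonne of primary product per year;
* `flow[food, origin, destination]` — consumer-level food supply produced
  in one country and eaten in another (processing happens in the country
  of production);
* `fishland[country]` — capture-fishery landings;
* `x[feed, system, country]` — feed allocations; variables exist only for
  (feed, species) pairs that are legal, so feed legality and the ruminant
  food-waste ban are structural, not penalized;
* `ff[feed, origin, destination]` — trade in tradeable feeds (grass and
  food waste are not tradeable and can only be used where they arise);
* `bcomp[feed, country]` — by-products diverted to composting;
* `orgn[source, zone]` and `artn/artp[zone]` — organic and artificial
  fertilizer applications; every organic source delivers N and P in a
  fixed N:P ratio;
* `mu` — a population multiplier, present only under the
  population-maximizing objective (all per-capita constraints scale with
  it, which keeps the program linear).

## Constraint families

1. **Land and rotation.** Total area per zone is capped by its cropland;
   each crop is additionally capped at `cropland / k` for a 1-in-`k`
   rotation, and flagged minor crops (e.g. rice) cannot exceed their
   current acreage. Grassland use is capped by the zone's grassland area.
2. **Production balances.** Flows out of a country cannot exceed what its
   areas, herds and landings produce after technical conversion (milling
   fractions) and the pre-consumer waste stages.
3. **Feed balances.** Feed availability per country is an expression in
   the other variables: fodder harvests, grass growth on used grassland,
   crop by-products proportional to the food actually supplied, slaughter
   by-products proportional to herd output, fish by-products proportional
   to landings, and 35% of consumption waste. Allocations plus composting
   diversions cannot exceed availability.
4. **Herd requirements.** Per system and country the ration must deliver
   the gross-energy and digestible-protein requirement of the full stock
   and fit within its dry-matter intake capacity. Fish systems are priced
   with fish-specific feed values.
5. **Fertilizer balances.** Crop N and P requirements (removal in harvest
   plus aboveground residues, inflated by loss fractions) must be met per
   zone from manure (intake minus retention, minus the grazing share and
   storage volatilization), compost (waste and by-product N less gaseous
   losses), sewage sludge (population-proportional) and, where allowed,
   artificial fertilizer.
6. **Diets.** Depending on the scenario: nutrient reference bounds over
   the 42 tracked nutrients and food-group intake bounds (with the grains
   bound expressed as a maximum share of energy intake), or a minimum of
   the current protein supply per country and food group.
7. **Fisheries.** Landings per country are capped by MSY quota shares.
8. **Transport.** Cross-border flows are charged with ton-kilometre
   emissions and capped at 1,500 kg CO2e per fed capita per year per
   country; this is the only emission term inside the LP.

Emissions are otherwise computed *after* solving, never optimized.

## Scenarios

Four canonical configurations mirror increasing circularity ambition:

| scenario   | diet constraint                    | objective        | recycling |
|------------|------------------------------------|------------------|-----------|
| AgriBase   | match current supply (calibration) | min. deviation   | by-products only |
| CirAgri    | current protein per food group     | min. land        | full      |
| CirHealth  | nutrient + food-group bounds       | min. land        | full      |
| CirPop+    | nutrient + food-group bounds       | max. population  | full      |

AgriBase fixes areas and grassland to the current baseline and minimizes
the summed relative deviation of per-food-group protein supply from the
current supply; the relative-deviation form makes food groups of very
different size commensurable in one objective. Artificial
fertilizer is available in every scenario, complementary to organic
sources.

# Greenhouse-gas accounting

Computed per solution with the standard inventory formulas: enteric CH4 as
gross energy × Ym / 55.65 (ruminants); manure-management CH4 as volatile
solids × MCF × B0 × 0.67; N2O from managed manure, grazing deposition,
fertilized soils (type- and climate-specific direct factors plus
volatilization and leaching pathways) and drained organic soils (area
based); aquaculture N2O as 1.8% of unconsumed-plus-excreted N; composting
N2O from waste N and CH4 from compost carbon obtained through a C:N ratio
of 15; CO2 from artificial-fertilizer production and from transport.
Totals use 100-year GWPs of 28 (biogenic CH4) and 265 (N2O). CH4 from rice
and CO2 from soils and cropping are excluded by design. Default emission
factors that the inventory literature parameterizes but the headline
method does not pin down (soil EF1 = 0.01; organic amendments 0.006 wet /
0.005 dry; volatilization fractions 0.10 synthetic / 0.21 organic;
leaching 0.24 in wet climates; compost N2O 0.01 kg N2O-N per kg N; 2.5% of
compost C as CH4) are instance data, visible and overridable in
`emission_constants`.

# The synthetic-instance generator

No real national crop statistics, supply data or food-composition tables
ship with the package; `generate_instance()` emulates their structure:

* **Zones and land.** Zones are distributed round-robin over countries;
  cropland (0.30 ha/capita) and grassland (0.22 ha/capita) scale with the
  drawn populations, so instance size and population are consistent.
* **Yield heterogeneity.** Zone yields are crop means times lognormal
  multipliers (σ = 0.3 on the log scale), strictly positive and
  right-skewed like real yield data; each crop is unsuitable in a random
  ~15% of zones but always cultivable somewhere.
* **Crops and animals.** Fourteen crop templates cover every plant food
  group plus two fodder crops; seven animal-system templates span dairy
  and beef (ruminants, with grazing shares, Ym and enteric emissions),
  pigs, poultry and aquaculture. Requirement magnitudes are set so that
  realistic feeds can satisfy them within intake capacity (e.g. dairy
  digestible-protein demand ≈ 55 g per kg dry-matter intake).
* **Animal-source-only nutrients.** Vitamin B12 is zero in every plant
  food and positive in every animal food, so healthy-diet scenarios
  cannot eliminate animal-source food entirely.
* **Self-consistent reference bounds.** Nutrient minima and maxima are
  anchored to the nutrient content of a reference diet priced with the
  instance's own (jittered) compositions, which makes the healthy-diet
  constraint set feasible by construction rather than by luck.
* **Self-consistent baseline.** The "current" situation is not drawn but
  *derived*: fixed cropland shares (within rotation caps) are allocated
  through the processing chain; feed pools are assigned to systems and
  the supportable herd per system is computed honestly with a small LP
  (feed may be discarded, intake capacity binds); the resulting supply
  becomes the current protein supply per food group. AgriBase therefore
  calibrates to within a fraction of a percent, and CirAgri's
  protein-matching constraints are feasible because the baseline
  allocation is itself a feasible point.

What the generator does **not** emulate: real spatial correlation between
climate, soil and yields; seasonality; price or trade-policy structure;
the long tail of minor crops; and observed consumption patterns. Passing
tests on synthetic instances therefore demonstrate correctness of the
model mechanics and accounting identities, not agreement with continental
statistics — analyses at national scale require the corresponding real
input data.

`generate_known_optimum_instance()` builds a deliberately degenerate
instance whose optimum is forced by strict dominance (a single crop beats
the alternative in energy yield per hectare, the energy minimum is the
only binding constraint, and every waste fraction is zero), with the land
minimum computed in closed form during construction.
`generate_oracle_instance()` builds tiny plant-only instances on which
`brute_force_optimum()` — a grid search over per-capita diets with
greedy best-zone-first land filling, valid because per-crop rotation caps
are the only binding land constraints there — bounds the solver from
above.

# Numerical choices

* The LP solver is a dense two-phase primal simplex written for this
  package: row/column equilibration (coefficients in natural units span
  ten orders of magnitude), lexicographic ratio-test tie-breaking against
  cycling, periodic exact refactorization of the tableau from the
  pristine columns, and a final verification step that certifies the
  optimal basis with exactly recomputed reduced costs before the basic
  solution is re-solved from the original data. If verification fails,
  the solve is repeated with more frequent refactorization and then with
  Bland pricing. Everything is deterministic: fixed variable ordering and
  deterministic pivot selection make repeated solves bit-identical, which
  is also how reproducibility of degenerate alternative optima is
  achieved (no secondary objective is needed).
* Homogeneous `>=` rows are rewritten as `<=` rows so that phase 1
  carries artificial variables only for genuinely positive requirements.
* All dietary bounds are inclusive (closed half-spaces), matching LP
  feasibility; validators re-check solutions at a relative tolerance of
  1e-6 with a 1e-4 allowance on herd nutrient margins for solver
  roundoff; variable values below 1e-6 in natural units are treated as
  zero.
* The N fertilizer requirement uses a composite loss multiplier
  (synthetic-fertilizer volatilization plus climate leaching); the
  emission module keeps source-specific fractions. Residue nutrients stay
  on the field and do not offset the requirement; the requirement
  includes them, consistent with a long-term soil equilibrium.
* The grazing share of ruminant excretion is fixed per system (instance
  data) rather than optimized; it affects only how much manure reaches
  the exportable management-system pool and the emission split, and
  keeping it fixed keeps the fertilizer coupling linear.
* Food-waste N and P content for compost accounting is the feed-item
  constant rather than a diet-weighted value, again for linearity.
* Feed energy is carried on a single gross-energy scale for requirements
  and enteric emissions alike.
* Sewage sludge available as fertilizer does not scale with the
  population multiplier in the population-maximizing scenario: the
  additional population served is fed, not resident, so its excreta do
  not enter the system.
* Current protein supply is matched as a minimum (`>=`), not an equality:
  a redesign that over-delivers protein in some group still meets the
  current supply, and the minimum is the weaker, safer reading of
  "meeting" it; sensitivity to this choice can be probed by adding group
  maxima.

# Problem sizes and test design

The default synthetic instance (3 zones, 2 countries, 10 crops, 4 animal
systems) yields LPs of roughly 200 variables and 180 constraints that
solve in well under a second; the full test suite, including twenty
solver-versus-brute-force comparisons and all four scenarios with
validator sweeps, runs in well under a minute. These sizes were chosen so
that the brute-force oracle (about a million grid points per instance)
remains exact enough to certify the solver at the 1% level while the
whole verification loop stays interactive.

# Known limitations

* Productivity levels ship as a single (high) level per species in the
  generated instances; the schema carries the level field and nothing in
  the model restricts the number of systems per species.
* Grassland is one aggregated type per zone (temporary grassland,
  permanent pasture and rangeland areas are summed for the cap, with one
  grass yield), as the nutritional content of the grass types is assumed
  identical.
* The brute-force oracle covers plant-only, single-country instances;
  animal systems are verified through unit tests, validators,
  monotonicity and the known-optimum construction instead.
* Scenario emission totals on synthetic instances should be read as
  internally consistent accounting, not as predictions; their magnitudes
  depend on generator constants that no real dataset has calibrated.
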