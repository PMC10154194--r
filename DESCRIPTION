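Package: circfood
Title: Circular Food-System Optimization with Nutrient Cycling and
    Greenhouse-Gas Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and solves land-minimizing or population-maximizing
    linear-programming models of self-sufficient food systems organised
    around circularity principles: crop rotations and zone-specific yields,
    livestock and aquaculture with full-lifecycle feed requirements,
    capture fisheries capped at maximum sustainable yield, and recycling of
    crop by-products, food waste, manure and human excreta as feed or
    fertilizer. Diets are constrained by per-nutrient dietary reference
    values and food-group intake guidelines. A tier-1/tier-2 inventory of
    methane and nitrous-oxide emissions (enteric fermentation, manure
    management, soils, aquaculture, composting, fertilizer production and
    transport) is computed for every solution and aggregated to CO2
    equivalents. Includes a synthetic-instance generator with
    known-optimum constructions and a brute-force oracle for verifying the
    solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
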