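## Independent verification tools: a constructive instance whose land
## minimum is known in closed form, a generator of tiny plant-only
## instances, and a brute-force grid search over per-capita diets that
## bounds the land optimum without using the LP machinery.

.tiny_common <- function(n_zones, country_pop, cropland_each) {
  countries <- data.frame(country = "C01", population = country_pop,
                          x = 0, y = 0, sludge_fresh_t = country_pop * 0.017)
  zones <- data.frame(
    zone = sprintf("Z%02d", seq_len(n_zones)), country = "C01",
    cropland_ha = cropland_each, temp_grassland_ha = 0,
    permanent_pasture_ha = 0, rangeland_ha = 0,
    climate = rep(c("wet", "dry"), length.out = n_zones),
    soil = "mineral", grass_yield_t_dm_ha = 5,
    x = 0, y = 0, stringsAsFactors = FALSE)
  list(countries = countries, zones = zones)
}

.tiny_instance <- function(crops, yields, composition_rows, nutrient_bounds,
                           food_group_bounds, stage_fracs, country_pop,
                           cropland_each, n_zones, name) {
  base <- .tiny_common(n_zones, country_pop, cropland_each)
  foods <- data.frame(food = crops$crop, food_group = crops$food_group,
                      source = "crop", crop = crops$crop,
                      stringsAsFactors = FALSE)
  comp <- matrix(0, nrow(foods), length(nutrient_ids()),
                 dimnames = list(foods$food, nutrient_ids()))
  for (f in names(composition_rows)) comp[f, names(composition_rows[[f]])] <-
    composition_rows[[f]]
  comp[, "fresh_weight"] <- 1000
  composition <- data.frame(food = foods$food, comp, stringsAsFactors = FALSE)
  rownames(composition) <- NULL
  nutrients <- data.frame(nutrient = nutrient_ids(),
                          unit = unname(nutrient_units()),
                          min = NA_real_, max = NA_real_)
  for (n in names(nutrient_bounds)) {
    i <- match(n, nutrients$nutrient)
    nutrients$min[i] <- nutrient_bounds[[n]][1]
    nutrients$max[i] <- nutrient_bounds[[n]][2]
  }
  stage_waste <- data.frame(food = foods$food,
                            post_harvest = stage_fracs[1],
                            processing = stage_fracs[2],
                            distribution = stage_fracs[3],
                            consumption = stage_fracs[4])
  inst <- food_system_instance(
    name = name,
    nutrients = nutrients, countries = base$countries, zones = base$zones,
    crops = crops, yields = yields, foods = foods, composition = composition,
    animal_systems = .ANIMAL_TEMPLATES[0, ],
    feeds = .FEED_TEMPLATES[.FEED_TEMPLATES$feed == "food_waste", ],
    feed_legal = data.frame(feed = character(), species = character(),
                            allowed = logical()),
    fish_stocks = data.frame(stock = character(), msy_t = numeric(),
                             edible_frac = numeric()),
    fish_quota = data.frame(stock = character(), country = character(),
                            share = numeric()),
    food_group_bounds = food_group_bounds,
    stage_waste = stage_waste,
    residual_params = list(waste_to_feed_frac = 0.35, sludge_use_frac = 0.36,
                           sludge_n_frac = 0.075, sludge_p_frac = 0.012,
                           compost_cn = 15, compost_n_loss = 0.05,
                           organic_np = c(manure = 4, compost = 6,
                                          sludge = 6.25)),
    emission_constants = list(
      ch4_energy_mj_kg = 55.65, ch4_m3_to_kg = 0.67, gwp_ch4 = 28,
      gwp_n2o = 265, aquaculture_n2o_frac = 0.018,
      p_unavoidable_loss = 0.125, n_volat_frac_synthetic = 0.10,
      n_volat_frac_organic = 0.21, n_leach_frac_wet = 0.24,
      n_leach_frac_dry = 0, ef_soil_synthetic = 0.01,
      ef_soil_organic_wet = 0.006, ef_soil_organic_dry = 0.005,
      ef_volat_indirect = 0.010, ef_leach_indirect = 0.011,
      ef_grazing_n2o = 0.02, ef_organic_soil_n2o_ha = 8,
      ef_fert_prod_n = 5.5, ef_fert_prod_p = 2.0, ef_transport = 0.1,
      transport_cap_co2e = 1500, compost_ef_n2o = 0.01,
      compost_c_to_ch4 = 0.025),
    current = NULL)
  inst <- canonicalize_instance(inst)
  assert_valid_instance(inst)
  inst
}

#' Instance with an analytically known land-use optimum
#'
#' Constructs a one-country, one-zone, two-crop instance in which a single
#' crop strictly dominates the alternative in energy yield per hectare,
#' the only binding dietary constraint is the energy minimum, and every
#' waste fraction is zero. The land minimum is then available in closed
#' form: population x 365 x (energy minimum / energy density) / yield,
#' computed during construction.
#'
#' @param seed integer seed controlling the drawn parameters
#' @return list with `instance`, `expected_objective` (ha) and
#'   `expected_areas` (data.frame crop/zone/area_ha)
#' @export
generate_known_optimum_instance <- function(seed = 7) {
  set.seed(seed)
  pop <- round(stats::runif(1, 1e6, 5e6))
  y_a <- round(stats::runif(1, 5, 9), 3)
  y_b <- round(y_a * stats::runif(1, 0.3, 0.6), 3)
  e_a <- round(stats::runif(1, 3200, 3800))   # kcal/kg
  e_b <- round(e_a * stats::runif(1, 0.5, 0.8))
  e_min <- round(stats::runif(1, 1900, 2300))
  crops <- data.frame(
    crop = c("staple_a", "staple_b"), food_group = "grains", use = "food",
    rotation_years = 1, residue_ratio = c(1.0, 1.0),
    n_conc_product = c(18, 18), p_conc_product = c(3, 3),
    n_conc_residue = c(6, 6), p_conc_residue = c(1, 1),
    tcf_main = 1, tcf_byproduct = 0, byproduct_feed = NA_character_,
    acreage_capped = FALSE, stringsAsFactors = FALSE)
  yields <- data.frame(crop = c("staple_a", "staple_b"), zone = "Z01",
                       yield_t_ha = c(y_a, y_b))
  ## supply needed and land in closed form (zero waste, conversion 1):
  ## e_min [kcal/cap/day] / e_a [kcal/kg] = kg/cap/day
  supply_t <- pop * 365 * (e_min / e_a) / 1000
  area <- supply_t / y_a
  inst <- .tiny_instance(
    crops, yields,
    composition_rows = list(
      staple_a = c(energy = e_a, protein = 110),
      staple_b = c(energy = e_b, protein = 110)),
    nutrient_bounds = list(energy = c(e_min, NA)),
    food_group_bounds = data.frame(group = character(), min = numeric(),
                                   max = numeric(), unit = character()),
    stage_fracs = c(0, 0, 0, 0),
    ## enough cropland that either crop alone could carry the diet
    country_pop = pop, cropland_each = ceiling(area * 8), n_zones = 1,
    name = sprintf("known-optimum-seed%d", seed))
  list(instance = inst, expected_objective = area,
       expected_areas = data.frame(crop = "staple_a", zone = "Z01",
                                   area_ha = area))
}

#' Generate a tiny plant-only instance for oracle comparison
#'
#' One country, two zones, three food crops (a staple, a vegetable and a
#' legume) with randomized yields, rotation limits of at least three
#' years (so per-crop rotation caps are the only binding land caps),
#' randomized stage-waste fractions, an energy and a protein minimum, and
#' a vegetable intake band. Small enough for [brute_force_optimum()].
#'
#' @param seed integer seed
#' @return a valid `food_system_instance`
#' @export
generate_oracle_instance <- function(seed = 1) {
  set.seed(seed)
  pop <- round(stats::runif(1, 5e5, 2e6))
  crops <- data.frame(
    crop = c("staple", "veg", "legume"),
    food_group = c("grains", "vegetables", "legumes"), use = "food",
    rotation_years = sample(3:6, 3, replace = TRUE),
    residue_ratio = stats::runif(3, 0.1, 1.2),
    n_conc_product = stats::runif(3, 2, 30),
    p_conc_product = stats::runif(3, 0.3, 5),
    n_conc_residue = stats::runif(3, 1, 8),
    p_conc_residue = stats::runif(3, 0.2, 1.5),
    tcf_main = round(stats::runif(3, 0.7, 0.95), 3),
    tcf_byproduct = 0, byproduct_feed = NA_character_,
    acreage_capped = FALSE, stringsAsFactors = FALSE)
  yields <- expand.grid(crop = crops$crop, zone = c("Z01", "Z02"),
                        stringsAsFactors = FALSE)
  base_y <- c(staple = stats::runif(1, 4, 8), veg = stats::runif(1, 15, 30),
              legume = stats::runif(1, 2, 4))
  yields$yield_t_ha <- round(base_y[yields$crop] *
                               exp(stats::rnorm(nrow(yields), 0, 0.3)), 3)
  comp <- list(
    staple = c(energy = round(stats::runif(1, 3200, 3700)),
               protein = round(stats::runif(1, 90, 130))),
    veg = c(energy = round(stats::runif(1, 250, 400)),
            protein = round(stats::runif(1, 15, 30))),
    legume = c(energy = round(stats::runif(1, 3100, 3600)),
               protein = round(stats::runif(1, 180, 250))))
  inst <- .tiny_instance(
    crops, yields, comp,
    nutrient_bounds = list(energy = c(round(stats::runif(1, 1900, 2300)), NA),
                           protein = c(round(stats::runif(1, 45, 60)), NA)),
    food_group_bounds = data.frame(group = "vegetables",
                                   min = 150, max = 600, unit = "g_day"),
    stage_fracs = round(stats::runif(4, 0.01, 0.1), 4),
    country_pop = pop, cropland_each = round(pop * 0.6), n_zones = 2,
    name = sprintf("oracle-seed%d", seed))
  inst
}

## piecewise-linear minimal land for a given harvested mass of one crop:
## fill zones in order of decreasing yield up to each rotation cap
.crop_land_curve <- function(instance, crop) {
  rows <- list()
  for (z in instance$zones$zone) {
    sv <- suitable_crops(z, instance)
    k <- match(crop, sv$crop)
    if (!is.na(k))
      rows[[length(rows) + 1]] <- data.frame(yield = sv$yield_t_ha[k],
                                             cap = sv$cap_ha[k])
  }
  cu <- do.call(rbind, rows)
  cu <- cu[order(-cu$yield), , drop = FALSE]
  prod_bk <- c(0, cumsum(cu$yield * cu$cap))
  land_bk <- c(0, cumsum(cu$cap))
  function(mass_t) {
    out <- stats::approx(prod_bk, land_bk, xout = pmin(mass_t,
                                                       max(prod_bk)),
                         rule = 2)$y
    out[mass_t > max(prod_bk) * (1 + 1e-12)] <- Inf
    out
  }
}

#' Brute-force land-use optimum by grid search over diets
#'
#' Independent oracle for the land-minimizing healthy-diet problem on
#' tiny plant-only, single-country instances: enumerates per-capita
#' supply combinations on a grid, keeps those satisfying the nutrient
#' minima and food-group bounds at intake level, converts each feasible
#' diet to its minimal land requirement by filling the highest-yield
#' zones first (valid because per-crop rotation caps are the only binding
#' land constraints on these instances), and returns the best feasible
#' objective. A second, finer local pass refines around the incumbent.
#'
#' @param instance a plant-only, one-country instance (e.g. from
#'   [generate_oracle_instance()])
#' @param grid relative grid resolution (default 0.01)
#' @param refine run the local refinement pass (default TRUE)
#' @return list with `status`, `objective` (ha), `diet_g_cap_day`
#' @export
brute_force_optimum <- function(instance, grid = 0.01, refine = TRUE) {
  inst <- instance
  if (nrow(inst$countries) != 1 || nrow(inst$animal_systems) > 0)
    stop_cf("the brute-force oracle handles one-country, plant-only instances")
  crops <- inst$crops$crop[inst$crops$use == "food"]
  pop <- inst$countries$population[1]
  comp <- comp_matrix(inst)
  w4 <- vapply(crops, function(f) waste_row(inst, f)$consumption, numeric(1))
  conv <- vapply(crops, function(f) supply_per_harvest(inst, f), numeric(1))
  nu <- inst$nutrients[!is.na(inst$nutrients$min) | !is.na(inst$nutrients$max), ]
  fg <- inst$food_group_bounds
  grp <- stats::setNames(inst$foods$food_group, inst$foods$food)
  curves <- lapply(crops, function(cr) .crop_land_curve(inst, cr))
  names(curves) <- crops

  e_min <- nu$min[nu$nutrient == "energy"]
  dmax <- vapply(crops, function(f) {
    by_energy <- if (length(e_min) && comp[f, "energy"] > 0)
      2.2 * e_min / (comp[f, "energy"] / 1000) else 800
    gmax <- fg$max[fg$group == grp[[f]] & fg$unit == "g_day"]
    max(by_energy, if (length(gmax)) 1.1 * gmax / (1 - w4[[f]]) else 0)
  }, numeric(1))

  eval_grid <- function(grids) {
    dd <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    colnames(dd) <- crops
    intake <- sweep(dd, 2, 1 - w4[crops], "*")
    feas <- rep(TRUE, nrow(dd))
    for (k in seq_len(nrow(nu))) {
      val <- intake %*% (comp[crops, nu$nutrient[k]] / 1000)
      if (!is.na(nu$min[k])) feas <- feas & val >= nu$min[k] - 1e-9
      if (!is.na(nu$max[k])) feas <- feas & val <= nu$max[k] + 1e-9
    }
    for (k in seq_len(nrow(fg))) {
      sel <- crops[grp[crops] == fg$group[k]]
      if (length(sel) == 0 || fg$unit[k] != "g_day") next
      val <- rowSums(intake[, sel, drop = FALSE])
      feas <- feas & val >= fg$min[k] - 1e-9 & val <= fg$max[k] + 1e-9
    }
    if (!any(feas)) return(NULL)
    dd <- dd[feas, , drop = FALSE]
    land <- numeric(nrow(dd))
    for (f in crops) {
      mass <- dd[, f] * pop * 365 / 1e6 / conv[[f]]
      land <- land + curves[[f]](mass)
    }
    best <- which.min(land)
    list(objective = land[best], diet = dd[best, ])
  }

  grids <- lapply(crops, function(f) seq(0, dmax[[f]], by = grid * dmax[[f]]))
  names(grids) <- crops
  res <- eval_grid(grids)
  if (is.null(res))
    return(list(status = "infeasible", objective = NA_real_,
                diet_g_cap_day = NULL))
  if (refine) {
    step <- grid * dmax
    grids2 <- lapply(crops, function(f)
      seq(max(0, res$diet[[f]] - 2 * step[[f]]),
          res$diet[[f]] + 2 * step[[f]], by = step[[f]] / 10))
    names(grids2) <- crops
    res2 <- eval_grid(grids2)
    if (!is.null(res2) && res2$objective < res$objective) res <- res2
  }
  list(status = "optimal", objective = res$objective,
       diet_g_cap_day = res$diet)
}
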