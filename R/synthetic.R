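## Synthetic-instance generation. Instances emulate the statistical
## structure of continental food-system data: multi-zone yield heterogeneity
## (lognormal zone multipliers), rotation frequency limits, by-product
## conversion factors, stage-wise waste fractions, animal-source-only
## nutrients (vitamin B12), and a self-consistent "current" baseline derived
## by actually allocating the current areas through the feed and processing
## chains, so that baseline calibration and current-protein matching are
## feasible by construction.

## ---- crop and animal templates --------------------------------------------

.CROP_TEMPLATES <- data.frame(
  crop = c("wheat", "potato", "greens", "apple", "faba_bean", "rapeseed",
           "sugar_beet", "sunflower_seed", "fodder_maize", "alfalfa",
           "rice", "chickpea", "carrot", "rest_crop"),
  food_group = c("grains", "tubers", "vegetables", "fruit", "legumes",
                 "oil_fat", "sugar", "nuts_seeds", "grains", "legumes",
                 "grains", "legumes", "vegetables", "other"),
  use = c(rep("food", 8), "fodder", "fodder", rep("food", 4)),
  yield_mean = c(6, 35, 25, 18, 3, 3.2, 70, 2.4, 40, 35, 6.5, 2.2, 40, 4),
  rotation_years = c(3, 3, 4, 1, 5, 4, 4, 6, 2, 1, 2, 5, 4, 3),
  residue_ratio = c(1.3, 0.2, 0.1, 0.05, 1.0, 1.5, 0.3, 1.6, 0, 0,
                    1.4, 1.2, 0.1, 0.8),
  n_conc_product = c(20, 3.2, 2.5, 1.0, 40, 35, 1.8, 28, 4.2, 8,
                     12, 36, 2.0, 15),
  p_conc_product = c(3.5, 0.6, 0.5, 0.2, 5, 7, 0.3, 6, 0.7, 0.8,
                     2.5, 4, 0.4, 2.5),
  n_conc_residue = c(6, 2, 2, 1, 15, 7, 2.5, 7, 0, 0, 6, 12, 2, 5),
  p_conc_residue = c(1, 0.3, 0.4, 0.2, 2, 1, 0.3, 1, 0, 0, 1, 1.5, 0.4, 0.8),
  tcf_main = c(0.78, 0.85, 0.92, 0.95, 0.90, 0.40, 0.14, 0.45, 1, 1,
               0.65, 0.88, 0.90, 0.85),
  tcf_byproduct = c(0.20, 0.10, 0, 0, 0.05, 0.55, 0.30, 0.50, 0, 0,
                    0.20, 0.08, 0.05, 0.10),
  byproduct_feed = c("bran", "potato_byproduct", NA, NA, "bran", "oilmeal",
                     "beet_pulp", "oilmeal", NA, NA, "bran", "bran",
                     "potato_byproduct", "bran"),
  acreage_capped = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

.ANIMAL_TEMPLATES <- data.frame(
  system = c("dairy_high", "pig_high", "broiler_high", "salmon",
             "beef_high", "layer_high", "tilapia"),
  species = c("dairy", "pig", "broiler", "salmon", "beef", "layer",
              "tilapia"),
  level = c("high", "high", "high", "single", "high", "high", "single"),
  product = c("milk", "pork", "chicken_meat", "farmed_fish", "beef", "egg",
              "farmed_fish"),
  ruminant = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
  fish = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
  ## per producing unit (1 t product/yr), gross energy MJ, digestible
  ## protein kg, intake t DM
  req_energy_mj = c(20000, 60000, 40000, 24000, 120000, 38000, 30000),
  req_protein_kg = c(75, 400, 360, 420, 600, 310, 380),
  intake_t_dm = c(1.45, 4.2, 3.0, 1.7, 8.5, 2.8, 2.2),
  parent_ratio = c(0.01, 0.08, 0.05, 0.01, 1.0, 0.04, 0.01),
  repro_ratio = c(0.04, 0.02, 0.01, 0.01, 0.30, 0.02, 0.01),
  aux_req_energy_mj = c(25000, 20000, 18000, 10000, 55000, 17000, 12000),
  aux_req_protein_kg = c(100, 100, 90, 120, 240, 85, 110),
  aux_intake_t_dm = c(1.8, 1.4, 1.3, 0.7, 4.0, 1.2, 0.9),
  n_retention = c(0.25, 0.30, 0.35, 0.40, 0.10, 0.30, 0.35),
  p_retention = c(0.30, 0.35, 0.35, 0.35, 0.15, 0.30, 0.35),
  grazing_share = c(0.5, 0, 0, 0, 0.7, 0, 0),
  byproduct_frac = c(0.02, 0.35, 0.30, 0.40, 0.45, 0.05, 0.40),
  mcf = c(0.17, 0.25, 0.015, 0, 0.10, 0.015, 0),
  b0 = c(0.24, 0.45, 0.36, 0, 0.24, 0.36, 0),
  ef_n2o_mms = c(0.005, 0.002, 0.001, 0, 0.005, 0.001, 0),
  mms_volat_frac = c(0.30, 0.40, 0.40, 0, 0.30, 0.40, 0),
  ym = c(6.5, NA, NA, NA, 6.3, NA, NA),
  stringsAsFactors = FALSE
)

.FEED_TEMPLATES <- data.frame(
  feed = c("grass", "fodder_maize_feed", "alfalfa_feed", "bran", "oilmeal",
           "beet_pulp", "potato_byproduct", "food_waste",
           "animal_byproduct", "fish_byproduct"),
  origin = c("grass", "fodder_crop", "fodder_crop", "crop_byproduct",
             "crop_byproduct", "crop_byproduct", "crop_byproduct",
             "food_waste", "animal_byproduct", "fish_byproduct"),
  dm_frac = c(1.0, 0.33, 0.25, 0.88, 0.89, 0.25, 0.20, 0.27, 0.35, 0.30),
  energy_mj_kg = c(18.0, 6.2, 4.6, 16.0, 17.0, 3.8, 2.2, 4.5, 7.5, 6.5),
  dig_protein_g_kg = c(100, 25, 35, 105, 280, 15, 3, 20, 80, 55),
  energy_mj_kg_fish = c(0, 0, 0, 8.0, 14.0, 0, 0, 5.0, 9.0, 8.0),
  dig_protein_g_kg_fish = c(0, 0, 0, 60, 250, 0, 0, 20, 90, 70),
  n_g_kg = c(25, 4.2, 8.0, 25, 55, 3.5, 3.0, 7.0, 25, 22),
  p_g_kg = c(3.5, 0.7, 0.8, 10, 11, 0.25, 0.5, 1.2, 5.0, 4.0),
  dig_om = c(0.72, 0.72, 0.62, 0.65, 0.75, 0.85, 0.85, 0.80, 0.80, 0.80),
  wet = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
  tradeable = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

## which species may eat which feed (grass: ruminants only; food waste and
## animal by-products: monogastrics and fish only; fodder: terrestrial only)
.feed_legality <- function(feed_origin, feed, species, ruminant, fish) {
  if (feed == "grass") return(ruminant)
  if (feed_origin == "fodder_crop") return(!fish)
  if (feed_origin == "food_waste") return(!ruminant)
  if (feed_origin %in% c("animal_byproduct", "fish_byproduct"))
    return(!ruminant)
  if (feed == "beet_pulp") return(ruminant || species == "pig")
  if (feed == "potato_byproduct") return(species %in% c("pig", "broiler",
                                                        "layer"))
  TRUE
}

## composition anchors per kg edible fresh matter:
## energy kcal, protein g, fat g, carbohydrates g, fibre g, calcium mg,
## iron mg, vitamin B12 ug
.COMP_ANCHORS <- list(
  grains = c(3500, 110, 20, 720, 100, 300, 35, 0),
  tubers = c(770, 20, 1, 170, 22, 120, 8, 0),
  vegetables = c(300, 25, 3, 45, 25, 400, 8, 0),
  fruit = c(550, 8, 3, 135, 22, 120, 3, 0),
  legumes = c(3400, 220, 15, 600, 150, 1000, 60, 0),
  nuts_seeds = c(6000, 200, 500, 200, 90, 1000, 40, 0),
  oil_fat = c(8800, 1, 990, 0, 0, 10, 1, 0),
  sugar = c(3870, 0, 0, 998, 0, 10, 1, 0),
  other = c(3000, 100, 50, 500, 50, 300, 20, 0),
  milk = c(640, 33, 36, 48, 0, 1200, 0.3, 4.5),
  beef = c(2500, 190, 180, 0, 0, 120, 22, 25),
  pork = c(2400, 180, 180, 0, 0, 100, 9, 7),
  chicken_meat = c(1900, 200, 120, 0, 0, 110, 9, 3),
  egg = c(1430, 125, 95, 70, 0, 500, 17, 9),
  farmed_fish = c(2000, 200, 130, 0, 0, 150, 5, 40),
  wild_fish = c(1400, 190, 60, 0, 0, 250, 10, 80)
)

.comp_row <- function(anchor, jitter) {
  vals <- anchor * jitter
  out <- stats::setNames(numeric(length(nutrient_ids())), nutrient_ids())
  out["fresh_weight"] <- 1000
  out[c("energy", "protein", "fat_total", "carbohydrates", "fibre",
        "calcium", "iron", "vit_b12")] <- vals
  out
}

## reference healthy-diet intake pattern, g fresh/capita/day, used to set
## nutrient reference bounds self-consistently (foods absent from the
## instance are dropped)
.REF_DIET <- c(wheat = 230, rice = 40, potato = 80, greens = 220,
               carrot = 80, apple = 150, faba_bean = 60, chickpea = 30,
               sunflower_seed = 20, rapeseed = 20, sugar_beet = 15,
               rest_crop = 20, milk = 250, beef = 7, pork = 13,
               chicken_meat = 25, egg = 12, farmed_fish = 20,
               wild_fish = 15)

## ---- generator -------------------------------------------------------------

#' Generate a synthetic food-system instance
#'
#' Draws a deterministic, self-consistent instance of the requested size:
#' zones with heterogeneous yields (lognormal multipliers, sd
#' `sigma_yield` on the log scale), crops covering every plant food group,
#' animal systems spanning ruminants, monogastrics and aquaculture, feed
#' items with species legality rules, capture-fishery stocks, stage-wise
#' waste fractions, nutrient reference bounds anchored to a reference diet
#' computed from the generated compositions, and a current baseline
#' (areas, grassland use, protein supply per food group) obtained by
#' allocating the current areas through the processing and feed chains.
#'
#' @param n_zones number of climate-soil zones (>= 1)
#' @param n_countries number of countries (>= 1, <= n_zones)
#' @param n_crops number of crops (>= 10 so every plant food group is
#'   covered; at most 14)
#' @param n_animal_systems number of animal systems (0 to 7; the first four
#'   are dairy, pig, broiler and salmon)
#' @param seed integer seed; identical arguments give identical instances
#' @param sigma_yield sd of the log-normal zone yield multipliers
#' @param population_per_country mean population per country
#' @param include_fisheries include capture-fishery stocks (default TRUE)
#' @return a valid `food_system_instance`
#' @export
generate_instance <- function(n_zones = 3, n_countries = 2, n_crops = 10,
                              n_animal_systems = 4, seed = 1,
                              sigma_yield = 0.3,
                              population_per_country = 8e6,
                              include_fisheries = TRUE) {
  if (n_zones < 1 || n_countries < 1 || n_crops < 1 || n_animal_systems < 0)
    stop_cf("generation failure: all size arguments must be >= 1 (systems >= 0)")
  if (n_countries > n_zones)
    stop_cf("generation failure: need at least one zone per country")
  if (n_crops < 10)
    stop_cf("generation failure: fewer than 10 crops cannot cover every plant food group plus fodder")
  if (n_crops > nrow(.CROP_TEMPLATES) ||
      n_animal_systems > nrow(.ANIMAL_TEMPLATES))
    stop_cf("generation failure: at most %d crops and %d animal systems available",
            nrow(.CROP_TEMPLATES), nrow(.ANIMAL_TEMPLATES))
  set.seed(seed)

  ## countries along a 600-km spaced line
  countries <- data.frame(
    country = sprintf("C%02d", seq_len(n_countries)),
    population = round(population_per_country *
                         exp(stats::rnorm(n_countries, 0, 0.3))),
    x = 600 * (seq_len(n_countries) - 1), y = 0)
  countries$sludge_fresh_t <- countries$population * 0.017

  ## zones round-robin over countries; land scaled to population
  zc <- countries$country[(seq_len(n_zones) - 1) %% n_countries + 1]
  pop_of <- stats::setNames(countries$population, countries$country)
  nz_of <- table(zc)
  zones <- data.frame(
    zone = sprintf("Z%02d", seq_len(n_zones)), country = zc,
    stringsAsFactors = FALSE)
  share <- stats::runif(n_zones, 0.7, 1.3)
  zones$cropland_ha <- round(0.30 * pop_of[zc] / nz_of[zc] * share)
  zones$temp_grassland_ha <- round(0.04 * pop_of[zc] / nz_of[zc] * share)
  zones$permanent_pasture_ha <- round(0.12 * pop_of[zc] / nz_of[zc] * share)
  zones$rangeland_ha <- round(0.06 * pop_of[zc] / nz_of[zc] * share)
  zones$climate <- ifelse(stats::runif(n_zones) < 0.6, "wet", "dry")
  zones$soil <- ifelse(stats::runif(n_zones) < 0.15, "organic", "mineral")
  zones$grass_yield_t_dm_ha <- round(stats::runif(n_zones, 4, 7), 2)
  zones$x <- countries$x[match(zc, countries$country)] +
    stats::runif(n_zones, -100, 100)
  zones$y <- stats::runif(n_zones, -100, 100)
  rownames(zones) <- NULL

  crops <- .CROP_TEMPLATES[seq_len(n_crops), ]
  rownames(crops) <- NULL

  ## zone-specific yields: lognormal multipliers; each crop unsuitable in a
  ## random ~15% of zones but always suitable somewhere
  yields <- list()
  for (i in seq_len(nrow(crops))) {
    mult <- exp(stats::rnorm(n_zones, 0, sigma_yield))
    suit <- stats::runif(n_zones) > 0.15
    if (!any(suit)) suit[sample.int(n_zones, 1)] <- TRUE
    yields[[i]] <- data.frame(
      crop = crops$crop[i], zone = zones$zone[suit],
      yield_t_ha = round(crops$yield_mean[i] * mult[suit], 3))
  }
  yields <- do.call(rbind, yields)
  rownames(yields) <- NULL

  systems <- .ANIMAL_TEMPLATES[seq_len(max(n_animal_systems, 0)), ]
  rownames(systems) <- NULL

  ## foods: every food crop's main product plus the products of the
  ## included animal systems plus wild fish
  animal_foods <- unique(systems$product)
  food_ids <- c(crops$crop[crops$use == "food"], animal_foods,
                if (include_fisheries) "wild_fish")
  food_grp <- c(crops$food_group[crops$use == "food"],
                c(milk = "dairy", beef = "red_meat", pork = "red_meat",
                  chicken_meat = "chicken", egg = "eggs",
                  farmed_fish = "fish")[animal_foods],
                if (include_fisheries) "fish")
  foods <- data.frame(food = food_ids, food_group = unname(food_grp),
                      source = c(rep("crop", sum(crops$use == "food")),
                                 rep("animal", length(animal_foods)),
                                 if (include_fisheries) "fish"),
                      crop = c(crops$crop[crops$use == "food"],
                               rep(NA, length(animal_foods)),
                               if (include_fisheries) NA),
                      stringsAsFactors = FALSE)

  comp <- matrix(0, nrow(foods), length(nutrient_ids()),
                 dimnames = list(foods$food, nutrient_ids()))
  for (i in seq_len(nrow(foods))) {
    f <- foods$food[i]
    anchor <- .COMP_ANCHORS[[f]] %||% .COMP_ANCHORS[[foods$food_group[i]]]
    jit <- exp(stats::rnorm(8, 0, 0.08))
    comp[i, ] <- .comp_row(anchor, jit)
  }
  composition <- data.frame(food = foods$food, comp, stringsAsFactors = FALSE)
  rownames(composition) <- NULL

  ## feeds restricted to those that can exist in this instance
  have_bp <- unique(stats::na.omit(crops$byproduct_feed))
  keep <- .FEED_TEMPLATES$feed %in% have_bp |
    .FEED_TEMPLATES$origin %in% c("grass", "food_waste") |
    (.FEED_TEMPLATES$origin == "fodder_crop" &
       sub("_feed$", "", .FEED_TEMPLATES$feed) %in% crops$crop) |
    (.FEED_TEMPLATES$feed == "animal_byproduct" & nrow(systems) > 0) |
    (.FEED_TEMPLATES$feed == "fish_byproduct" &
       (include_fisheries || any(systems$fish)))
  feeds <- .FEED_TEMPLATES[keep, ]
  rownames(feeds) <- NULL

  feed_legal <- expand.grid(feed = feeds$feed, species = unique(systems$species),
                            stringsAsFactors = FALSE)
  if (nrow(feed_legal)) {
    feed_legal$allowed <- mapply(function(f, sp) {
      i <- match(f, feeds$feed); j <- match(sp, systems$species)
      .feed_legality(feeds$origin[i], f, sp, systems$ruminant[j],
                     systems$fish[j])
    }, feed_legal$feed, feed_legal$species)
  } else feed_legal$allowed <- logical(0)

  ## stage-wise waste fractions per food, all within (0, 0.3)
  stage_waste <- data.frame(
    food = foods$food,
    post_harvest = round(stats::runif(nrow(foods), 0.02, 0.08), 4),
    processing = round(stats::runif(nrow(foods), 0.02, 0.10), 4),
    distribution = round(stats::runif(nrow(foods), 0.02, 0.08), 4),
    consumption = round(stats::runif(nrow(foods), 0.08, 0.25), 4))

  ## fisheries: MSY scaled to population (about 22 kg landings/capita/yr
  ## across stocks), country quota shares proportional to population
  if (include_fisheries) {
    tot <- sum(countries$population) * 0.022
    fish_stocks <- data.frame(stock = c("pelagic", "demersal"),
                              msy_t = round(tot * c(0.6, 0.4)),
                              edible_frac = c(0.55, 0.5))
    fish_quota <- expand.grid(stock = fish_stocks$stock,
                              country = countries$country,
                              stringsAsFactors = FALSE)
    fish_quota$share <- countries$population[match(fish_quota$country,
                                                   countries$country)] /
      sum(countries$population)
  } else {
    fish_stocks <- data.frame(stock = character(), msy_t = numeric(),
                              edible_frac = numeric())
    fish_quota <- data.frame(stock = character(), country = character(),
                             share = numeric())
  }

  residual_params <- list(
    waste_to_feed_frac = 0.35, sludge_use_frac = 0.36,
    sludge_n_frac = 0.075, sludge_p_frac = 0.012,
    compost_cn = 15, compost_n_loss = 0.05,
    organic_np = c(manure = 4, compost = 6, sludge = 6.25))

  emission_constants <- list(
    ch4_energy_mj_kg = 55.65, ch4_m3_to_kg = 0.67,
    gwp_ch4 = 28, gwp_n2o = 265,
    aquaculture_n2o_frac = 0.018, p_unavoidable_loss = 0.125,
    n_volat_frac_synthetic = 0.10, n_volat_frac_organic = 0.21,
    n_leach_frac_wet = 0.24, n_leach_frac_dry = 0,
    ef_soil_synthetic = 0.01, ef_soil_organic_wet = 0.006,
    ef_soil_organic_dry = 0.005, ef_volat_indirect = 0.010,
    ef_leach_indirect = 0.011, ef_grazing_n2o = 0.02,
    ef_organic_soil_n2o_ha = 8,
    ef_fert_prod_n = 5.5, ef_fert_prod_p = 2.0,
    ef_transport = 0.1, transport_cap_co2e = 1500,
    compost_ef_n2o = 0.01, compost_c_to_ch4 = 0.025)

  inst <- food_system_instance(
    name = sprintf("synthetic-%dz-%dc-%dcrops-%dsys-seed%d", n_zones,
                   n_countries, n_crops, n_animal_systems, seed),
    nutrients = data.frame(nutrient = nutrient_ids(),
                           unit = unname(nutrient_units()),
                           min = NA_real_, max = NA_real_),
    countries = countries, zones = zones, crops = crops, yields = yields,
    foods = foods, composition = composition, animal_systems = systems,
    feeds = feeds, feed_legal = feed_legal, fish_stocks = fish_stocks,
    fish_quota = fish_quota,
    food_group_bounds = default_food_group_bounds(),
    stage_waste = stage_waste, residual_params = residual_params,
    emission_constants = emission_constants, current = NULL)

  ## nutrient reference bounds anchored to the reference diet achievable
  ## with this instance's own foods and compositions
  ref <- .REF_DIET[names(.REF_DIET) %in% foods$food]
  refnv <- diet_nutrients(ref, composition)
  nu <- inst$nutrients
  set_bound <- function(nu, n, lo = NA, hi = NA) {
    i <- match(n, nu$nutrient)
    nu$min[i] <- if (is.na(lo)) NA else round(lo, 3)
    nu$max[i] <- if (is.na(hi)) NA else round(hi, 3)
    nu
  }
  nu <- set_bound(nu, "energy", 0.92 * refnv[["energy"]], 1.35 * refnv[["energy"]])
  nu <- set_bound(nu, "protein", 0.70 * refnv[["protein"]], NA)
  nu <- set_bound(nu, "fibre", 0.50 * refnv[["fibre"]], NA)
  nu <- set_bound(nu, "calcium", 0.70 * refnv[["calcium"]], 3.0 * refnv[["calcium"]])
  nu <- set_bound(nu, "iron", 0.60 * refnv[["iron"]], NA)
  if (nrow(systems) > 0 || include_fisheries)
    nu <- set_bound(nu, "vit_b12", 0.80 * refnv[["vit_b12"]], NA)
  inst$nutrients <- nu

  inst$current <- .build_current_baseline(inst)
  inst <- canonicalize_instance(inst)
  assert_valid_instance(inst)
  inst
}

## Construct the current baseline: areas as fixed cropland shares (within
## rotation caps), full grassland use, and the protein supply per food
## group actually delivered when those areas are allocated through the
## processing and feed chains.
.build_current_baseline <- function(inst) {
  crops <- inst$crops; zones <- inst$zones
  target_share <- c(wheat = 0.25, potato = 0.04, greens = 0.02, apple = 0.02,
                    faba_bean = 0.04, rapeseed = 0.10, sugar_beet = 0.05,
                    sunflower_seed = 0.03, fodder_maize = 0.20,
                    alfalfa = 0.14, rice = 0.01, chickpea = 0.02,
                    carrot = 0.01, rest_crop = 0.02)
  areas <- list()
  for (i in seq_len(nrow(crops))) {
    cr <- crops$crop[i]
    sh <- min(unname(target_share[cr]) %||% 0.01,
              0.95 * rotation_share(crops$rotation_years[i]))
    suit <- inst$yields$zone[inst$yields$crop == cr]
    for (z in suit) {
      zi <- match(z, zones$zone)
      areas[[length(areas) + 1]] <- data.frame(
        crop = cr, zone = z, area_ha = round(sh * zones$cropland_ha[zi]))
    }
  }
  areas <- do.call(rbind, areas)
  grassland <- data.frame(zone = zones$zone,
                          grassland_ha = zones$temp_grassland_ha +
                            zones$permanent_pasture_ha + zones$rangeland_ha)

  ## EU-pooled allocation of baseline production to a current diet
  pop_total <- sum(inst$countries$population)
  comp <- comp_matrix(inst)
  food_crops <- crops$crop[crops$use == "food"]
  harvest <- vapply(crops$crop, function(cr) {
    sel <- areas$crop == cr
    sum(vapply(which(sel), function(k)
      areas$area_ha[k] * (yield_of(inst, cr, areas$zone[k]) %||% 0),
      numeric(1)))
  }, numeric(1))

  supply_t <- stats::setNames(numeric(0), character(0))
  byprod_t <- stats::setNames(numeric(length(inst$feeds$feed)),
                              inst$feeds$feed)
  for (cr in food_crops) {
    s <- harvest[[cr]] * supply_per_harvest(inst, cr)
    supply_t[cr] <- s
    bf <- crop_row(inst, cr)$byproduct_feed
    if (!is.na(bf) && bf %in% names(byprod_t))
      byprod_t[bf] <- byprod_t[bf] + s * byproduct_per_supply(inst, cr)
  }

  ## feed pools: grass (80% of grassland growth), fodder harvest, crop
  ## by-products; allocated with fixed baseline weights
  systems <- inst$animal_systems
  supply_animal <- stats::setNames(numeric(0), character(0))
  if (nrow(systems) > 0) {
    grass_dm <- 0.8 * sum(grassland$grassland_ha *
                            zones$grass_yield_t_dm_ha[match(grassland$zone,
                                                            zones$zone)])
    fodder_pools <- stats::setNames(
      harvest[crops$crop[crops$use == "fodder"]],
      paste0(crops$crop[crops$use == "fodder"], "_feed"))
    rum <- which(systems$ruminant)
    terr <- which(!systems$fish)
    alloc_items <- rep(list(stats::setNames(numeric(0), character(0))),
                       nrow(systems))
    add_feed <- function(sys_i, feed, t_amount) {
      if (t_amount <= 0 || length(sys_i) == 0) return(invisible(NULL))
      per <- t_amount / length(sys_i)
      for (i in sys_i) {
        prev <- if (feed %in% names(alloc_items[[i]]))
          alloc_items[[i]][[feed]] else 0
        alloc_items[[i]][feed] <<- prev + per
      }
      invisible(NULL)
    }
    if ("grass" %in% inst$feeds$feed) add_feed(rum, "grass", grass_dm)
    for (f in names(fodder_pools)) if (f %in% inst$feeds$feed)
      add_feed(terr, f, fodder_pools[[f]])
    for (f in names(byprod_t)) {
      if (byprod_t[[f]] <= 0) next
      legal <- which(vapply(seq_len(nrow(systems)), function(i)
        feed_allowed(inst, f, systems$species[i]) &&
          (!systems$fish[i] || feed_row(inst, f)$energy_mj_kg_fish > 0),
        logical(1)))
      add_feed(legal, f, byprod_t[[f]])
    }
    ## supportable production per system from its allocated pools: a tiny
    ## LP per system (part of the feed may be discarded) so the claimed
    ## units are exactly reproducible by the scenario optimizer
    units <- numeric(nrow(systems))
    for (i in seq_len(nrow(systems))) {
      r <- unit_requirements(systems[i, ])
      alloc <- alloc_items[[i]]
      if (length(alloc) == 0) next
      dv <- vapply(names(alloc), function(f)
        feed_delivery(feed_row(inst, f), isTRUE(systems$fish[i])),
        numeric(5))
      nx <- length(alloc)
      A <- rbind(cbind(diag(nx), 0),
                 c(dv["energy_mj", ], -r[["energy_mj"]]),
                 c(dv["protein_kg", ], -r[["protein_kg"]]),
                 c(dv["dm_t", ], -r[["intake_t_dm"]]))
      res <- simplex_lp(c(rep(0, nx), 1), A,
                        c(rep("<=", nx), ">=", ">=", "<="),
                        c(unname(alloc), 0, 0, 0), maximize = TRUE)
      if (res$status == "optimal") units[i] <- res$x[nx + 1]
    }
    for (i in seq_len(nrow(systems))) {
      p <- systems$product[i]
      w <- waste_row(inst, p)
      s <- units[i] * (1 - w$processing) * (1 - w$distribution)
      prev <- if (p %in% names(supply_animal)) supply_animal[[p]] else 0
      supply_animal[p] <- prev + s
    }
  }

  if (nrow(inst$fish_stocks) > 0) {
    edible <- 0.8 * sum(inst$fish_stocks$msy_t * inst$fish_stocks$edible_frac)
    w <- waste_row(inst, "wild_fish")
    prev <- if ("wild_fish" %in% names(supply_animal))
      supply_animal[["wild_fish"]] else 0
    supply_animal["wild_fish"] <- prev +
      edible * (1 - w$post_harvest) * (1 - w$processing) * (1 - w$distribution)
  }

  supply_all <- c(supply_t, supply_animal)
  grp <- stats::setNames(inst$foods$food_group, inst$foods$food)
  protein_g_kg <- comp[names(supply_all), "protein"]
  g_prot_cap_day <- supply_all * 1000 * protein_g_kg / (pop_total * 365)
  by_group <- tapply(g_prot_cap_day, grp[names(supply_all)], sum)
  supply_protein <- do.call(rbind, lapply(inst$countries$country, function(cc)
    data.frame(country = cc, group = names(by_group),
               g_protein_cap_day = round(as.numeric(by_group), 4))))
  rownames(supply_protein) <- NULL

  ## current artificial fertilizer: requirement of current areas minus a
  ## nominal organic contribution (reporting anchor only)
  req_n <- req_p <- 0
  for (k in seq_len(nrow(areas))) {
    r <- fertilizer_requirement(areas$crop[k], areas$zone[k],
                                areas$area_ha[k], inst)
    req_n <- req_n + r[["N_kg"]]; req_p <- req_p + r[["P_kg"]]
  }
  sl <- sludge_fertilizer(sum(inst$countries$sludge_fresh_t),
                          inst$residual_params)

  list(areas = areas, grassland = grassland,
       supply_protein = supply_protein,
       artificial_fert_t = round(max(0, 0.75 * (req_n + req_p) / 1000)),
       sludge_applied_t = round(sl$usable_t))
}

#' Scale an instance's population
#'
#' Multiplies the country populations (only) by `factor`; used for
#' population-scaling linearity checks and population-maximizing analyses.
#'
#' @param instance a `food_system_instance`
#' @param factor positive scaling factor
#' @return the scaled instance
#' @export
scale_population <- function(instance, factor) {
  if (!is.numeric(factor) || factor <= 0)
    stop_cf("population scaling factor must be > 0")
  instance$countries$population <- instance$countries$population * factor
  instance
}
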