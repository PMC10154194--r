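## A food-system instance is a plain list of data.frames and parameter lists,
## classed "food_system_instance". Units are fixed package-wide and converted
## at construction time:
##   areas ha; biomass t fresh matter (grass t dry matter); nutrients in crops
##   and feeds kg/t (= g/kg); food composition per kg edible fresh matter;
##   diets g/capita/day; energy of feed MJ (gross energy); emissions kg/yr.
##
## Components:
##   nutrients        42 rows: nutrient, unit, min, max (per capita per day;
##                    NA = unbounded)
##   countries        country, population, x, y (km coordinates of the
##                    centroid, used for transport distances), sludge_fresh_t
##   zones            zone, country, cropland_ha, temp_grassland_ha,
##                    permanent_pasture_ha, rangeland_ha, climate (wet/dry),
##                    soil (mineral/organic), grass_yield_t_dm_ha, x, y
##   crops            crop, food_group, use (food/fodder), rotation_years,
##                    residue_ratio, n/p concentrations of product and residue
##                    (kg/t), tcf_main, tcf_byproduct, byproduct_feed,
##                    acreage_capped
##   yields           crop, zone, yield_t_ha (absent row = unsuitable)
##   foods            food, food_group, source (crop/animal/fish), crop
##   composition      food x nutrient table, per kg edible fresh matter
##   animal_systems   one producing unit = capacity for 1 t product/yr;
##                    requirements per unit-year, auxiliary (parent +
##                    reproduction) stock ratios and their requirements,
##                    retention fractions, manure-management parameters
##   feeds            feed item compositions for livestock and (separately)
##                    fish, N/P content, organic-matter digestibility,
##                    wet/tradeable flags
##   feed_legal       (feed, species, allowed) long table
##   fish_stocks      stock, msy_t, edible_frac; fish_quota: country shares
##   food_group_bounds, stage_waste, residual_params, emission_constants
##   current          baseline anchors: areas, grassland use, protein supply
##                    per food group, artificial fertilizer, applied sludge

#' Construct a food-system instance
#'
#' Assembles the component tables into a classed instance. This performs no
#' validation beyond classing; call [validate_instance()] to check the
#' invariants.
#'
#' @param ... named instance components (see the package vignette for the
#'   schema).
#' @return an object of class `food_system_instance`
#' @export
food_system_instance <- function(...) {
  x <- list(...)
  structure(x, class = "food_system_instance")
}

## strip incidental attributes (row names, names carried in from named
## vectors, expand.grid metadata) so that structurally equal instances
## compare equal and serialization round-trips exactly
canonicalize_instance <- function(x) {
  fix_df <- function(df) {
    if (!is.data.frame(df)) return(df)
    out <- lapply(df, function(col) {
      if (is.factor(col)) col <- as.character(col)
      attributes(col) <- NULL
      col
    })
    as.data.frame(out, stringsAsFactors = FALSE, optional = FALSE)
  }
  for (k in c("nutrients", "countries", "zones", "crops", "yields", "foods",
              "composition", "animal_systems", "feeds", "feed_legal",
              "fish_stocks", "fish_quota", "food_group_bounds",
              "stage_waste"))
    if (!is.null(x[[k]])) x[[k]] <- fix_df(x[[k]])
  if (!is.null(x$current)) {
    x$current$areas <- fix_df(x$current$areas)
    x$current$grassland <- fix_df(x$current$grassland)
    x$current$supply_protein <- fix_df(x$current$supply_protein)
  }
  if (!is.null(x$residual_params$organic_np))
    x$residual_params$organic_np <-
      unlist(as.list(x$residual_params$organic_np))
  x
}

#' @export
print.food_system_instance <- function(x, ...) {
  cat("Food-system instance:", x$name %||% "<unnamed>", "\n")
  cat(sprintf("  %d countries, %d zones, %d crops (%d fodder), %d animal systems, %d fish stocks\n",
              nrow(x$countries), nrow(x$zones), nrow(x$crops),
              sum(x$crops$use == "fodder"), nrow(x$animal_systems),
              nrow(x$fish_stocks)))
  cat(sprintf("  population %.2f million; agricultural land %.0f kha (%.0f kha cropland)\n",
              sum(x$countries$population) / 1e6,
              (sum(x$zones$cropland_ha) + sum(x$zones$temp_grassland_ha) +
                 sum(x$zones$permanent_pasture_ha) + sum(x$zones$rangeland_ha)) / 1e3,
              sum(x$zones$cropland_ha) / 1e3))
  invisible(x)
}

## ---- internal accessors ----------------------------------------------------

comp_matrix <- function(instance) {
  m <- as.matrix(instance$composition[, nutrient_ids(), drop = FALSE])
  rownames(m) <- instance$composition$food
  m
}

crop_row <- function(instance, crop) {
  i <- match(crop, instance$crops$crop)
  if (is.na(i)) stop_cf("unknown crop '%s'", crop)
  instance$crops[i, ]
}

zone_row <- function(instance, zone) {
  i <- match(zone, instance$zones$zone)
  if (is.na(i)) stop_cf("unknown zone '%s'", zone)
  instance$zones[i, ]
}

system_row <- function(instance, system) {
  i <- match(system, instance$animal_systems$system)
  if (is.na(i)) stop_cf("unknown animal system '%s'", system)
  instance$animal_systems[i, ]
}

feed_row <- function(instance, feed) {
  i <- match(feed, instance$feeds$feed)
  if (is.na(i)) stop_cf("unknown feed item '%s'", feed)
  instance$feeds[i, ]
}

yield_of <- function(instance, crop, zone) {
  y <- instance$yields
  i <- which(y$crop == crop & y$zone == zone)
  if (length(i) == 0) NA_real_ else y$yield_t_ha[i[1]]
}

feed_allowed <- function(instance, feed, species) {
  fl <- instance$feed_legal
  i <- which(fl$feed == feed & fl$species == species)
  if (length(i) == 0) TRUE else isTRUE(fl$allowed[i[1]])
}

grassland_ha <- function(zrow) {
  zrow$temp_grassland_ha + zrow$permanent_pasture_ha + zrow$rangeland_ha
}

country_dist_km <- function(instance) {
  cc <- instance$countries
  d <- outer(seq_len(nrow(cc)), seq_len(nrow(cc)), function(i, j)
    point_dist_km(cc$x[i], cc$y[i], cc$x[j], cc$y[j]))
  dimnames(d) <- list(cc$country, cc$country)
  d
}

## stage-waste row for a food (all four stage fractions)
waste_row <- function(instance, food) {
  sw <- instance$stage_waste
  i <- match(food, sw$food)
  if (is.na(i)) stop_cf("no stage-waste fractions for food '%s'", food)
  sw[i, c("post_harvest", "processing", "distribution", "consumption")]
}

## t of consumer-level supply per t raw harvest of a food crop
supply_per_harvest <- function(instance, crop) {
  cr <- crop_row(instance, crop)
  w <- waste_row(instance, crop)
  (1 - w$post_harvest) * cr$tcf_main * (1 - w$processing) * (1 - w$distribution)
}

## t of by-product per t of consumer-level supply of a food crop
byproduct_per_supply <- function(instance, crop) {
  cr <- crop_row(instance, crop)
  if (is.na(cr$byproduct_feed) || cr$tcf_byproduct <= 0) return(0)
  w <- waste_row(instance, crop)
  cr$tcf_byproduct /
    (cr$tcf_main * (1 - w$processing) * (1 - w$distribution))
}

## ---- validation ------------------------------------------------------------

#' Validate a food-system instance
#'
#' Checks every structural invariant of the instance schema: nonnegative
#' areas, yields and concentrations; rotation frequencies in (0, 1];
#' exactly 42 nutrient specifications with min <= max; stage waste fractions
#' in [0, 1); technical conversion factors summing to at most one; feed
#' legality (food waste illegal for ruminants); ruminant-only parameters;
#' resolvable cross-references. Violations are returned as data, never
#' raised.
#'
#' @param instance a `food_system_instance`
#' @return data.frame with columns `type`, `id`, `rule`; zero rows when the
#'   instance is valid.
#' @export
validate_instance <- function(instance) {
  v <- list()
  bad <- function(type, id, rule) {
    v[[length(v) + 1]] <<- data.frame(type = type, id = id, rule = rule,
                                      stringsAsFactors = FALSE)
  }

  zs <- instance$zones
  for (col in c("cropland_ha", "temp_grassland_ha", "permanent_pasture_ha",
                "rangeland_ha")) {
    i <- which(is.na(zs[[col]]) | zs[[col]] < 0)
    for (k in i) bad("Zone", zs$zone[k], sprintf("%s must be >= 0", col))
  }
  i <- which(!zs$country %in% instance$countries$country)
  for (k in i) bad("Zone", zs$zone[k], "country reference does not resolve")
  i <- which(!zs$climate %in% c("wet", "dry"))
  for (k in i) bad("Zone", zs$zone[k], "climate class must be wet or dry")
  i <- which(!zs$soil %in% c("mineral", "organic"))
  for (k in i) bad("Zone", zs$zone[k], "soil class must be mineral or organic")

  cr <- instance$crops
  i <- which(!(cr$rotation_years >= 1))
  for (k in i) bad("Crop", cr$crop[k],
                   "rotation_years must be >= 1 (max frequency in (0, 1])")
  for (col in c("residue_ratio", "n_conc_product", "p_conc_product",
                "n_conc_residue", "p_conc_residue")) {
    i <- which(cr[[col]] < 0)
    for (k in i) bad("Crop", cr$crop[k], sprintf("%s must be >= 0", col))
  }
  i <- which(cr$tcf_main + cr$tcf_byproduct > 1 + 1e-9)
  for (k in i) bad("Crop", cr$crop[k],
                   "technical conversion factors must sum to <= 1")
  i <- which(!cr$food_group %in% food_groups())
  for (k in i) bad("Crop", cr$crop[k], "unknown food group")
  i <- which(!is.na(cr$byproduct_feed) & !cr$byproduct_feed %in% instance$feeds$feed)
  for (k in i) bad("Crop", cr$crop[k], "byproduct_feed reference does not resolve")
  i <- which(!cr$crop %in% instance$yields$crop)
  for (k in i) bad("Crop", cr$crop[k], "yield must be defined for at least one zone")

  ys <- instance$yields
  i <- which(ys$yield_t_ha < 0)
  for (k in i) bad("Yield", paste(ys$crop[k], ys$zone[k]), "yield must be >= 0")
  i <- which(!ys$zone %in% zs$zone)
  for (k in i) bad("Yield", paste(ys$crop[k], ys$zone[k]),
                   "zone reference does not resolve")

  nu <- instance$nutrients
  if (nrow(nu) != 42 || !setequal(nu$nutrient, nutrient_ids()))
    bad("NutrientSpec", "<table>", "exactly the 42 tracked nutrients required")
  i <- which(!is.na(nu$min) & !is.na(nu$max) & nu$min > nu$max)
  for (k in i) bad("NutrientSpec", nu$nutrient[k], "min must be <= max")

  fg <- instance$food_group_bounds
  i <- which(fg$min > fg$max)
  for (k in i) bad("FoodGroupBound", fg$group[k], "min must be <= max")
  i <- which(fg$unit == "energy_share" & fg$group != "grains")
  for (k in i) bad("FoodGroupBound", fg$group[k],
                   "only grains carry an energy-share bound")

  fo <- instance$foods
  i <- which(!fo$food %in% instance$composition$food)
  for (k in i) bad("Food", fo$food[k], "food has no composition row")
  i <- which(fo$source == "crop" & !fo$crop %in% cr$crop)
  for (k in i) bad("Food", fo$food[k], "crop reference does not resolve")
  ## animal-source exclusivity of B12 is a realism property of generated
  ## data, not a schema invariant, so it is not checked here

  as_ <- instance$animal_systems
  for (col in c("parent_ratio", "repro_ratio", "byproduct_frac")) {
    i <- which(as_[[col]] < 0)
    for (k in i) bad("AnimalSystem", as_$system[k], sprintf("%s must be >= 0", col))
  }
  for (col in c("n_retention", "p_retention", "grazing_share", "mcf",
                "mms_volat_frac")) {
    i <- which(as_[[col]] < 0 | as_[[col]] > 1)
    for (k in i) bad("AnimalSystem", as_$system[k],
                     sprintf("%s must lie in [0, 1]", col))
  }
  i <- which(!as_$ruminant & !is.na(as_$ym))
  for (k in i) bad("AnimalSystem", as_$system[k],
                   "Ym may only be set for ruminant systems")
  i <- which(as_$ruminant & (is.na(as_$ym) | as_$ym < 0 | as_$ym > 100))
  for (k in i) bad("AnimalSystem", as_$system[k],
                   "ruminant Ym must lie in [0, 100] percent")
  i <- which(!as_$product %in% fo$food)
  for (k in i) bad("AnimalSystem", as_$system[k],
                   "product reference does not resolve")

  fe <- instance$feeds
  for (col in c("dm_frac", "dig_om")) {
    i <- which(fe[[col]] < 0 | fe[[col]] > 1)
    for (k in i) bad("FeedItem", fe$feed[k], sprintf("%s must lie in [0, 1]", col))
  }
  for (col in c("energy_mj_kg", "dig_protein_g_kg", "n_g_kg", "p_g_kg")) {
    i <- which(fe[[col]] < 0)
    for (k in i) bad("FeedItem", fe$feed[k], sprintf("%s must be >= 0", col))
  }
  ## ruminants must never be allowed to eat food losses or waste
  rum_species <- unique(as_$species[as_$ruminant])
  for (k in which(fe$origin == "food_waste")) {
    for (sp in rum_species) {
      if (feed_allowed(instance, fe$feed[k], sp))
        bad("FeedItem", fe$feed[k],
            sprintf("food-waste feed must be illegal for ruminant species '%s'", sp))
    }
  }

  sw <- instance$stage_waste
  for (col in c("post_harvest", "processing", "distribution", "consumption")) {
    i <- which(sw[[col]] < 0 | sw[[col]] >= 1)
    for (k in i) bad("StageWaste", sw$food[k],
                     sprintf("%s fraction must lie in [0, 1)", col))
  }
  i <- which(!sw$food %in% fo$food)
  for (k in i) bad("StageWaste", sw$food[k], "food reference does not resolve")
  i <- which(!fo$food %in% sw$food)
  for (k in i) bad("Food", fo$food[k], "food has no stage-waste fractions")

  rp <- instance$residual_params
  for (nm in c("waste_to_feed_frac", "sludge_use_frac", "sludge_n_frac",
               "sludge_p_frac")) {
    x <- rp[[nm]]
    if (is.null(x) || x < 0 || x > 1)
      bad("ResidualParams", nm, "fraction must lie in [0, 1]")
  }
  if ((rp$compost_cn %||% -1) <= 0)
    bad("ResidualParams", "compost_cn", "C:N ratio must be > 0")

  fs <- instance$fish_stocks
  i <- which(fs$msy_t < 0 | fs$edible_frac < 0 | fs$edible_frac > 1)
  for (k in i) bad("FishStock", fs$stock[k],
                   "msy must be >= 0 and edible fraction in [0, 1]")
  fq <- instance$fish_quota
  if (nrow(fq)) {
    i <- which(!fq$stock %in% fs$stock)
    for (k in i) bad("FishQuota", paste(fq$stock[k], fq$country[k]),
                     "stock reference does not resolve")
    agg <- tapply(fq$share, fq$stock, sum)
    for (nm in names(agg)[agg > 1 + 1e-9])
      bad("FishQuota", nm, "country quota shares must sum to <= 1")
  }

  ec <- instance$emission_constants
  for (nm in c("ch4_energy_mj_kg", "ch4_m3_to_kg", "gwp_ch4", "gwp_n2o",
               "ef_transport", "transport_cap_co2e")) {
    if ((ec[[nm]] %||% -1) <= 0)
      bad("EmissionConstants", nm, "constant must be > 0")
  }

  cu <- instance$current
  if (!is.null(cu)) {
    i <- which(!cu$areas$crop %in% cr$crop)
    for (k in i) bad("Current", cu$areas$crop[k],
                     "current-area crop reference does not resolve")
    i <- which(!cu$areas$zone %in% zs$zone)
    for (k in i) bad("Current", cu$areas$zone[k],
                     "current-area zone reference does not resolve")
  }

  if (length(v) == 0)
    data.frame(type = character(), id = character(), rule = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, v)
}

assert_valid_instance <- function(instance) {
  rep <- validate_instance(instance)
  if (nrow(rep) > 0)
    stop_cf("invalid instance: %s", paste(sprintf("[%s %s] %s", rep$type,
                                                  rep$id, rep$rule),
                                          collapse = "; "))
  invisible(instance)
}
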