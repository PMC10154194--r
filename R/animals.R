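## Farmed-animal and fishery computations. A "producing unit" is the herd
## slice that delivers one tonne of primary product (milk, carcass weight,
## eggs, fish) per year, including its share of parent and reproduction
## stock; requirements, intake capacity and outputs are all linear in the
## number of producing units.

#' Stock and requirement totals for a production target
#'
#' The full lifecycle is priced in: producing a tonne of product requires
#' the producing unit plus parent and reproduction units in fixed ratios,
#' and the nutrient requirements and intake capacities of all three stock
#' classes are summed.
#'
#' @param target_t target output, t product/yr (>= 0)
#' @param system one row of the instance `animal_systems` table
#' @return list with `producing_units`, `parent_units`, `repro_units`,
#'   `req_energy_mj`, `req_protein_kg`, `intake_t_dm`
#' @export
stock_requirements <- function(target_t, system) {
  if (target_t < 0) stop_cf("production target must be >= 0")
  aux <- system$parent_ratio + system$repro_ratio
  list(
    producing_units = target_t,
    parent_units = target_t * system$parent_ratio,
    repro_units = target_t * system$repro_ratio,
    req_energy_mj = target_t * (system$req_energy_mj + aux * system$aux_req_energy_mj),
    req_protein_kg = target_t * (system$req_protein_kg + aux * system$aux_req_protein_kg),
    intake_t_dm = target_t * (system$intake_t_dm + aux * system$aux_intake_t_dm)
  )
}

## per-unit requirement totals including auxiliary stock
unit_requirements <- function(system) {
  r <- stock_requirements(1, system)
  c(energy_mj = r$req_energy_mj, protein_kg = r$req_protein_kg,
    intake_t_dm = r$intake_t_dm)
}

## nutrient delivery of one t (as fed) of a feed item to a species
feed_delivery <- function(frow, fish) {
  if (fish)
    c(energy_mj = 1000 * frow$energy_mj_kg_fish,
      protein_kg = frow$dig_protein_g_kg_fish,
      dm_t = frow$dm_frac,
      n_kg = frow$n_g_kg, p_kg = frow$p_g_kg)
  else
    c(energy_mj = 1000 * frow$energy_mj_kg,
      protein_kg = frow$dig_protein_g_kg,
      dm_t = frow$dm_frac,
      n_kg = frow$n_g_kg, p_kg = frow$p_g_kg)
}

#' Check a feed ration against a herd's requirements
#'
#' A ration is feasible iff it (a) delivers at least the energy and
#' digestible-protein requirement of the full stock (producing plus
#' auxiliary animals), (b) fits within the herd's dry-matter intake
#' capacity, and (c) contains only feed items legal for the species — food
#' losses and waste are never legal for ruminants. Fish systems are
#' evaluated with the fish-specific feed composition.
#'
#' @param ration named numeric vector, t as-fed per feed item per year
#' @param system one row of `animal_systems`
#' @param target_t production the ration must support, t product/yr
#' @param instance a `food_system_instance`
#' @return data.frame of violations (`rule`, `detail`, `required`,
#'   `delivered`); empty iff the ration is feasible
#' @export
ration_check <- function(ration, system, target_t, instance) {
  unknown <- setdiff(names(ration), instance$feeds$feed)
  if (length(unknown) > 0)
    stop_cf("unknown feed item(s): %s", paste(unknown, collapse = ", "))
  need <- stock_requirements(target_t, system)
  got <- c(energy_mj = 0, protein_kg = 0, dm_t = 0)
  out <- list()
  for (f in names(ration)) {
    frow <- feed_row(instance, f)
    if (!feed_allowed(instance, f, system$species))
      out[[length(out) + 1]] <- data.frame(
        rule = "illegal_feed",
        detail = sprintf("feed '%s' is not legal for species '%s'", f,
                         system$species),
        required = 0, delivered = ration[[f]])
    d <- feed_delivery(frow, isTRUE(system$fish))
    got <- got + ration[[f]] * d[c("energy_mj", "protein_kg", "dm_t")]
  }
  tol <- 1e-9 * (1 + abs(need$req_energy_mj))
  if (got[["energy_mj"]] < need$req_energy_mj - tol)
    out[[length(out) + 1]] <- data.frame(
      rule = "nutrient_shortfall", detail = "energy",
      required = need$req_energy_mj, delivered = got[["energy_mj"]])
  tol <- 1e-9 * (1 + abs(need$req_protein_kg))
  if (got[["protein_kg"]] < need$req_protein_kg - tol)
    out[[length(out) + 1]] <- data.frame(
      rule = "nutrient_shortfall", detail = "digestible_protein",
      required = need$req_protein_kg, delivered = got[["protein_kg"]])
  tol <- 1e-9 * (1 + abs(need$intake_t_dm))
  if (got[["dm_t"]] > need$intake_t_dm + tol)
    out[[length(out) + 1]] <- data.frame(
      rule = "intake_capacity", detail = "dry matter",
      required = need$intake_t_dm, delivered = got[["dm_t"]])
  if (length(out) == 0)
    data.frame(rule = character(), detail = character(),
               required = numeric(), delivered = numeric())
  else do.call(rbind, out)
}

#' Product output and nutrient totals of a herd
#'
#' @param producing_units number of producing units (t product/yr capacity)
#' @param system one row of `animal_systems`
#' @param instance a `food_system_instance`
#' @return list with `product_t`, `byproduct_t` (slaughter by-products
#'   available as feed) and `nutrients` (total nutrient content of the
#'   product, composition x mass)
#' @export
animal_outputs <- function(producing_units, system, instance) {
  if (producing_units < 0) stop_cf("producing units must be >= 0")
  product_t <- producing_units  # one unit == 1 t product/yr
  comp <- comp_matrix(instance)[system$product, ]
  list(product_t = product_t,
       byproduct_t = product_t * system$byproduct_frac,
       nutrients = comp * product_t * 1000)  # per kg x kg
}

#' Manure excretion split between management system and pasture
#'
#' Excretion is intake minus retention in product; the grazing share of a
#' ruminant herd deposits its excreta directly on grassland while the rest
#' is captured in the manure management system (MMS). Volatile solids are
#' computed from the dry matter and organic-matter digestibility of the
#' realized ration.
#'
#' @param n_intake_kg,p_intake_kg nutrient intake of the herd, kg/yr
#' @param n_retention,p_retention fractions of intake retained in product,
#'   in \[0, 1\]
#' @param grazing_share fraction of excreta deposited on grassland
#' @param dm_intake_t ration dry matter, t/yr
#' @param dig_om mean organic-matter digestibility of the ration
#' @param ash_frac ash fraction of excreted dry matter (default 0.08)
#' @return list with `n_excreted_kg`, `p_excreted_kg`, `n_mms_kg`,
#'   `p_mms_kg`, `n_pasture_kg`, `p_pasture_kg`, `vs_kg`
#' @export
manure_excretion <- function(n_intake_kg, p_intake_kg, n_retention,
                             p_retention, grazing_share, dm_intake_t,
                             dig_om, ash_frac = 0.08) {
  if (n_retention < 0 || n_retention > 1 || p_retention < 0 || p_retention > 1)
    stop_cf("retention fractions must lie in [0, 1]")
  if (grazing_share < 0 || grazing_share > 1)
    stop_cf("grazing share must lie in [0, 1]")
  n_ex <- n_intake_kg * (1 - n_retention)
  p_ex <- p_intake_kg * (1 - p_retention)
  vs <- dm_intake_t * 1000 * (1 - dig_om) * (1 - ash_frac)
  list(n_excreted_kg = n_ex, p_excreted_kg = p_ex,
       n_mms_kg = n_ex * (1 - grazing_share),
       p_mms_kg = p_ex * (1 - grazing_share),
       n_pasture_kg = n_ex * grazing_share,
       p_pasture_kg = p_ex * grazing_share,
       vs_kg = vs)
}

#' Capture-fishery supply under MSY caps
#'
#' Landings per stock are clipped to the maximum sustainable yield times
#' the country's quota share; the edible fraction becomes food and the
#' remainder feed-eligible fish by-product.
#'
#' @param quotas data.frame (`stock`, `country`, `requested_t`)
#' @param instance a `food_system_instance`
#' @return data.frame (`stock`, `country`, `landed_t`, `edible_t`,
#'   `byproduct_t`, `clipped`)
#' @export
fishery_supply <- function(quotas, instance) {
  if (any(quotas$requested_t < 0)) stop_cf("fishery quotas must be >= 0")
  fs <- instance$fish_stocks
  out <- quotas
  out$landed_t <- out$edible_t <- out$byproduct_t <- numeric(nrow(out))
  out$clipped <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    j <- match(out$stock[i], fs$stock)
    if (is.na(j)) stop_cf("unknown fish stock '%s'", out$stock[i])
    q <- instance$fish_quota
    k <- which(q$stock == out$stock[i] & q$country == out$country[i])
    share <- if (length(k)) q$share[k[1]] else 0
    cap <- fs$msy_t[j] * share
    landed <- min(out$requested_t[i], cap)
    if (out$requested_t[i] > cap + 1e-9) {
      out$clipped[i] <- TRUE
      warning(sprintf("requested landings of stock '%s' in '%s' exceed the MSY quota (%.3f > %.3f t); clipped",
                      out$stock[i], out$country[i], out$requested_t[i], cap),
              call. = FALSE)
    }
    out$landed_t[i] <- landed
    out$edible_t[i] <- landed * fs$edible_frac[j]
    out$byproduct_t[i] <- landed * (1 - fs$edible_frac[j])
  }
  out
}
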