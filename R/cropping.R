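## Cropping and fertilization: rotation-share caps, zone suitability,
## nutrient removal in harvest plus aboveground residues, and the N/P
## fertilizer requirement and supply balance.
##
## Crop residues stay on the field and are never exported as feed or
## fertilizer; their nutrients are nevertheless part of the removal and
## hence of the fertilizer requirement (the crop must regrow them each
## season under the assumed long-term soil equilibrium).

#' Maximum annual area share from a rotation frequency
#'
#' A crop grown at most once in k years occupies at most 1/k of the
#' cropland on a yearly-average basis; e.g. a 1-in-4 rotation gives a 0.25
#' area share, and a 1-in-6 crop such as sunflower 1/6.
#'
#' @param rotation_years integer k >= 1 (k = 1 means monoculture allowed)
#' @return fraction in (0, 1]
#' @export
rotation_share <- function(rotation_years) {
  if (any(rotation_years < 1)) stop_cf("rotation_years must be >= 1")
  1 / rotation_years
}

#' Crops cultivable in a zone, with their binding area caps
#'
#' A crop is suitable only where it has a yield entry. Its cap is the
#' rotation share times the zone's cropland; crops flagged as
#' acreage-capped (rice, minor crops) may in addition not exceed their
#' current acreage in the zone, and the binding cap is the minimum of the
#' two.
#'
#' @param zone zone id
#' @param instance a `food_system_instance`
#' @return data.frame (`crop`, `yield_t_ha`, `cap_ha`)
#' @export
suitable_crops <- function(zone, instance) {
  zr <- zone_row(instance, zone)
  ys <- instance$yields[instance$yields$zone == zone, , drop = FALSE]
  ys <- ys[ys$yield_t_ha > 0, , drop = FALSE]
  if (nrow(ys) == 0)
    return(data.frame(crop = character(), yield_t_ha = numeric(),
                      cap_ha = numeric()))
  caps <- numeric(nrow(ys))
  for (i in seq_len(nrow(ys))) {
    cr <- crop_row(instance, ys$crop[i])
    cap <- rotation_share(cr$rotation_years) * zr$cropland_ha
    if (isTRUE(cr$acreage_capped)) {
      cur <- instance$current$areas
      j <- which(cur$crop == ys$crop[i] & cur$zone == zone)
      cap <- min(cap, if (length(j)) sum(cur$area_ha[j]) else 0)
    }
    caps[i] <- cap
  }
  data.frame(crop = ys$crop, yield_t_ha = ys$yield_t_ha, cap_ha = caps,
             stringsAsFactors = FALSE)
}

#' N and P removal by a crop (harvest plus aboveground residues)
#'
#' removal = area x yield x (product concentration + residue ratio x
#' residue concentration), per nutrient; linear in area.
#'
#' @param crop crop id
#' @param zone zone id (the crop must be suitable there)
#' @param area_ha cultivated area, ha
#' @param instance a `food_system_instance`
#' @return named vector `c(N_kg, P_kg)`
#' @export
crop_nutrient_removal <- function(crop, zone, area_ha, instance) {
  y <- yield_of(instance, crop, zone)
  if (is.na(y)) stop_cf("crop '%s' is unsuitable in zone '%s'", crop, zone)
  cr <- crop_row(instance, crop)
  harvest <- area_ha * y
  c(N_kg = harvest * (cr$n_conc_product + cr$residue_ratio * cr$n_conc_residue),
    P_kg = harvest * (cr$p_conc_product + cr$residue_ratio * cr$p_conc_residue))
}

## composite N loss multiplier used in the requirement (volatilization at
## the synthetic-fertilizer fraction plus leaching/run-off in wet climates)
n_loss_multiplier <- function(instance, climate) {
  ec <- instance$emission_constants
  leach <- if (climate == "wet") ec$n_leach_frac_wet else ec$n_leach_frac_dry
  1 + ec$n_volat_frac_synthetic + leach
}

#' N and P fertilizer requirement of a cultivated area
#'
#' P requirement is the P removal inflated by the unavoidable loss
#' fraction (default 12.5%, i.e. x1.125). N requirement inflates the N
#' removal by volatilization plus climate-dependent leaching/run-off
#' fractions, so N requirement >= N removal always.
#'
#' @inheritParams crop_nutrient_removal
#' @return named vector `c(N_kg, P_kg)`
#' @export
fertilizer_requirement <- function(crop, zone, area_ha, instance) {
  rem <- crop_nutrient_removal(crop, zone, area_ha, instance)
  zr <- zone_row(instance, zone)
  ec <- instance$emission_constants
  c(N_kg = unname(rem["N_kg"]) * n_loss_multiplier(instance, zr$climate),
    P_kg = unname(rem["P_kg"]) * (1 + ec$p_unavoidable_loss))
}

#' Fertilizer supply-vs-requirement balance
#'
#' Checks that applications from the five admissible sources (by-products
#' via compost, manure, compost, human excreta and artificial fertilizer)
#' meet the N and P requirement of every (crop, zone). Organic sources
#' deliver N and P in their fixed N:P ratio and are fully plant-available;
#' each application row may state N only, in which case P is derived from
#' the source ratio.
#'
#' @param applications data.frame (`source`, `crop`, `zone`, `n_kg`,
#'   optionally `p_kg`)
#' @param requirements data.frame (`crop`, `zone`, `n_req_kg`, `p_req_kg`)
#' @param instance a `food_system_instance` (supplies the N:P ratios)
#' @return data.frame of deficits per (crop, zone, nutrient); empty iff the
#'   requirement is met everywhere
#' @export
fertilizer_supply_balance <- function(applications, requirements, instance) {
  ok_sources <- c("artificial", "manure", "compost", "sludge", "byproduct")
  bad <- setdiff(unique(applications$source), ok_sources)
  if (length(bad) > 0)
    stop_cf("unknown fertilizer source(s): %s", paste(bad, collapse = ", "))
  if (any(applications$n_kg < 0))
    stop_cf("fertilizer applications must be >= 0")
  npr <- instance$residual_params$organic_np
  if (is.null(applications$p_kg)) {
    applications$p_kg <- ifelse(
      applications$source == "artificial", 0,
      applications$n_kg / npr[applications$source])
  }
  out <- list()
  for (i in seq_len(nrow(requirements))) {
    sel <- applications$crop == requirements$crop[i] &
      applications$zone == requirements$zone[i]
    n_got <- sum(applications$n_kg[sel])
    p_got <- sum(applications$p_kg[sel])
    if (n_got < requirements$n_req_kg[i] - 1e-6)
      out[[length(out) + 1]] <- data.frame(
        crop = requirements$crop[i], zone = requirements$zone[i],
        nutrient = "N", required_kg = requirements$n_req_kg[i],
        applied_kg = n_got, deficit_kg = requirements$n_req_kg[i] - n_got)
    if (p_got < requirements$p_req_kg[i] - 1e-6)
      out[[length(out) + 1]] <- data.frame(
        crop = requirements$crop[i], zone = requirements$zone[i],
        nutrient = "P", required_kg = requirements$p_req_kg[i],
        applied_kg = p_got, deficit_kg = requirements$p_req_kg[i] - p_got)
  }
  if (length(out) == 0)
    data.frame(crop = character(), zone = character(), nutrient = character(),
               required_kg = numeric(), applied_kg = numeric(),
               deficit_kg = numeric())
  else do.call(rbind, out)
}
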