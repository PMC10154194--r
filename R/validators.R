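## Solution validators. Every constraint family of the optimization
## problem can be re-checked on an extracted solution, independently of
## the LP algebra: the checks below recompute balances from the solution
## tables. check_solution() returns an empty data.frame exactly when the
## solution is feasible for its scenario.

viol_df <- function() data.frame(family = character(), id = character(),
                                 detail = character(),
                                 stringsAsFactors = FALSE)

#' Re-check a solution against every constraint family
#'
#' Recomputes, from the solution tables alone: land and rotation caps,
#' production-vs-flow balances per food and country, feed legality (no
#' food waste to ruminants), the waste-to-feed share cap, in-country-use
#' rules for grass and food waste, herd feed requirements, fertilizer
#' requirements versus applications, fishery MSY caps, nutrient and
#' food-group bounds (healthy-diet scenarios), protein-supply matching
#' (supply-side scenarios) and the per-capita transport-emission cap.
#'
#' @param solution a `food_system_solution`
#' @param rel_tol relative feasibility tolerance
#' @return data.frame (`family`, `id`, `detail`); zero rows iff feasible
#' @export
check_solution <- function(solution, rel_tol = 1e-6) {
  inst <- solution$instance
  sc <- solution$config
  out <- viol_df()
  bad <- function(family, id, detail) {
    out[nrow(out) + 1, ] <<- list(family, id, detail)
  }
  tol <- function(x) rel_tol * (1 + abs(x))

  ## land + rotation caps
  zones <- inst$zones
  for (zi in seq_len(nrow(zones))) {
    z <- zones$zone[zi]
    used <- sum(solution$area$area_ha[solution$area$zone == z])
    if (used > zones$cropland_ha[zi] + tol(zones$cropland_ha[zi]))
      bad("land", z, sprintf("cropland used %.2f > available %.2f", used,
                             zones$cropland_ha[zi]))
    g <- solution$grassland$grassland_used_ha[solution$grassland$zone == z]
    g <- if (length(g)) g[1] else 0
    gmax <- grassland_ha(zones[zi, ])
    if (g > gmax + tol(gmax))
      bad("land", z, sprintf("grassland used %.2f > available %.2f", g, gmax))
    sv <- suitable_crops(z, inst)
    for (k in seq_len(nrow(sv))) {
      a <- solution$area$area_ha[solution$area$zone == z &
                                   solution$area$crop == sv$crop[k]]
      a <- if (length(a)) sum(a) else 0
      if (a > sv$cap_ha[k] + tol(sv$cap_ha[k]))
        bad("rotation_cap", paste(sv$crop[k], z, sep = "/"),
            sprintf("area %.2f > cap %.2f", a, sv$cap_ha[k]))
    }
  }
  for (k in seq_len(nrow(solution$area))) {
    if (is.na(yield_of(inst, solution$area$crop[k], solution$area$zone[k])) &&
        solution$area$area_ha[k] > 0)
      bad("suitability", paste(solution$area$crop[k], solution$area$zone[k],
                               sep = "/"), "area on unsuitable zone")
  }

  ## production balance: flows out of a country cannot exceed production
  w4 <- vapply(inst$foods$food, function(f) waste_row(inst, f)$consumption,
               numeric(1))
  systems <- inst$animal_systems
  for (cc in inst$countries$country) {
    for (fi in seq_len(nrow(inst$foods))) {
      f <- inst$foods$food[fi]
      outflow <- sum(solution$flows$t_supply[solution$flows$food == f &
                                               solution$flows$from == cc])
      prodn <- 0
      if (inst$foods$source[fi] == "crop") {
        sel <- solution$area$crop == f &
          solution$area$zone %in% zones$zone[zones$country == cc]
        for (k in which(sel))
          prodn <- prodn + solution$area$area_ha[k] *
            yield_of(inst, f, solution$area$zone[k]) *
            supply_per_harvest(inst, f)
      } else if (inst$foods$source[fi] == "animal") {
        w <- waste_row(inst, f)
        ss <- systems$system[systems$product == f]
        u <- sum(solution$animals$producing_units[
          solution$animals$system %in% ss & solution$animals$country == cc])
        prodn <- u * (1 - w$processing) * (1 - w$distribution)
      } else {
        L <- solution$fishland$landed_t[solution$fishland$country == cc]
        L <- if (length(L)) L[1] else 0
        q <- inst$fish_quota[inst$fish_quota$country == cc, ]
        msy_c <- sum(inst$fish_stocks$msy_t[match(q$stock,
                                                  inst$fish_stocks$stock)] *
                       q$share)
        ebar <- if (msy_c > 0)
          sum(inst$fish_stocks$msy_t[match(q$stock, inst$fish_stocks$stock)] *
                q$share * inst$fish_stocks$edible_frac[
                  match(q$stock, inst$fish_stocks$stock)]) / msy_c else 0
        w <- waste_row(inst, f)
        prodn <- L * ebar * (1 - w$post_harvest) * (1 - w$processing) *
          (1 - w$distribution)
      }
      if (outflow > prodn + tol(prodn))
        bad("production_balance", paste(f, cc, sep = "/"),
            sprintf("flows out %.3f > production %.3f", outflow, prodn))
    }
    ## fishery cap
    L <- solution$fishland$landed_t[solution$fishland$country == cc]
    L <- if (length(L)) L[1] else 0
    q <- inst$fish_quota[inst$fish_quota$country == cc, ]
    msy_c <- if (nrow(q)) sum(inst$fish_stocks$msy_t[
      match(q$stock, inst$fish_stocks$stock)] * q$share) else 0
    if (L > msy_c + tol(msy_c))
      bad("fishery_cap", cc, sprintf("landings %.2f > MSY quota %.2f", L,
                                     msy_c))
  }

  ## feed legality, ruminant waste ban, waste share cap, in-country rules
  fa <- solution$feed_alloc
  for (k in seq_len(nrow(fa))) {
    j <- match(fa$system[k], systems$system)
    if (!feed_allowed(inst, fa$feed[k], systems$species[j]) &&
        fa$t_as_fed[k] > 0)
      bad("feed_legality", paste(fa$feed[k], fa$system[k], sep = "/"),
          "illegal feed item in ration")
    fr <- feed_row(inst, fa$feed[k])
    if (fr$origin == "food_waste" && isTRUE(systems$ruminant[j]) &&
        fa$t_as_fed[k] > 0)
      bad("feed_legality", paste(fa$feed[k], fa$system[k], sep = "/"),
          "food waste fed to a ruminant")
  }
  for (cc in inst$countries$country) {
    inflow <- solution$flows[solution$flows$to == cc, , drop = FALSE]
    waste_t <- sum(inflow$t_supply * w4[inflow$food])
    fed <- sum(fa$t_as_fed[fa$feed == "food_waste" & fa$country == cc])
    capw <- inst$residual_params$waste_to_feed_frac * waste_t
    if (fed > capw + tol(capw))
      bad("waste_availability", cc,
          sprintf("waste fed %.3f > %.0f%% of consumption waste %.3f", fed,
                  100 * inst$residual_params$waste_to_feed_frac, waste_t))
  }
  ntf <- inst$feeds$feed[!inst$feeds$tradeable]
  if (nrow(solution$feed_flows)) {
    ff <- solution$feed_flows
    sel <- ff$feed %in% ntf & ff$from != ff$to & ff$t_as_fed > 0
    for (k in which(sel))
      bad("in_country_use", ff$feed[k],
          sprintf("non-tradeable feed moved %s -> %s", ff$from[k], ff$to[k]))
  }

  ## herd requirements via ration_check
  for (j in seq_len(nrow(systems))) {
    for (cc in inst$countries$country) {
      u <- sum(solution$animals$producing_units[
        solution$animals$system == systems$system[j] &
          solution$animals$country == cc])
      rows <- fa[fa$system == systems$system[j] & fa$country == cc, ,
                 drop = FALSE]
      if (u <= 0 && nrow(rows) == 0) next
      ## numerical crumbs (sub-gram herds and rations) are not herds
      if (u < 1e-5 && sum(rows$t_as_fed) < 1e-3) next
      ration <- stats::setNames(rows$t_as_fed, rows$feed)
      rc <- ration_check(ration, systems[j, ], u, inst)
      for (r in seq_len(nrow(rc))) {
        ## ignore solver-roundoff-sized margins
        rel <- abs(rc$required[r] - rc$delivered[r]) /
          max(abs(rc$required[r]), 1e-9)
        if (rc$rule[r] != "illegal_feed" && rel <= 1e-4) next
        bad("feed_requirement", paste(systems$system[j], cc, sep = "/"),
            sprintf("%s: %s (required %.4g, delivered %.4g)", rc$rule[r],
                    rc$detail[r], rc$required[r], rc$delivered[r]))
      }
    }
  }

  ## fertilizer balance per zone
  reqs <- list()
  for (k in seq_len(nrow(solution$area))) {
    r <- fertilizer_requirement(solution$area$crop[k], solution$area$zone[k],
                                solution$area$area_ha[k], inst)
    reqs[[k]] <- data.frame(crop = solution$area$crop[k],
                            zone = solution$area$zone[k],
                            n_req_kg = r[["N_kg"]], p_req_kg = r[["P_kg"]])
  }
  if (length(reqs)) {
    reqz <- do.call(rbind, reqs)
    nreq <- tapply(reqz$n_req_kg, reqz$zone, sum)
    preq <- tapply(reqz$p_req_kg, reqz$zone, sum)
    for (z in names(nreq)) {
      fz <- solution$fertilizer[solution$fertilizer$zone == z, , drop = FALSE]
      n_got <- sum(fz$n_kg); p_got <- sum(fz$p_kg)
      if (n_got < nreq[[z]] - tol(nreq[[z]]))
        bad("fertilizer_balance", z,
            sprintf("N applied %.2f < required %.2f", n_got, nreq[[z]]))
      if (p_got < preq[[z]] - tol(preq[[z]]))
        bad("fertilizer_balance", z,
            sprintf("P applied %.2f < required %.2f", p_got, preq[[z]]))
    }
  }

  ## diet-side families
  comp <- inst$composition
  grp <- stats::setNames(inst$foods$food_group, inst$foods$food)
  if (sc$diet_mode == "efsa_eat" && nrow(solution$diet)) {
    for (cc in unique(solution$diet$country)) {
      dd <- solution$diet[solution$diet$country == cc, ]
      intake <- stats::setNames(dd$intake_g_cap_day, dd$food)
      nv <- diet_nutrients(intake, comp)
      nb <- nutrient_bound_violations(nv, inst$nutrients)
      ## scale-aware re-check: the LP works on annual country totals, so
      ## re-test marginal violations at the LP's own tolerance
      for (r in seq_len(nrow(nb))) {
        rel <- abs(nb$value[r] - nb$limit[r]) / max(nb$limit[r], 1e-9)
        if (rel > rel_tol * 100)
          bad("nutrition", paste(nb$nutrient[r], cc, sep = "/"),
              sprintf("%s bound %.4g, value %.4g", nb$bound[r], nb$limit[r],
                      nb$value[r]))
      }
      fg <- food_group_violations(intake, inst$food_group_bounds,
                                  grp, comp)
      for (r in seq_len(nrow(fg))) {
        rel <- abs(fg$value[r] - fg$limit[r]) / max(fg$limit[r], 1e-9)
        if (rel > rel_tol * 100)
          bad("food_group", paste(fg$group[r], cc, sep = "/"),
              sprintf("%s bound %.4g, value %.4g", fg$bound[r], fg$limit[r],
                      fg$value[r]))
      }
    }
  }
  if (sc$diet_mode == "current_protein") {
    delivered <- list()
    for (cc in unique(solution$diet$country)) {
      dd <- solution$diet[solution$diet$country == cc, ]
      p <- dd$supply_g_cap_day *
        comp[match(dd$food, comp$food), "protein"] / 1000
      agg <- tapply(p, grp[dd$food], sum)
      delivered[[length(delivered) + 1]] <-
        data.frame(country = cc, group = names(agg),
                   g_protein_cap_day = as.numeric(agg))
    }
    delivered <- do.call(rbind, delivered)
    sh <- protein_supply_match(delivered, inst$current$supply_protein)
    for (r in seq_len(nrow(sh)))
      if (sh$shortfall_frac[r] > rel_tol * 100)
        bad("protein_match", paste(sh$group[r], sh$country[r], sep = "/"),
            sprintf("delivered %.4g < required %.4g", sh$delivered[r],
                    sh$required[r]))
  }

  ## transport cap
  ec <- inst$emission_constants
  dist <- country_dist_km(inst)
  tf <- rbind(
    data.frame(from = solution$flows$from, to = solution$flows$to,
               t = solution$flows$t_supply),
    data.frame(from = solution$feed_flows$from, to = solution$feed_flows$to,
               t = solution$feed_flows$t_as_fed))
  tf <- tf[tf$from != tf$to & tf$t > 0, , drop = FALSE]
  pop <- stats::setNames(inst$countries$population *
                           solution$population_multiplier,
                         inst$countries$country)
  tr <- transport_emissions(tf, dist, ec$ef_transport, population = pop,
                            cap = ec$transport_cap_co2e)
  for (cc in tr$violations)
    bad("transport_cap", cc,
        sprintf("per-capita transport emissions %.1f > cap %.0f",
                tr$per_capita[[cc]], ec$transport_cap_co2e))

  out
}

#' Full biomass flow ledger of a solution
#'
#' One row per (commodity, origin, use, destination): food supply flows,
#' feed allocations, feed trade, by-product composting and fishery
#' landings, in t/yr. Used for conservation accounting and export.
#'
#' @param solution a `food_system_solution`
#' @return data.frame (`commodity`, `origin`, `use`, `destination`, `t`)
#' @export
flow_ledger <- function(solution) {
  led <- list()
  f <- solution$flows
  if (nrow(f)) led[[length(led) + 1]] <-
    data.frame(commodity = f$food, origin = f$from, use = "food",
               destination = f$to, t = f$t_supply)
  fa <- solution$feed_alloc
  if (nrow(fa)) led[[length(led) + 1]] <-
    data.frame(commodity = fa$feed, origin = fa$country,
               use = paste0("feed:", fa$system), destination = fa$country,
               t = fa$t_as_fed)
  ff <- solution$feed_flows
  if (nrow(ff)) led[[length(led) + 1]] <-
    data.frame(commodity = ff$feed, origin = ff$from, use = "feed_trade",
               destination = ff$to, t = ff$t_as_fed)
  bc <- solution$byproduct_compost
  if (nrow(bc)) led[[length(led) + 1]] <-
    data.frame(commodity = bc$feed, origin = bc$country, use = "compost",
               destination = bc$country, t = bc$t_composted)
  fl <- solution$fishland
  if (nrow(fl)) led[[length(led) + 1]] <-
    data.frame(commodity = "fish_landings", origin = fl$country,
               use = "landings", destination = fl$country, t = fl$landed_t)
  if (length(led)) do.call(rbind, led) else
    data.frame(commodity = character(), origin = character(),
               use = character(), destination = character(), t = numeric())
}
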