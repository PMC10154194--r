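## Solving and solution extraction. The solution object carries tabular
## views of every variable block plus the post-hoc greenhouse-gas
## inventory; emissions are computed from the solution, never optimized
## (only the transport cap enters the LP).

.solution_tol <- 1e-6

#' Solve a food-system scenario
#'
#' Builds the scenario LP and solves it. Deterministic: fixed variable
#' ordering and deterministic pivoting, so repeated solves return the
#' identical solution vector. On infeasibility the error lists the
#' constraint families present in the problem.
#'
#' @param instance a valid `food_system_instance`
#' @param scenario a `scenario_config` (default [scenario_cirhealth()])
#' @param ghg attach the greenhouse-gas inventory (default TRUE)
#' @return object of class `food_system_solution`
#' @export
solve_food_system <- function(instance, scenario = scenario_cirhealth(),
                              ghg = TRUE) {
  prob <- build_problem(instance, scenario)
  res <- simplex_lp(prob$obj, prob$A, prob$dir, prob$rhs,
                    maximize = prob$maximize)
  if (res$status == "infeasible")
    stop_cf("scenario '%s' is infeasible (phase-1 residual %.3g); constraint families: %s",
            scenario$name, res$phase1_residual %||% NA,
            paste(prob$families, collapse = ", "))
  if (res$status == "unbounded")
    stop_cf("scenario '%s' is unbounded in direction of variable '%s'",
            scenario$name, prob$vars[res$unbounded_col %||% NA] %||% "?")
  extract_solution(res, prob, ghg = ghg)
}

v_get <- function(x, name) if (name %in% names(x)) x[[name]] else 0

split_vars <- function(x, prefix, fields) {
  sel <- startsWith(names(x), paste0(prefix, "|"))
  if (!any(sel))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(fields) + 1)),
                           c(fields, "value")))
  parts <- strsplit(sub(paste0("^", prefix, "\\|"), "", names(x)[sel]),
                    "|", fixed = TRUE)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- fields
  df$value <- unname(x[sel])
  df
}

extract_solution <- function(res, prob, ghg = TRUE) {
  inst <- prob$instance
  sc <- prob$scenario
  x <- stats::setNames(res$x, prob$vars)
  x[abs(x) < .solution_tol] <- 0
  mu <- if ("mu" %in% names(x)) x[["mu"]] else 1
  pop <- stats::setNames(inst$countries$population, inst$countries$country)
  pop_fed <- sum(pop) * mu

  area <- split_vars(x, "area", c("crop", "zone"))
  names(area)[3] <- "area_ha"
  grassland <- split_vars(x, "gha", "zone")
  names(grassland)[2] <- "grassland_used_ha"
  animals <- split_vars(x, "units", c("system", "country"))
  names(animals)[3] <- "producing_units"
  flows <- split_vars(x, "flow", c("food", "from", "to"))
  names(flows)[4] <- "t_supply"
  feed_alloc <- split_vars(x, "x", c("feed", "system", "country"))
  names(feed_alloc)[4] <- "t_as_fed"
  feed_flows <- split_vars(x, "ff", c("feed", "from", "to"))
  names(feed_flows)[4] <- "t_as_fed"
  bcomp <- split_vars(x, "bcomp", c("feed", "country"))
  names(bcomp)[3] <- "t_composted"
  fishland <- split_vars(x, "fishland", "country")
  names(fishland)[2] <- "landed_t"

  orgn <- split_vars(x, "orgn", c("source", "zone"))
  names(orgn)[3] <- "n_kg"
  npr <- inst$residual_params$organic_np
  orgn$p_kg <- orgn$n_kg / npr[orgn$source]
  artn <- split_vars(x, "artn", "zone"); names(artn)[2] <- "n_kg"
  artp <- split_vars(x, "artp", "zone"); names(artp)[2] <- "p_kg"
  art <- merge(artn, artp, by = "zone", all = TRUE)
  fertilizer <- rbind(
    orgn[, c("source", "zone", "n_kg", "p_kg")],
    if (nrow(art)) data.frame(source = "artificial", zone = art$zone,
                              n_kg = art$n_kg %||% 0, p_kg = art$p_kg %||% 0))
  fertilizer <- fertilizer[fertilizer$n_kg + fertilizer$p_kg > 0, ,
                           drop = FALSE]

  ## per-country diet at supply and intake level, g per fed capita per day
  w4 <- vapply(inst$foods$food, function(f) waste_row(inst, f)$consumption,
               numeric(1))
  diet <- list()
  for (cc in inst$countries$country) {
    inflow <- flows[flows$to == cc, , drop = FALSE]
    if (nrow(inflow) == 0) next
    sup_t <- tapply(inflow$t_supply, inflow$food, sum)
    persons <- pop[[cc]] * mu
    for (f in names(sup_t)) {
      if (sup_t[[f]] <= 0) next
      gday <- sup_t[[f]] * 1e6 / (persons * 365)
      diet[[length(diet) + 1]] <- data.frame(
        country = cc, food = f,
        supply_g_cap_day = gday,
        intake_g_cap_day = gday * (1 - w4[[f]]))
    }
  }
  diet <- if (length(diet)) do.call(rbind, diet) else
    data.frame(country = character(), food = character(),
               supply_g_cap_day = numeric(), intake_g_cap_day = numeric())

  total_land <- sum(area$area_ha) + sum(grassland$grassland_used_ha)
  sol <- structure(list(
    scenario = sc$name, status = "optimal",
    objective_value = res$objective,
    population_fed = pop_fed, population_multiplier = mu,
    area = area, grassland = grassland, animals = animals, flows = flows,
    feed_alloc = feed_alloc, feed_flows = feed_flows,
    byproduct_compost = bcomp, fishland = fishland,
    fertilizer = fertilizer, diet = diet,
    total_land_ha = total_land,
    var = x, families = prob$families,
    instance = inst, config = sc), class = "food_system_solution")
  sol$ghg <- if (ghg) ghg_inventory(sol, inst) else
    list(inventory = data.frame(category = character(), gas = character(),
                                kg = numeric()),
         total_co2e_kg = NA_real_, co2e_kg_per_capita = NA_real_)
  sol
}

## herd-level feed intake summaries per (system, country)
herd_intakes <- function(sol, inst) {
  systems <- inst$animal_systems
  fa <- sol$feed_alloc
  out <- list()
  for (j in seq_len(nrow(systems))) {
    for (cc in inst$countries$country) {
      rows <- fa[fa$system == systems$system[j] & fa$country == cc, ,
                 drop = FALSE]
      if (nrow(rows) == 0 || sum(rows$t_as_fed) == 0) next
      e <- n <- p <- dmv <- vs <- 0
      for (k in seq_len(nrow(rows))) {
        fr <- feed_row(inst, rows$feed[k])
        d <- feed_delivery(fr, isTRUE(systems$fish[j]))
        t_ <- rows$t_as_fed[k]
        e <- e + t_ * d[["energy_mj"]]
        n <- n + t_ * fr$n_g_kg
        p <- p + t_ * fr$p_g_kg
        dmv <- dmv + t_ * fr$dm_frac
        vs <- vs + t_ * fr$dm_frac * 1000 * (1 - fr$dig_om) * (1 - 0.08)
      }
      out[[length(out) + 1]] <- data.frame(
        system = systems$system[j], country = cc, ge_mj = e, n_kg = n,
        p_kg = p, dm_t = dmv, vs_kg = vs)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(system = character(), country = character(), ge_mj = numeric(),
               n_kg = numeric(), p_kg = numeric(), dm_t = numeric(),
               vs_kg = numeric())
}

#' Greenhouse-gas inventory of a solution
#'
#' Computes the full post-hoc emission inventory by source category
#' (enteric fermentation, manure-management CH4 and N2O, grassland
#' deposition N2O, aquaculture N2O, fertilized-soil N2O, drained organic
#' soils, composting, artificial-fertilizer production, transport) and
#' aggregates to CO2e. Rice CH4 and soil/cropping CO2 are excluded by
#' design.
#'
#' @param solution a `food_system_solution`
#' @param instance the instance it was solved on
#' @return list with `inventory` (category, gas, kg), `total_co2e_kg`,
#'   `co2e_kg_per_capita`
#' @export
ghg_inventory <- function(solution, instance) {
  inst <- instance
  ec <- inst$emission_constants
  systems <- inst$animal_systems
  rows <- list()
  emit <- function(category, gas, kg) {
    rows[[length(rows) + 1]] <<- data.frame(category = category, gas = gas,
                                            kg = max(kg, 0))
  }

  hi <- herd_intakes(solution, inst)
  ent <- mms_ch4 <- mms_n2o <- graz_n2o <- aqua <- 0
  for (k in seq_len(nrow(hi))) {
    j <- match(hi$system[k], systems$system)
    sy <- systems[j, ]
    n_ex <- hi$n_kg[k] * (1 - sy$n_retention)
    if (isTRUE(sy$fish)) {
      aqua <- aqua + aquaculture_n2o(n_ex, ec$aquaculture_n2o_frac)
      next
    }
    if (isTRUE(sy$ruminant))
      ent <- ent + enteric_ch4(hi$ge_mj[k], sy$ym, ec$ch4_energy_mj_kg)
    n_mms <- n_ex * (1 - sy$grazing_share)
    n_past <- n_ex * sy$grazing_share
    vs_mms <- hi$vs_kg[k] * (1 - sy$grazing_share)
    mms_ch4 <- mms_ch4 + manure_ch4(vs_mms, sy$mcf, sy$b0, ec$ch4_m3_to_kg)
    mms_n2o <- mms_n2o + manure_n2o(n_mms, sy$ef_n2o_mms, sy$mms_volat_frac,
                                    ec$ef_volat_indirect)
    graz_n2o <- graz_n2o + grassland_n2o(n_past, ec)
  }
  emit("enteric", "CH4", ent)
  emit("manure_mgmt_CH4", "CH4", mms_ch4)
  emit("manure_N2O", "N2O", mms_n2o)
  emit("grassland_N2O", "N2O", graz_n2o)
  emit("aquaculture_N2O", "N2O", aqua)

  ## soils: applied N by source and zone
  soil <- org_soil <- 0
  fert <- solution$fertilizer
  for (zi in seq_len(nrow(inst$zones))) {
    z <- inst$zones$zone[zi]
    climate <- inst$zones$climate[zi]
    rowsz <- fert[fert$zone == z, , drop = FALSE]
    if (nrow(rowsz)) {
      byz <- tapply(rowsz$n_kg, rowsz$source, sum)
      soil <- soil + soil_n2o(as.list(byz), climate, ec)
    }
    if (inst$zones$soil[zi] == "organic") {
      a <- solution$area
      used <- sum(a$area_ha[a$zone == z])
      org_soil <- org_soil + soil_n2o(list(), climate, ec,
                                      organic_soil_ha = used)
    }
  }
  emit("soil_N2O", "N2O", soil)
  emit("organic_soil_N2O", "N2O", org_soil)

  ## composting: waste not fed plus by-products routed to compost
  comp_n <- 0
  if (isTRUE(solution$config$waste_to_compost_allowed)) {
    n_fw <- if ("food_waste" %in% inst$feeds$feed)
      feed_row(inst, "food_waste")$n_g_kg else 7
    w4 <- vapply(inst$foods$food, function(f) waste_row(inst, f)$consumption,
                 numeric(1))
    for (cc in inst$countries$country) {
      inflow <- solution$flows[solution$flows$to == cc, , drop = FALSE]
      waste_t <- sum(inflow$t_supply * w4[inflow$food])
      fed_t <- sum(solution$feed_alloc$t_as_fed[
        solution$feed_alloc$feed == "food_waste" &
          solution$feed_alloc$country == cc])
      comp_n <- comp_n + max(waste_t - fed_t, 0) * n_fw
    }
    bc <- solution$byproduct_compost
    for (k in seq_len(nrow(bc)))
      comp_n <- comp_n + bc$t_composted[k] * feed_row(inst, bc$feed[k])$n_g_kg
  }
  ce <- compost_emissions(comp_n, ec, inst$residual_params$compost_cn)
  emit("compost", "N2O", ce$n2o_kg)
  emit("compost", "CH4", ce$ch4_kg)

  art_n <- sum(fert$n_kg[fert$source == "artificial"])
  art_p <- sum(fert$p_kg[fert$source == "artificial"])
  emit("fertilizer_production", "CO2",
       fertilizer_production_emissions(art_n / 1000, art_p / 1000, ec))

  dist <- country_dist_km(inst)
  tf <- rbind(
    data.frame(from = solution$flows$from, to = solution$flows$to,
               t = solution$flows$t_supply),
    data.frame(from = solution$feed_flows$from, to = solution$feed_flows$to,
               t = solution$feed_flows$t_as_fed))
  tf <- tf[tf$from != tf$to & tf$t > 0, , drop = FALSE]
  tr <- transport_emissions(tf, dist, ec$ef_transport)
  emit("transport", "CO2", tr$co2e_kg)

  inventory <- do.call(rbind, rows)
  tot <- total_co2e(inventory, population = solution$population_fed,
                    gwp_ch4 = ec$gwp_ch4, gwp_n2o = ec$gwp_n2o)
  list(inventory = inventory, total_co2e_kg = tot$total_co2e_kg,
       co2e_kg_per_capita = tot$co2e_kg_per_capita)
}

#' @export
print.food_system_solution <- function(x, ...) {
  cat(sprintf("Solution for scenario '%s' (%s)\n", x$scenario, x$status))
  cat(sprintf("  objective: %.4g; population fed: %.3f million (multiplier %.3f)\n",
              x$objective_value, x$population_fed / 1e6,
              x$population_multiplier))
  cat(sprintf("  land: %.1f kha (%.1f kha cropland, %.1f kha grassland)\n",
              x$total_land_ha / 1e3, sum(x$area$area_ha) / 1e3,
              sum(x$grassland$grassland_used_ha) / 1e3))
  if (is.finite(x$ghg$total_co2e_kg))
    cat(sprintf("  GHG: %.3f Mt CO2e/yr (%.0f kg CO2e/capita/yr)\n",
                x$ghg$total_co2e_kg / 1e9, x$ghg$co2e_kg_per_capita))
  invisible(x)
}

#' @export
summary.food_system_solution <- function(object, ...) {
  x <- object
  print(x)
  inst <- x$instance
  grp <- stats::setNames(inst$foods$food_group, inst$foods$food)
  if (nrow(x$diet)) {
    cat("\nIntake by food group (g/capita/day, averaged over countries):\n")
    pop <- stats::setNames(inst$countries$population, inst$countries$country)
    w <- pop[x$diet$country] / sum(pop)
    agg <- tapply(x$diet$intake_g_cap_day * w, grp[x$diet$food], sum)
    print(round(agg[order(-agg)], 1))
  }
  if (nrow(x$ghg$inventory)) {
    cat("\nGHG inventory (kt CO2e/yr):\n")
    ec <- inst$emission_constants
    wgt <- c(CO2 = 1, CH4 = ec$gwp_ch4, N2O = ec$gwp_n2o)
    co2e <- tapply(x$ghg$inventory$kg * wgt[x$ghg$inventory$gas],
                   x$ghg$inventory$category, sum) / 1e6
    print(round(co2e[order(-co2e)], 2))
  }
  invisible(x)
}

#' @export
plot.food_system_solution <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  inst <- x$instance
  cg <- stats::setNames(inst$crops$food_group, inst$crops$crop)
  land <- tapply(x$area$area_ha, cg[x$area$crop], sum) / 1e3
  land <- c(land, grassland = sum(x$grassland$grassland_used_ha) / 1e3)
  graphics::barplot(land, las = 2, ylab = "kha",
                    main = paste(x$scenario, "land use"))
  ec <- inst$emission_constants
  wgt <- c(CO2 = 1, CH4 = ec$gwp_ch4, N2O = ec$gwp_n2o)
  co2e <- tapply(x$ghg$inventory$kg * wgt[x$ghg$inventory$gas],
                 x$ghg$inventory$category, sum) / 1e6
  graphics::barplot(co2e, las = 2, ylab = "kt CO2e/yr",
                    main = paste(x$scenario, "emissions"))
  invisible(x)
}
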