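## Scenario reports: solve a scenario and tabulate the quantities the
## analysis is about — land by crop group and land type, emissions by
## source, N and P applied by source, animal protein by species, nutrient
## intake against the reference bounds, and the population fed. Reports
## from two scenarios can be compared with percent changes.

#' Run a scenario end to end
#'
#' Solves the scenario and assembles the report tables. When a baseline
#' report is supplied, percent changes of land, emissions and animal
#' protein against it are included.
#'
#' @param instance a valid `food_system_instance`
#' @param config a `scenario_config`
#' @param baseline optional `scenario_report` to compare against
#' @return object of class `scenario_report`
#' @export
run_scenario <- function(instance, config, baseline = NULL) {
  sol <- solve_food_system(instance, config)
  inst <- instance
  cg <- stats::setNames(inst$crops$food_group, inst$crops$crop)
  land_by_group <- if (nrow(sol$area))
    tapply(sol$area$area_ha, cg[sol$area$crop], sum) else numeric(0)
  land <- data.frame(
    category = c(names(land_by_group), "grassland"),
    area_ha = c(as.numeric(land_by_group),
                sum(sol$grassland$grassland_used_ha)))

  ec <- inst$emission_constants
  wgt <- c(CO2 = 1, CH4 = ec$gwp_ch4, N2O = ec$gwp_n2o)
  ghg <- sol$ghg$inventory
  ghg_co2e <- tapply(ghg$kg * wgt[ghg$gas], ghg$category, sum)
  ghg_tab <- data.frame(category = names(ghg_co2e),
                        co2e_kg = as.numeric(ghg_co2e))

  fert <- sol$fertilizer
  np <- if (nrow(fert)) {
    n <- tapply(fert$n_kg, fert$source, sum)
    p <- tapply(fert$p_kg, fert$source, sum)
    data.frame(source = names(n), n_kg = as.numeric(n),
               p_kg = as.numeric(p[names(n)]))
  } else data.frame(source = character(), n_kg = numeric(), p_kg = numeric())

  ## animal protein supplied per species, g protein per fed capita per day
  comp <- comp_matrix(inst)
  sysr <- inst$animal_systems
  prot <- list()
  if (nrow(sol$animals)) {
    for (j in seq_len(nrow(sysr))) {
      u <- sum(sol$animals$producing_units[sol$animals$system ==
                                             sysr$system[j]])
      if (u <= 0) next
      prot[[length(prot) + 1]] <- data.frame(
        species = sysr$species[j],
        protein_t = u * comp[sysr$product[j], "protein"] / 1000)
    }
  }
  animal_protein <- if (length(prot)) {
    ap <- do.call(rbind, prot)
    agg <- tapply(ap$protein_t, ap$species, sum)
    data.frame(species = names(agg), protein_t = as.numeric(agg))
  } else data.frame(species = character(), protein_t = numeric())

  ## nutrient intake vs bounds, population-weighted over countries
  pop <- stats::setNames(inst$countries$population, inst$countries$country)
  intake <- stats::setNames(numeric(length(nutrient_ids())), nutrient_ids())
  if (nrow(sol$diet)) {
    for (cc in unique(sol$diet$country)) {
      dd <- sol$diet[sol$diet$country == cc, ]
      nv <- diet_nutrients(stats::setNames(dd$intake_g_cap_day, dd$food),
                           inst$composition)
      intake <- intake + nv * pop[[cc]] / sum(pop)
    }
  }
  nutrient_tab <- data.frame(nutrient = inst$nutrients$nutrient,
                             unit = inst$nutrients$unit,
                             intake = as.numeric(intake[inst$nutrients$nutrient]),
                             min = inst$nutrients$min,
                             max = inst$nutrients$max)

  rep <- structure(list(
    scenario = config$name, solution = sol,
    land = land, total_land_ha = sol$total_land_ha,
    ghg = ghg_tab, total_co2e_kg = sol$ghg$total_co2e_kg,
    co2e_kg_per_capita = sol$ghg$co2e_kg_per_capita,
    fertilizer_by_source = np, animal_protein = animal_protein,
    nutrients = nutrient_tab,
    population_fed = sol$population_fed,
    comparison = NULL), class = "scenario_report")

  if (!is.null(baseline)) {
    cmp <- data.frame(
      quantity = c("total_land", "total_co2e", "co2e_per_capita",
                   "population_fed"),
      baseline = c(baseline$total_land_ha, baseline$total_co2e_kg,
                   baseline$co2e_kg_per_capita, baseline$population_fed),
      scenario = c(rep$total_land_ha, rep$total_co2e_kg,
                   rep$co2e_kg_per_capita, rep$population_fed))
    cmp$percent_change <- ifelse(cmp$baseline > 0,
                                 percent_change(cmp$baseline, cmp$scenario),
                                 NA_integer_)
    sp <- merge(baseline$animal_protein, rep$animal_protein, by = "species",
                all = TRUE, suffixes = c("_baseline", "_scenario"))
    sp[is.na(sp)] <- 0
    sp$percent_change <- ifelse(sp$protein_t_baseline > 0,
                                percent_change(sp$protein_t_baseline,
                                               sp$protein_t_scenario),
                                NA_integer_)
    rep$comparison <- list(totals = cmp, animal_protein = sp)
  }
  rep
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario report: %s\n", x$scenario))
  cat(sprintf("  population fed: %.3f million\n", x$population_fed / 1e6))
  cat(sprintf("  agricultural land: %.1f kha\n", x$total_land_ha / 1e3))
  cat(sprintf("  GHG: %.1f kt CO2e/yr (%.0f kg/capita/yr)\n",
              x$total_co2e_kg / 1e6, x$co2e_kg_per_capita))
  if (!is.null(x$comparison)) {
    cat("  vs baseline:\n")
    cm <- x$comparison$totals
    for (i in seq_len(nrow(cm)))
      if (!is.na(cm$percent_change[i]))
        cat(sprintf("    %s: %+d%%\n", cm$quantity[i], cm$percent_change[i]))
  }
  invisible(x)
}
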