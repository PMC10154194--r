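test_that("scenario configurations gate the right constraint families", {
  inst <- toy_instance()
  ph <- build_problem(inst, scenario_cirhealth())
  expect_true(all(c("nutrition", "food_group", "land", "rotation_cap",
                    "feed_balance", "feed_requirement", "feed_legality",
                    "fertilizer_balance", "waste_availability",
                    "fishery_cap", "in_country_use", "transport_cap",
                    "production_balance") %in% ph$families))
  expect_false("protein_match" %in% ph$families)

  pa <- build_problem(inst, scenario_ciragri())
  expect_true("protein_match" %in% pa$families)
  expect_false("nutrition" %in% pa$families)
  expect_false("food_group" %in% pa$families)

  pb <- build_problem(inst, scenario_agribase())
  expect_true(all(c("fixed_area", "calibration") %in% pb$families))
  expect_error(
    build_problem(inst,
                  scenario_config(objective = "calibrate",
                                  diet_mode = "calibrate")),
    "fixed current areas")
})

test_that("the solver recovers the constructed optimum to 1e-6 relative", {
  for (seed in c(7, 19)) {
    ko <- generate_known_optimum_instance(seed)
    sol <- solve_food_system(ko$instance, scenario_cirhealth(), ghg = FALSE)
    expect_equal(sol$objective_value, ko$expected_objective,
                 tolerance = 1e-6)
    expect_true(all(ko$expected_areas$area_ha >= 0))
    ## the dominant crop carries the whole diet
    expect_setequal(sol$area$crop[sol$area$area_ha > 1e-6], "staple_a")
    ## at the optimum the energy minimum is met exactly
    intake <- stats::setNames(sol$diet$intake_g_cap_day, sol$diet$food)
    nv <- diet_nutrients(intake, ko$instance$composition)
    e_min <- ko$instance$nutrients$min[
      ko$instance$nutrients$nutrient == "energy"]
    expect_equal(nv[["energy"]], e_min, tolerance = 1e-6)
  }
})

test_that("collapsing the dominant crop's yield flips the optimal crop", {
  ko <- generate_known_optimum_instance(7)
  inst <- ko$instance
  i <- which(inst$yields$crop == "staple_a")
  inst$yields$yield_t_ha[i] <- inst$yields$yield_t_ha[i] / 10
  sol <- solve_food_system(inst, scenario_cirhealth(), ghg = FALSE)
  used <- sol$area$crop[sol$area$area_ha > 1e-6]
  expect_setequal(used, "staple_b")
})

test_that("an unreachable nutrient minimum yields a structured infeasibility", {
  inst <- toy_instance()
  inst$nutrients$min[inst$nutrients$nutrient == "energy"] <- 1e9
  expect_error(solve_food_system(inst, scenario_cirhealth()),
               "infeasible.*nutrition")
})

test_that("re-solving returns the identical solution vector", {
  inst <- toy_instance()
  s1 <- solve_food_system(inst, scenario_cirhealth(), ghg = FALSE)
  s2 <- solve_food_system(inst, scenario_cirhealth(), ghg = FALSE)
  expect_identical(s1$var, s2$var)
  expect_identical(s1$objective_value, s2$objective_value)
})

test_that("brute force and solver agree within 1% on twenty tiny instances", {
  worst <- 0
  for (seed in 1:20) {
    oi <- generate_oracle_instance(seed)
    sol <- solve_food_system(oi, scenario_cirhealth(), ghg = FALSE)
    bf <- brute_force_optimum(oi, grid = 0.01)
    expect_equal(bf$status, "optimal")
    rel <- (bf$objective - sol$objective_value) / sol$objective_value
    ## the grid search is an upper bound on the minimum ...
    expect_gte(rel, -1e-9)
    ## ... and lands within 1%
    expect_lt(rel, 0.01)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.01)
})

test_that("refining the oracle grid moves it toward the solver monotonically", {
  oi <- generate_oracle_instance(6)
  sol <- solve_food_system(oi, scenario_cirhealth(), ghg = FALSE)
  coarse <- brute_force_optimum(oi, grid = 0.05, refine = FALSE)$objective
  mid <- brute_force_optimum(oi, grid = 0.01, refine = FALSE)$objective
  fine <- brute_force_optimum(oi, grid = 0.01, refine = TRUE)$objective
  if (is.na(coarse)) coarse <- Inf  # too coarse to find a feasible diet
  expect_gte(coarse, mid - 1e-9)
  expect_gte(mid, fine - 1e-9)
  expect_gte(fine, sol$objective_value - 1e-9)
})

test_that("oracle and solver agree that an impossible diet is infeasible", {
  oi <- generate_oracle_instance(2)
  oi$nutrients$min[oi$nutrients$nutrient == "energy"] <- 1e8
  expect_error(solve_food_system(oi, scenario_cirhealth()), "infeasible")
  bf <- brute_force_optimum(oi, grid = 0.02)
  expect_equal(bf$status, "infeasible")
})

test_that("enabling recycling options never increases the land objective", {
  inst <- toy_instance()
  base <- scenario_ciragri()
  no_waste <- scenario_ciragri(); no_waste$waste_to_feed_allowed <- FALSE
  s_with <- solve_food_system(inst, base, ghg = FALSE)
  s_without <- solve_food_system(inst, no_waste, ghg = FALSE)
  expect_gte(s_without$objective_value,
             s_with$objective_value * (1 - 1e-9))

  art <- scenario_cirhealth()
  no_art <- scenario_cirhealth(); no_art$artificial_fertilizer_allowed <- FALSE
  s_art <- solve_food_system(inst, art, ghg = FALSE)
  s_noart <- solve_food_system(inst, no_art, ghg = FALSE)
  expect_gte(s_noart$objective_value, s_art$objective_value * (1 - 1e-9))
})

test_that("with all caps slack, the land minimum is homogeneous in population", {
  oi <- generate_oracle_instance(3)
  s1 <- solve_food_system(oi, scenario_cirhealth(), ghg = FALSE)
  s2 <- solve_food_system(scale_population(oi, 2), scenario_cirhealth(),
                          ghg = FALSE)
  expect_equal(s2$objective_value, 2 * s1$objective_value,
               tolerance = 1e-6)
})

test_that("max-population feeds at least the current population when land is slack", {
  inst <- toy_instance()
  minland <- solve_food_system(inst, scenario_cirhealth(), ghg = FALSE)
  total_cropland <- sum(inst$zones$cropland_ha)
  expect_lt(sum(minland$area$area_ha), total_cropland)  # slack land
  maxpop <- solve_food_system(inst, scenario_cirpop(), ghg = FALSE)
  expect_gte(maxpop$population_fed,
             sum(inst$countries$population) * (1 - 1e-9))
})

test_that("every scenario solution passes every validator", {
  inst <- toy_instance()
  for (cfg in list(scenario_agribase(), scenario_ciragri(),
                   scenario_cirhealth(), scenario_cirpop())) {
    sol <- solve_food_system(inst, cfg)
    v <- check_solution(sol)
    expect_equal(nrow(v), 0, info = cfg$name)
  }
})

test_that("scenario reports tabulate land, emissions, fertilizer and diet", {
  inst <- toy_instance()
  base <- run_scenario(inst, scenario_agribase())
  rep <- run_scenario(inst, scenario_cirhealth(), baseline = base)
  expect_s3_class(rep, "scenario_report")
  expect_equal(sum(rep$land$area_ha), rep$total_land_ha)
  expect_true(nrow(rep$ghg) > 0)
  expect_true(all(c("artificial", "manure") %in%
                    c(rep$fertilizer_by_source$source, "manure")))
  expect_equal(nrow(rep$nutrients), 42)
  cmp <- rep$comparison$totals
  expect_equal(cmp$percent_change[cmp$quantity == "total_land"],
               percent_change(base$total_land_ha, rep$total_land_ha))
  ## circular redesign frees land relative to the calibrated baseline
  expect_lt(rep$total_land_ha, base$total_land_ha)
})

test_that("percent change rounds to integers and matches hand values", {
  expect_equal(percent_change(172, 50), -71L)
  expect_equal(percent_change(100, 100), 0L)
  expect_equal(percent_change(1.17, 0.83), -29L)
  expect_error(percent_change(0, 5), "> 0")
})

test_that("the flow ledger covers every commodity movement in the solution", {
  sol <- toy_solution()
  led <- flow_ledger(sol)
  expect_true(all(led$t >= 0))
  expect_equal(sum(led$t[led$use == "food"]), sum(sol$flows$t_supply))
  feed_uses <- led[grepl("^feed:", led$use), ]
  expect_equal(sum(feed_uses$t), sum(sol$feed_alloc$t_as_fed))
})
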