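test_that("generation is deterministic in (size, seed)", {
  a <- generate_instance(n_zones = 3, n_countries = 2, n_crops = 10,
                         n_animal_systems = 4, seed = 11)
  b <- generate_instance(n_zones = 3, n_countries = 2, n_crops = 10,
                         n_animal_systems = 4, seed = 11)
  expect_identical(unclass(a), unclass(b))
  c_ <- generate_instance(seed = 12)
  expect_false(identical(a$yields$yield_t_ha, c_$yields$yield_t_ha))
})

test_that("vitamin B12 is zero in plant foods and positive in all animal-source foods", {
  inst <- toy_instance()
  comp <- inst$composition
  src <- inst$foods$source[match(comp$food, inst$foods$food)]
  expect_true(all(comp$vit_b12[src == "crop"] == 0))
  expect_true(all(comp$vit_b12[src != "crop"] > 0))
})

test_that("generated instances keep their structural realism promises", {
  for (seed in c(1, 4)) {
    inst <- generate_instance(seed = seed)
    expect_equal(nrow(validate_instance(inst)), 0)
    ## every consumption-stage waste pool is strictly positive
    expect_true(all(inst$stage_waste$consumption > 0))
    expect_true(all(inst$stage_waste[, -1] < 0.3))
    ## grass is legal only for ruminants
    rum <- inst$animal_systems$species[inst$animal_systems$ruminant]
    gl <- inst$feed_legal[inst$feed_legal$feed == "grass", ]
    expect_true(all(gl$allowed == (gl$species %in% rum)))
    ## conversion fractions per process sum to at most one
    expect_true(all(inst$crops$tcf_main + inst$crops$tcf_byproduct <= 1))
    ## every plant food group is covered
    expect_true(all(c("grains", "tubers", "vegetables", "fruit", "legumes",
                      "nuts_seeds", "oil_fat", "sugar") %in%
                      inst$crops$food_group))
    ## yields vary across zones
    spread <- tapply(inst$yields$yield_t_ha, inst$yields$crop,
                     function(y) diff(range(y)))
    expect_true(any(spread > 0))
  }
})

test_that("impossible size requests fail with the violated requirement named", {
  expect_error(generate_instance(n_crops = 5), "food group")
  expect_error(generate_instance(n_zones = 0), ">= 1")
  expect_error(generate_instance(n_zones = 1, n_countries = 2), "zone per country")
})

test_that("the generated baseline is feasible under the calibration scenario", {
  sol <- solve_food_system(toy_instance(), scenario_agribase(), ghg = FALSE)
  expect_equal(sol$status, "optimal")
  ## areas are fixed to the current baseline
  cur <- toy_instance()$current$areas
  cur <- cur[cur$area_ha > 0, ]
  m <- merge(sol$area, cur, by = c("crop", "zone"), all = TRUE)
  m[is.na(m)] <- 0
  expect_lt(max(abs(m$area_ha.x - m$area_ha.y)), 1e-6 * max(cur$area_ha))
})

test_that("population scaling touches population only and rejects bad factors", {
  inst <- toy_instance()
  expect_identical(unclass(scale_population(inst, 1)), unclass(inst))
  s2 <- scale_population(inst, 2)
  expect_equal(s2$countries$population, 2 * inst$countries$population)
  s2$countries$population <- inst$countries$population
  expect_identical(unclass(s2), unclass(inst))
  expect_error(scale_population(inst, 0), "> 0")
  expect_error(scale_population(inst, -1), "> 0")
})
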