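sys_row <- function(...) {
  inst <- toy_instance()
  inst$animal_systems[1, ]  # dairy
}

test_that("stock requirements include parent and reproduction animals and scale linearly", {
  sy <- sys_row()
  sy$parent_ratio <- 0.1
  sy$repro_ratio <- 0.2
  r0 <- stock_requirements(0, sy)
  expect_true(all(unlist(r0) == 0))

  r <- stock_requirements(100, sy)
  expect_equal(r$parent_units, 10)
  expect_equal(r$repro_units, 20)
  expect_equal(r$req_energy_mj,
               100 * (sy$req_energy_mj + 0.3 * sy$aux_req_energy_mj))

  r2 <- stock_requirements(200, sy)
  for (f in names(r)) expect_equal(r2[[f]], 2 * r[[f]])
  expect_error(stock_requirements(-1, sy), ">= 0")
})

test_that("rations are vetted for legality, nutrient delivery and intake capacity", {
  inst <- toy_instance()
  dairy <- inst$animal_systems[inst$animal_systems$species == "dairy", ]

  ## food waste in a dairy ration is an illegal item
  rc <- ration_check(c(food_waste = 10, grass = 1000), dairy, 100, inst)
  expect_true(any(rc$rule == "illegal_feed"))

  ## a ration meeting requirements exactly at full intake capacity is fine
  need <- stock_requirements(100, dairy)
  gr <- inst$feeds[inst$feeds$feed == "grass", ]
  t_for_protein <- need$req_protein_kg / gr$dig_protein_g_kg
  t_for_energy <- need$req_energy_mj / (1000 * gr$energy_mj_kg)
  t_grass <- max(t_for_protein, t_for_energy)
  expect_lte(t_grass * gr$dm_frac, need$intake_t_dm)  # fits capacity
  expect_equal(nrow(ration_check(c(grass = t_grass), dairy, 100, inst)), 0)

  ## a 1% energy deficit is reported with the nutrient named
  short <- ration_check(c(grass = 0.99 * t_for_energy), dairy, 100, inst)
  expect_true(any(short$rule == "nutrient_shortfall"))
  expect_true("energy" %in% short$detail)

  expect_error(ration_check(c(unobtainium = 1), dairy, 1, inst),
               "unobtainium")
})

test_that("animal outputs are linear with nutrient totals from the composition", {
  inst <- toy_instance()
  dairy <- inst$animal_systems[1, ]
  out0 <- animal_outputs(0, dairy, inst)
  expect_equal(out0$product_t, 0)
  expect_true(all(out0$nutrients == 0))

  out <- animal_outputs(10, dairy, inst)
  expect_equal(out$product_t, 10)
  expect_equal(out$byproduct_t, 10 * dairy$byproduct_frac)
  comp <- inst$composition
  prot <- comp$protein[comp$food == dairy$product]
  expect_equal(unname(out$nutrients["protein"]), 10 * 1000 * prot)
  expect_error(animal_outputs(-1, dairy, inst), ">= 0")
})

test_that("manure excretion is intake minus retention, split by grazing share", {
  m <- manure_excretion(100, 20, n_retention = 0.3, p_retention = 0.5,
                        grazing_share = 0, dm_intake_t = 10, dig_om = 0.7)
  expect_equal(m$n_excreted_kg, 70)
  expect_equal(m$p_excreted_kg, 10)
  expect_equal(m$n_mms_kg, 70)
  expect_equal(m$n_pasture_kg, 0)
  expect_equal(m$vs_kg, 10 * 1000 * 0.3 * 0.92)

  full <- manure_excretion(100, 20, 1, 1, 0.5, 10, 0.7)
  expect_equal(full$n_excreted_kg, 0)

  graz <- manure_excretion(100, 20, 0.3, 0.5, 1, 10, 0.7)
  expect_equal(graz$n_mms_kg, 0)
  expect_equal(graz$n_pasture_kg, 70)
  expect_error(manure_excretion(1, 1, 1.2, 0, 0, 1, 0.5), "\\[0, 1\\]")
})

test_that("fishery landings respect MSY quotas and split into food and by-product", {
  inst <- toy_instance()
  st <- inst$fish_stocks$stock[1]
  cc <- inst$countries$country[1]
  q <- inst$fish_quota
  cap <- inst$fish_stocks$msy_t[1] * q$share[q$stock == st & q$country == cc]
  ef <- inst$fish_stocks$edible_frac[1]

  z <- fishery_supply(data.frame(stock = st, country = cc, requested_t = 0),
                      inst)
  expect_equal(z$landed_t, 0)

  full <- fishery_supply(data.frame(stock = st, country = cc,
                                    requested_t = cap), inst)
  expect_equal(full$landed_t, cap)
  expect_equal(full$edible_t, cap * ef)
  expect_equal(full$byproduct_t, cap * (1 - ef))

  expect_warning(
    over <- fishery_supply(data.frame(stock = st, country = cc,
                                      requested_t = 1.2 * cap), inst),
    "clipped")
  expect_equal(over$landed_t, cap)
  expect_true(over$clipped)
  expect_error(fishery_supply(data.frame(stock = st, country = cc,
                                         requested_t = -1), inst), ">= 0")
})

test_that("removing every feed item of a species drives its output to zero", {
  inst <- toy_instance()
  inst$feed_legal$allowed[inst$feed_legal$species == "pig"] <- FALSE
  sol <- solve_food_system(inst, scenario_cirhealth(), ghg = FALSE)
  pigs <- sol$animals[sol$animals$system == "pig_high", ]
  expect_true(nrow(pigs) == 0 || all(pigs$producing_units == 0))
})
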