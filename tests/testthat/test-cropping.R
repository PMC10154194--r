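test_that("rotation frequencies convert to annual area shares", {
  expect_equal(rotation_share(4), 0.25)
  expect_equal(rotation_share(1), 1)
  expect_equal(rotation_share(6), 1 / 6)
  expect_error(rotation_share(0), ">= 1")
})

test_that("suitability and caps compose: no yield means excluded, minor crops capped at current acreage", {
  inst <- generate_instance(n_crops = 11, seed = 8)  # includes capped rice
  z <- inst$zones$zone[1]
  sv <- suitable_crops(z, inst)
  with_yield <- inst$yields$crop[inst$yields$zone == z &
                                   inst$yields$yield_t_ha > 0]
  expect_setequal(sv$crop, intersect(inst$crops$crop, with_yield))

  for (zz in inst$zones$zone) {
    svz <- suitable_crops(zz, inst)
    if (!"rice" %in% svz$crop) next
    cur <- inst$current$areas
    cur_rice <- sum(cur$area_ha[cur$crop == "rice" & cur$zone == zz])
    expect_lte(svz$cap_ha[svz$crop == "rice"], cur_rice + 1e-9)
  }
  ## ordinary crops: cap is the rotation share times the zone cropland
  ord <- sv[sv$crop == "wheat", ]
  k <- inst$crops$rotation_years[inst$crops$crop == "wheat"]
  expect_equal(ord$cap_ha,
               zone_cropland <- inst$zones$cropland_ha[1] / k)
})

test_that("nutrient removal covers harvest plus residues and is linear in area", {
  inst <- toy_instance()
  ## constructed case: yield 5, P concentrations 3 (product) and 1
  ## (residue), residue ratio 1 -> 20 kg P per ha
  inst$crops[1, c("residue_ratio", "p_conc_product", "p_conc_residue")] <-
    list(1, 3, 1)
  cr <- inst$crops$crop[1]
  z <- inst$yields$zone[inst$yields$crop == cr][1]
  inst$yields$yield_t_ha[inst$yields$crop == cr & inst$yields$zone == z] <- 5
  expect_equal(unname(crop_nutrient_removal(cr, z, 1, inst)["P_kg"]), 20)
  expect_equal(unname(crop_nutrient_removal(cr, z, 0, inst)), c(0, 0))
  expect_equal(crop_nutrient_removal(cr, z, 7, inst),
               7 * crop_nutrient_removal(cr, z, 1, inst))
  expect_error(crop_nutrient_removal(cr, "Z99", 1, inst), "unsuitable")
})

test_that("fertilizer requirements inflate removal by the loss fractions", {
  inst <- toy_instance()
  inst$crops[1, c("residue_ratio", "p_conc_product", "p_conc_residue")] <-
    list(1, 3, 1)
  cr <- inst$crops$crop[1]
  z <- inst$yields$zone[inst$yields$crop == cr][1]
  inst$yields$yield_t_ha[inst$yields$crop == cr & inst$yields$zone == z] <- 5
  req <- fertilizer_requirement(cr, z, 1, inst)
  ## 20 kg P removal x 1.125 unavoidable-loss multiplier
  expect_equal(unname(req["P_kg"]), 22.5)
  expect_equal(unname(fertilizer_requirement(cr, z, 0, inst)), c(0, 0))
  rem <- crop_nutrient_removal(cr, z, 3, inst)
  req3 <- fertilizer_requirement(cr, z, 3, inst)
  expect_gte(req3[["N_kg"]], rem[["N_kg"]])
})

test_that("the supply balance honors fixed organic N:P ratios and reports deficits", {
  inst <- toy_instance()
  reqs <- data.frame(crop = "wheat", zone = "Z01", n_req_kg = 100,
                     p_req_kg = 20)
  exact <- data.frame(source = c("artificial", "artificial"),
                      crop = "wheat", zone = "Z01",
                      n_kg = c(100, 0), p_kg = c(0, 20))
  expect_equal(nrow(fertilizer_supply_balance(exact, reqs, inst)), 0)

  ## an organic source applied for N delivers P at its fixed ratio
  inst$residual_params$organic_np["manure"] <- 5
  organic <- data.frame(source = "manure", crop = "wheat", zone = "Z01",
                        n_kg = 100)
  bal <- fertilizer_supply_balance(organic, reqs, inst)
  expect_equal(nrow(bal), 0)  # P delivered = 100/5 = 20 >= 20

  reqs2 <- reqs; reqs2$p_req_kg <- 25
  bal2 <- fertilizer_supply_balance(organic, reqs2, inst)
  expect_equal(bal2$nutrient, "P")
  expect_equal(bal2$deficit_kg, 5)

  none <- data.frame(source = "manure", crop = "wheat", zone = "Z01",
                     n_kg = 10)
  expect_gte(nrow(fertilizer_supply_balance(none, reqs, inst)), 1)
  expect_error(fertilizer_supply_balance(
    data.frame(source = "pixie_dust", crop = "a", zone = "z", n_kg = 1),
    reqs, inst), "unknown fertilizer source")
})

test_that("crop residues stay on the field: no residue feed or fertilizer source exists", {
  inst <- toy_instance()
  expect_false(any(grepl("residue", inst$feeds$feed)))
  sol <- toy_solution()
  expect_false(any(grepl("residue", sol$fertilizer$source)))
  ## but residues do raise the requirement
  cr <- inst$crops[inst$crops$residue_ratio > 0, ][1, ]
  z <- inst$yields$zone[inst$yields$crop == cr$crop][1]
  with_res <- fertilizer_requirement(cr$crop, z, 10, inst)
  inst2 <- inst
  inst2$crops$residue_ratio[inst2$crops$crop == cr$crop] <- 0
  without <- fertilizer_requirement(cr$crop, z, 10, inst2)
  expect_gt(with_res[["N_kg"]], without[["N_kg"]])
})
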