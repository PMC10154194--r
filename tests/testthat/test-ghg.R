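ec_test <- function() toy_instance()$emission_constants

test_that("enteric methane divides gross energy by the energy content of methane", {
  expect_equal(enteric_ch4(0, 6.5), 0)
  expect_equal(enteric_ch4(55.65, 100), 1)
  expect_equal(enteric_ch4(10000, 6.5), 10000 * 0.065 / 55.65)
  expect_equal(enteric_ch4(10000, 6.5), 11.68, tolerance = 1e-3)
  expect_error(enteric_ch4(1, 101), "\\[0, 100\\]")
})

test_that("manure methane converts volume to mass with 0.67", {
  expect_equal(manure_ch4(0, 0.1, 0.24), 0)
  expect_equal(manure_ch4(1, 1, 1), 0.67)
  expect_equal(manure_ch4(100, 0.1, 0.24), 1.608)
})

test_that("manure N2O includes direct and indirect pathways with the 44/28 conversion", {
  expect_equal(manure_n2o(0, 0.01), 0)
  expect_equal(manure_n2o(100, 0.01, volat_frac = 0), 100 * 0.01 * 44 / 28)
  expect_equal(manure_n2o(100, 0.01, volat_frac = 0), 1.571, tolerance = 1e-3)
  expect_gt(manure_n2o(100, 0.01, volat_frac = 0.3),
            manure_n2o(100, 0.01, volat_frac = 0))
})

test_that("aquaculture N2O applies the 1.8% emission fraction", {
  expect_equal(aquaculture_n2o(0), 0)
  expect_equal(aquaculture_n2o(100), 100 * 0.018 * 44 / 28)
  expect_equal(aquaculture_n2o(100), 2.829, tolerance = 1e-3)
  expect_equal(aquaculture_n2o(200), 2 * aquaculture_n2o(100))
})

test_that("soil N2O composes direct, volatilization, leaching and organic-soil terms", {
  ec <- ec_test()
  expect_equal(soil_n2o(list(), "dry", ec), 0)

  ## composite factor of exactly 0.01: no indirect pathways
  ec0 <- ec
  ec0$n_volat_frac_synthetic <- 0
  ec0$n_leach_frac_dry <- 0
  expect_equal(soil_n2o(list(artificial = 1000), "dry", ec0),
               1000 * 0.01 * 44 / 28)
  expect_equal(soil_n2o(list(artificial = 1000), "dry", ec0), 15.71,
               tolerance = 1e-3)

  ## the organic-soil term is area-based and additive, independent of N
  base <- soil_n2o(list(artificial = 500), "wet", ec)
  with_peat <- soil_n2o(list(artificial = 500), "wet", ec,
                        organic_soil_ha = 10)
  expect_equal(with_peat - base, 10 * ec$ef_organic_soil_n2o_ha * 44 / 28)
  ## wet climates add leaching
  expect_gt(soil_n2o(list(manure = 100), "wet", ec),
            soil_n2o(list(manure = 100), "dry", ec))
})

test_that("composting emissions derive carbon from N through the C:N ratio of 15", {
  ec <- ec_test()
  z <- compost_emissions(0, ec)
  expect_equal(z$n2o_kg, 0); expect_equal(z$ch4_kg, 0)
  r <- compost_emissions(10, ec)
  expect_equal(r$ch4_kg, 10 * 15 * ec$compost_c_to_ch4)  # C = N x 15
  expect_equal(r$n2o_kg, 10 * 0.01 * 44 / 28)
  expect_equal(r$n2o_kg, 0.157, tolerance = 1e-2)
})

test_that("transport emissions multiply ton-kilometres and flag the per-capita cap", {
  dist <- matrix(c(0, 500, 500, 0), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  none <- transport_emissions(data.frame(from = character(),
                                         to = character(), t = numeric()),
                              dist, 0.1)
  expect_equal(none$co2e_kg, 0)

  r <- transport_emissions(data.frame(from = "A", to = "B", t = 10),
                           dist, 0.1)
  expect_equal(r$co2e_kg, 500)

  pop <- c(A = 1000, B = 1)
  over <- transport_emissions(data.frame(from = "A", to = "B", t = 1501 / 50),
                              dist, 0.1, population = pop, cap = 1500)
  expect_equal(over$violations, "B")
  under <- transport_emissions(data.frame(from = "A", to = "B", t = 1499 / 50),
                               dist, 0.1, population = pop, cap = 1500)
  expect_length(under$violations, 0)
})

test_that("fertilizer production emissions are linear and additive over N and P", {
  ec <- ec_test()
  expect_equal(fertilizer_production_emissions(0, 0, ec), 0)
  ec2 <- ec; ec2$ef_fert_prod_n <- 5
  expect_equal(fertilizer_production_emissions(1, 0, ec2), 5000)
  expect_equal(fertilizer_production_emissions(2, 3, ec),
               fertilizer_production_emissions(2, 0, ec) +
                 fertilizer_production_emissions(0, 3, ec))
})

test_that("CO2e aggregation uses GWP 28 for CH4 and 265 for N2O", {
  inv_ch4 <- data.frame(category = "enteric", gas = "CH4", kg = 1)
  expect_equal(total_co2e(inv_ch4)$total_co2e_kg, 28)
  inv_n2o <- data.frame(category = "soil_N2O", gas = "N2O", kg = 1)
  expect_equal(total_co2e(inv_n2o)$total_co2e_kg, 265)
  empty <- data.frame(category = character(), gas = character(),
                      kg = numeric())
  expect_equal(total_co2e(empty)$total_co2e_kg, 0)
  expect_error(total_co2e(inv_ch4, population = 0), "> 0")
  expect_error(total_co2e(data.frame(category = "x", gas = "CFC", kg = 1)),
               "unknown gas")
})

test_that("the solution inventory is category-exhaustive and sums exactly to its total", {
  sol <- toy_solution()
  inv <- sol$ghg$inventory
  expect_setequal(unique(inv$category),
                  c("enteric", "manure_mgmt_CH4", "manure_N2O",
                    "grassland_N2O", "aquaculture_N2O", "soil_N2O",
                    "organic_soil_N2O", "compost", "fertilizer_production",
                    "transport"))
  expect_true(all(inv$kg >= 0))
  w <- c(CO2 = 1, CH4 = 28, N2O = 265)
  expect_equal(sum(inv$kg * w[inv$gas]), sol$ghg$total_co2e_kg)
  expect_equal(sol$ghg$total_co2e_kg / sol$population_fed,
               sol$ghg$co2e_kg_per_capita)
  ## no rice CH4 and no soil CO2 categories exist by design
  expect_false(any(grepl("rice", inv$category)))
  expect_false(any(inv$category == "soil_N2O" & inv$gas == "CO2"))
})

test_that("every emission operation is homogeneous of degree one", {
  ec <- ec_test()
  for (s in c(0.5, 2, 10)) {
    expect_equal(enteric_ch4(s * 1000, 6.5), s * enteric_ch4(1000, 6.5))
    expect_equal(manure_ch4(s * 50, 0.1, 0.24), s * manure_ch4(50, 0.1, 0.24))
    expect_equal(manure_n2o(s * 10, 0.01, 0.3), s * manure_n2o(10, 0.01, 0.3))
    expect_equal(aquaculture_n2o(s * 10), s * aquaculture_n2o(10))
    expect_equal(soil_n2o(list(artificial = s * 100, manure = s * 40),
                          "wet", ec),
                 s * soil_n2o(list(artificial = 100, manure = 40), "wet", ec))
    expect_equal(compost_emissions(s * 10, ec)$ch4_kg,
                 s * compost_emissions(10, ec)$ch4_kg)
  }
})
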