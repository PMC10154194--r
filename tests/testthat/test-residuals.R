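test_that("technical conversion factors split mass and never create it", {
  expect_equal(unname(byproducts_from_processing(0, c(flour = 0.75))), 0)
  out <- byproducts_from_processing(100, c(flour = 0.75, bran = 0.22))
  expect_equal(unname(out["flour"]), 75)
  expect_equal(unname(out["bran"]), 22)
  expect_lte(sum(out), 100)
  set.seed(5)
  for (k in 1:10) {
    tcf <- runif(3); tcf <- tcf / sum(tcf) * runif(1, 0.5, 1)
    names(tcf) <- c("a", "b", "c")
    x <- runif(1, 0, 1000)
    expect_lte(sum(byproducts_from_processing(x, tcf)), x + 1e-9)
  }
  expect_error(byproducts_from_processing(1, c(a = 0.7, b = 0.4)), "> 1")
})

test_that("consumption waste splits 35% to feed and the rest to compost", {
  rp <- toy_instance()$residual_params
  w <- waste_feed_allocation(100, rp)
  expect_equal(w$feed_eligible_t, 35)
  expect_equal(w$compostable_t, 65)
  w0 <- waste_feed_allocation(0, rp)
  expect_equal(w0$feed_eligible_t, 0)
  expect_equal(w0$compostable_t, 0)
  expect_error(waste_feed_allocation(-1, rp), ">= 0")
})

test_that("sludge fertilizer value follows the use share and nutrient contents", {
  rp <- toy_instance()$residual_params
  s <- sludge_fertilizer(100, rp)
  expect_equal(s$usable_t, 36)
  expect_equal(s$n_t, 2.7)
  expect_equal(s$p_t, 0.432)
  expect_equal(sludge_fertilizer(0, rp)$n_t, 0)

  ## applied-quantity convention: 3.2 Mt already-applied sludge carries
  ## 240 kt N and 38.4 kt P
  s2 <- sludge_fertilizer(3.2e6, rp, already_usable = TRUE)
  expect_equal(s2$n_t, 240e3)
  expect_equal(s2$p_t, 38.4e3)
  expect_error(sludge_fertilizer(-1, rp), ">= 0")
})

test_that("compost nutrients pass through with gaseous N loss only", {
  z <- compost_nutrients(0, 0, 0.05)
  expect_equal(z$n_t, 0); expect_equal(z$p_t, 0)
  r <- compost_nutrients(10, 3, 0.05)
  expect_equal(r$n_t, 9.5)
  expect_equal(r$p_t, 3)  # P is conserved exactly
  expect_error(compost_nutrients(-1, 0, 0), ">= 0")
})

test_that("solver solutions respect the waste rules: share cap, no ruminants, in-country use", {
  inst <- toy_instance()
  for (cfg in list(scenario_ciragri(), scenario_cirhealth())) {
    sol <- solve_food_system(inst, cfg, ghg = FALSE)
    w4 <- vapply(inst$foods$food,
                 function(f) inst$stage_waste$consumption[
                   inst$stage_waste$food == f], numeric(1))
    for (cc in inst$countries$country) {
      inflow <- sol$flows[sol$flows$to == cc, ]
      waste <- sum(inflow$t_supply * w4[inflow$food])
      fed <- sum(sol$feed_alloc$t_as_fed[sol$feed_alloc$feed == "food_waste" &
                                           sol$feed_alloc$country == cc])
      expect_lte(fed, 0.35 * waste * (1 + 1e-6))
    }
    rum <- inst$animal_systems$system[inst$animal_systems$ruminant]
    expect_equal(sum(sol$feed_alloc$t_as_fed[
      sol$feed_alloc$feed == "food_waste" &
        sol$feed_alloc$system %in% rum]), 0)
    ## neither grass nor waste ever crosses a border
    ntf <- inst$feeds$feed[!inst$feeds$tradeable]
    cross <- sol$feed_flows[sol$feed_flows$feed %in% ntf &
                              sol$feed_flows$from != sol$feed_flows$to, ]
    expect_true(nrow(cross) == 0 || all(cross$t_as_fed == 0))
  }
})
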