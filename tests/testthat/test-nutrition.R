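comp_two_foods <- function() {
  comp <- as.data.frame(matrix(0, 2, length(nutrient_ids()),
                               dimnames = list(NULL, nutrient_ids())))
  comp <- cbind(food = c("bread", "beans"), comp)
  comp$energy <- c(2500, 3300)
  comp$protein <- c(200, 220)  # per kg, i.e. 0.2 g per g
  comp$fibre <- c(70, 150)
  comp
}

test_that("diet nutrient computation is linear, additive and strict about coverage", {
  comp <- comp_two_foods()
  expect_true(all(diet_nutrients(numeric(0), comp) == 0))
  nv <- diet_nutrients(c(bread = 100), comp)
  expect_equal(nv[["protein"]], 20)   # 100 g/day x 0.2 protein per g
  expect_equal(nv[["energy"]], 250)

  set.seed(99)
  for (k in 1:5) {
    d1 <- stats::setNames(runif(2, 0, 300), comp$food)
    d2 <- stats::setNames(runif(2, 0, 300), comp$food)
    expect_equal(diet_nutrients(d1, comp) + diet_nutrients(d2, comp),
                 diet_nutrients(d1 + d2, comp))
    expect_true(all(diet_nutrients(2 * d1, comp) >=
                      diet_nutrients(d1, comp)))
  }
  expect_error(diet_nutrients(c(cake = 10), comp), "cake")
})

test_that("the waste cascade multiplies stages and conserves mass exactly", {
  r0 <- apply_waste_chain(c(a = 100), c(post_harvest = 0, processing = 0,
                                        distribution = 0, consumption = 0))
  expect_equal(unname(r0$intake["a"]), 100)

  r <- apply_waste_chain(c(a = 100), c(post_harvest = 0.1, processing = 0.1,
                                       distribution = 0, consumption = 0))
  expect_equal(unname(r$intake["a"]), 81)
  expect_equal(unname(rowSums(r$losses)["a"]), 19)
  expect_equal(unname(r$losses["a", 1]), 10)
  expect_equal(unname(r$losses["a", 2]), 9)

  set.seed(7)
  for (k in 1:10) {
    supply <- stats::setNames(runif(3, 0, 500), c("x", "y", "z"))
    fr <- runif(4, 0, 0.5)
    names(fr) <- c("post_harvest", "processing", "distribution", "consumption")
    r <- apply_waste_chain(supply, fr)
    expect_equal(r$intake + rowSums(r$losses), supply)
  }
  expect_error(apply_waste_chain(c(a = 1), c(0.2, 1, 0, 0)), "\\[0, 1\\)")
})

test_that("nutrient bounds are inclusive and violations enumerate correctly", {
  specs <- data.frame(nutrient = nutrient_ids(), min = NA_real_,
                      max = NA_real_)
  specs$min[specs$nutrient == "energy"] <- 2000
  specs$max[specs$nutrient == "energy"] <- 2600
  specs$min[specs$nutrient == "protein"] <- 50

  at_min <- stats::setNames(numeric(42), nutrient_ids())
  at_min["energy"] <- 2000; at_min["protein"] <- 50
  expect_equal(nrow(nutrient_bound_violations(at_min, specs)), 0)

  over <- at_min; over["energy"] <- 2700
  v <- nutrient_bound_violations(over, specs)
  expect_equal(nrow(v), 1)
  expect_equal(v$nutrient, "energy")
  expect_equal(v$bound, "max")

  zero <- stats::setNames(numeric(42), nutrient_ids())
  v0 <- nutrient_bound_violations(zero, specs)
  expect_setequal(v0$nutrient,
                  specs$nutrient[!is.na(specs$min) & specs$min > 0])
})

test_that("food-group bounds check grams directly and grains as an energy share", {
  comp <- as.data.frame(matrix(0, 3, length(nutrient_ids()),
                               dimnames = list(NULL, nutrient_ids())))
  comp <- cbind(food = c("steak", "salad", "bread"), comp)
  comp$energy <- c(2500, 300, 3500)
  groups <- c(steak = "red_meat", salad = "vegetables", bread = "grains")
  bounds <- default_food_group_bounds()

  diet_ok <- c(steak = 28, salad = 300, bread = 200)
  v <- food_group_violations(diet_ok, bounds, groups, comp)
  expect_false("red_meat" %in% v$group)  # 28 g/day is inclusive

  diet_lowveg <- c(steak = 20, salad = 150, bread = 250)
  v2 <- food_group_violations(diet_lowveg, bounds, groups, comp)
  expect_true(any(v2$group == "vegetables" & v2$bound == "min"))

  ## grains supplying 61% of energy violates the 60% share bound
  diet_grain <- c(steak = 50, salad = 300,
                  bread = 0.61 * (50 * 2.5 + 300 * 0.3) / (0.39 * 3.5))
  v3 <- food_group_violations(diet_grain, bounds, groups, comp)
  expect_true(any(v3$group == "grains"))
  expect_error(food_group_violations(c(cake = 1), bounds, groups, comp),
               "cake")
})

test_that("protein supply matching reports shortfalls per country and group", {
  cur <- data.frame(country = "C01", group = c("dairy", "grains"),
                    g_protein_cap_day = c(10, 30))
  ok <- data.frame(country = "C01", group = c("dairy", "grains"),
                   g_protein_cap_day = c(10, 30))
  expect_equal(nrow(protein_supply_match(ok, cur)), 0)

  short <- ok; short$g_protein_cap_day[1] <- 9
  sh <- protein_supply_match(short, cur)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$shortfall_frac, 0.1)

  none <- ok[0, ]
  sh2 <- protein_supply_match(none, cur)
  expect_equal(sh2$shortfall, cur$g_protein_cap_day)
})
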