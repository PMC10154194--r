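test_that("the packaged fixture parses, cross-links and validates", {
  inst <- load_instance(packaged_fixture_path())
  expect_s3_class(inst, "food_system_instance")
  expect_equal(nrow(inst$zones), 3)
  expect_equal(nrow(inst$crops), 10)
  expect_equal(nrow(inst$animal_systems), 4)
  expect_equal(nrow(validate_instance(inst)), 0)
})

test_that("instances round-trip through serialization unchanged", {
  for (seed in c(1, 5)) {
    inst <- generate_instance(seed = seed)
    f <- withr::local_tempfile(fileext = ".yaml")
    write_instance(inst, f)
    inst2 <- load_instance(f)
    expect_equal(unclass(inst2), unclass(inst), tolerance = 1e-12)
  }
})

test_that("unknown keys and dangling references are rejected at load", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_instance(toy_instance(), f)
  txt <- readLines(f)
  writeLines(c(txt, "mystery_key: 1"), f)
  expect_error(load_instance(f), "unknown instance key")

  inst <- toy_instance()
  inst$crops$byproduct_feed[1] <- "no_such_feed"
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_instance(inst, f2)
  expect_error(load_instance(f2), "byproduct_feed")
})

test_that("validate_instance reports violations as data and never raises", {
  inst <- toy_instance()
  expect_equal(nrow(validate_instance(inst)), 0)

  bad <- inst
  bad$crops$rotation_years[1] <- 0.5  # max frequency would exceed 1
  rep <- validate_instance(bad)
  expect_true(any(grepl("rotation", rep$rule)))
  expect_equal(rep$id[grepl("rotation", rep$rule)][1], bad$crops$crop[1])

  bad2 <- inst
  i <- which(bad2$feed_legal$feed == "food_waste" &
               bad2$feed_legal$species == "dairy")
  bad2$feed_legal$allowed[i] <- TRUE
  rep2 <- validate_instance(bad2)
  expect_true(any(grepl("ruminant", rep2$rule)))

  bad3 <- inst
  bad3$zones$cropland_ha[1] <- -10
  bad3$nutrients <- bad3$nutrients[-1, ]
  bad3$stage_waste$consumption[2] <- 1.2
  expect_no_error(rep3 <- validate_instance(bad3))
  expect_gte(nrow(rep3), 3)
})

test_that("nutrient vocabulary is fixed at 42 tracked ids", {
  expect_length(nutrient_ids(), 42)
  expect_length(nutrient_units(), 42)
  expect_true("vit_b12" %in% nutrient_ids())
  expect_setequal(toy_instance()$nutrients$nutrient, nutrient_ids())
})

test_that("solution export is deterministic and re-read tables sum back", {
  sol <- toy_solution()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_solution(sol, d1)
  f2 <- write_solution(sol, d2)
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  areas <- utils::read.delim(file.path(d1, "area.tsv"))
  expect_equal(sum(areas$area_ha), sum(sol$area$area_ha))
  fert <- utils::read.delim(file.path(d1, "fertilizer.tsv"))
  expect_equal(sum(fert$n_kg), sum(sol$fertilizer$n_kg))
})

test_that("an empty solution exports files with headers only", {
  sol <- toy_solution()
  empty <- sol
  for (nm in c("area", "grassland", "animals", "feed_alloc", "flows",
               "fertilizer", "diet"))
    empty[[nm]] <- sol[[nm]][0, , drop = FALSE]
  d <- withr::local_tempdir()
  write_solution(empty, d)
  tab <- utils::read.delim(file.path(d, "area.tsv"))
  expect_equal(nrow(tab), 0)
  expect_named(tab, c("crop", "zone", "area_ha"))
})
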