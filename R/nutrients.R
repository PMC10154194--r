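## Canonical nutrient and food-group vocabularies.
##
## The diet model tracks 42 nutrients: general (fresh weight, energy),
## macronutrients, fat types and cholesterol, minerals, vitamins and the nine
## essential amino acids. Compositions are stored per kg edible fresh matter;
## intakes per capita per day in each nutrient's own unit.

.NUTRIENTS <- data.frame(
  nutrient = c(
    "fresh_weight", "energy",
    "protein", "fat_total", "carbohydrates", "fibre",
    "la", "ala", "dha", "epa", "cholesterol",
    "sodium", "potassium", "calcium", "phosphorus", "magnesium",
    "iron", "copper", "selenium", "zinc", "iodine",
    "vit_a", "vit_b1", "vit_b2", "vit_b3", "vit_b5", "vit_b6", "vit_b9",
    "vit_b12", "vit_c", "vit_d", "vit_e", "vit_k",
    "his", "ile", "leu", "lys", "met", "phe", "thr", "trp", "val"),
  unit = c(
    "g/day", "kcal/day",
    "g/day", "g/day", "g/day", "g/day",
    "g/day", "g/day", "g/day", "g/day", "mg/day",
    "mg/day", "mg/day", "mg/day", "mg/day", "mg/day",
    "mg/day", "mg/day", "ug/day", "mg/day", "ug/day",
    "ug/day", "mg/day", "mg/day", "mg/day", "mg/day", "mg/day", "ug/day",
    "ug/day", "mg/day", "ug/day", "mg/day", "ug/day",
    "g/day", "g/day", "g/day", "g/day", "g/day", "g/day", "g/day", "g/day",
    "g/day"),
  stringsAsFactors = FALSE
)

.FOOD_GROUPS <- c("grains", "tubers", "vegetables", "fruit", "dairy",
                  "red_meat", "chicken", "eggs", "fish", "legumes",
                  "nuts_seeds", "oil_fat", "sugar", "other")

#' Tracked nutrient identifiers
#'
#' @return character vector of the 42 nutrient ids carried by every instance.
#' @export
nutrient_ids <- function() .NUTRIENTS$nutrient

#' Nutrient units
#'
#' @return named character vector mapping nutrient id to its per-capita/day
#'   unit.
#' @export
nutrient_units <- function() {
  stats::setNames(.NUTRIENTS$unit, .NUTRIENTS$nutrient)
}

#' Food-group identifiers
#'
#' The food groups used for diet bounds and for matching current protein
#' supply: grains, tubers, vegetables, fruit, dairy, red meat, chicken, eggs,
#' fish, legumes, nuts/seeds, oil and fat, sugar and other.
#'
#' @return character vector of group ids.
#' @export
food_groups <- function() .FOOD_GROUPS

#' Dietary food-group intake bounds
#'
#' Reference intake ranges per food group, in g fresh weight per capita per
#' day except grains, which are bounded as a maximum share of energy intake.
#' Groups without a guideline bound (oil/fat, other) are unbounded.
#'
#' @return data.frame with columns group, min, max, unit
#'   (`"g_day"` or `"energy_share"`).
#' @export
default_food_group_bounds <- function() {
  data.frame(
    group = c("grains", "tubers", "vegetables", "fruit", "dairy", "red_meat",
              "chicken", "eggs", "fish", "legumes", "nuts_seeds", "sugar"),
    min  = c(0, 0, 200, 100, 0, 0, 0, 0, 0, 0, 0, 0),
    max  = c(0.60, 100, 600, 300, 500, 28, 58, 25, 100, 225, 75, 31),
    unit = c("energy_share", rep("g_day", 11)),
    stringsAsFactors = FALSE
  )
}
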