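## Scenario configurations. Four canonical scenarios are provided:
##   agribase  — production baseline: areas fixed to current, objective
##               minimizes the deviation of per-food-group protein supply
##               from the current supply; no waste recycling.
##   ciragri   — supply-side circularity: minimize agricultural land while
##               meeting the current protein supply per country and food
##               group; waste-to-feed, composting and by-product feeding on.
##   cirhealth — circularity plus a healthy diet: minimize land under
##               nutrient reference bounds and food-group intake bounds.
##   cirpop    — healthy circular diet, maximize the population fed from
##               the available land.
## Artificial fertilizer is optional and complementary to organic sources
## in all scenarios; transport between countries is capped per fed capita.

#' Scenario configuration
#'
#' @param name scenario label
#' @param diet_mode one of `"calibrate"` (match current supply),
#'   `"current_protein"` (meet current protein supply per food group) or
#'   `"efsa_eat"` (nutrient reference bounds plus food-group bounds)
#' @param objective one of `"calibrate"`, `"min_land"`, `"max_population"`
#' @param artificial_fertilizer_allowed,waste_to_feed_allowed,waste_to_compost_allowed,byproducts_to_feed_allowed circularity switches
#' @param trade_allowed_between_countries allow intra-system trade (the
#'   system as a whole is always self-sufficient: no external imports)
#' @param fixed_current_areas fix crop areas and grassland use to the
#'   current baseline (calibration only)
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(name = "custom",
                            diet_mode = c("efsa_eat", "current_protein",
                                          "calibrate"),
                            objective = c("min_land", "max_population",
                                          "calibrate"),
                            artificial_fertilizer_allowed = TRUE,
                            waste_to_feed_allowed = TRUE,
                            waste_to_compost_allowed = TRUE,
                            byproducts_to_feed_allowed = TRUE,
                            trade_allowed_between_countries = TRUE,
                            fixed_current_areas = FALSE) {
  diet_mode <- match.arg(diet_mode)
  objective <- match.arg(objective)
  if (objective == "calibrate" && !fixed_current_areas)
    stop_cf("the calibration objective requires fixed current areas")
  structure(list(
    name = name, diet_mode = diet_mode, objective = objective,
    artificial_fertilizer_allowed = artificial_fertilizer_allowed,
    waste_to_feed_allowed = waste_to_feed_allowed,
    waste_to_compost_allowed = waste_to_compost_allowed,
    byproducts_to_feed_allowed = byproducts_to_feed_allowed,
    trade_allowed_between_countries = trade_allowed_between_countries,
    fixed_current_areas = fixed_current_areas), class = "scenario_config")
}

#' @rdname scenario_config
#' @export
scenario_agribase <- function() {
  scenario_config("AgriBase", diet_mode = "calibrate",
                  objective = "calibrate",
                  waste_to_feed_allowed = FALSE,
                  waste_to_compost_allowed = FALSE,
                  fixed_current_areas = TRUE)
}

#' @rdname scenario_config
#' @export
scenario_ciragri <- function() {
  scenario_config("CirAgri", diet_mode = "current_protein",
                  objective = "min_land")
}

#' @rdname scenario_config
#' @export
scenario_cirhealth <- function() {
  scenario_config("CirHealth", diet_mode = "efsa_eat",
                  objective = "min_land")
}

#' @rdname scenario_config
#' @export
scenario_cirpop <- function() {
  scenario_config("CirPop+", diet_mode = "efsa_eat",
                  objective = "max_population")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': diet=%s, objective=%s\n", x$name, x$diet_mode,
              x$objective))
  cat(sprintf("  artificial fertilizer: %s; waste->feed: %s; waste->compost: %s; by-products->feed: %s; trade: %s%s\n",
              x$artificial_fertilizer_allowed, x$waste_to_feed_allowed,
              x$waste_to_compost_allowed, x$byproducts_to_feed_allowed,
              x$trade_allowed_between_countries,
              if (x$fixed_current_areas) "; areas fixed to current" else ""))
  invisible(x)
}
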