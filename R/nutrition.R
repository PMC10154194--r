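## Diet-side computations: nutrient intake from a diet, the stage-wise waste
## chain between supply and intake, and the three dietary constraint
## families (nutrient reference bounds, food-group bounds, current protein
## supply matching). All bounds are inclusive: the optimizer's feasible set
## is the closed region on which the violation lists returned here are
## empty.

#' Nutrient content of a diet
#'
#' Linear combination of food amounts with the composition table:
#' `amount (g/day) x composition (per kg) / 1000`, summed over foods. The
#' result is additive and monotone in the diet.
#'
#' @param diet named numeric vector, g fresh weight per capita per day by
#'   food
#' @param composition food x nutrient table as in an instance (data.frame
#'   with a `food` column, per kg edible fresh matter)
#' @return named numeric vector over the 42 nutrients, per capita per day
#' @export
diet_nutrients <- function(diet, composition) {
  out <- stats::setNames(numeric(length(nutrient_ids())), nutrient_ids())
  if (length(diet) == 0) return(out)
  missing <- setdiff(names(diet), composition$food)
  if (length(missing) > 0)
    stop_cf("no composition row for food(s): %s", paste(missing, collapse = ", "))
  m <- as.matrix(composition[match(names(diet), composition$food),
                             nutrient_ids(), drop = FALSE])
  out + drop(crossprod(m, diet)) / 1000
}

#' Apply the supply-chain waste cascade
#'
#' Food is lost at the post-harvest, processing, distribution and
#' consumption stages; intake is supply times the product of (1 - fraction)
#' over the stages. The stage-wise losses are returned alongside the
#' intake and conserve mass exactly: intake + sum(losses) == supply.
#'
#' @param supply named numeric vector of supply per food (any mass unit)
#' @param stage_fracs either a numeric vector of stage fractions applied to
#'   every food, or a data.frame in the instance `stage_waste` layout with a
#'   `food` column
#' @return list with `intake` (named vector), `losses` (food x stage
#'   matrix) and `consumption_waste` (named vector, the last-stage loss)
#' @export
apply_waste_chain <- function(supply, stage_fracs) {
  stages <- c("post_harvest", "processing", "distribution", "consumption")
  if (is.data.frame(stage_fracs)) {
    i <- match(names(supply), stage_fracs$food)
    if (anyNA(i))
      stop_cf("no stage-waste fractions for food(s): %s",
              paste(names(supply)[is.na(i)], collapse = ", "))
    fr <- as.matrix(stage_fracs[i, stages, drop = FALSE])
  } else {
    fr <- matrix(rep(as.numeric(stage_fracs), each = length(supply)),
                 nrow = length(supply),
                 dimnames = list(names(supply), names(stage_fracs) %||% stages))
  }
  if (any(fr < 0) || any(fr >= 1))
    stop_cf("stage waste fractions must lie in [0, 1)")
  losses <- fr * NA_real_
  remaining <- supply
  for (s in seq_len(ncol(fr))) {
    losses[, s] <- remaining * fr[, s]
    remaining <- remaining - losses[, s]
  }
  rownames(losses) <- names(supply)
  list(intake = remaining, losses = losses,
       consumption_waste = losses[, ncol(losses)])
}

#' Nutrient reference-bound violations
#'
#' @param intake_nutrients named vector over the 42 nutrients (per capita
#'   per day), as returned by [diet_nutrients()]
#' @param specs nutrient spec table (`nutrient`, `min`, `max`; NA bounds are
#'   unbounded)
#' @return data.frame (`nutrient`, `bound`, `limit`, `value`); empty iff
#'   min <= value <= max holds (inclusively) for every bounded nutrient
#' @export
nutrient_bound_violations <- function(intake_nutrients, specs) {
  out <- list()
  for (i in seq_len(nrow(specs))) {
    n <- specs$nutrient[i]
    val <- intake_nutrients[[n]]
    if (is.null(val)) stop_cf("intake vector lacks nutrient '%s'", n)
    if (!is.na(specs$min[i]) && val < specs$min[i] - 1e-9)
      out[[length(out) + 1]] <- data.frame(nutrient = n, bound = "min",
                                           limit = specs$min[i], value = val)
    if (!is.na(specs$max[i]) && val > specs$max[i] + 1e-9)
      out[[length(out) + 1]] <- data.frame(nutrient = n, bound = "max",
                                           limit = specs$max[i], value = val)
  }
  if (length(out) == 0)
    data.frame(nutrient = character(), bound = character(),
               limit = numeric(), value = numeric())
  else do.call(rbind, out)
}

#' Food-group intake-bound violations
#'
#' Gram-per-day groups are checked directly against the diet; the grains
#' bound is checked as a share of total energy intake.
#'
#' @param diet named vector, g fresh/capita/day at intake level
#' @param bounds food-group bound table (`group`, `min`, `max`, `unit`)
#' @param food_group named character vector mapping each diet food to its
#'   group
#' @param composition composition table (needed for the energy-share bound)
#' @return data.frame of violations; empty iff the diet respects every bound
#' @export
food_group_violations <- function(diet, bounds, food_group, composition) {
  unmapped <- setdiff(names(diet), names(food_group))
  if (length(unmapped) > 0)
    stop_cf("food(s) not mapped to a food group: %s",
            paste(unmapped, collapse = ", "))
  grp <- food_group[names(diet)]
  totals <- tapply(diet, grp, sum)
  nv <- diet_nutrients(diet, composition)
  energy_total <- nv[["energy"]]
  out <- list()
  for (i in seq_len(nrow(bounds))) {
    g <- bounds$group[i]
    if (bounds$unit[i] == "energy_share") {
      in_g <- names(diet)[grp == g]
      e_g <- if (length(in_g)) diet_nutrients(diet[in_g], composition)[["energy"]] else 0
      share <- if (energy_total > 0) e_g / energy_total else 0
      if (share > bounds$max[i] + 1e-9)
        out[[length(out) + 1]] <- data.frame(group = g, bound = "max",
                                             limit = bounds$max[i],
                                             value = share,
                                             unit = "energy_share")
    } else {
      val <- if (g %in% names(totals)) totals[[g]] else 0
      if (val < bounds$min[i] - 1e-9)
        out[[length(out) + 1]] <- data.frame(group = g, bound = "min",
                                             limit = bounds$min[i],
                                             value = val, unit = "g_day")
      if (val > bounds$max[i] + 1e-9)
        out[[length(out) + 1]] <- data.frame(group = g, bound = "max",
                                             limit = bounds$max[i],
                                             value = val, unit = "g_day")
    }
  }
  if (length(out) == 0)
    data.frame(group = character(), bound = character(), limit = numeric(),
               value = numeric(), unit = character())
  else do.call(rbind, out)
}

#' Shortfalls against current protein supply
#'
#' In supply-side circular scenarios the redesigned system must deliver at
#' least the current protein supply per country and food group; this
#' reports every (country, group) pair falling short.
#'
#' @param delivered data.frame (`country`, `group`, `g_protein_cap_day`)
#'   achieved by a solution
#' @param current same layout, the baseline supply
#' @return data.frame of shortfalls with absolute and relative size; empty
#'   iff delivered >= current everywhere
#' @export
protein_supply_match <- function(delivered, current) {
  out <- list()
  for (i in seq_len(nrow(current))) {
    j <- which(delivered$country == current$country[i] &
                 delivered$group == current$group[i])
    got <- if (length(j)) sum(delivered$g_protein_cap_day[j]) else 0
    want <- current$g_protein_cap_day[i]
    if (got < want - 1e-9)
      out[[length(out) + 1]] <- data.frame(
        country = current$country[i], group = current$group[i],
        required = want, delivered = got, shortfall = want - got,
        shortfall_frac = (want - got) / want)
  }
  if (length(out) == 0)
    data.frame(country = character(), group = character(),
               required = numeric(), delivered = numeric(),
               shortfall = numeric(), shortfall_frac = numeric())
  else do.call(rbind, out)
}
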