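## LP assembly. Decision variables (fixed order for determinism):
##   area|crop|zone      ha/yr cultivated (suitable pairs only)
##   gha|zone            ha grassland in use
##   units|system|c      producing units (1 unit = 1 t primary product/yr)
##   flow|food|c1|c2     t/yr of consumer-level food supply produced in c1
##                       and consumed in c2
##   fishland|c          t/yr capture-fishery landings
##   x|feed|system|c     t as-fed/yr allocated (legal pairs only)
##   ff|feed|c1|c2       t/yr feed moved from c1 to c2 (tradeable feeds)
##   bcomp|feed|c        t/yr of by-product composted instead of fed
##   orgn|src|zone       kg N/yr of organic fertilizer applied (manure,
##                       compost, sludge; P follows the fixed N:P ratio)
##   artn|z, artp|z      kg/yr artificial N and P
##   mu                  population multiplier (max-population mode)
##   devp|grp|c, devm|..  calibration deviation slacks (t protein-eq)
##
## Feed legality and in-country rules (food waste, grass) are structural:
## illegal variables are never created, which makes those constraint
## families trivially tight in every solution.

pb_new <- function() {
  env <- new.env(parent = emptyenv())
  env$vars <- character(0)
  env$obj <- numeric(0)
  env$cons <- list()
  env
}

pb_var <- function(pb, name, obj = 0) {
  if (!name %in% pb$vars) {
    pb$vars <- c(pb$vars, name)
    pb$obj <- c(pb$obj, obj)
  }
  name
}

pb_con <- function(pb, coef, dir, rhs, family, name = NULL) {
  coef <- coef[!is.na(coef) & coef != 0]
  if (length(coef) == 0) {
    ## constant constraint: check satisfiability directly; an unsatisfiable
    ## one (e.g. a positive requirement no variable can serve) is encoded
    ## as an infeasible row so the solver reports it
    ok <- switch(dir, "<=" = 0 <= rhs + 1e-9, ">=" = 0 >= rhs - 1e-9,
                 "=" = abs(rhs) <= 1e-9)
    if (!ok) {
      pb_var(pb, "__infeasible__")
      pb$cons[[length(pb$cons) + 1]] <-
        list(coef = c(`__infeasible__` = 1), dir = "<=", rhs = -1,
             family = family, name = name %||% family)
    }
    return(invisible(NULL))
  }
  pb$cons[[length(pb$cons) + 1]] <-
    list(coef = coef, dir = dir, rhs = rhs, family = family,
         name = name %||% family)
  invisible(NULL)
}

#' Assemble the scenario optimization problem
#'
#' Translates an instance plus a scenario configuration into a linear
#' program over areas, grassland use, animal units, feed allocations,
#' food and feed flows, fishery landings, fertilizer applications and
#' (in max-population mode) a population multiplier, with the constraint
#' families: land, rotation/suitability caps, production balances, feed
#' balance (legality structural), fertilizer balance, waste availability,
#' fishery caps, nutrition bounds, food-group bounds, protein-supply
#' matching, in-country-use rules (structural) and the per-capita
#' transport-emission cap.
#'
#' @param instance a valid `food_system_instance`
#' @param scenario a `scenario_config`
#' @return a `food_system_problem` list: objective, constraint matrix,
#'   directions, right-hand sides, variable names, constraint families and
#'   index maps used for solution extraction
#' @export
build_problem <- function(instance, scenario) {
  inst <- instance
  sc <- scenario
  if (sc$diet_mode %in% c("calibrate", "current_protein") &&
      is.null(inst$current))
    stop_cf("scenario '%s' needs current-supply data, but the instance has none",
            sc$name)
  pb <- pb_new()
  countries <- inst$countries$country
  pop <- stats::setNames(inst$countries$population, countries)
  zones <- inst$zones
  crops <- inst$crops
  foods <- inst$foods$food
  grp <- stats::setNames(inst$foods$food_group, foods)
  comp <- comp_matrix(inst)
  systems <- inst$animal_systems
  feeds <- inst$feeds
  dist <- country_dist_km(inst)
  ec <- inst$emission_constants
  rp <- inst$residual_params
  minimize <- sc$objective != "max_population"

  ## consumption-stage waste fraction and post-farm conversion per food
  w4 <- vapply(foods, function(f) waste_row(inst, f)$consumption, numeric(1))
  postconv <- vapply(foods, function(f) {
    w <- waste_row(inst, f)
    src <- inst$foods$source[match(f, inst$foods$food)]
    if (src == "crop") supply_per_harvest(inst, f)
    else if (src == "animal") (1 - w$processing) * (1 - w$distribution)
    else (1 - w$post_harvest) * (1 - w$processing) * (1 - w$distribution)
  }, numeric(1))

  suit <- stats::setNames(
    lapply(zones$zone, function(z) suitable_crops(z, inst)), zones$zone)

  ## ---- variables -----------------------------------------------------------
  land_obj <- if (sc$objective == "min_land") 1 else 0
  for (z in zones$zone) for (cr in suit[[z]]$crop)
    pb_var(pb, paste("area", cr, z, sep = "|"), obj = land_obj)
  for (z in zones$zone) pb_var(pb, paste0("gha|", z), obj = land_obj)
  for (s in systems$system) for (cc in countries)
    pb_var(pb, paste("units", s, cc, sep = "|"))
  pairs <- if (sc$trade_allowed_between_countries)
    expand.grid(c1 = countries, c2 = countries, stringsAsFactors = FALSE)
  else data.frame(c1 = countries, c2 = countries)
  for (f in foods) for (k in seq_len(nrow(pairs)))
    pb_var(pb, paste("flow", f, pairs$c1[k], pairs$c2[k], sep = "|"))
  has_fishery <- nrow(inst$fish_stocks) > 0
  if (has_fishery) for (cc in countries) pb_var(pb, paste0("fishland|", cc))

  feed_included <- vapply(seq_len(nrow(feeds)), function(i) {
    f <- feeds$feed[i]
    if (feeds$origin[i] == "food_waste" && !sc$waste_to_feed_allowed)
      return(FALSE)
    if (feeds$origin[i] %in% c("crop_byproduct", "animal_byproduct") &&
        !sc$byproducts_to_feed_allowed && !sc$waste_to_compost_allowed)
      return(FALSE)
    TRUE
  }, logical(1))
  names(feed_included) <- feeds$feed
  feed_feedable <- vapply(seq_len(nrow(feeds)), function(i) {
    if (feeds$origin[i] == "food_waste") sc$waste_to_feed_allowed
    else if (feeds$origin[i] %in% c("crop_byproduct", "animal_byproduct"))
      sc$byproducts_to_feed_allowed
    else TRUE
  }, logical(1))
  names(feed_feedable) <- feeds$feed

  legal_x <- list()
  for (i in seq_len(nrow(feeds))) {
    f <- feeds$feed[i]
    if (!feed_included[[f]] || !feed_feedable[[f]]) next
    for (j in seq_len(nrow(systems))) {
      if (!feed_allowed(inst, f, systems$species[j])) next
      if (isTRUE(systems$fish[j]) && feeds$energy_mj_kg_fish[i] <= 0) next
      for (cc in countries) {
        v <- paste("x", f, systems$system[j], cc, sep = "|")
        pb_var(pb, v)
        legal_x[[length(legal_x) + 1]] <-
          data.frame(var = v, feed = f, system = systems$system[j],
                     country = cc)
      }
    }
  }
  legal_x <- if (length(legal_x)) do.call(rbind, legal_x) else
    data.frame(var = character(), feed = character(), system = character(),
               country = character())

  for (i in seq_len(nrow(feeds))) {
    f <- feeds$feed[i]
    if (!feed_included[[f]] || !feeds$tradeable[i] || !feed_feedable[[f]]) next
    for (k in seq_len(nrow(pairs)))
      pb_var(pb, paste("ff", f, pairs$c1[k], pairs$c2[k], sep = "|"))
  }
  if (sc$waste_to_compost_allowed) {
    for (i in which(feeds$origin %in% c("crop_byproduct", "animal_byproduct",
                                        "fish_byproduct"))) {
      f <- feeds$feed[i]
      if (!feed_included[[f]]) next
      for (cc in countries) pb_var(pb, paste("bcomp", f, cc, sep = "|"))
    }
  }
  org_sources <- c("manure"[nrow(systems) > 0],
                   "compost"[sc$waste_to_compost_allowed], "sludge")
  for (src in org_sources) for (z in zones$zone)
    pb_var(pb, paste("orgn", src, z, sep = "|"))
  if (sc$artificial_fertilizer_allowed) for (z in zones$zone) {
    pb_var(pb, paste0("artn|", z)); pb_var(pb, paste0("artp|", z))
  }
  use_mu <- sc$objective == "max_population"
  if (use_mu) pb_var(pb, "mu", obj = 1)
  if (sc$objective == "calibrate") {
    ## deviation slacks live on the annual-population-gram scale of the
    ## matching constraints; weighting by the inverse target on that same
    ## scale makes the objective a sum of relative deviations
    cur <- inst$current$supply_protein
    for (k in seq_len(nrow(cur))) {
      tgt <- max(cur$g_protein_cap_day[k] * pop[[cur$country[k]]] * 365, 1)
      pb_var(pb, paste("devp", cur$group[k], cur$country[k], sep = "|"),
             obj = 1 / tgt)
      pb_var(pb, paste("devm", cur$group[k], cur$country[k], sep = "|"),
             obj = 1 / tgt)
    }
  }

  ## ---- land, rotation, suitability ----------------------------------------
  for (zi in seq_len(nrow(zones))) {
    z <- zones$zone[zi]
    sv <- suit[[z]]
    if (nrow(sv) > 0) {
      coef <- stats::setNames(rep(1, nrow(sv)), paste("area", sv$crop, z,
                                                      sep = "|"))
      pb_con(pb, coef, "<=", zones$cropland_ha[zi], "land",
             paste0("cropland|", z))
      for (k in seq_len(nrow(sv)))
        pb_con(pb, stats::setNames(1, paste("area", sv$crop[k], z, sep = "|")),
               "<=", sv$cap_ha[k], "rotation_cap",
               paste("cap", sv$crop[k], z, sep = "|"))
    }
    pb_con(pb, stats::setNames(1, paste0("gha|", z)), "<=",
           grassland_ha(zones[zi, ]), "land", paste0("grassland|", z))
  }
  if (sc$fixed_current_areas) {
    cur <- inst$current
    for (z in zones$zone) {
      sv <- suit[[z]]
      for (cr in sv$crop) {
        k <- which(cur$areas$crop == cr & cur$areas$zone == z)
        a0 <- if (length(k)) sum(cur$areas$area_ha[k]) else 0
        pb_con(pb, stats::setNames(1, paste("area", cr, z, sep = "|")), "=",
               min(a0, sv$cap_ha[match(cr, sv$crop)]), "fixed_area",
               paste("fix", cr, z, sep = "|"))
      }
      k <- which(cur$grassland$zone == z)
      g0 <- if (length(k)) cur$grassland$grassland_ha[k] else 0
      pb_con(pb, stats::setNames(1, paste0("gha|", z)), "=",
             min(g0, grassland_ha(zones[match(z, zones$zone), ])),
             "fixed_area", paste0("fixg|", z))
    }
  }

  ## ---- production balances -------------------------------------------------
  out_flows <- function(f, cc) {
    k <- which(pairs$c1 == cc)
    stats::setNames(rep(-1, length(k)),
                    paste("flow", f, cc, pairs$c2[k], sep = "|"))
  }
  in_flow_vars <- function(f, cc) {
    k <- which(pairs$c2 == cc)
    paste("flow", f, pairs$c1[k], cc, sep = "|")
  }
  for (fi in seq_len(nrow(inst$foods))) {
    f <- inst$foods$food[fi]
    src <- inst$foods$source[fi]
    for (cc in countries) {
      coef <- out_flows(f, cc)  # -(flows out) + production >= 0
      if (src == "crop") {
        zz <- zones$zone[zones$country == cc]
        for (z in zz) {
          if (f %in% suit[[z]]$crop)
            coef[paste("area", f, z, sep = "|")] <-
              yield_of(inst, f, z) * postconv[[f]]
        }
      } else if (src == "animal") {
        ss <- systems$system[systems$product == f]
        for (s in ss)
          coef[paste("units", s, cc, sep = "|")] <- postconv[[f]]
      } else if (src == "fish" && has_fishery) {
        q <- inst$fish_quota[inst$fish_quota$country == cc, ]
        msy_c <- sum(inst$fish_stocks$msy_t[match(q$stock,
                                                  inst$fish_stocks$stock)] *
                       q$share)
        ebar <- if (msy_c > 0)
          sum(inst$fish_stocks$msy_t[match(q$stock, inst$fish_stocks$stock)] *
                q$share *
                inst$fish_stocks$edible_frac[match(q$stock,
                                                   inst$fish_stocks$stock)]) /
            msy_c else 0
        coef[paste0("fishland|", cc)] <- ebar * postconv[[f]]
      }
      pb_con(pb, coef, ">=", 0, "production_balance",
             paste("prod", f, cc, sep = "|"))
    }
  }
  if (has_fishery) for (cc in countries) {
    q <- inst$fish_quota[inst$fish_quota$country == cc, ]
    msy_c <- sum(inst$fish_stocks$msy_t[match(q$stock,
                                              inst$fish_stocks$stock)] *
                   q$share)
    pb_con(pb, stats::setNames(1, paste0("fishland|", cc)), "<=", msy_c,
           "fishery_cap", paste0("msy|", cc))
  }

  ## ---- feed balances -------------------------------------------------------
  avail_coef <- function(f, i, cc) {
    ## negative coefficients of the availability expression
    coef <- numeric(0)
    orig <- feeds$origin[i]
    if (orig == "grass") {
      zz <- which(zones$country == cc)
      coef[paste0("gha|", zones$zone[zz])] <- -zones$grass_yield_t_dm_ha[zz]
    } else if (orig == "fodder_crop") {
      crn <- sub("_feed$", "", f)
      zz <- zones$zone[zones$country == cc]
      for (z in zz) if (crn %in% suit[[z]]$crop)
        coef[paste("area", crn, z, sep = "|")] <- -yield_of(inst, crn, z)
    } else if (orig == "crop_byproduct") {
      for (j in which(!is.na(crops$byproduct_feed) &
                        crops$byproduct_feed == f & crops$use == "food")) {
        crn <- crops$crop[j]
        bps <- byproduct_per_supply(inst, crn)
        k <- which(pairs$c1 == cc)
        vs <- paste("flow", crn, cc, pairs$c2[k], sep = "|")
        coef[vs] <- (if (length(coef)) coef[vs] else 0)
        coef[vs] <- ifelse(is.na(coef[vs]), 0, coef[vs]) - bps
      }
    } else if (orig == "animal_byproduct") {
      for (j in which(!systems$fish))
        coef[paste("units", systems$system[j], cc, sep = "|")] <-
          -systems$byproduct_frac[j]
    } else if (orig == "fish_byproduct") {
      if (has_fishery) {
        q <- inst$fish_quota[inst$fish_quota$country == cc, ]
        msy_c <- sum(inst$fish_stocks$msy_t[match(q$stock,
                                                  inst$fish_stocks$stock)] *
                       q$share)
        ebar <- if (msy_c > 0)
          sum(inst$fish_stocks$msy_t[match(q$stock, inst$fish_stocks$stock)] *
                q$share *
                inst$fish_stocks$edible_frac[match(q$stock,
                                                   inst$fish_stocks$stock)]) /
            msy_c else 0
        coef[paste0("fishland|", cc)] <- -(1 - ebar)
      }
      for (j in which(systems$fish))
        coef[paste("units", systems$system[j], cc, sep = "|")] <-
          -systems$byproduct_frac[j]
    } else if (orig == "food_waste") {
      for (f2 in foods) {
        vs <- in_flow_vars(f2, cc)
        coef[vs] <- (if (length(coef)) ifelse(is.na(coef[vs]), 0, coef[vs]) else 0) -
          rp$waste_to_feed_frac * w4[[f2]]
      }
    }
    coef[!is.na(coef)]
  }

  for (i in seq_len(nrow(feeds))) {
    f <- feeds$feed[i]
    if (!feed_included[[f]]) next
    tradeable <- feeds$tradeable[i] && sc$trade_allowed_between_countries &&
      feed_feedable[[f]]
    for (cc in countries) {
      av <- avail_coef(f, i, cc)
      use <- numeric(0)
      xs <- legal_x$var[legal_x$feed == f & legal_x$country == cc]
      bc <- paste("bcomp", f, cc, sep = "|")
      has_bc <- bc %in% pb$vars
      if (tradeable) {
        k <- which(pairs$c1 == cc)
        outv <- paste("ff", f, cc, pairs$c2[k], sep = "|")
        coef <- av
        coef[outv] <- 1
        if (has_bc) coef[bc] <- 1
        fam <- if (feeds$origin[i] == "food_waste") "waste_availability"
               else "feed_balance"
        pb_con(pb, coef, "<=", 0, fam, paste("avail", f, cc, sep = "|"))
        if (length(xs)) {
          k2 <- which(pairs$c2 == cc)
          inv <- paste("ff", f, pairs$c1[k2], cc, sep = "|")
          coef2 <- stats::setNames(rep(1, length(xs)), xs)
          coef2[inv] <- -1
          pb_con(pb, coef2, "<=", 0, "feed_balance",
                 paste("use", f, cc, sep = "|"))
        }
      } else {
        coef <- av
        if (length(xs)) coef[xs] <- 1
        if (has_bc) coef[bc] <- 1
        fam <- if (feeds$origin[i] == "food_waste") "waste_availability"
               else "feed_balance"
        pb_con(pb, coef, "<=", 0, fam, paste("avail", f, cc, sep = "|"))
      }
    }
  }

  ## ---- animal requirements -------------------------------------------------
  for (j in seq_len(nrow(systems))) {
    s <- systems$system[j]
    r <- unit_requirements(systems[j, ])
    for (cc in countries) {
      uv <- paste("units", s, cc, sep = "|")
      xs <- legal_x[legal_x$system == s & legal_x$country == cc, ]
      e_coef <- p_coef <- d_coef <- stats::setNames(numeric(nrow(xs)), xs$var)
      for (k in seq_len(nrow(xs))) {
        d <- feed_delivery(feed_row(inst, xs$feed[k]), isTRUE(systems$fish[j]))
        e_coef[k] <- d[["energy_mj"]]
        p_coef[k] <- d[["protein_kg"]]
        d_coef[k] <- d[["dm_t"]]
      }
      pb_con(pb, c(e_coef, stats::setNames(-r[["energy_mj"]], uv)), ">=", 0,
             "feed_requirement", paste("energy", s, cc, sep = "|"))
      pb_con(pb, c(p_coef, stats::setNames(-r[["protein_kg"]], uv)), ">=", 0,
             "feed_requirement", paste("protein", s, cc, sep = "|"))
      pb_con(pb, c(d_coef, stats::setNames(-r[["intake_t_dm"]], uv)), "<=", 0,
             "feed_requirement", paste("intake", s, cc, sep = "|"))
    }
  }

  ## ---- fertilizer balance --------------------------------------------------
  npr <- rp$organic_np
  for (zi in seq_len(nrow(zones))) {
    z <- zones$zone[zi]
    sv <- suit[[z]]
    nmult <- n_loss_multiplier(inst, zones$climate[zi])
    pmult <- 1 + ec$p_unavoidable_loss
    ncoef <- pcoef <- numeric(0)
    for (k in seq_len(nrow(sv))) {
      cr <- crop_row(inst, sv$crop[k])
      y <- sv$yield_t_ha[k]
      av <- paste("area", sv$crop[k], z, sep = "|")
      ncoef[av] <- y * (cr$n_conc_product + cr$residue_ratio * cr$n_conc_residue) * nmult
      pcoef[av] <- y * (cr$p_conc_product + cr$residue_ratio * cr$p_conc_residue) * pmult
    }
    for (src in org_sources) {
      ov <- paste("orgn", src, z, sep = "|")
      ncoef[ov] <- -1
      pcoef[ov] <- -1 / npr[[src]]
    }
    if (sc$artificial_fertilizer_allowed) {
      ncoef[paste0("artn|", z)] <- -1
      pcoef[paste0("artp|", z)] <- -1
    }
    pb_con(pb, ncoef, "<=", 0, "fertilizer_balance", paste0("nreq|", z))
    pb_con(pb, pcoef, "<=", 0, "fertilizer_balance", paste0("preq|", z))
  }
  ## organic pools per country
  for (cc in countries) {
    zz <- zones$zone[zones$country == cc]
    if ("manure" %in% org_sources) {
      coef <- stats::setNames(rep(1, length(zz)),
                              paste("orgn", "manure", zz, sep = "|"))
      xs <- legal_x[legal_x$country == cc, ]
      for (k in seq_len(nrow(xs))) {
        j <- match(xs$system[k], systems$system)
        if (isTRUE(systems$fish[j])) next
        nf <- feed_row(inst, xs$feed[k])$n_g_kg
        coef[xs$var[k]] <- (coef[xs$var[k]] %||% 0)
        coef[xs$var[k]] <- ifelse(is.na(coef[xs$var[k]]), 0, coef[xs$var[k]]) -
          nf * (1 - systems$n_retention[j]) *
          (1 - systems$grazing_share[j]) * (1 - systems$mms_volat_frac[j])
      }
      pb_con(pb, coef, "<=", 0, "fertilizer_balance", paste0("manure_pool|", cc))
    }
    if ("compost" %in% org_sources) {
      coef <- stats::setNames(rep(1, length(zz)),
                              paste("orgn", "compost", zz, sep = "|"))
      loss <- 1 - rp$compost_n_loss
      if (sc$waste_to_feed_allowed || TRUE) {
        n_fw <- if ("food_waste" %in% feeds$feed)
          feed_row(inst, "food_waste")$n_g_kg else 7
        for (f2 in foods) {
          vs <- in_flow_vars(f2, cc)
          coef[vs] <- ifelse(is.na(coef[vs]), 0, coef[vs]) -
            loss * n_fw * w4[[f2]]
        }
        xs <- legal_x$var[legal_x$feed == "food_waste" &
                            legal_x$country == cc]
        if (length(xs))
          coef[xs] <- ifelse(is.na(coef[xs]), 0, coef[xs]) + loss * n_fw
      }
      for (i in which(feeds$origin %in% c("crop_byproduct",
                                          "animal_byproduct",
                                          "fish_byproduct"))) {
        bc <- paste("bcomp", feeds$feed[i], cc, sep = "|")
        if (bc %in% pb$vars)
          coef[bc] <- ifelse(is.na(coef[bc]), 0, coef[bc] %||% 0) -
            loss * feeds$n_g_kg[i]
      }
      pb_con(pb, coef, "<=", 0, "fertilizer_balance", paste0("compost_pool|", cc))
    }
    sl <- sludge_fertilizer(sum(inst$countries$sludge_fresh_t[
      inst$countries$country == cc]), rp)
    coef <- stats::setNames(rep(1, length(zz)),
                            paste("orgn", "sludge", zz, sep = "|"))
    pb_con(pb, coef, "<=", sl$n_t * 1000, "fertilizer_balance",
           paste0("sludge_pool|", cc))
  }

  ## ---- diet constraints ----------------------------------------------------
  intake_coef <- function(cc, foods_sel, per_kg) {
    ## coefficients of annual intake-level quantity in units of per_kg x kg
    coef <- numeric(0)
    for (f in foods_sel) {
      if (per_kg[[f]] == 0) next
      vs <- in_flow_vars(f, cc)
      coef[vs] <- ifelse(is.na(coef[vs]), 0, coef[vs]) +
        (1 - w4[[f]]) * 1000 * per_kg[[f]]
    }
    coef
  }
  if (sc$diet_mode == "efsa_eat") {
    nu <- inst$nutrients
    for (cc in countries) {
      for (k in which(!is.na(nu$min) | !is.na(nu$max))) {
        n <- nu$nutrient[k]
        per_kg <- stats::setNames(comp[foods, n], foods)
        coef <- intake_coef(cc, foods, per_kg)
        if (!is.na(nu$min[k])) {
          cf <- coef
          rhs <- nu$min[k] * pop[[cc]] * 365
          if (use_mu) { cf["mu"] <- -rhs; rhs <- 0 }
          pb_con(pb, cf, ">=", rhs, "nutrition", paste("nutmin", n, cc, sep = "|"))
        }
        if (!is.na(nu$max[k])) {
          cf <- coef
          rhs <- nu$max[k] * pop[[cc]] * 365
          if (use_mu) { cf["mu"] <- -rhs; rhs <- 0 }
          pb_con(pb, cf, "<=", rhs, "nutrition", paste("nutmax", n, cc, sep = "|"))
        }
      }
      fb <- inst$food_group_bounds
      for (k in seq_len(nrow(fb))) {
        g <- fb$group[k]
        sel <- foods[grp[foods] == g]
        if (fb$unit[k] == "energy_share") {
          ## energy from group <= share x total energy
          eg <- intake_coef(cc, sel, stats::setNames(comp[sel, "energy"], sel))
          et <- intake_coef(cc, foods, stats::setNames(comp[foods, "energy"],
                                                       foods))
          coef <- -fb$max[k] * et
          coef[names(eg)] <- ifelse(is.na(coef[names(eg)]), 0,
                                    coef[names(eg)]) + eg
          pb_con(pb, coef, "<=", 0, "food_group",
                 paste("fgshare", g, cc, sep = "|"))
        } else {
          ones <- stats::setNames(rep(1, length(sel)), sel)
          coef <- numeric(0)
          for (f in sel) {
            vs <- in_flow_vars(f, cc)
            coef[vs] <- ifelse(is.na(coef[vs]), 0, coef[vs]) +
              (1 - w4[[f]]) * 1e6
          }
          if (fb$min[k] > 0) {
            cf <- coef; rhs <- fb$min[k] * pop[[cc]] * 365
            if (use_mu) { cf["mu"] <- -rhs; rhs <- 0 }
            pb_con(pb, cf, ">=", rhs, "food_group",
                   paste("fgmin", g, cc, sep = "|"))
          }
          cf <- coef; rhs <- fb$max[k] * pop[[cc]] * 365
          if (use_mu) { cf["mu"] <- -rhs; rhs <- 0 }
          pb_con(pb, cf, "<=", rhs, "food_group",
                 paste("fgmax", g, cc, sep = "|"))
        }
      }
    }
  }
  if (sc$diet_mode == "current_protein") {
    cur <- inst$current$supply_protein
    for (k in seq_len(nrow(cur))) {
      cc <- cur$country[k]; g <- cur$group[k]
      sel <- foods[grp[foods] == g]
      coef <- numeric(0)
      for (f in sel) {
        vs <- in_flow_vars(f, cc)
        coef[vs] <- ifelse(is.na(coef[vs]), 0, coef[vs]) +
          1000 * comp[f, "protein"]
      }
      pb_con(pb, coef, ">=", cur$g_protein_cap_day[k] * pop[[cc]] * 365,
             "protein_match", paste("protmatch", g, cc, sep = "|"))
    }
  }
  if (sc$objective == "calibrate") {
    cur <- inst$current$supply_protein
    for (k in seq_len(nrow(cur))) {
      cc <- cur$country[k]; g <- cur$group[k]
      sel <- foods[grp[foods] == g]
      coef <- numeric(0)
      for (f in sel) {
        vs <- in_flow_vars(f, cc)
        coef[vs] <- ifelse(is.na(coef[vs]), 0, coef[vs]) +
          1000 * comp[f, "protein"]
      }
      coef[paste("devp", g, cc, sep = "|")] <- -1
      coef[paste("devm", g, cc, sep = "|")] <- 1
      pb_con(pb, coef, "=", cur$g_protein_cap_day[k] * pop[[cc]] * 365,
             "calibration", paste("calib", g, cc, sep = "|"))
    }
  }

  ## ---- transport cap -------------------------------------------------------
  if (sc$trade_allowed_between_countries && length(countries) > 1) {
    for (cc in countries) {
      coef <- numeric(0)
      for (c1 in setdiff(countries, cc)) {
        dkm <- dist[c1, cc]
        for (f in foods)
          coef[paste("flow", f, c1, cc, sep = "|")] <- dkm * ec$ef_transport
        for (i in seq_len(nrow(feeds))) {
          v <- paste("ff", feeds$feed[i], c1, cc, sep = "|")
          if (v %in% pb$vars) coef[v] <- dkm * ec$ef_transport
        }
      }
      rhs <- ec$transport_cap_co2e * pop[[cc]]
      if (use_mu) { coef["mu"] <- -rhs; rhs <- 0 }
      pb_con(pb, coef, "<=", rhs, "transport_cap", paste0("tcap|", cc))
    }
  }

  A <- matrix(0, length(pb$cons), length(pb$vars),
              dimnames = list(NULL, pb$vars))
  dirv <- character(length(pb$cons)); rhsv <- numeric(length(pb$cons))
  fams <- names_ <- character(length(pb$cons))
  for (i in seq_along(pb$cons)) {
    co <- pb$cons[[i]]
    bad <- setdiff(names(co$coef), pb$vars)
    co$coef <- co$coef[!names(co$coef) %in% bad]
    A[i, names(co$coef)] <- co$coef
    dirv[i] <- co$dir; rhsv[i] <- co$rhs
    fams[i] <- co$family; names_[i] <- co$name
  }
  structure(list(
    obj = pb$obj, A = A, dir = dirv, rhs = rhsv, vars = pb$vars,
    con_family = fams, con_name = names_, maximize = !minimize,
    families = sort(unique(c(fams, "feed_legality", "in_country_use"))),
    instance = inst, scenario = sc,
    n_vars = length(pb$vars), n_cons = length(pb$cons)),
    class = "food_system_problem")
}

#' @export
print.food_system_problem <- function(x, ...) {
  cat(sprintf("Food-system LP for scenario '%s': %d variables, %d constraints\n",
              x$scenario$name, x$n_vars, x$n_cons))
  cat("  constraint families:", paste(x$families, collapse = ", "), "\n")
  invisible(x)
}
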