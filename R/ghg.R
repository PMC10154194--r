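## Greenhouse-gas inventory. All operations are homogeneous of degree one
## in their activity input and follow tier-1/tier-2 inventory formulas:
## enteric CH4 from gross energy and Ym, manure CH4 from volatile solids,
## N2O from managed manure, grazing deposition, fertilized soils, drained
## organic soils, aquaculture and composting, CO2 from fertilizer
## production and transport. CH4 from rice and CO2 from soils and cropping
## are excluded by design. Gases aggregate to CO2e with 100-year GWPs of
## 28 (biogenic CH4) and 265 (N2O).

.N_TO_N2O <- 44 / 28

#' Enteric methane from gross energy intake
#'
#' CH4 (kg) = gross energy (MJ) x Ym / 100 / 55.65, where 55.65 MJ/kg is
#' the gross energy content of methane and Ym the percentage of gross feed
#' energy converted to methane (ruminants only).
#'
#' @param gross_energy_mj gross energy intake, MJ/yr
#' @param ym_percent Ym in percent, in \[0, 100\]
#' @param ch4_energy_mj_kg energy content of methane (default 55.65)
#' @return kg CH4/yr
#' @export
enteric_ch4 <- function(gross_energy_mj, ym_percent,
                        ch4_energy_mj_kg = 55.65) {
  if (any(ym_percent < 0 | ym_percent > 100))
    stop_cf("Ym must lie in [0, 100] percent")
  gross_energy_mj * (ym_percent / 100) / ch4_energy_mj_kg
}

#' Manure-management methane
#'
#' CH4 (kg) = volatile solids (kg) x MCF x B0 x 0.67, with 0.67 kg/m3
#' converting the methane volume to mass.
#'
#' @param vs_kg volatile solid excretion captured in the MMS, kg/yr
#' @param mcf methane conversion factor of the MMS, fraction
#' @param b0 maximum methane-producing capacity, m3 CH4/kg VS
#' @param ch4_m3_to_kg volume-to-mass conversion (default 0.67)
#' @return kg CH4/yr
#' @export
manure_ch4 <- function(vs_kg, mcf, b0, ch4_m3_to_kg = 0.67) {
  vs_kg * mcf * b0 * ch4_m3_to_kg
}

#' Manure-management nitrous oxide (direct + indirect)
#'
#' Direct emissions apply the MMS emission factor to the managed N;
#' indirect emissions apply the volatilization emission factor to the
#' volatilized ammonia-N share. Both are converted from N2O-N to N2O by
#' 44/28.
#'
#' @param n_mms_kg N excreted into the MMS, kg/yr
#' @param ef_direct kg N2O-N per kg N for the MMS
#' @param volat_frac fraction of managed N volatilized
#' @param ef_indirect kg N2O-N per kg volatilized N (default 0.010)
#' @return kg N2O/yr
#' @export
manure_n2o <- function(n_mms_kg, ef_direct, volat_frac = 0,
                       ef_indirect = 0.010) {
  (n_mms_kg * ef_direct + n_mms_kg * volat_frac * ef_indirect) * .N_TO_N2O
}

#' Aquaculture nitrous oxide
#'
#' The N in unconsumed feed plus excreta is multiplied by 1.8% and
#' converted from N to N2O.
#'
#' @param n_kg unconsumed plus excreted N, kg/yr
#' @param frac emission fraction (default 0.018)
#' @return kg N2O/yr
#' @export
aquaculture_n2o <- function(n_kg, frac = 0.018) {
  n_kg * frac * .N_TO_N2O
}

#' Soil nitrous oxide from fertilization
#'
#' Tier-1: applied N times a direct emission factor that depends on the
#' fertilizer type (synthetic vs organic amendment) and climate, plus
#' indirect emissions from volatilization and from leaching in wet
#' climates, plus an area-based term for drained organic (peat) soils that
#' applies regardless of N input.
#'
#' @param n_applied_kg named vector of applied N by source type
#'   (`artificial`, `manure`, `compost`, `sludge`)
#' @param climate `"wet"` or `"dry"`
#' @param ec the instance `emission_constants` list
#' @param organic_soil_ha cultivated area on drained organic soils, ha
#' @return kg N2O/yr
#' @export
soil_n2o <- function(n_applied_kg, climate, ec, organic_soil_ha = 0) {
  stopifnot(climate %in% c("wet", "dry"))
  leach <- if (climate == "wet") ec$n_leach_frac_wet else ec$n_leach_frac_dry
  ef_org <- if (climate == "wet") ec$ef_soil_organic_wet else ec$ef_soil_organic_dry
  n2o_n <- 0
  for (src in names(n_applied_kg)) {
    n <- n_applied_kg[[src]]
    synth <- src == "artificial"
    ef_dir <- if (synth) ec$ef_soil_synthetic else ef_org
    volat <- if (synth) ec$n_volat_frac_synthetic else ec$n_volat_frac_organic
    n2o_n <- n2o_n + n * (ef_dir + volat * ec$ef_volat_indirect +
                            leach * ec$ef_leach_indirect)
  }
  n2o_n <- n2o_n + organic_soil_ha * ec$ef_organic_soil_n2o_ha
  n2o_n * .N_TO_N2O
}

#' Grazing-deposition nitrous oxide
#'
#' Direct emissions from urine and dung deposited on pasture plus the
#' indirect volatilization pathway; distinct emission factors from managed
#' manure.
#'
#' @param n_pasture_kg N deposited on grassland, kg/yr
#' @param ec the instance `emission_constants` list
#' @return kg N2O/yr
#' @export
grassland_n2o <- function(n_pasture_kg, ec) {
  (n_pasture_kg * ec$ef_grazing_n2o +
     n_pasture_kg * ec$n_volat_frac_organic * ec$ef_volat_indirect) * .N_TO_N2O
}

#' Composting emissions
#'
#' N2O from the N content of the composted waste; CH4 from its carbon
#' content, obtained from the N content through the C:N ratio of an
#' average compost (15).
#'
#' @param n_kg N entering the composter, kg/yr
#' @param ec the instance `emission_constants` list
#' @param compost_cn C:N ratio (default 15)
#' @return list with `n2o_kg` and `ch4_kg`
#' @export
compost_emissions <- function(n_kg, ec, compost_cn = 15) {
  c_kg <- n_kg * compost_cn
  list(n2o_kg = n_kg * ec$compost_ef_n2o * .N_TO_N2O,
       ch4_kg = c_kg * ec$compost_c_to_ch4)
}

#' Transport emissions and the per-capita cap check
#'
#' Ton-kilometres times an emission factor; intra-country distances are
#' zero. Flags every country whose per-capita transport emissions exceed
#' the cap (default 1500 kg CO2e/person/yr).
#'
#' @param flows data.frame (`from`, `to`, `t`) of transported mass
#' @param dist_km symmetric country distance matrix with zero diagonal
#' @param ef_t_km kg CO2e per ton-km
#' @param population named vector of persons per country (destination
#'   attribution)
#' @param cap per-capita cap, kg CO2e/yr
#' @return list with `co2e_kg`, `per_capita` (named by country) and
#'   `violations` (countries over the cap)
#' @export
transport_emissions <- function(flows, dist_km, ef_t_km, population = NULL,
                                cap = 1500) {
  if (nrow(flows) == 0) {
    return(list(co2e_kg = 0, per_capita = NULL, violations = character(0)))
  }
  d <- mapply(function(a, b) {
    if (is.na(dist_km[a, b])) stop_cf("missing distance %s -> %s", a, b)
    dist_km[a, b]
  }, flows$from, flows$to)
  e <- flows$t * d * ef_t_km
  total <- sum(e)
  per_capita <- NULL
  violations <- character(0)
  if (!is.null(population)) {
    by_dest <- tapply(e, flows$to, sum)
    per_capita <- by_dest / population[names(by_dest)]
    violations <- names(per_capita)[per_capita > cap + 1e-9]
  }
  list(co2e_kg = total, per_capita = per_capita, violations = violations)
}

#' Emissions from artificial-fertilizer production
#'
#' @param n_t,p_t artificial N and P applied, t/yr
#' @param ec the instance `emission_constants` list
#' @return kg CO2e/yr
#' @export
fertilizer_production_emissions <- function(n_t, p_t, ec) {
  n_t * 1000 * ec$ef_fert_prod_n + p_t * 1000 * ec$ef_fert_prod_p
}

#' Aggregate an inventory to CO2 equivalents
#'
#' total = CO2 + 28 x CH4 + 265 x N2O (100-year horizon, biogenic CH4).
#'
#' @param inventory data.frame (`category`, `gas`, `kg`)
#' @param population persons fed (for the per-capita total); may be NULL
#' @param gwp_ch4,gwp_n2o global-warming potentials
#' @return list with `total_co2e_kg` and `co2e_kg_per_capita`
#' @export
total_co2e <- function(inventory, population = NULL, gwp_ch4 = 28,
                       gwp_n2o = 265) {
  w <- c(CO2 = 1, CH4 = gwp_ch4, N2O = gwp_n2o)
  bad <- setdiff(unique(inventory$gas), names(w))
  if (length(bad) > 0) stop_cf("unknown gas(es): %s", paste(bad, collapse = ", "))
  total <- sum(inventory$kg * w[inventory$gas])
  per_cap <- if (is.null(population)) NA_real_ else {
    if (population <= 0) stop_cf("population must be > 0 for per-capita totals")
    total / population
  }
  list(total_co2e_kg = total, co2e_kg_per_capita = per_cap)
}
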