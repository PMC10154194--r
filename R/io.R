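## Instance files are human-editable YAML: every table is written as a list
## of columns, every parameter block as a named mapping. Units are fixed by
## the schema (see R/instance.R) and stated in the file header comment.

.INSTANCE_KEYS <- c("name", "nutrients", "countries", "zones", "crops",
                    "yields", "foods", "composition", "animal_systems",
                    "feeds", "feed_legal", "fish_stocks", "fish_quota",
                    "food_group_bounds", "stage_waste", "residual_params",
                    "emission_constants", "current")

.INSTANCE_TABLES <- c("nutrients", "countries", "zones", "crops", "yields",
                      "foods", "composition", "animal_systems", "feeds",
                      "feed_legal", "fish_stocks", "fish_quota",
                      "food_group_bounds", "stage_waste")

df_to_list <- function(df) lapply(as.list(df), function(col) {
  if (is.factor(col)) as.character(col) else col
})

list_to_df <- function(x, what) {
  if (length(x) == 0) return(data.frame())
  n <- lengths(x)
  if (length(unique(n)) > 1)
    stop_cf("parse error in table '%s': columns have unequal lengths", what)
  as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
}

#' Write an instance to a YAML file
#'
#' @param instance a `food_system_instance`
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [load_instance()]
#' @export
write_instance <- function(instance, path) {
  x <- unclass(instance)
  ## named numeric parameters become YAML maps (names survive the trip)
  if (!is.null(x$residual_params$organic_np))
    x$residual_params$organic_np <- as.list(x$residual_params$organic_np)
  for (k in .INSTANCE_TABLES) if (!is.null(x[[k]])) x[[k]] <- df_to_list(x[[k]])
  if (!is.null(x$current)) {
    x$current$areas <- df_to_list(x$current$areas)
    x$current$grassland <- df_to_list(x$current$grassland)
    x$current$supply_protein <- df_to_list(x$current$supply_protein)
  }
  header <- paste0(
    "# food-system instance (units: ha, t fresh matter, kg nutrient/t,\n",
    "# MJ gross energy, g/capita/day, kg CO2e; see package documentation)\n")
  txt <- yaml::as.yaml(x, precision = 15)
  writeLines(paste0(header, txt), path)
  invisible(path)
}

#' Load an instance from a YAML file
#'
#' Parses and cross-links a food-system instance. Unknown top-level keys are
#' rejected; dangling references (a feed, crop, zone or food named but not
#' defined) surface as validation errors.
#'
#' @param path file written by [write_instance()] or hand-edited in the same
#'   schema
#' @param check validate the instance and stop on violations (default TRUE)
#' @return a `food_system_instance`
#' @export
load_instance <- function(path, check = TRUE) {
  if (!file.exists(path)) stop_cf("instance file '%s' does not exist", path)
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), .INSTANCE_KEYS)
  if (length(unknown) > 0)
    stop_cf("parse error: unknown instance key(s): %s",
            paste(unknown, collapse = ", "))
  missing <- setdiff(setdiff(.INSTANCE_KEYS, "name"), names(x))
  if (length(missing) > 0)
    stop_cf("parse error: missing instance key(s): %s",
            paste(missing, collapse = ", "))
  for (k in .INSTANCE_TABLES) x[[k]] <- list_to_df(x[[k]], k)
  x$current$areas <- list_to_df(x$current$areas, "current$areas")
  x$current$grassland <- list_to_df(x$current$grassland, "current$grassland")
  x$current$supply_protein <- list_to_df(x$current$supply_protein,
                                         "current$supply_protein")
  rp <- x$residual_params
  rp$organic_np <- unlist(rp$organic_np)
  x$residual_params <- rp
  inst <- canonicalize_instance(structure(x, class = "food_system_instance"))
  if (check) {
    rep <- validate_instance(inst)
    if (nrow(rep) > 0)
      stop_cf("dangling reference or invalid value in '%s': %s", path,
              paste(sprintf("[%s %s] %s", rep$type, rep$id, rep$rule),
                    collapse = "; "))
  }
  inst
}

## deterministic table writer: fixed column order, rows sorted on key columns
write_tsv_sorted <- function(df, path) {
  if (nrow(df) > 0) {
    keys <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(keys) > 0) df <- df[do.call(order, df[keys]), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a solution as delimited tables
#'
#' Writes one tab-separated file per solution component (areas, grassland
#' use, animal units, feed allocations, trade flows, fertilizer
#' applications, diets, greenhouse-gas inventory, summary) with units
#' declared in the column names. Row order is deterministic, so two writes
#' of the same solution are byte-identical.
#'
#' @param solution a `food_system_solution`
#' @param dir output directory (created if absent)
#' @return character vector of the files written, invisibly
#' @export
write_solution <- function(solution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    area = "area.tsv", grassland = "grassland.tsv", animals = "animals.tsv",
    feed_alloc = "feed_alloc.tsv", flows = "flows.tsv",
    fertilizer = "fertilizer.tsv", diet = "diet.tsv", ghg = "ghg.tsv",
    summary = "summary.tsv")
  out <- character(0)
  for (nm in names(files)) {
    df <- switch(nm,
      area = solution$area, grassland = solution$grassland,
      animals = solution$animals, feed_alloc = solution$feed_alloc,
      flows = solution$flows, fertilizer = solution$fertilizer,
      diet = solution$diet, ghg = solution$ghg$inventory,
      summary = data.frame(
        quantity = c("objective_value", "population_fed_persons",
                     "total_land_ha", "total_co2e_kg", "co2e_kg_per_capita"),
        value = c(solution$objective_value, solution$population_fed,
                  solution$total_land_ha, solution$ghg$total_co2e_kg,
                  solution$ghg$co2e_kg_per_capita)))
    p <- file.path(dir, files[[nm]])
    write_tsv_sorted(df, p)
    out <- c(out, p)
  }
  invisible(out)
}
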