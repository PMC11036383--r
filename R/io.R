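# Structured-config and CSV interfaces. Interface units are the bench units
# of the case-study tables (mbar, mL, um, g, mm); everything is converted to
# SI on ingestion.

scenario_config_keys <- c(
  "name", "solid_species", "solid_mass_g", "liquor_mass_g", "temperature_c",
  "liquor", "particles", "filter", "conditions", "cake", "wash_program",
  "species_overrides", "provenance"
)

#' Read an isolation scenario from a YAML config
#'
#' The config mirrors the case-study tables: masses in g, diameters in mm,
#' pressures in mbar, particle sizes in um, volumes in mL. Unknown top-level
#' keys are rejected before any computation.
#'
#' @param path Path to a YAML scenario config (see
#'   `system.file("extdata", "example_scenario.yaml", package = "cakewash")`).
#' @return An `isolation_scenario`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), scenario_config_keys)
  if (length(unknown) > 0) {
    abort_cw(paste0("unknown config keys: ", paste(unknown, collapse = ", ")), "config_error")
  }
  required <- c("name", "solid_species", "solid_mass_g", "liquor_mass_g",
                "liquor", "particles", "filter", "conditions", "cake")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    abort_cw(paste0("missing config keys: ", paste(missing, collapse = ", ")), "config_error")
  }
  db <- species_table()
  if (!is.null(cfg$species_overrides)) {
    db <- do.call(with_species, c(list(db), cfg$species_overrides))
  }
  p <- cfg$particles
  particles <- particle_population(
    mean_size = p$mean_size_um, sphericity = p$sphericity,
    x10 = p$x10_um %||% NA_real_, x50 = p$x50_um %||% NA_real_,
    x90 = p$x90_um %||% NA_real_, sd = p$sd_um %||% NA_real_
  )
  filt <- filter_spec(
    diameter = mm_to_m(cfg$filter$diameter_mm),
    medium_resistance = cfg$filter$medium_resistance_per_m,
    equipment_volume = ml_to_m3(cfg$filter$equipment_volume_ml %||% NA_real_)
  )
  conditions <- operating_conditions(
    driving_force_mbar = cfg$conditions$driving_force_mbar,
    temperature = cfg$conditions$temperature_c %||% cfg$temperature_c %||% 25
  )
  ck <- cfg$cake
  props <- cake_properties(
    porosity = ck$porosity, sphericity = ck$sphericity,
    compressibility_index = ck$compressibility_index %||% 0,
    reference_pressure = mbar_to_pa(ck$reference_pressure_mbar %||% 1000),
    alpha_ref = ck$alpha_ref %||% NA_real_
  )
  stages <- purrr::map(cfg$wash_program %||% list(), function(s) {
    wash_stage(
      composition = composition(unlist(s$composition)),
      mechanism = s$mechanism %||% "displacement",
      wash_ratio = s$wash_ratio,
      volume_ml = s$volume_ml,
      peclet = s$peclet %||% 10,
      mode = s$mode %||% "accumulate",
      duration = s$duration_s %||% NA_real_
    )
  })
  scenario(
    name = cfg$name,
    solid_species = cfg$solid_species,
    solid_mass_g = cfg$solid_mass_g,
    liquor_mass_g = cfg$liquor_mass_g,
    liquor = composition(unlist(cfg$liquor)),
    particles = particles,
    filter = filt,
    conditions = conditions,
    cake_props = props,
    wash_program = stages,
    db = db,
    temperature = cfg$temperature_c %||% 25,
    provenance = cfg$provenance %||% paste0("config: ", path)
  )
}

#' Write an isolation scenario to a YAML config
#'
#' Inverse of [read_scenario_config()] (species overrides are not exported;
#' the config round-trips against the default property table).
#'
#' @param scenario An `isolation_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  comp_list <- function(comp) as.list(stats::setNames(comp$mass_fraction, comp$species))
  p <- scenario$suspension$particles
  cfg <- list(
    name = scenario$name,
    solid_species = scenario$suspension$solid_species,
    solid_mass_g = kg_to_g(scenario$suspension$solid_mass),
    liquor_mass_g = kg_to_g(scenario$suspension$liquor_mass),
    temperature_c = scenario$suspension$temperature,
    liquor = comp_list(scenario$suspension$liquor),
    particles = list(
      mean_size_um = p$mean_size, sphericity = p$sphericity,
      x10_um = p$x10, x50_um = p$x50, x90_um = p$x90, sd_um = p$sd
    ),
    filter = list(
      diameter_mm = scenario$filter$diameter * 1e3,
      medium_resistance_per_m = scenario$filter$medium_resistance,
      equipment_volume_ml = m3_to_ml(scenario$filter$equipment_volume)
    ),
    conditions = list(
      driving_force_mbar = pa_to_mbar(scenario$conditions$driving_force),
      temperature_c = scenario$conditions$temperature
    ),
    cake = list(
      porosity = scenario$cake_properties$porosity,
      sphericity = scenario$cake_properties$sphericity,
      compressibility_index = scenario$cake_properties$compressibility_index,
      reference_pressure_mbar = pa_to_mbar(scenario$cake_properties$reference_pressure),
      alpha_ref = scenario$cake_properties$alpha_ref
    ),
    wash_program = purrr::map(scenario$wash_program, function(s) {
      out <- list(
        mechanism = s$mechanism,
        composition = comp_list(s$composition),
        peclet = s$peclet, mode = s$mode
      )
      if (!is.null(s$wash_ratio)) out$wash_ratio <- s$wash_ratio
      if (!is.null(s$volume)) out$volume_ml <- m3_to_ml(s$volume)
      out
    }),
    provenance = scenario$provenance
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read an experimental filtrate series CSV
#'
#' Expects the header `time_s,filtrate_volume_ml`.
#'
#' @param path CSV path.
#' @return Tibble with `time_s` and `volume_m3` (SI).
#' @export
read_filtration_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_s", "filtrate_volume_ml") %in% names(d))) {
    abort_cw("CSV must have columns time_s,filtrate_volume_ml", "config_error")
  }
  tibble::tibble(time_s = d$time_s, volume_m3 = ml_to_m3(d$filtrate_volume_ml))
}

#' Write a filtration series CSV
#'
#' Writes `time_s,filtrate_volume_ml,filtrate_mass_g`.
#'
#' @param result A `filtration_result` (or a tibble with `time_s`,
#'   `volume_m3` and optionally `mass_kg`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_filtration_csv <- function(result, path) {
  d <- if (inherits(result, "filtration_result")) result$series else result
  out <- data.frame(
    time_s = d$time_s,
    filtrate_volume_ml = m3_to_ml(d$volume_m3),
    filtrate_mass_g = if ("mass_kg" %in% names(d)) kg_to_g(d$mass_kg) else NA_real_
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
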