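# Shared fixtures: a minimal synthetic system with round physical properties
# so oracles can be evaluated by hand, plus balance checkers.

# two synthetic liquids and a synthetic solid with round-number properties
toy_db <- function() {
  with_species(
    species_table(),
    solventA = list(role = "crystallization_solvent", liquid_density = 1000, viscosity = 1e-3),
    solventB = list(role = "wash_solvent", liquid_density = 800, viscosity = 2e-3),
    solidX = list(role = "api", solid_density = 1200, liquid_density = 1200, viscosity = 1e-3),
    impY = list(role = "impurity", liquid_density = 1000, viscosity = 1e-3)
  )
}

# small synthetic isolation scenario with known parameters; incompressible by
# default so the constant-pressure closed form is exact
toy_scenario <- function(sphericity = 0.7, porosity = 0.5, Rm = 1e9, n = 0,
                         pressure_mbar = 500, name = "toy") {
  scenario(
    name = name,
    solid_species = "solidX",
    solid_mass_g = 5,
    liquor_mass_g = 50,
    liquor = composition(solventA = 0.93, solidX = 0.05, impY = 0.02),
    particles = particle_population(mean_size = 50, sphericity = 0.7),
    filter = filter_spec(diameter = 0.025, medium_resistance = Rm),
    conditions = operating_conditions(pressure_mbar),
    cake_props = cake_properties(
      porosity = porosity, sphericity = sphericity, compressibility_index = n
    ),
    wash_program = list(
      wash_stage(composition(solventB = 1), "displacement", wash_ratio = 2)
    ),
    db = toy_db()
  )
}

# max relative species-balance error over a wash program:
# initial pore mass + wash feed = filtrate out + final cake liquor
wash_species_balance_error <- function(cake, stages, res) {
  m0 <- stats::setNames(
    cake$liquor$mass_fraction * cake$liquor_mass, cake$liquor$species
  )
  fed <- numeric(0)
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    v <- res$stage_summary$wash_volume_m3[i]
    rho <- mixture_properties(st$composition, cake$species)$density
    add <- stats::setNames(st$composition$mass_fraction * v * rho, st$composition$species)
    for (sp in names(add)) fed[sp] <- (fed[sp] %||% 0) + add[[sp]]
  }
  fc <- res$final_cake
  final <- stats::setNames(fc$liquor$mass_fraction * fc$liquor_mass, fc$liquor$species)
  removed <- stats::setNames(numeric(0), character(0))
  if (nrow(res$per_stage) > 0) {
    agg <- stats::aggregate(mass_removed_kg ~ species, data = res$per_stage, FUN = sum)
    removed <- stats::setNames(agg$mass_removed_kg, agg$species)
  }
  all_sp <- unique(c(names(m0), names(fed), names(final), names(removed)))
  errs <- vapply(all_sp, function(sp) {
    inn <- (m0[sp] %||% 0) + (fed[sp] %||% 0)
    inn <- ifelse(is.na(inn), 0, inn)
    out <- (removed[sp] %||% 0) + (final[sp] %||% 0)
    out[is.na(out)] <- 0
    if (inn == 0) return(abs(out))
    abs(inn - out) / inn
  }, numeric(1))
  max(errs)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
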