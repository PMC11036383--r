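# Built-in MFA and PCM case-study scenarios and synthetic-observation
# generators, so every module is testable without external data.

#' Assemble an isolation scenario
#'
#' A scenario bundles one isolation experiment: the suspension, filter,
#' operating conditions, calibrated cake properties and wash program. If
#' `cake_props$alpha_ref` is unset it is filled from the Carman-Kozeny
#' relation evaluated at the cake sphericity, porosity, scenario mean
#' particle size and crystal density, and interpreted as the resistance at
#' the reference pressure of the compressibility power law.
#'
#' @param name Scenario name.
#' @param solid_species Name of the crystallizing solid (must be in `db`).
#' @param solid_mass_g,liquor_mass_g Suspension masses (g).
#' @param liquor Mother-liquor composition (see [composition()]).
#' @param particles A [particle_population()].
#' @param filter A [filter_spec()].
#' @param conditions An [operating_conditions()].
#' @param cake_props A [cake_properties()].
#' @param wash_program List of [wash_stage()] objects.
#' @param db Species property table.
#' @param temperature Suspension temperature (deg C).
#' @param provenance Free-text provenance notes.
#' @return An `isolation_scenario` list.
#' @export
scenario <- function(name, solid_species, solid_mass_g, liquor_mass_g, liquor,
                     particles, filter, conditions, cake_props,
                     wash_program = list(), db = species_table(),
                     temperature = 25, provenance = "") {
  if (solid_mass_g <= 0 || liquor_mass_g <= 0) {
    abort_cw("suspension masses must be positive", "invalid_argument")
  }
  liquor <- as_composition(liquor)
  validate_composition(liquor)
  if (!solid_species %in% db$name) abort_cw("unknown solid species", "missing_property")
  if (is.na(cake_props$alpha_ref)) {
    p_ck <- particles
    p_ck$sphericity <- cake_props$sphericity
    rho_s <- db$solid_density[db$name == solid_species]
    cake_props$alpha_ref <- carman_kozeny_alpha(p_ck, cake_props$porosity, rho_s)
  }
  structure(
    list(
      name = name,
      suspension = list(
        solid_species = solid_species,
        solid_mass = g_to_kg(solid_mass_g),
        liquor = liquor,
        liquor_mass = g_to_kg(liquor_mass_g),
        particles = particles,
        temperature = temperature
      ),
      filter = filter,
      conditions = conditions,
      cake_properties = cake_props,
      wash_program = wash_program,
      species = db,
      provenance = provenance
    ),
    class = "isolation_scenario"
  )
}

# volume-fraction solvent pair -> mass-fraction composition
vv_to_composition <- function(frac_a, species_a, species_b, db) {
  rho_a <- db$liquid_density[db$name == species_a]
  rho_b <- db$liquid_density[db$name == species_b]
  ma <- frac_a * rho_a
  mb <- (1 - frac_a) * rho_b
  if (frac_a <= 0) return(composition(stats::setNames(1, species_b)))
  if (frac_a >= 1) return(composition(stats::setNames(1, species_a)))
  composition(stats::setNames(c(ma, mb) / (ma + mb), c(species_a, species_b)))
}

mfa_experiments <- function() {
  tibble::tribble(
    ~expt, ~cryst,           ~wash,         ~pressure_mbar, ~wash_ratio, ~n_washes,
    1,     "ethyl acetate",  "cyclohexane", 100,            2,           3,
    2,     "diglyme-water",  "heptane",     600,            2,           3,
    3,     "ethyl acetate",  "heptane",     600,            2,           2,
    4,     "ethyl acetate",  "heptane",     100,            4,           2,
    5,     "diglyme-water",  "cyclohexane", 100,            4,           2,
    6,     "diglyme-water",  "cyclohexane", 350,            3,           3,
    7,     "diglyme-water",  "cyclohexane", 350,            3,           3,
    8,     "diglyme-water",  "heptane",     100,            4,           3,
    9,     "diglyme-water",  "cyclohexane", 350,            3,           3
  )
}

# Calibrated cake/filtration parameters per solvent pair (MFA case study).
mfa_pair_params <- function(cryst, wash) {
  key <- paste(cryst, wash, sep = "|")
  switch(key,
    "diglyme-water|heptane"     = list(sphericity = 0.526,  porosity = 0.694,  Rm = 1.31e8, n = 0.833),
    "diglyme-water|cyclohexane" = list(sphericity = 0.4964, porosity = 0.5258, Rm = 1.31e7, n = 0),
    "ethyl acetate|heptane"     = list(sphericity = 0.4134, porosity = 0.4804, Rm = 1.6e9,  n = 1.312),
    "ethyl acetate|cyclohexane" = list(sphericity = 0.399,  porosity = 0.476,  Rm = 1.46e9, n = 0),
    abort_cw("unknown MFA solvent pair", "not_found")
  )
}

pcm_experiments <- function() {
  tibble::tribble(
    ~expt, ~cryst,            ~wash,               ~solid_load, ~grade,       ~pressure_mbar, ~wash_ratio, ~n_washes,
    1,     "ethanol",         "dodecane",          0.25,        "powder",     800,            2,           2,
    2,     "ethanol",         "dodecane",          0.25,        "powder",     200,            2,           2,
    3,     "isoamyl alcohol", "dodecane",          0.15,        "powder",     200,            2,           2,
    4,     "isoamyl alcohol", "dodecane",          0.15,        "micronized", 800,            2,           2,
    5,     "ethanol",         "isopropyl acetate", 0.15,        "micronized", 800,            2,           2,
    6,     "ethanol",         "isopropyl acetate", 0.15,        "powder",     200,            2,           2,
    7,     "isoamyl alcohol", "isopropyl acetate", 0.20,        "powder",     500,            3,           2,
    8,     "isoamyl alcohol", "isopropyl acetate", 0.20,        "powder",     500,            3,           2,
    9,     "isoamyl alcohol", "isopropyl acetate", 0.20,        "powder",     500,            3,           2
  )
}

pcm_pair_params <- function(cryst, wash) {
  key <- paste(cryst, wash, sep = "|")
  switch(key,
    "ethanol|dodecane"                   = list(sphericity = 0.676, porosity = 0.44, Rm = 1e8, n = 0.321),
    "isoamyl alcohol|dodecane"           = list(sphericity = 0.691, porosity = 0.44, Rm = 1e8, n = 0.61),
    "ethanol|isopropyl acetate"          = list(sphericity = 0.636, porosity = 0.44, Rm = 1e8, n = 0),
    "isoamyl alcohol|isopropyl acetate"  = list(sphericity = 0.328, porosity = 0.44, Rm = 1e8, n = 0),
    abort_cw("unknown PCM solvent pair", "not_found")
  )
}

# crystallization-solvent volume fraction of the first (anti-solvent-safe)
# wash mixture per case study
wash1_cryst_vfrac <- function(compound, cryst, wash) {
  if (compound == "mfa") return(0.10)
  key <- paste(cryst, wash, sep = "|")
  switch(key,
    "ethanol|dodecane" = 0.30,
    "ethanol|isopropyl acetate" = 0.30,
    "isoamyl alcohol|dodecane" = 0.20,
    "isoamyl alcohol|isopropyl acetate" = 0.0,
    0.10
  )
}

#' Names of the built-in case-study scenarios
#'
#' @return Character vector `mfa_expt1..9`, `pcm_expt1..9`.
#' @export
scenario_names <- function() {
  c(paste0("mfa_expt", 1:9), paste0("pcm_expt", 1:9))
}

#' Build a case-study scenario
#'
#' Fully populated fixtures for the mefenamic acid (MFA, bench pressure filter) and
#' paracetamol (PCM, continuous dead-end unit) isolation case studies:
#' suspension compositions, filter geometry, per-experiment driving force and
#' wash program, particle summaries, and the calibrated cake properties
#' (sphericity, porosity, medium resistance, compressibility index) of the
#' matching crystallization/wash solvent pair. The first wash stage uses the
#' anti-solvent-safe mixture of crystallization and wash solvent; later
#' stages use pure wash solvent.
#'
#' @param name One of [scenario_names()].
#' @param mechanism Wash mechanism for every program stage: `"displacement"`
#'   (default), `"dispersion"` or `"well_mixed"`.
#' @param mode Well-mixed mode, see [wash_stage()].
#' @param peclet Peclet number for dispersion stages.
#' @param db Species property table (override to change physical property
#'   assumptions).
#' @return An `isolation_scenario`.
#' @examples
#' make_scenario("mfa_expt2")
#' @export
make_scenario <- function(name, mechanism = "displacement",
                          mode = "accumulate", peclet = 10,
                          db = species_table()) {
  if (!name %in% scenario_names()) {
    abort_cw(paste0("unknown scenario '", name, "'"), "not_found")
  }
  compound <- substr(name, 1, 3)
  i <- as.integer(sub(".*expt", "", name))
  if (compound == "mfa") {
    row <- mfa_experiments()[i, ]
    pars <- mfa_pair_params(row$cryst, row$wash)
    solid <- "MFA"
    solid_mass_g <- 4.34
    liquor_mass_g <- 43.4
    liquor <- if (row$cryst == "ethyl acetate") {
      composition(
        "ethyl acetate" = 0.876, "MFA" = 0.097, "CBA" = 0.009,
        "copper(II) acetate" = 0.008, "2,3-dimethylaniline" = 0.01
      )
    } else {
      # printed column sums to 1.001; renormalized to satisfy the
      # sum-to-one invariant (diglyme+water carried as one pseudo-solvent)
      composition(
        "diglyme-water" = 0.821, "MFA" = 0.141, "CBA" = 0.012,
        "copper(II) acetate" = 0.012, "2,3-dimethylaniline" = 0.015,
        normalize = TRUE
      )
    }
    particles <- particle_population(
      mean_size = 94, sphericity = 0.4680,
      x10 = 39.03, x50 = 86.95, x90 = 176.48, sd = 174
    )
    filt <- filter_spec(diameter = mm_to_m(27), medium_resistance = pars$Rm,
                        equipment_volume = ml_to_m3(50))
  } else {
    row <- pcm_experiments()[i, ]
    pars <- pcm_pair_params(row$cryst, row$wash)
    solid <- "PCM"
    total_g <- 65
    solid_mass_g <- row$solid_load * total_g
    liquor_mass_g <- total_g - solid_mass_g
    w_imp <- 0.0015 * total_g / liquor_mass_g # each impurity, per total charge
    liquor <- composition(stats::setNames(
      c(1 - 0.13 - 2 * w_imp, 0.13, w_imp, w_imp),
      c(row$cryst, "PCM", "acetanilide", "metacetamol")
    ))
    particles <- if (row$grade == "micronized") {
      particle_population(mean_size = 61, sphericity = 0.629,
                          x10 = 11.1, x50 = 31.7, x90 = 195, sd = 77)
    } else {
      particle_population(mean_size = 61, sphericity = 0.4127,
                          x10 = 16.6, x50 = 69.8, x90 = 198, sd = 77)
    }
    filt <- filter_spec(diameter = mm_to_m(24), medium_resistance = pars$Rm,
                        equipment_volume = ml_to_m3(100))
  }
  props <- cake_properties(
    porosity = pars$porosity, sphericity = pars$sphericity,
    compressibility_index = pars$n
  )
  wash1 <- vv_to_composition(
    wash1_cryst_vfrac(compound, row$cryst, row$wash), row$cryst, row$wash, db
  )
  pure_wash <- composition(stats::setNames(1, row$wash))
  stages <- purrr::map(seq_len(row$n_washes), function(k) {
    wash_stage(
      composition = if (k == 1) wash1 else pure_wash,
      mechanism = mechanism, wash_ratio = row$wash_ratio,
      peclet = peclet, mode = mode
    )
  })
  scenario(
    name = name,
    solid_species = solid,
    solid_mass_g = solid_mass_g,
    liquor_mass_g = liquor_mass_g,
    liquor = liquor,
    particles = particles,
    filter = filt,
    conditions = operating_conditions(row$pressure_mbar),
    cake_props = props,
    wash_program = stages,
    db = db,
    provenance = sprintf(
      "%s case study, experiment %d: %s / %s, %g mbar, wash ratio %g x %d washes; calibrated cake parameters of the matching solvent pair",
      toupper(compound), i, row$cryst, row$wash, row$pressure_mbar,
      row$wash_ratio, row$n_washes
    )
  )
}

#' Synthetic filtrate volume-time observations
#'
#' Forward-simulates the scenario, samples the V(t) grid and applies
#' multiplicative Gaussian noise: V_obs = V (1 + sd * eps). Reproducible
#' bit-for-bit from `(scenario, noise_sd, seed)`.
#'
#' @param scenario An `isolation_scenario`.
#' @param noise_sd Relative noise standard deviation (>= 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param n Number of grid points.
#' @return Tibble `time_s`, `volume_m3` with attributes `scenario`,
#'   `noise_sd`, `seed`.
#' @export
generate_filtration_observations <- function(scenario, noise_sd = 0, seed = NULL,
                                             n = 50) {
  if (noise_sd < 0) abort_cw("noise_sd must be >= 0", "invalid_argument")
  res <- simulate_filtration(scenario, n_out = n)
  obs <- res$series[, c("time_s", "volume_m3")]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs$volume_m3 <- obs$volume_m3 * (1 + noise_sd * stats::rnorm(nrow(obs)))
  }
  attr(obs, "scenario") <- scenario$name
  attr(obs, "noise_sd") <- noise_sd
  attr(obs, "seed") <- seed
  obs
}

#' Synthetic per-stage wash filtrate compositions
#'
#' Runs filtration to dryland and the scenario's wash program, then perturbs
#' the per-stage filtrate mass fractions with multiplicative Gaussian noise
#' and renormalizes, so emitted compositions keep the sum-to-one invariant.
#'
#' @inheritParams generate_filtration_observations
#' @param mechanism,mode Overrides passed to [run_wash_program()].
#' @return Tibble `stage`, `species`, `mass_fraction` with attributes as in
#'   [generate_filtration_observations()].
#' @export
generate_wash_observations <- function(scenario, mechanism = NULL, mode = NULL,
                                       noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) abort_cw("noise_sd must be >= 0", "invalid_argument")
  cake <- dryland_state(simulate_filtration(scenario))
  res <- run_wash_program(cake, scenario$wash_program, mechanism = mechanism, mode = mode)
  if (!is.null(seed)) set.seed(seed)
  obs <- purrr::map_dfr(seq_len(nrow(res$stage_summary)), function(i) {
    comp <- res$stage_summary$filtrate_composition[[i]]
    if (is.null(comp)) return(tibble::tibble())
    w <- comp$mass_fraction
    if (noise_sd > 0) {
      w <- pmax(w * (1 + noise_sd * stats::rnorm(length(w))), 0)
      w <- w / sum(w)
    }
    tibble::tibble(stage = i, species = comp$species, mass_fraction = w)
  })
  attr(obs, "scenario") <- scenario$name
  attr(obs, "noise_sd") <- noise_sd
  attr(obs, "seed") <- seed
  obs
}
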