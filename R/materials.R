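# Species data model, mixture property rules, particle population and
# wash-ratio geometry shared by the filtration, washing and design-space
# modules.

COMP_TOL <- 1e-9

#' Default species property table
#'
#' Literature physical properties at 25 C for the solids, crystallization
#' solvents, wash solvents and dissolved impurities of the built-in mefenamic
#' acid (MFA) and paracetamol (PCM) case studies. Dissolved solids are
#' assigned a liquid density equal to their crystal density and a nominal
#' 1 mPa.s viscosity contribution; both are overridable per scenario via
#' [with_species()].
#'
#' `diglyme-water` is a pseudo-solvent: the fixed 89:11 (w/w) diglyme-water
#' synthesis liquor, with density from the mass-weighted specific-volume rule
#' and viscosity from the log-linear rule applied to the two components.
#'
#' @return A tibble with columns `name`, `role` (one of `api`, `impurity`,
#'   `crystallization_solvent`, `wash_solvent`), `solid_density` (kg/m3, `NA`
#'   for liquids), `liquid_density` (kg/m3) and `viscosity` (Pa.s).
#' @examples
#' species_table()
#' @export
species_table <- function() {
  tb <- tibble::tribble(
    ~name,                 ~role,                      ~solid_density, ~liquid_density, ~viscosity,
    "MFA",                 "api",                      1300,           1300,            1.0e-3,
    "PCM",                 "api",                      1293,           1293,            1.0e-3,
    "CBA",                 "impurity",                 1544,           1544,            1.0e-3,
    "copper(II) acetate",  "impurity",                 1880,           1880,            1.0e-3,
    "2,3-dimethylaniline", "impurity",                 980,            980,             1.0e-3,
    "acetanilide",         "impurity",                 1219,           1219,            1.0e-3,
    "metacetamol",         "impurity",                 1250,           1250,            1.0e-3,
    "ethyl acetate",       "crystallization_solvent",  NA,             902,             4.23e-4,
    "diglyme",             "crystallization_solvent",  NA,             937,             9.89e-4,
    "water",               "crystallization_solvent",  NA,             997,             8.90e-4,
    "ethanol",             "crystallization_solvent",  NA,             789,             1.074e-3,
    "isoamyl alcohol",     "crystallization_solvent",  NA,             810,             3.692e-3,
    "heptane",             "wash_solvent",             NA,             680,             3.87e-4,
    "cyclohexane",         "wash_solvent",             NA,             774,             8.94e-4,
    "dodecane",            "wash_solvent",             NA,             750,             1.34e-3,
    "isopropyl acetate",   "wash_solvent",             NA,             870,             4.90e-4
  )
  # 89:11 w/w diglyme-water pseudo-solvent, derived once with the package's
  # own mixing rules from the diglyme and water rows above.
  dg <- tb[tb$name == "diglyme", ]
  wa <- tb[tb$name == "water", ]
  rho <- 1 / (0.89 / dg$liquid_density + 0.11 / wa$liquid_density)
  mu <- exp(0.89 * log(dg$viscosity) + 0.11 * log(wa$viscosity))
  dplyr::bind_rows(
    tb,
    tibble::tibble(
      name = "diglyme-water", role = "crystallization_solvent",
      solid_density = NA_real_, liquid_density = rho, viscosity = mu
    )
  )
}

#' Override or extend species properties
#'
#' @param db Species table, as from [species_table()].
#' @param ... Named lists: each name a species, each value a list of fields to
#'   override (e.g. `MFA = list(solid_density = 1260)`). Unknown species are
#'   appended (all fields must then be supplied).
#' @return The modified species tibble.
#' @examples
#' with_species(species_table(), MFA = list(solid_density = 1260))
#' @export
with_species <- function(db, ...) {
  mods <- list(...)
  for (nm in names(mods)) {
    fields <- mods[[nm]]
    if (nm %in% db$name) {
      for (f in names(fields)) db[db$name == nm, f] <- fields[[f]]
    } else {
      row <- tibble::tibble(
        name = nm,
        role = fields$role %||% "impurity",
        solid_density = fields$solid_density %||% NA_real_,
        liquid_density = fields$liquid_density,
        viscosity = fields$viscosity %||% 1e-3
      )
      db <- dplyr::bind_rows(db, row)
    }
  }
  db
}

#' Build a liquid composition
#'
#' A liquid composition is a tibble with columns `species` and
#' `mass_fraction`; fractions must be in \[0, 1\] and sum to 1 within 1e-9.
#'
#' @param ... Named mass fractions, e.g. `composition("ethyl acetate" = 0.876,
#'   MFA = 0.097, ...)`.
#' @param normalize If `TRUE`, rescale the fractions to sum to exactly 1.
#' @return A composition tibble.
#' @examples
#' composition(heptane = 1)
#' @export
composition <- function(..., normalize = FALSE) {
  w <- c(...)
  if (is.null(names(w)) || any(names(w) == "")) {
    abort_cw("all mass fractions must be named by species", "invalid_composition")
  }
  out <- tibble::tibble(species = names(w), mass_fraction = as.numeric(w))
  if (normalize) out$mass_fraction <- out$mass_fraction / sum(out$mass_fraction)
  validate_composition(out)
  out
}

as_composition <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("species", "mass_fraction") %in% names(x)))
    tibble::as_tibble(x[, c("species", "mass_fraction")])
  } else {
    composition(x)
  }
}

validate_composition <- function(comp) {
  w <- comp$mass_fraction
  if (anyDuplicated(comp$species)) {
    abort_cw("duplicate species in composition", "invalid_composition")
  }
  if (any(w < -COMP_TOL) || any(w > 1 + COMP_TOL)) {
    abort_cw("mass fractions must lie in [0, 1]", "invalid_composition")
  }
  if (abs(sum(w) - 1) > COMP_TOL) {
    abort_cw(
      sprintf("mass fractions sum to %.12f, not 1 (tolerance 1e-9)", sum(w)),
      "invalid_composition"
    )
  }
  invisible(comp)
}

# composition tibble -> named mass vector of length nrow
comp_vec <- function(comp) {
  stats::setNames(comp$mass_fraction, comp$species)
}

# named species-mass vector -> composition tibble
masses_to_composition <- function(m, tol = 1e-15) {
  m <- m[m > tol * max(sum(m), 1)]
  out <- tibble::tibble(species = names(m), mass_fraction = as.numeric(m) / sum(m))
  out
}

#' Mixture density and viscosity of a liquid composition
#'
#' Density from mass-weighted specific volumes (1/rho = sum w_i / rho_i);
#' viscosity from mass-weighted log viscosities (ln mu = sum w_i ln mu_i).
#' Single-species compositions return that species' properties exactly.
#'
#' @param comp Composition tibble (see [composition()]).
#' @param db Species property table, default [species_table()].
#' @return One-row tibble with `density` (kg/m3) and `viscosity` (Pa.s).
#' @examples
#' mixture_properties(composition(heptane = 1))
#' @export
mixture_properties <- function(comp, db = species_table()) {
  comp <- as_composition(comp)
  validate_composition(comp)
  missing <- setdiff(comp$species, db$name)
  if (length(missing) > 0) {
    abort_cw(
      paste0("species missing from property table: ", paste(missing, collapse = ", ")),
      "missing_property"
    )
  }
  idx <- match(comp$species, db$name)
  rho_i <- db$liquid_density[idx]
  mu_i <- db$viscosity[idx]
  if (anyNA(rho_i) || anyNA(mu_i)) {
    abort_cw("species lacking liquid density or viscosity", "missing_property")
  }
  w <- comp$mass_fraction
  if (nrow(comp) == 1) {
    return(tibble::tibble(density = rho_i, viscosity = mu_i))
  }
  tibble::tibble(
    density = 1 / sum(w / rho_i),
    viscosity = exp(sum(w * log(mu_i)))
  )
}

#' Particle population summary
#'
#' @param mean_size Volume-weighted mean particle size (um); the size entering
#'   the Carman-Kozeny relation.
#' @param sphericity Particle sphericity in (0, 1].
#' @param x10,x50,x90 Distribution percentiles (um), optional metadata.
#' @param sd Distribution standard deviation (um), optional metadata.
#' @return A `particle_population` list.
#' @examples
#' particle_population(mean_size = 94, sphericity = 0.468)
#' @export
particle_population <- function(mean_size, sphericity,
                                x10 = NA_real_, x50 = NA_real_, x90 = NA_real_,
                                sd = NA_real_) {
  if (!is.na(x10) && !is.na(x50) && !is.na(x90) && !(x10 <= x50 && x50 <= x90)) {
    abort_cw("particle percentiles must satisfy x10 <= x50 <= x90", "invalid_argument")
  }
  if (sphericity <= 0 || sphericity > 1) {
    abort_cw("sphericity must be in (0, 1]", "invalid_argument")
  }
  if (mean_size <= 0) abort_cw("mean particle size must be positive", "invalid_argument")
  structure(
    list(
      mean_size = mean_size, sphericity = sphericity,
      x10 = x10, x50 = x50, x90 = x90, sd = sd
    ),
    class = "particle_population"
  )
}

#' Wash ratio to wash-liquid volume
#'
#' A wash ratio of 1 delivers one cake void (pore) volume of wash liquid.
#'
#' @param W Wash ratio (dimensionless, >= 0). Vectorized.
#' @param cake A `cake_state`, as from [dryland_state()].
#' @return Wash volume in m3.
#' @examples
#' \dontrun{
#' cake <- dryland_state(simulate_filtration(make_scenario("mfa_expt2")))
#' wash_ratio_to_volume(2, cake)
#' }
#' @export
wash_ratio_to_volume <- function(W, cake) {
  if (any(W < 0)) abort_cw("wash ratio must be non-negative", "invalid_argument")
  if (!inherits(cake, "cake_state") || cake$void_volume <= 0) {
    abort_cw("cake must be a cake_state with positive void volume", "invalid_argument")
  }
  W * cake$void_volume
}

`%||%` <- function(a, b) if (is.null(a)) b else a
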