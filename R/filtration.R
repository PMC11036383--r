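# Constant-pressure dead-end cake filtration with a Carman-Kozeny
# compressible specific cake resistance, integrated to dryland, plus the
# Darcy t/V-vs-V linearization and the ln-ln compressibility fit applied to
# experimental filtrate series.

#' Filter specification
#'
#' @param diameter Filter diameter (m).
#' @param medium_resistance Medium resistance Rm (1/m), >= 0.
#' @param equipment_volume Equipment hold-up volume (m3), metadata.
#' @return A `filter_spec` list with derived `area` (m2).
#' @examples
#' filter_spec(diameter = 0.027, medium_resistance = 1.31e8)
#' @export
filter_spec <- function(diameter, medium_resistance, equipment_volume = NA_real_) {
  if (diameter <= 0) abort_cw("filter diameter must be positive", "invalid_argument")
  if (medium_resistance < 0) {
    abort_cw("medium resistance must be non-negative for simulation", "invalid_argument")
  }
  structure(
    list(
      diameter = diameter, area = pi * diameter^2 / 4,
      medium_resistance = medium_resistance, equipment_volume = equipment_volume
    ),
    class = "filter_spec"
  )
}

#' Operating conditions
#'
#' @param driving_force_mbar Constant driving pressure difference (mbar).
#' @param temperature Temperature (deg C), metadata.
#' @return An `operating_conditions` list with `driving_force` in Pa.
#' @export
operating_conditions <- function(driving_force_mbar, temperature = 25) {
  dp <- mbar_to_pa(driving_force_mbar)
  if (dp <= 0) abort_cw("driving force must be positive", "invalid_argument")
  structure(
    list(driving_force = dp, temperature = temperature),
    class = "operating_conditions"
  )
}

#' Cake properties
#'
#' The specific cake resistance follows the compressibility power law
#' alpha(dP) = alpha_ref * (dP / reference_pressure)^n. When `alpha_ref` is
#' `NA` it is filled in from the Carman-Kozeny relation at the scenario's
#' particle size, sphericity and solid density (see [carman_kozeny_alpha()]).
#'
#' @param porosity Cake porosity in (0, 1).
#' @param sphericity Particle sphericity in (0, 1].
#' @param compressibility_index Power-law exponent n >= 0.
#' @param reference_pressure Reference pressure for `alpha_ref` (Pa),
#'   default 1e5 (1 bar).
#' @param alpha_ref Specific cake resistance at `reference_pressure` (m/kg).
#' @return A `cake_properties` list.
#' @export
cake_properties <- function(porosity, sphericity, compressibility_index = 0,
                            reference_pressure = 1e5, alpha_ref = NA_real_) {
  if (porosity <= 0 || porosity >= 1) abort_cw("porosity must be in (0, 1)", "invalid_argument")
  if (sphericity <= 0 || sphericity > 1) abort_cw("sphericity must be in (0, 1]", "invalid_argument")
  if (compressibility_index < 0) abort_cw("compressibility index must be >= 0", "invalid_argument")
  structure(
    list(
      porosity = porosity, sphericity = sphericity,
      compressibility_index = compressibility_index,
      reference_pressure = reference_pressure, alpha_ref = alpha_ref
    ),
    class = "cake_properties"
  )
}

#' Carman-Kozeny specific cake resistance
#'
#' alpha = 180 (1 - eps) / (rho_s psi^2 x^2 eps^3), with x the mean particle
#' size in meters.
#'
#' @param particles A [particle_population()] (sizes in um).
#' @param porosity Cake porosity eps in (0, 1).
#' @param solid_density Crystal density rho_s (kg/m3).
#' @return Specific cake resistance (m/kg).
#' @examples
#' p <- particle_population(mean_size = 100, sphericity = 1)
#' carman_kozeny_alpha(p, porosity = 0.5, solid_density = 1000) # 7.2e7
#' @export
carman_kozeny_alpha <- function(particles, porosity, solid_density) {
  if (porosity <= 0 || porosity >= 1) abort_cw("porosity must be in (0, 1)", "invalid_argument")
  x <- um_to_m(particles$mean_size)
  psi <- particles$sphericity
  180 * (1 - porosity) / (solid_density * psi^2 * x^2 * porosity^3)
}

#' Specific cake resistance at a given pressure
#'
#' Evaluates the compressibility power law alpha(dP) = alpha_ref *
#' (dP / reference_pressure)^n.
#'
#' @param props A [cake_properties()] with `alpha_ref` set.
#' @param dP Driving pressure (Pa), > 0. Vectorized.
#' @return alpha at `dP` (m/kg).
#' @export
alpha_at_pressure <- function(props, dP) {
  if (any(dP <= 0)) abort_cw("pressure must be positive", "invalid_argument")
  if (is.na(props$alpha_ref)) abort_cw("alpha_ref is not set", "invalid_argument")
  props$alpha_ref * (dP / props$reference_pressure)^props$compressibility_index
}

classify_compressibility <- function(n) {
  if (n > 100) "extreme" else if (n >= 1) "high" else "low/moderate"
}

#' Fit the compressibility power law from (pressure, alpha) pairs
#'
#' Least-squares slope/intercept of ln alpha against ln dP. The slope is the
#' compressibility index n; cakes are labelled `low/moderate` (n < 1),
#' `high` (n >= 1) or `extreme` (n > 100). When all pressures coincide the
#' slope is unidentifiable: n is pinned to 0 and a flag raised.
#'
#' @param data Data frame with columns `pressure` (Pa) and `alpha` (m/kg),
#'   >= 2 rows.
#' @param reference_pressure Pressure at which `alpha_ref` is reported (Pa).
#' @return A `compressibility_fit` list: `n`, `alpha_ref`,
#'   `reference_pressure`, `label`, `unidentifiable`.
#' @examples
#' fit_compressibility(data.frame(pressure = c(1e4, 6e4), alpha = c(9.84e7, 1.84e9)))
#' @export
fit_compressibility <- function(data, reference_pressure = 1e5) {
  stopifnot(all(c("pressure", "alpha") %in% names(data)))
  if (nrow(data) < 2) abort_cw("need at least two (pressure, alpha) pairs", "invalid_argument")
  if (any(data$pressure <= 0) || any(data$alpha <= 0)) {
    abort_cw("pressures and resistances must be positive", "invalid_argument")
  }
  lp <- log(data$pressure)
  la <- log(data$alpha)
  if (diff(range(lp)) < 1e-12) {
    n <- 0
    a_ref <- exp(mean(la))
    unident <- TRUE
  } else {
    fit <- stats::lm(la ~ lp)
    n <- unname(stats::coef(fit)[2])
    a_ref <- exp(unname(stats::coef(fit)[1]) + n * log(reference_pressure))
    unident <- FALSE
  }
  structure(
    list(
      n = n, alpha_ref = a_ref, reference_pressure = reference_pressure,
      label = classify_compressibility(n), unidentifiable = unident
    ),
    class = "compressibility_fit"
  )
}

#' Analytic constant-pressure filtration time
#'
#' Closed-form solution of dV/dt = dP A^2 / (mu (alpha w V + Rm A)) at
#' constant pressure and constant alpha:
#' t(V) = (mu / (A dP)) (alpha w V^2 / (2 A) + Rm V).
#'
#' @param V Cumulative filtrate volume (m3). Vectorized.
#' @param alpha Specific cake resistance (m/kg).
#' @param w Dry solids deposited per unit filtrate volume (kg/m3).
#' @param Rm Medium resistance (1/m).
#' @param area Filter area (m2).
#' @param dP Driving pressure (Pa).
#' @param mu Filtrate viscosity (Pa.s).
#' @return Time (s) at which volume `V` has been collected.
#' @export
constant_pressure_time <- function(V, alpha, w, Rm, area, dP, mu) {
  mu / (area * dP) * (alpha * w * V^2 / (2 * area) + Rm * V)
}

#' Analytic constant-pressure filtrate volume
#'
#' Inverse of [constant_pressure_time()]: the positive root of the quadratic
#' in V.
#'
#' @inheritParams constant_pressure_time
#' @param t Time (s). Vectorized.
#' @return Cumulative filtrate volume (m3) at time `t`.
#' @export
constant_pressure_volume <- function(t, alpha, w, Rm, area, dP, mu) {
  a <- mu * alpha * w / (2 * area^2 * dP)
  b <- mu * Rm / (area * dP)
  if (a < .Machine$double.eps * b^2) {
    return(ifelse(b > 0, t / b, Inf))
  }
  (-b + sqrt(b^2 + 4 * a * t)) / (2 * a)
}

# Shared derived quantities for a filtration run.
filtration_setup <- function(scenario) {
  susp <- scenario$suspension
  db <- scenario$species
  lp <- mixture_properties(susp$liquor, db)
  rho_l <- lp$density
  mu <- lp$viscosity
  rho_s <- db$solid_density[db$name == susp$solid_species]
  if (length(rho_s) != 1 || is.na(rho_s)) {
    abort_cw("solid species lacks a solid density", "missing_property")
  }
  eps <- scenario$cake_properties$porosity
  area <- scenario$filter$area
  v_solid <- susp$solid_mass / rho_s
  bulk <- v_solid / (1 - eps)
  void <- eps * bulk
  v_liq0 <- susp$liquor_mass / rho_l
  v_end <- v_liq0 - void
  if (v_end <= 0) {
    abort_cw("suspension holds less liquid than the cake pore volume; dryland unreachable", "invalid_argument")
  }
  dP <- scenario$conditions$driving_force
  alpha <- alpha_at_pressure(scenario$cake_properties, dP)
  list(
    rho_l = rho_l, mu = mu, rho_s = rho_s, eps = eps, area = area,
    v_solid = v_solid, bulk = bulk, void = void, v_liq0 = v_liq0,
    v_end = v_end, w = susp$solid_mass / v_end, dP = dP, alpha = alpha,
    Rm = scenario$filter$medium_resistance
  )
}

new_cake_state <- function(scenario, setup, liquor, liquor_mass, liquor_volume) {
  height <- setup$bulk / setup$area
  structure(
    list(
      solid_species = scenario$suspension$solid_species,
      solid_mass = scenario$suspension$solid_mass,
      solid_density = setup$rho_s,
      porosity = setup$eps,
      area = setup$area,
      height = height,
      bulk_volume = setup$bulk,
      void_volume = setup$void,
      liquor = liquor,
      liquor_mass = liquor_mass,
      liquor_volume = liquor_volume,
      saturation = min(1, liquor_volume / setup$void),
      species = scenario$species
    ),
    class = "cake_state"
  )
}

#' Simulate constant-pressure filtration to dryland
#'
#' Integrates dV/dt = dP A^2 / (mu (alpha w V + Rm A)) with `deSolve`, where
#' w is the dry solids deposited per unit filtrate volume (solved
#' self-consistently with the dryland end point, assuming all solids deposit)
#' and alpha follows the compressibility power law at the scenario's driving
#' force. Integration stops when the free liquid height above the cake
#' reaches zero (event detection, absolute tolerance 1e-6 m); the terminal
#' state is then snapped to the exact dryland volume so that mass balances
#' close to machine precision. The cake at dryland remains pore-saturated
#' with mother liquor.
#'
#' @param scenario An `isolation_scenario`, see [make_scenario()].
#' @param n_out Number of output grid points.
#' @param max_time Optional wall-clock cap on simulated time (s); if dryland
#'   is not reached the result is flagged `stopped_at = "max_time"` and
#'   carries no end state.
#' @param height_tol Free-liquid-height event tolerance (m).
#' @return A `filtration_result`: `series` (tibble `time_s`, `volume_m3`,
#'   `mass_kg`), `alpha_used`, `medium_resistance`, `w`, `viscosity`,
#'   `liquor_density`, `end_state` ([dryland_state()]), `stopped_at`.
#' @examples
#' res <- simulate_filtration(make_scenario("mfa_expt2"))
#' dplyr::glimpse(res$series)
#' @export
simulate_filtration <- function(scenario, n_out = 101, max_time = Inf,
                                height_tol = 1e-6) {
  st <- filtration_setup(scenario)
  if (st$mu <= 0 || st$dP <= 0) abort_cw("viscosity and pressure must be positive", "invalid_argument")
  if (st$Rm < 0) abort_cw("negative medium resistance not allowed in simulation", "invalid_argument")

  t_end <- constant_pressure_time(st$v_end, st$alpha, st$w, st$Rm, st$area, st$dP, st$mu)
  t_stop <- min(max_time, 1.05 * t_end)
  times <- seq(0, t_stop, length.out = n_out)
  pore_coef <- st$eps / (1 - st$eps) * st$w / st$rho_s # pore volume per filtrate volume
  deriv <- function(t, y, parms) {
    list(st$dP * st$area^2 / (st$mu * (st$alpha * st$w * y[1] + st$Rm * st$area)))
  }
  rootf <- function(t, y, parms) {
    free_h <- (st$v_liq0 - y[1] - pore_coef * y[1]) / st$area
    free_h - height_tol
  }
  sol <- deSolve::ode(
    y = c(V = 0), times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = 1e-10, atol = 1e-16,
    rootfunc = rootf, events = list(root = TRUE, terminalroot = 1)
  )
  troot <- attributes(sol)$troot
  sol <- as.data.frame(sol)
  v_root <- (st$v_liq0 - st$area * height_tol) / (1 + pore_coef)
  reached <- (!is.null(troot) && length(troot) > 0) || max(sol$V) >= v_root
  if (!reached && !is.finite(max_time)) {
    abort_cw("integration failed to reach dryland", "numerical_error")
  }
  series <- tibble::tibble(time_s = sol$time, volume_m3 = pmin(sol$V, st$v_end))
  if (reached) {
    # the event fires at free height = height_tol; extend the terminal sample
    # to the exact dryland point (the analytic solution of the same ODE) so
    # mass balances and the dryland geometry close to machine precision
    series$volume_m3[nrow(series)] <- st$v_end
    series$time_s[nrow(series)] <- max(t_end, series$time_s[nrow(series)])
    stopped_at <- "dryland"
  } else {
    stopped_at <- "max_time"
  }
  series$mass_kg <- series$volume_m3 * st$rho_l
  end_state <- NULL
  if (stopped_at == "dryland") {
    end_state <- new_cake_state(
      scenario, st,
      liquor = scenario$suspension$liquor,
      liquor_mass = st$void * st$rho_l,
      liquor_volume = st$void
    )
  }
  structure(
    list(
      scenario = scenario$name,
      series = series,
      alpha_used = st$alpha,
      medium_resistance = st$Rm,
      w = st$w,
      viscosity = st$mu,
      liquor_density = st$rho_l,
      filtrate_volume = series$volume_m3[nrow(series)],
      filtrate_mass = series$mass_kg[nrow(series)],
      filtrate_composition = scenario$suspension$liquor,
      end_state = end_state,
      stopped_at = stopped_at
    ),
    class = "filtration_result"
  )
}

#' Saturated cake state at dryland
#'
#' Cake geometry from the deposited solid mass, crystal density, porosity and
#' filter area; retained liquor fills the pores (saturation 1) with the
#' mother-liquor composition.
#'
#' @param result A `filtration_result` with `stopped_at == "dryland"`.
#' @return A `cake_state`.
#' @export
dryland_state <- function(result) {
  if (!inherits(result, "filtration_result")) abort_cw("not a filtration_result", "invalid_state")
  if (!identical(result$stopped_at, "dryland")) {
    abort_cw("filtration did not stop at dryland", "invalid_state")
  }
  result$end_state
}

#' Darcy linearization of a filtrate volume-time series
#'
#' Linear regression of t/V against V for a constant-pressure run:
#' slope = mu alpha w / (2 A^2 dP), intercept = mu Rm / (A dP). Negative
#' intercepts (pre-settled cakes) are reported verbatim with a warning flag.
#'
#' @param data Data frame with columns `time_s` and `volume_m3`, >= 3 rows
#'   with positive volume.
#' @param area Filter area (m2).
#' @param dP Driving pressure (Pa).
#' @param mu Filtrate viscosity (Pa.s).
#' @param w Dry solids deposited per unit filtrate volume (kg/m3).
#' @param strict If `TRUE` (default), non-monotone volumes signal an
#'   invalid-series error; if `FALSE` they only warn (noisy bench data).
#' @return A `darcy_fit` list: `alpha`, `medium_resistance`, `slope`,
#'   `intercept`, `r_squared`, `negative_rm`, `n_points`.
#' @export
darcy_fit <- function(data, area, dP, mu, w, strict = TRUE) {
  stopifnot(all(c("time_s", "volume_m3") %in% names(data)))
  keep <- data$volume_m3 > 0 & data$time_s > 0
  d <- data[keep, ]
  if (nrow(d) < 3) abort_cw("need at least three points with positive volume", "invalid_series")
  if (any(diff(d$volume_m3) <= 0)) {
    msg <- "filtrate volumes are not strictly increasing"
    if (strict) abort_cw(msg, "invalid_series") else rlang::warn(msg)
  }
  y <- d$time_s / d$volume_m3
  fit <- stats::lm(y ~ d$volume_m3)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  alpha <- slope * 2 * area^2 * dP / (mu * w)
  Rm <- intercept * area * dP / mu
  if (Rm < 0) rlang::warn("negative fitted medium resistance (pre-settled cake?)")
  structure(
    list(
      alpha = alpha, medium_resistance = Rm, slope = slope,
      intercept = intercept, r_squared = summary(fit)$r.squared,
      negative_rm = Rm < 0, n_points = nrow(d)
    ),
    class = "darcy_fit"
  )
}
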