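# Multi-stage cake washing under three mechanisms: ideal piston displacement,
# axial-dispersion washout (Peclet-number closed form), and well-mixed
# semibatch dilution (MSMPR-style, accumulate or feed-and-bleed).

#' Axial-dispersion washout curve
#'
#' Exit concentration ratio c/c0 of the pore mother liquor for a uniformly
#' saturated cake washed at wash ratio W with axial Peclet number Pe:
#'
#' c/c0 = 1/2 erfc\((W - 1) sqrt(Pe / 4W)\) -
#'        1/2 exp(Pe) erfc\((W + 1) sqrt(Pe / 4W)\)
#'
#' The exp(Pe) term is evaluated in log space (via the Gaussian tail in log
#' probability), so the curve stays finite at any Pe. This closed form
#' conserves mass exactly: the integral of c/c0 over all W is 1, and as
#' Pe grows the curve approaches the plug-flow step at W = 1.
#'
#' @param W Wash ratio grid, >= 0. Vectorized.
#' @param Pe Peclet number, > 0.
#' @return c/c0 at each `W`, clamped to \[0, 1\].
#' @examples
#' dispersion_washout(c(0, 0.5, 1, 1.5, 3), Pe = 10)
#' @export
dispersion_washout <- function(W, Pe) {
  if (length(Pe) != 1 || !is.finite(Pe) || Pe <= 0) {
    abort_cw("Peclet number must be a single positive value", "invalid_argument")
  }
  if (any(W < 0)) abort_cw("wash ratios must be non-negative", "invalid_argument")
  out <- numeric(length(W))
  pos <- W > 0
  out[!pos] <- 1
  if (any(pos)) {
    w <- W[pos]
    a <- sqrt(Pe / (4 * w))
    t1 <- 0.5 * erfc_((w - 1) * a)
    # exp(Pe) * erfc(z) = exp(Pe + log erfc(z)), log erfc from the Gaussian
    # log tail: erfc(z) = 2 * P(Z > z * sqrt(2))
    z <- (w + 1) * a
    log_t2 <- Pe + log(2) + stats::pnorm(z * sqrt(2), lower.tail = FALSE, log.p = TRUE)
    out[pos] <- t1 - 0.5 * exp(log_t2)
  }
  pmin(pmax(out, 0), 1)
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Fraction of the initial pore liquor removed after wash ratio W
# (integral of the washout curve from 0 to W).
dispersion_removed_fraction <- function(W, Pe) {
  f_one <- function(w) {
    if (w <= 0) return(0)
    stats::integrate(dispersion_washout, 0, w, Pe = Pe,
                     rel.tol = 1e-12, abs.tol = 1e-14, subdivisions = 500L)$value
  }
  f <- vapply(W, f_one, numeric(1))
  pmin(f, W, 1)
}

#' Define a wash stage
#'
#' Exactly one of `wash_ratio` (volume per cake void volume) or `volume`
#' (m3, or `volume_ml`) must be given.
#'
#' @param composition Wash liquid composition (see [composition()]).
#' @param mechanism One of `"displacement"`, `"dispersion"`, `"well_mixed"`.
#' @param wash_ratio Dimensionless wash ratio W >= 0.
#' @param volume Wash liquid volume (m3).
#' @param volume_ml Wash liquid volume (mL), convenience alternative.
#' @param peclet Peclet number (> 0), dispersion mechanism only. Default 10
#'   (mid-range dispersion producing a three-regime washing curve; the case
#'   studies report no measured value).
#' @param mode Well-mixed mode: `"accumulate"` (semibatch, no outflow;
#'   faithful to a hold-up MSMPR stage) or `"feed_and_bleed"` (constant
#'   hold-up CSTR washout, residual exp(-W)).
#' @param duration Stage duration (s), reporting metadata only.
#' @return A `wash_stage` list.
#' @examples
#' wash_stage(composition(heptane = 1), "displacement", wash_ratio = 2)
#' @export
wash_stage <- function(composition, mechanism = c("displacement", "dispersion", "well_mixed"),
                       wash_ratio = NULL, volume = NULL, volume_ml = NULL,
                       peclet = 10, mode = c("accumulate", "feed_and_bleed"),
                       duration = NA_real_) {
  mechanism <- match.arg(mechanism)
  mode <- match.arg(mode)
  if (!is.null(volume_ml)) {
    if (!is.null(volume)) abort_cw("give volume or volume_ml, not both", "invalid_argument")
    volume <- ml_to_m3(volume_ml)
  }
  if (is.null(wash_ratio) == is.null(volume)) {
    abort_cw("exactly one of wash_ratio or volume must be given", "invalid_argument")
  }
  if (!is.null(wash_ratio) && wash_ratio < 0) abort_cw("wash ratio must be >= 0", "invalid_argument")
  if (!is.null(volume) && volume < 0) abort_cw("wash volume must be >= 0", "invalid_argument")
  if (mechanism == "dispersion" && (!is.finite(peclet) || peclet <= 0)) {
    abort_cw("dispersion stage needs a positive Peclet number", "invalid_argument")
  }
  comp <- as_composition(composition)
  validate_composition(comp)
  structure(
    list(
      composition = comp, mechanism = mechanism, wash_ratio = wash_ratio,
      volume = volume, peclet = peclet, mode = mode, duration = duration
    ),
    class = "wash_stage"
  )
}

stage_volume <- function(stage, cake) {
  if (!is.null(stage$volume)) stage$volume else stage$wash_ratio * cake$void_volume
}

# union-aligned named mass vectors
vec_union <- function(a, b) {
  nm <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(nm)), nm)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  list(a = av, b = bv)
}

cake_species_masses <- function(cake) {
  stats::setNames(
    cake$liquor$mass_fraction * cake$liquor_mass,
    cake$liquor$species
  )
}

update_cake_liquor <- function(cake, masses, liquor_volume) {
  cake$liquor <- masses_to_composition(masses)
  cake$liquor_mass <- sum(masses)
  cake$liquor_volume <- liquor_volume
  cake$saturation <- min(1, liquor_volume / cake$void_volume)
  cake
}

# Core single-stage bookkeeping. Front mechanisms (displacement, dispersion)
# remove the fraction F of the initial pore liquor and refill the displaced
# pore volume with wash liquid; the well-mixed modes dilute the hold-up.
apply_wash_stage <- function(cake, stage) {
  v_wash <- stage_volume(stage, cake)
  W <- v_wash / cake$void_volume
  rho_w <- mixture_properties(stage$composition, cake$species)$density
  # inter-stage deliquoring: a preceding accumulate stage leaves excess
  # liquid above the pore volume; it is withdrawn as filtrate (at the mixed
  # liquor composition) before the new aliquot is charged, returning the
  # cake to pore saturation
  drained <- stats::setNames(numeric(0), character(0))
  if (cake$liquor_volume > cake$void_volume * (1 + 1e-12)) {
    m_all <- cake_species_masses(cake)
    frac_out <- (cake$liquor_volume - cake$void_volume) / cake$liquor_volume
    drained <- frac_out * m_all
    cake <- update_cake_liquor(cake, (1 - frac_out) * m_all, cake$void_volume)
  }
  m0 <- cake_species_masses(cake)
  wash_w <- comp_vec(stage$composition)

  if (stage$mechanism %in% c("displacement", "dispersion")) {
    if (cake$saturation < 1 - 1e-9) {
      abort_cw("front washing requires a saturated cake", "invalid_state")
    }
    Fr <- if (stage$mechanism == "displacement") {
      min(W, 1)
    } else {
      dispersion_removed_fraction(W, stage$peclet)
    }
    pore_v <- cake$liquor_volume
    removed_mother <- Fr * m0
    wash_in <- v_wash * rho_w * wash_w
    wash_retained <- Fr * pore_v * rho_w * wash_w
    wash_out <- wash_in - wash_retained
    u <- vec_union(removed_mother, wash_out)
    filtrate <- u$a + u$b
    u2 <- vec_union((1 - Fr) * m0, wash_retained)
    new_m <- u2$a + u2$b
    cake <- update_cake_liquor(cake, new_m, pore_v)
    residual_ratio <- 1 - Fr
  } else { # well_mixed
    V0 <- cake$liquor_volume
    if (stage$mode == "accumulate") {
      wash_in <- v_wash * rho_w * wash_w
      u <- vec_union(m0, wash_in)
      new_m <- u$a + u$b
      filtrate <- stats::setNames(numeric(0), character(0))
      cake <- update_cake_liquor(cake, new_m, V0 + v_wash)
      residual_ratio <- V0 / (V0 + v_wash)
    } else { # feed_and_bleed: constant-volume CSTR in volumetric concentration
      Wv <- v_wash / V0
      feed_conc <- rho_w * wash_w # kg per m3 of feed
      u <- vec_union(m0, V0 * feed_conc)
      m0u <- u$a
      m_inf <- u$b # hold-up masses at full washout
      new_m <- m_inf + (m0u - m_inf) * exp(-Wv)
      # exact balance: out = initial + fed - final
      fed_full <- stats::setNames(numeric(length(m0u)), names(m0u))
      fed_full[names(wash_w)] <- v_wash * feed_conc[names(wash_w)]
      filtrate <- m0u + fed_full - new_m
      filtrate[filtrate < 0] <- 0
      cake <- update_cake_liquor(cake, new_m, V0)
      residual_ratio <- exp(-Wv)
    }
  }
  if (length(drained) > 0) {
    u <- vec_union(filtrate, drained)
    filtrate <- u$a + u$b
  }
  filtrate <- filtrate[filtrate > 0]
  list(
    cake = cake,
    filtrate_masses = filtrate,
    filtrate_mass = sum(filtrate),
    wash_volume = v_wash,
    wash_ratio = W,
    residual_ratio = residual_ratio
  )
}

new_wash_result <- function(initial_cake, steps, stages, curve = NULL) {
  per_stage <- purrr::imap_dfr(steps, function(s, i) {
    if (length(s$filtrate_masses) == 0) {
      return(tibble::tibble(
        stage = i, species = NA_character_, mass_removed_kg = 0
      )[0, ])
    }
    tibble::tibble(
      stage = i, species = names(s$filtrate_masses),
      mass_removed_kg = as.numeric(s$filtrate_masses)
    )
  })
  stage_summary <- purrr::imap_dfr(steps, function(s, i) {
    filtrate_comp <- if (s$filtrate_mass > 0) {
      list(masses_to_composition(s$filtrate_masses))
    } else {
      list(NULL)
    }
    tibble::tibble(
      stage = i,
      mechanism = stages[[i]]$mechanism,
      mode = ifelse(stages[[i]]$mechanism == "well_mixed", stages[[i]]$mode, NA_character_),
      wash_volume_m3 = s$wash_volume,
      wash_ratio = s$wash_ratio,
      filtrate_mass_kg = s$filtrate_mass,
      residual_ratio = s$residual_ratio,
      filtrate_composition = filtrate_comp
    )
  })
  structure(
    list(
      initial_cake = initial_cake,
      per_stage = per_stage,
      stage_summary = stage_summary,
      final_cake = if (length(steps) > 0) steps[[length(steps)]]$cake else initial_cake,
      curve = curve
    ),
    class = "wash_result"
  )
}

#' Single-stage piston-displacement wash
#'
#' Ideal displacement: the first min(W, 1) pore volumes of filtrate carry
#' pure mother liquor, any excess carries wash liquid; the residual
#' mother-liquor fraction in the pores is max(0, 1 - W).
#'
#' @param cake A saturated `cake_state`.
#' @param stage A [wash_stage()] with mechanism `"displacement"`.
#' @return A single-stage `wash_result`.
#' @export
displacement_wash <- function(cake, stage) {
  if (!identical(stage$mechanism, "displacement")) {
    abort_cw("stage mechanism must be displacement", "invalid_argument")
  }
  step <- apply_wash_stage(cake, stage)
  new_wash_result(cake, list(step), list(stage))
}

#' Single-stage axial-dispersion wash
#'
#' Washout per [dispersion_washout()]; the fraction of initial pore liquor
#' removed is the quadrature of the exit curve up to the stage wash ratio.
#'
#' @param cake A saturated `cake_state`.
#' @param stage A [wash_stage()] with mechanism `"dispersion"`.
#' @return A single-stage `wash_result`.
#' @export
dispersion_wash <- function(cake, stage) {
  if (!identical(stage$mechanism, "dispersion")) {
    abort_cw("stage mechanism must be dispersion", "invalid_argument")
  }
  step <- apply_wash_stage(cake, stage)
  new_wash_result(cake, list(step), list(stage))
}

#' Single-stage well-mixed (MSMPR-style) wash
#'
#' Mode `"accumulate"`: the wash liquid joins the pore liquor with no outflow
#' (semibatch hold-up); concentrations dilute as c = c0 V0 / (V0 + Vwash) and
#' the retained liquid grows. Mode `"feed_and_bleed"`: constant hold-up CSTR
#' washout, c = cf + (c0 - cf) exp(-Vwash / V0).
#'
#' In a multi-stage program any excess hold-up left by a previous accumulate
#' stage is deliquored back to the pore volume (withdrawn as filtrate at the
#' mixed composition) before the next aliquot is charged, so successive
#' accumulate stages follow the dilution product prod_i V0 / (V0 + V_i) and
#' splitting a fixed total volume changes the final purity.
#'
#' @param cake A `cake_state`.
#' @param stage A [wash_stage()] with mechanism `"well_mixed"`.
#' @return A single-stage `wash_result`.
#' @export
well_mixed_wash <- function(cake, stage) {
  if (!identical(stage$mechanism, "well_mixed")) {
    abort_cw("stage mechanism must be well_mixed", "invalid_argument")
  }
  if (!stage$mode %in% c("accumulate", "feed_and_bleed")) {
    abort_cw("unknown well-mixed mode", "invalid_argument")
  }
  step <- apply_wash_stage(cake, stage)
  new_wash_result(cake, list(step), list(stage))
}

#' Run a multi-stage wash program
#'
#' Applies the stages sequentially, threading the cake liquor state; the
#' solid phase is immutable (no dissolution or growth). Per-stage filtrates
#' and a program-level washing curve for the tracked solutes are aggregated.
#'
#' @param cake A `cake_state` from [dryland_state()].
#' @param stages List of [wash_stage()] objects (non-empty).
#' @param mechanism Optional mechanism overriding every stage (convenience
#'   for comparing models on the same program).
#' @param mode Optional well-mixed mode override.
#' @param peclet Optional Peclet number override.
#' @param curve_points Grid points per stage for the washing curve.
#' @return A `wash_result`: `per_stage` species masses removed, per-stage
#'   summary with filtrate compositions, `final_cake`, and `curve`
#'   (see [wash_program_curve()]).
#' @examples
#' sc <- make_scenario("mfa_expt2")
#' cake <- dryland_state(simulate_filtration(sc))
#' res <- run_wash_program(cake, sc$wash_program)
#' res$stage_summary
#' @export
run_wash_program <- function(cake, stages, mechanism = NULL, mode = NULL,
                             peclet = NULL, curve_points = 41) {
  if (length(stages) == 0) abort_cw("wash program must have at least one stage", "invalid_argument")
  if (inherits(stages, "wash_stage")) stages <- list(stages)
  stages <- purrr::map(stages, function(s) {
    if (!is.null(mechanism)) s$mechanism <- match.arg(mechanism, c("displacement", "dispersion", "well_mixed"))
    if (!is.null(mode)) s$mode <- match.arg(mode, c("accumulate", "feed_and_bleed"))
    if (!is.null(peclet)) s$peclet <- peclet
    s
  })
  steps <- vector("list", length(stages))
  cur <- cake
  for (i in seq_along(stages)) {
    steps[[i]] <- apply_wash_stage(cur, stages[[i]])
    cur <- steps[[i]]$cake
  }
  curve <- wash_program_curve(cake, stages, curve_points)
  new_wash_result(cake, steps, stages, curve)
}

# Washing curve for a program: exit/hold-up concentration ratio of each
# tracked solute (API + impurities initially in the pores) versus cumulative
# wash ratio.
wash_program_curve <- function(cake, stages, curve_points = 41) {
  db <- cake$species
  tracked <- intersect(
    cake$liquor$species,
    db$name[db$role %in% c("api", "impurity")]
  )
  if (length(tracked) == 0) tracked <- cake$liquor$species[1]
  c0 <- stats::setNames(
    cake$liquor$mass_fraction[match(tracked, cake$liquor$species)] *
      cake$liquor_mass / cake$liquor_volume,
    tracked
  )
  rows <- list()
  cur <- cake
  W_off <- 0
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    v_wash <- stage_volume(st, cur)
    W_st <- v_wash / cake$void_volume
    grid <- seq(0, W_st, length.out = curve_points)
    conc0 <- stats::setNames(numeric(length(tracked)), tracked)
    present <- intersect(tracked, cur$liquor$species)
    conc0[present] <- cur$liquor$mass_fraction[match(present, cur$liquor$species)] *
      cur$liquor_mass / cur$liquor_volume
    ratio_grid <- switch(st$mechanism,
      displacement = as.numeric(grid < 1),
      dispersion = dispersion_washout(grid, st$peclet),
      well_mixed = if (st$mode == "feed_and_bleed") {
        exp(-grid * cake$void_volume / cur$liquor_volume)
      } else {
        cur$liquor_volume / (cur$liquor_volume + grid * cake$void_volume)
      }
    )
    for (sp in tracked) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        wash_ratio = W_off + grid,
        species = sp,
        c_over_c0 = conc0[sp] * ratio_grid / ifelse(c0[sp] > 0, c0[sp], 1),
        stage = i
      )
    }
    step <- apply_wash_stage(cur, st)
    cur <- step$cake
    W_off <- W_off + W_st
  }
  curve <- dplyr::bind_rows(rows)
  class(curve) <- c("wash_curve", class(curve))
  curve
}

#' Washing curve for a single tracer
#'
#' Convenience constructor of the washing curve c/c0 versus wash ratio for a
#' given mechanism, with regime labels per [segment_wash_curve()].
#'
#' @param W_grid Strictly increasing wash-ratio grid, >= 0.
#' @param mechanism `"displacement"`, `"dispersion"` or `"well_mixed"`
#'   (feed-and-bleed washout).
#' @param peclet Peclet number for the dispersion mechanism.
#' @return A `wash_curve` tibble: `wash_ratio`, `c_over_c0`, `regime`.
#' @examples
#' wash_curve(seq(0, 4, 0.1), "dispersion", peclet = 10)
#' @export
wash_curve <- function(W_grid, mechanism = c("dispersion", "displacement", "well_mixed"),
                       peclet = 10) {
  mechanism <- match.arg(mechanism)
  if (any(diff(W_grid) <= 0)) abort_cw("wash-ratio grid must be strictly increasing", "invalid_argument")
  cc <- switch(mechanism,
    dispersion = dispersion_washout(W_grid, peclet),
    displacement = as.numeric(W_grid < 1),
    well_mixed = exp(-W_grid)
  )
  curve <- tibble::tibble(wash_ratio = W_grid, species = "tracer", c_over_c0 = cc)
  class(curve) <- c("wash_curve", class(curve))
  segment_wash_curve(curve)
}

#' Label the regimes of a washing curve
#'
#' Grid points are labelled `constant_rate` while c/c0 is at or above the
#' upper threshold times its initial value, `diffusion` once it is at or
#' below the lower threshold times the initial value, and `intermediate`
#' between.
#'
#' @param curve A `wash_curve` tibble (columns `wash_ratio`, `c_over_c0`,
#'   optionally `species`), monotone non-increasing per species.
#' @param upper Constant-rate threshold (fraction of initial), default 0.95.
#' @param lower Diffusion threshold, default 0.05.
#' @param tol Monotonicity tolerance.
#' @return The curve with a `regime` column; attribute `"boundaries"` holds
#'   per-species regime boundary wash ratios.
#' @export
segment_wash_curve <- function(curve, upper = 0.95, lower = 0.05, tol = 1e-9) {
  stopifnot(all(c("wash_ratio", "c_over_c0") %in% names(curve)))
  if (!"species" %in% names(curve)) curve$species <- "tracer"
  labelled <- dplyr::group_modify(
    dplyr::group_by(curve, .data$species),
    function(d, key) {
      if (any(diff(d$c_over_c0) > tol)) {
        abort_cw("washing curve must be monotone non-increasing", "invalid_curve")
      }
      c_init <- d$c_over_c0[1]
      d$regime <- dplyr::case_when(
        d$c_over_c0 >= upper * c_init ~ "constant_rate",
        d$c_over_c0 <= lower * c_init ~ "diffusion",
        TRUE ~ "intermediate"
      )
      d
    }
  )
  labelled <- dplyr::ungroup(labelled)
  bounds <- dplyr::summarise(
    dplyr::group_by(labelled, .data$species, .data$regime),
    W_start = min(.data$wash_ratio), W_end = max(.data$wash_ratio),
    .groups = "drop"
  )
  out <- labelled[, union(names(curve), "regime")]
  class(out) <- c("wash_curve", setdiff(class(out), "wash_curve"))
  attr(out, "boundaries") <- bounds
  out
}
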