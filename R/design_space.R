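# Design-space sweeps (wash volume, number of washes -> residual impurity),
# knee detection, wash-split comparison and impurity-minimizing wash-plan
# search.

SWEEP_VARS <- c("wash1_volume_ml", "wash2_volume_ml", "wash3_volume_ml",
                "n_washes", "peclet")

impurity_species <- function(cake) {
  db <- cake$species
  intersect(cake$liquor$species, db$name[db$role == "impurity"])
}

# impurity concentrations (kg per m3 of retained liquor) in a cake state
cake_impurity_conc <- function(cake, species = impurity_species(cake)) {
  m <- cake_species_masses(cake)
  out <- stats::setNames(numeric(length(species)), species)
  present <- intersect(species, names(m))
  out[present] <- m[present] / cake$liquor_volume
  out
}

#' Run filtration and washing end to end
#'
#' @param scenario An `isolation_scenario`.
#' @param mechanism,mode,peclet Optional overrides applied to every wash
#'   stage (see [run_wash_program()]).
#' @param n_out Filtration output grid size.
#' @return An `isolation_result` list with elements `filtration`
#'   (a `filtration_result`), `wash` (a `wash_result`) and `scenario`.
#' @examples
#' iso <- simulate_isolation(make_scenario("mfa_expt2"))
#' iso$wash$stage_summary
#' @export
simulate_isolation <- function(scenario, mechanism = NULL, mode = NULL,
                               peclet = NULL, n_out = 101) {
  filt <- simulate_filtration(scenario, n_out = n_out)
  cake <- dryland_state(filt)
  wash <- run_wash_program(cake, scenario$wash_program,
                           mechanism = mechanism, mode = mode, peclet = peclet)
  structure(
    list(scenario = scenario$name, filtration = filt, wash = wash),
    class = "isolation_result"
  )
}

# stage compositions for programs whose stage count may exceed the
# scenario's: stage 1 keeps the scenario's first-wash mixture, later stages
# the last (pure wash solvent) composition
program_compositions <- function(scenario, n) {
  prog <- scenario$wash_program
  purrr::map(seq_len(n), function(k) {
    prog[[min(k, length(prog))]]$composition
  })
}

build_program <- function(scenario, cake, volumes_ml, mechanism, mode, peclet) {
  comps <- program_compositions(scenario, length(volumes_ml))
  purrr::map2(volumes_ml, comps, function(v, comp) {
    wash_stage(comp, mechanism = mechanism, volume_ml = v,
               peclet = peclet, mode = mode)
  })
}

eval_plan_conc <- function(cake, program, species) {
  res <- run_wash_program(cake, program)
  cake_impurity_conc(res$final_cake, species)
}

#' Full-factorial design-space sweep
#'
#' Evaluates the filtration + washing pipeline over a grid of wash-program
#' variables and reports the final-cake impurity concentrations (kg per m3 of
#' retained liquor, per impurity species) and the total wash solvent used.
#' Filtration to dryland is computed once; each grid point reruns the wash
#' program. Grid-point failures are recorded as `NA` rows with a diagnostic
#' and the sweep continues. An unwashed baseline (all volumes zero) is
#' stored in the `"baseline"` attribute; results are deterministic.
#'
#' @param scenario An `isolation_scenario`.
#' @param variables Named list of strictly increasing grids; names among
#'   `wash1_volume_ml`, `wash2_volume_ml`, `wash3_volume_ml`, `n_washes`,
#'   `peclet`. The program length is `n_washes` when swept, otherwise the
#'   highest swept stage index (so sweeping `wash1_volume_ml` alone explores
#'   a single-wash program), otherwise the scenario's own program; stage
#'   volumes not swept keep the scenario's wash ratio.
#' @param mechanism Wash mechanism for all stages (default `"well_mixed"`).
#' @param mode Well-mixed mode (default `"feed_and_bleed"`).
#' @param peclet Peclet number when not itself swept.
#' @return A `sweep_result` tibble: one row per grid combination with the
#'   swept variables, `conc_<species>` columns and `total_wash_volume_ml`.
#' @examples
#' sc <- make_scenario("mfa_expt2")
#' sw <- sweep_design_space(sc, list(wash1_volume_ml = c(5, 10, 20)))
#' sw
#' @export
sweep_design_space <- function(scenario, variables,
                               mechanism = c("well_mixed", "displacement", "dispersion"),
                               mode = c("feed_and_bleed", "accumulate"),
                               peclet = 10) {
  mechanism <- match.arg(mechanism)
  mode <- match.arg(mode)
  if (length(variables) == 0 || is.null(names(variables))) {
    abort_cw("variables must be a named list of grids", "invalid_argument")
  }
  bad <- setdiff(names(variables), SWEEP_VARS)
  if (length(bad) > 0) {
    abort_cw(paste0("unknown sweep variables: ", paste(bad, collapse = ", ")), "invalid_argument")
  }
  for (v in names(variables)) {
    g <- variables[[v]]
    if (length(g) == 0 || any(diff(g) <= 0) && length(g) > 1) {
      abort_cw(sprintf("grid for %s must be non-empty and strictly increasing", v), "invalid_argument")
    }
  }
  filt <- simulate_filtration(scenario)
  cake <- dryland_state(filt)
  species <- impurity_species(cake)
  grid <- tidyr::expand_grid(!!!variables)

  default_v_ml <- function(k) {
    prog <- scenario$wash_program
    st <- prog[[min(k, length(prog))]]
    m3_to_ml(stage_volume(st, cake))
  }
  vol_idx <- as.integer(sub("wash(\\d)_volume_ml", "\\1",
                            grep("^wash\\d_volume_ml$", names(variables), value = TRUE)))
  eval_row <- function(row) {
    n <- if ("n_washes" %in% names(row)) {
      row$n_washes
    } else if (length(vol_idx) > 0) {
      max(vol_idx)
    } else {
      length(scenario$wash_program)
    }
    pe <- if ("peclet" %in% names(row)) row$peclet else peclet
    vols <- vapply(seq_len(n), function(k) {
      key <- paste0("wash", k, "_volume_ml")
      if (key %in% names(row)) row[[key]] else default_v_ml(k)
    }, 1)
    program <- build_program(scenario, cake, vols, mechanism, mode, pe)
    conc <- eval_plan_conc(cake, program, species)
    c(as.list(conc), list(total_wash_volume_ml = sum(vols)))
  }
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- as.list(grid[i, ])
    tryCatch(eval_row(row), error = function(e) {
      out <- as.list(stats::setNames(rep(NA_real_, length(species)), species))
      c(out, list(total_wash_volume_ml = NA_real_, diagnostic = conditionMessage(e)))
    })
  })
  resp <- purrr::map_dfr(rows, function(r) {
    tibble::as_tibble(stats::setNames(
      r[c(species, "total_wash_volume_ml")],
      c(paste0("conc_", species), "total_wash_volume_ml")
    ))
  })
  out <- dplyr::bind_cols(grid, resp)
  diag <- purrr::map_chr(rows, function(r) r$diagnostic %||% NA_character_)
  if (any(!is.na(diag))) out$diagnostic <- diag

  baseline <- cake_impurity_conc(cake, species)
  attr(out, "baseline") <- stats::setNames(as.numeric(baseline), paste0("conc_", species))
  attr(out, "sweep_variables") <- names(variables)
  attr(out, "provenance") <- list(
    scenario = scenario$name, mechanism = mechanism, mode = mode, peclet = peclet
  )
  class(out) <- c("sweep_result", class(out))
  out
}

#' Knee of a single-variable wash-volume sweep
#'
#' The knee is the smallest grid volume at which the marginal impurity
#' reduction per mL of wash solvent falls below `threshold` times the initial
#' marginal reduction. The initial rate is anchored at the stored unwashed
#' baseline (volume 0), so for an exponential response c0 exp(-V/V*) the knee
#' sits at V* ln(1/threshold) to within the grid spacing.
#'
#' @param result A `sweep_result` over a single volume variable.
#' @param species Impurity species to use; default the first tracked one.
#' @param threshold Fraction of the initial per-mL reduction, default 0.05.
#' @return Knee volume (mL), with attributes `species` and `degenerate`
#'   (`TRUE` when the response is flat and the smallest grid volume is
#'   returned).
#' @export
knee_volume <- function(result, species = NULL, threshold = 0.05) {
  vars <- attr(result, "sweep_variables")
  vol_vars <- grep("volume_ml$", vars, value = TRUE)
  if (length(vars) != 1 || length(vol_vars) != 1) {
    abort_cw("knee detection needs a single-volume-variable sweep", "invalid_sweep")
  }
  vv <- vol_vars[1]
  col <- if (is.null(species)) {
    grep("^conc_", names(result), value = TRUE)[1]
  } else {
    paste0("conc_", species)
  }
  if (!col %in% names(result)) abort_cw("unknown response species", "invalid_sweep")
  d <- dplyr::arrange(tibble::tibble(v = result[[vv]], r = result[[col]]), v)
  base <- attr(result, "baseline")[col]
  if (d$v[1] > 0) d <- dplyr::bind_rows(tibble::tibble(v = 0, r = unname(base)), d)
  if (any(diff(d$r) > 1e-9 * max(abs(d$r), 1e-300))) {
    abort_cw("sweep response must be monotone non-increasing in volume", "invalid_sweep")
  }
  dr <- -diff(d$r) / diff(d$v)
  degenerate <- FALSE
  if (dr[1] <= 0) {
    knee <- d$v[2]
    degenerate <- TRUE
  } else {
    hit <- which(dr < threshold * dr[1])
    knee <- if (length(hit) == 0) {
      degenerate <- TRUE
      d$v[length(d$v)]
    } else {
      d$v[hit[1] + 1]
    }
  }
  structure(knee, species = sub("^conc_", "", col), degenerate = degenerate)
}

#' Compare equal-split wash programs at fixed total solvent volume
#'
#' Splits a total wash volume into 1..k equal aliquots of pure wash solvent
#' and reports the final-cake impurity concentrations per split count. Under
#' the feed-and-bleed well-mixed mechanism the final purity is
#' split-invariant (the residual depends only on the total wash ratio);
#' under the accumulate mode splitting changes the dilution product.
#'
#' @param scenario An `isolation_scenario`.
#' @param total_volume_ml Total wash solvent volume (mL), > 0.
#' @param n_washes Integer vector of split counts (<= 3 in the case studies,
#'   any positive count accepted).
#' @param mechanism,mode,peclet Wash mechanism settings as in
#'   [sweep_design_space()].
#' @return Tibble: `n_washes`, `stage_volume_ml`, `conc_<species>` columns.
#' @export
compare_wash_splits <- function(scenario, total_volume_ml, n_washes = 1:3,
                                mechanism = c("well_mixed", "displacement", "dispersion"),
                                mode = c("feed_and_bleed", "accumulate"),
                                peclet = 10) {
  mechanism <- match.arg(mechanism)
  mode <- match.arg(mode)
  if (total_volume_ml <= 0) abort_cw("total volume must be positive", "invalid_argument")
  cake <- dryland_state(simulate_filtration(scenario))
  species <- impurity_species(cake)
  pure_wash <- scenario$wash_program[[length(scenario$wash_program)]]$composition
  purrr::map_dfr(n_washes, function(n) {
    program <- purrr::map(seq_len(n), function(k) {
      wash_stage(pure_wash, mechanism = mechanism,
                 volume_ml = total_volume_ml / n, peclet = peclet, mode = mode)
    })
    conc <- eval_plan_conc(cake, program, species)
    dplyr::bind_cols(
      tibble::tibble(n_washes = n, stage_volume_ml = total_volume_ml / n),
      tibble::as_tibble(as.list(stats::setNames(conc, paste0("conc_", species))))
    )
  })
}

#' Impurity-minimizing wash plan under a solvent budget
#'
#' Exhaustive grid search over per-stage wash volumes (multiples of
#' `step_ml`, summing to at most the budget) for 1 to `max_washes` stages of
#' pure wash solvent; returns the plan minimizing the total final-cake
#' impurity concentration. Ties are broken in favour of fewer stages, then
#' lexicographically larger first aliquots.
#'
#' @param scenario An `isolation_scenario`.
#' @param budget_ml Total wash solvent budget (mL), > 0.
#' @param max_washes Maximum number of stages (default 3).
#' @param mechanism,mode,peclet Wash mechanism settings.
#' @param step_ml Volume grid step (mL), default `budget_ml / 10`.
#' @return A `wash_plan` list: `plan` (tibble `stage`, `volume_ml`),
#'   `objective` (total impurity concentration, kg/m3), `final_composition`,
#'   `evaluations` (tibble of every plan searched).
#' @export
optimize_wash_plan <- function(scenario, budget_ml, max_washes = 3,
                               mechanism = c("well_mixed", "displacement", "dispersion"),
                               mode = c("feed_and_bleed", "accumulate"),
                               peclet = 10, step_ml = budget_ml / 10) {
  mechanism <- match.arg(mechanism)
  mode <- match.arg(mode)
  if (budget_ml <= 0) abort_cw("budget must be positive", "invalid_budget")
  if (step_ml > budget_ml) abort_cw("budget smaller than one grid step", "invalid_budget")
  cake <- dryland_state(simulate_filtration(scenario))
  species <- impurity_species(cake)
  pure_wash <- scenario$wash_program[[length(scenario$wash_program)]]$composition
  steps <- seq(step_ml, budget_ml, by = step_ml)

  plans <- list()
  gen <- function(prefix, remaining, depth) {
    for (v in steps) {
      if (v > remaining + 1e-9) break
      plan <- c(prefix, v)
      plans[[length(plans) + 1]] <<- plan
      if (depth < max_washes) gen(plan, remaining - v, depth + 1)
    }
  }
  gen(numeric(0), budget_ml, 1)

  evals <- purrr::map_dfr(plans, function(vols) {
    program <- purrr::map(vols, function(v) {
      wash_stage(pure_wash, mechanism = mechanism, volume_ml = v,
                 peclet = peclet, mode = mode)
    })
    conc <- eval_plan_conc(cake, program, species)
    tibble::tibble(
      n_washes = length(vols),
      volumes_ml = paste(vols, collapse = "+"),
      total_volume_ml = sum(vols),
      objective = sum(conc)
    )
  })
  # plans identical up to floating-point noise count as ties, so the
  # fewest-stages tie-break can act (split-invariant mechanisms)
  ord <- order(signif(evals$objective, 9), evals$n_washes, -evals$total_volume_ml)
  best_i <- ord[1]
  best_vols <- as.numeric(strsplit(evals$volumes_ml[best_i], "\\+")[[1]])
  program <- purrr::map(best_vols, function(v) {
    wash_stage(pure_wash, mechanism = mechanism, volume_ml = v,
               peclet = peclet, mode = mode)
  })
  res <- run_wash_program(cake, program)
  structure(
    list(
      plan = tibble::tibble(stage = seq_along(best_vols), volume_ml = best_vols),
      objective = evals$objective[best_i],
      final_composition = res$final_cake$liquor,
      final_cake = res$final_cake,
      evaluations = evals,
      mechanism = mechanism, mode = mode
    ),
    class = "wash_plan"
  )
}
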