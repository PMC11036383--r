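# broom-style tidiers and print methods.

#' @export
tidy.filtration_result <- function(x, ...) {
  dplyr::rename(x$series, filtrate_volume_m3 = "volume_m3", filtrate_mass_kg = "mass_kg")
}

#' @export
glance.filtration_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    stopped_at = x$stopped_at,
    filtration_time_s = x$series$time_s[nrow(x$series)],
    filtrate_volume_ml = m3_to_ml(x$filtrate_volume),
    filtrate_mass_g = kg_to_g(x$filtrate_mass),
    alpha_m_per_kg = x$alpha_used,
    medium_resistance_per_m = x$medium_resistance,
    retained_liquor_mass_g = if (!is.null(x$end_state)) kg_to_g(x$end_state$liquor_mass) else NA_real_,
    cake_height_mm = if (!is.null(x$end_state)) x$end_state$height * 1e3 else NA_real_
  )
}

#' @export
tidy.darcy_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "medium_resistance"),
    estimate = c(x$alpha, x$medium_resistance),
    unit = c("m/kg", "1/m")
  )
}

#' @export
glance.darcy_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, n_points = x$n_points, negative_rm = x$negative_rm
  )
}

#' @export
tidy.compressibility_fit <- function(x, ...) {
  tibble::tibble(
    term = c("compressibility_index", "alpha_ref"),
    estimate = c(x$n, x$alpha_ref),
    unit = c("", "m/kg")
  )
}

#' @export
glance.wash_result <- function(x, ...) {
  tibble::tibble(
    n_stages = nrow(x$stage_summary),
    total_wash_volume_ml = m3_to_ml(sum(x$stage_summary$wash_volume_m3)),
    total_filtrate_mass_g = kg_to_g(sum(x$stage_summary$filtrate_mass_kg)),
    final_liquor_mass_g = kg_to_g(x$final_cake$liquor_mass),
    final_saturation = x$final_cake$saturation
  )
}

#' @export
tidy.wash_result <- function(x, ...) x$per_stage

#' @export
print.isolation_scenario <- function(x, ...) {
  cat("<isolation_scenario>", x$name, "\n")
  cat("  ", x$provenance, "\n", sep = "")
  cat(sprintf("  solid: %.3g g %s; liquor: %.3g g\n",
              kg_to_g(x$suspension$solid_mass), x$suspension$solid_species,
              kg_to_g(x$suspension$liquor_mass)))
  cat(sprintf("  filter: d = %.0f mm, Rm = %.3g 1/m; dP = %.0f mbar\n",
              x$filter$diameter * 1e3, x$filter$medium_resistance,
              pa_to_mbar(x$conditions$driving_force)))
  cat(sprintf("  cake: porosity %.3g, sphericity %.3g, n = %.3g, alpha_ref = %.3g m/kg at %.0f mbar\n",
              x$cake_properties$porosity, x$cake_properties$sphericity,
              x$cake_properties$compressibility_index, x$cake_properties$alpha_ref,
              pa_to_mbar(x$cake_properties$reference_pressure)))
  cat(sprintf("  wash program: %d stage(s)\n", length(x$wash_program)))
  invisible(x)
}

#' @export
print.filtration_result <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' @export
print.cake_state <- function(x, ...) {
  cat("<cake_state>\n")
  cat(sprintf("  solid: %.3g g %s; porosity %.3g; height %.2f mm\n",
              kg_to_g(x$solid_mass), x$solid_species, x$porosity, x$height * 1e3))
  cat(sprintf("  void volume: %.3g mL; liquor: %.3g g (saturation %.3g)\n",
              m3_to_ml(x$void_volume), kg_to_g(x$liquor_mass), x$saturation))
  print(x$liquor)
  invisible(x)
}

#' @export
print.wash_result <- function(x, ...) {
  print(glance(x))
  print(x$stage_summary)
  invisible(x)
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result>\n")
  print(tidy(x))
  print(glance(x))
  invisible(x)
}

#' @export
print.wash_plan <- function(x, ...) {
  cat("<wash_plan>", x$mechanism,
      if (x$mechanism == "well_mixed") paste0("(", x$mode, ")") else "", "\n")
  print(x$plan)
  cat(sprintf("  final total impurity concentration: %.4g kg/m3 liquor\n", x$objective))
  invisible(x)
}
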