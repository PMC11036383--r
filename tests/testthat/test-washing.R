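test_that("dispersion washout obeys its limit and shape properties", {
  # no wash delivered
  expect_identical(dispersion_washout(0, 5), 1)
  expect_identical(dispersion_washout(0, 1e6), 1)
  # near-plug-flow limit
  expect_equal(dispersion_washout(0.5, 1e6), 1, tolerance = 1e-3)
  expect_equal(dispersion_washout(1.5, 1e6), 0, tolerance = 1e-3)
  # finite at huge Pe (log-space evaluation of the exp(Pe) term)
  expect_true(all(is.finite(dispersion_washout(seq(0, 5, 0.01), 1e6))))
  # bounded and monotone non-increasing in W
  for (Pe in c(0.5, 2, 10, 100)) {
    cc <- dispersion_washout(seq(0, 8, 0.005), Pe)
    expect_true(all(cc >= 0 & cc <= 1 + 1e-9))
    expect_true(all(diff(cc) <= 1e-12))
  }
  # for fixed W beyond the front, non-increasing in Pe (sharper fronts wash
  # the tail less); just past W = 1 at small Pe the exact solution is briefly
  # non-monotone in Pe, so the tail region is asserted
  pe_grid <- c(5, 10, 30, 100)
  for (W in c(1.2, 1.5, 2.5)) {
    vals <- vapply(pe_grid, function(p) dispersion_washout(W, p), 1)
    expect_true(all(diff(vals) <= 1e-12))
  }
  expect_error(dispersion_washout(1, -2), class = "invalid_argument")
  expect_error(dispersion_washout(-1, 2), class = "invalid_argument")
})

test_that("dispersion washout conserves pore solute by quadrature", {
  for (Pe in c(2, 10, 50)) {
    total <- stats::integrate(dispersion_washout, 0, 60, Pe = Pe,
                              rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(total, 1, tolerance = 0.01)
  }
})

test_that("piston displacement follows exact volume bookkeeping", {
  cake <- dryland_state(simulate_filtration(toy_scenario()))
  wash <- composition(solventB = 1)

  r0 <- displacement_wash(cake, wash_stage(wash, "displacement", wash_ratio = 0))
  expect_equal(r0$final_cake$liquor, cake$liquor)
  expect_identical(r0$stage_summary$filtrate_mass_kg, 0)

  # W >= 1: pores hold pure wash liquid, residual mother liquor zero
  r2 <- displacement_wash(cake, wash_stage(wash, "displacement", wash_ratio = 2))
  expect_identical(r2$final_cake$liquor$species, "solventB")
  expect_equal(r2$final_cake$liquor$mass_fraction, 1)

  # W = 0.5: filtrate is half a pore volume of pure mother liquor
  rh <- displacement_wash(cake, wash_stage(wash, "displacement", wash_ratio = 0.5))
  imp0 <- cake$liquor$mass_fraction[cake$liquor$species == "impY"] * cake$liquor_mass
  removed <- rh$per_stage$mass_removed_kg[rh$per_stage$species == "impY"]
  expect_equal(removed, 0.5 * imp0, tolerance = 1e-12)
  expect_false("solventB" %in% rh$per_stage$species)
  expect_equal(rh$stage_summary$filtrate_mass_kg, 0.5 * cake$liquor_mass, tolerance = 1e-12)

  # unsaturated cakes cannot be front-washed
  dry <- cake
  dry$saturation <- 0.8
  expect_error(displacement_wash(dry, wash_stage(wash, "displacement", wash_ratio = 1)),
               class = "invalid_state")
})

test_that("well-mixed washing matches its closed forms exactly", {
  cake <- dryland_state(simulate_filtration(toy_scenario()))
  wash <- composition(solventB = 1)
  imp_conc <- function(ck) {
    m <- ck$liquor$mass_fraction[ck$liquor$species == "impY"] * ck$liquor_mass
    m / ck$liquor_volume
  }
  c0 <- imp_conc(cake)

  for (mode in c("accumulate", "feed_and_bleed")) {
    r <- well_mixed_wash(cake, wash_stage(wash, "well_mixed", wash_ratio = 0, mode = mode))
    expect_equal(imp_conc(r$final_cake), c0, tolerance = 1e-12)
  }
  # feed-and-bleed W = 1 -> exp(-1)
  r1 <- well_mixed_wash(cake, wash_stage(wash, "well_mixed", wash_ratio = 1, mode = "feed_and_bleed"))
  expect_equal(imp_conc(r1$final_cake) / c0, exp(-1), tolerance = 1e-12)
  # accumulate with Vwash = V0 -> exactly half
  ra <- well_mixed_wash(cake, wash_stage(wash, "well_mixed",
                                         volume = cake$liquor_volume, mode = "accumulate"))
  expect_equal(imp_conc(ra$final_cake) / c0, 0.5, tolerance = 1e-12)
  expect_identical(ra$stage_summary$filtrate_mass_kg, 0) # semibatch: no outflow
  expect_gt(ra$final_cake$liquor_volume, cake$void_volume)
})

test_that("wash programs thread state and compose closed forms", {
  cake <- dryland_state(simulate_filtration(toy_scenario()))
  wash <- composition(solventB = 1)
  imp_mass <- function(ck) {
    m <- ck$liquor$mass_fraction[ck$liquor$species == "impY"] * ck$liquor_mass
    if (length(m) == 0) 0 else m
  }
  two_fb <- purrr::map(1:2, ~ wash_stage(wash, "well_mixed", wash_ratio = 1, mode = "feed_and_bleed"))
  res <- run_wash_program(cake, two_fb)
  expect_equal(imp_mass(res$final_cake) / imp_mass(cake), exp(-2), tolerance = 1e-9)
  expect_equal(res$final_cake$solid_mass, cake$solid_mass) # solid phase immutable

  zeros <- purrr::map(1:3, ~ wash_stage(wash, "displacement", wash_ratio = 0))
  rid <- run_wash_program(cake, zeros)
  expect_equal(rid$final_cake$liquor, cake$liquor)
  expect_equal(rid$final_cake$liquor_mass, cake$liquor_mass)

  expect_error(run_wash_program(cake, list()), class = "invalid_argument")
})

test_that("the first displacement wash of the MFA program removes all pore impurity", {
  sc <- make_scenario("mfa_expt2") # W = 2 stages
  cake <- dryland_state(simulate_filtration(sc))
  res <- run_wash_program(cake, sc$wash_program)
  pore_cba <- cake$liquor$mass_fraction[cake$liquor$species == "CBA"] * cake$liquor_mass
  removed1 <- res$per_stage$mass_removed_kg[
    res$per_stage$stage == 1 & res$per_stage$species == "CBA"
  ]
  expect_equal(removed1, pore_cba, tolerance = 1e-12)
  # first-stage filtrate is mother-liquor dominated
  comp1 <- res$stage_summary$filtrate_composition[[1]]
  ml_frac <- sum(comp1$mass_fraction[comp1$species %in% cake$liquor$species])
  expect_gt(ml_frac, 0.5)
})

test_that("dispersion converges to the displacement step as Pe grows", {
  W <- seq(0, 3, 0.01)
  off_front <- abs(W - 1) > 0.05
  step <- as.numeric(W < 1)
  cc <- dispersion_washout(W, 1e6)
  expect_lt(max(abs(cc - step)[off_front]), 1e-3)
})

test_that("feed-and-bleed washing is split-invariant over random partitions", {
  cake <- dryland_state(simulate_filtration(toy_scenario()))
  wash <- composition(solventB = 1)
  imp <- function(res) {
    ck <- res$final_cake
    ck$liquor$mass_fraction[ck$liquor$species == "impY"] * ck$liquor_mass
  }
  total_W <- 3
  one <- run_wash_program(cake, list(
    wash_stage(wash, "well_mixed", wash_ratio = total_W, mode = "feed_and_bleed")
  ))
  set.seed(11)
  for (k in 1:5) {
    cuts <- sort(runif(2, 0, total_W))
    ws <- diff(c(0, cuts, total_W))
    prog <- purrr::map(ws, ~ wash_stage(wash, "well_mixed", wash_ratio = .x, mode = "feed_and_bleed"))
    expect_equal(imp(run_wash_program(cake, prog)), imp(one), tolerance = 1e-9)
  }
})

test_that("accumulate washing is split-sensitive and matches the dilution product", {
  cake <- dryland_state(simulate_filtration(toy_scenario()))
  wash <- composition(solventB = 1)
  V0 <- cake$void_volume
  imp <- function(res) {
    ck <- res$final_cake
    m <- ck$liquor$mass_fraction[ck$liquor$species == "impY"] * ck$liquor_mass
    m / ck$liquor_volume
  }
  c0 <- cake$liquor$mass_fraction[cake$liquor$species == "impY"] *
    cake$liquor_mass / cake$liquor_volume
  vols <- c(1.5, 0.8) * V0
  prog <- purrr::map(vols, ~ wash_stage(wash, "well_mixed", volume = .x, mode = "accumulate"))
  got <- imp(run_wash_program(cake, prog))
  hand <- c0 * prod(V0 / (V0 + vols))
  expect_equal(got, hand, tolerance = 1e-9)
  single <- imp(run_wash_program(cake, list(
    wash_stage(wash, "well_mixed", volume = sum(vols), mode = "accumulate")
  )))
  expect_false(isTRUE(all.equal(got, single, tolerance = 1e-6)))
  expect_lt(got, single) # splitting wins under accumulate
})

test_that("washing-curve regimes are segmented against a threshold oracle", {
  # plug-flow step: no intermediate points
  step <- wash_curve(seq(0.05, 3, 0.05), "displacement")
  expect_false("intermediate" %in% step$regime)

  # dispersion at Pe = 10: three non-empty regimes, boundaries at thresholds
  crv <- wash_curve(seq(0.01, 6, 0.01), "dispersion", peclet = 10)
  expect_setequal(unique(crv$regime), c("constant_rate", "intermediate", "diffusion"))
  c_init <- crv$c_over_c0[1]
  oracle_cr <- crv$wash_ratio[crv$c_over_c0 >= 0.95 * c_init]
  expect_equal(max(crv$wash_ratio[crv$regime == "constant_rate"]), max(oracle_cr))
  oracle_diff <- crv$wash_ratio[crv$c_over_c0 <= 0.05 * c_init]
  expect_equal(min(crv$wash_ratio[crv$regime == "diffusion"]), min(oracle_diff))

  # all-ones curve (grid below breakthrough) is entirely constant-rate
  flat <- segment_wash_curve(tibble::tibble(wash_ratio = seq(0, 0.5, 0.1),
                                            c_over_c0 = 1))
  expect_true(all(flat$regime == "constant_rate"))

  bad <- tibble::tibble(wash_ratio = c(0, 1, 2), c_over_c0 = c(1, 0.2, 0.5))
  expect_error(segment_wash_curve(bad), class = "invalid_curve")
})

test_that("program washing curves stay within bounds and track every solute", {
  sc <- make_scenario("mfa_expt2", mechanism = "dispersion")
  cake <- dryland_state(simulate_filtration(sc))
  res <- run_wash_program(cake, sc$wash_program)
  expect_true(all(res$curve$c_over_c0 >= 0 & res$curve$c_over_c0 <= 1 + 1e-9))
  expect_true(all(c("MFA", "CBA") %in% unique(res$curve$species)))
  expect_true(all(diff(unique(res$curve$wash_ratio)) > 0))
})
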