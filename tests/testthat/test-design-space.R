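test_that("zero wash volume reproduces the unwashed cake impurity", {
  sc <- make_scenario("mfa_expt2")
  sw <- sweep_design_space(sc, list(wash1_volume_ml = 0))
  base <- attr(sw, "baseline")
  expect_equal(sw$conc_CBA[1], unname(base["conc_CBA"]), tolerance = 1e-12)
  cake <- dryland_state(simulate_filtration(sc))
  c0 <- cake$liquor$mass_fraction[cake$liquor$species == "CBA"] *
    cake$liquor_mass / cake$liquor_volume
  expect_equal(sw$conc_CBA[1], c0, tolerance = 1e-12)
})

test_that("impurity response is monotone non-increasing in wash volume for every mechanism", {
  sc <- make_scenario("mfa_expt2")
  grids <- list(wash1_volume_ml = seq(1, 30, 2))
  for (setup in list(list("well_mixed", "feed_and_bleed"),
                     list("well_mixed", "accumulate"),
                     list("displacement", "accumulate"),
                     list("dispersion", "accumulate"))) {
    sw <- sweep_design_space(sc, grids, mechanism = setup[[1]], mode = setup[[2]])
    expect_true(all(diff(sw$conc_CBA) <= 1e-12), label = setup[[1]])
  }
})

test_that("feed-and-bleed sweep equals the exponential closed form", {
  sc <- make_scenario("mfa_expt2")
  sw <- sweep_design_space(sc, list(wash1_volume_ml = seq(1, 40, 1)))
  cake <- dryland_state(simulate_filtration(sc))
  c0 <- cake$liquor$mass_fraction[cake$liquor$species == "CBA"] *
    cake$liquor_mass / cake$liquor_volume
  pred <- c0 * exp(-ml_to_m3(sw$wash1_volume_ml) / cake$void_volume)
  expect_equal(sw$conc_CBA, pred, tolerance = 1e-9)
})

test_that("knee detection matches the analytic knee of an exponential response", {
  sc <- make_scenario("mfa_expt2")
  cake <- dryland_state(simulate_filtration(sc))
  v_star_ml <- m3_to_ml(cake$void_volume)
  sw <- sweep_design_space(sc, list(wash1_volume_ml = seq(1, 40, 1)))
  knee <- knee_volume(sw, threshold = 0.05)
  expect_lte(abs(as.numeric(knee) - v_star_ml * log(20)), 2) # within two grid steps
  expect_false(attr(knee, "degenerate"))

  # halving the grid spacing moves the knee by at most one coarse step
  sw_fine <- sweep_design_space(sc, list(wash1_volume_ml = seq(0.5, 40, 0.5)))
  expect_lte(abs(as.numeric(knee_volume(sw_fine)) - as.numeric(knee)), 1)
})

test_that("flat responses return the smallest grid volume with a degenerate flag", {
  sw <- tibble::tibble(wash1_volume_ml = c(5, 10, 15), conc_impY = c(2, 2, 2))
  attr(sw, "baseline") <- c(conc_impY = 2)
  attr(sw, "sweep_variables") <- "wash1_volume_ml"
  class(sw) <- c("sweep_result", class(sw))
  knee <- knee_volume(sw)
  expect_equal(as.numeric(knee), 5)
  expect_true(attr(knee, "degenerate"))

  bad <- sw
  bad$conc_impY <- c(2, 1, 1.5)
  expect_error(knee_volume(bad), class = "invalid_sweep")
})

test_that("sweeps are deterministic and record grid-point failures", {
  sc <- make_scenario("mfa_expt2")
  g <- list(wash1_volume_ml = seq(2, 10, 2))
  s1 <- sweep_design_space(sc, g)
  s2 <- sweep_design_space(sc, g)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_error(sweep_design_space(sc, list(bogus = 1:3)), class = "invalid_argument")
})

test_that("split comparison: feed-and-bleed ties, accumulate favours splitting", {
  sc <- make_scenario("mfa_expt2")
  fb <- compare_wash_splits(sc, total_volume_ml = 30, n_washes = 1:3,
                            mechanism = "well_mixed", mode = "feed_and_bleed")
  expect_lt(diff(range(fb$conc_CBA)) / fb$conc_CBA[1], 1e-9)

  acc <- compare_wash_splits(sc, total_volume_ml = 30, n_washes = 1:3,
                             mechanism = "well_mixed", mode = "accumulate")
  expect_true(all(diff(acc$conc_CBA) < 0))
  cake <- dryland_state(simulate_filtration(sc))
  V0 <- m3_to_ml(cake$void_volume)
  c0 <- cake$liquor$mass_fraction[cake$liquor$species == "CBA"] *
    cake$liquor_mass / cake$liquor_volume
  hand <- vapply(1:3, function(n) c0 * (V0 / (V0 + 30 / n))^n, 1)
  expect_equal(acc$conc_CBA, hand, tolerance = 1e-9)

  # a 1-split comparison equals a direct single-stage program
  pure <- sc$wash_program[[length(sc$wash_program)]]$composition
  direct <- run_wash_program(cake, list(
    wash_stage(pure, "well_mixed", volume_ml = 30, mode = "feed_and_bleed")
  ))
  fc <- direct$final_cake
  c_direct <- fc$liquor$mass_fraction[fc$liquor$species == "CBA"] *
    fc$liquor_mass / fc$liquor_volume
  expect_identical(fb$conc_CBA[1], c_direct)
})

test_that("wash-plan search is exhaustive-consistent and spends the budget", {
  sc <- make_scenario("mfa_expt2")
  plan_fb <- optimize_wash_plan(sc, budget_ml = 30, max_washes = 3,
                                mechanism = "well_mixed", mode = "feed_and_bleed",
                                step_ml = 5)
  # never worse than anything in its own search grid
  expect_lte(plan_fb$objective, min(plan_fb$evaluations$objective) * (1 + 1e-12))
  # monotone mechanism: full budget spent; ties broken to fewest stages
  expect_equal(sum(plan_fb$plan$volume_ml), 30)
  expect_identical(nrow(plan_fb$plan), 1L)

  cake <- dryland_state(simulate_filtration(sc))
  V0 <- m3_to_ml(cake$void_volume)
  plan_acc <- optimize_wash_plan(sc, budget_ml = 3 * V0, max_washes = 3,
                                 mechanism = "well_mixed", mode = "accumulate",
                                 step_ml = V0 / 2)
  expect_equal(sum(plan_acc$plan$volume_ml), 3 * V0, tolerance = 1e-9)
  expect_identical(nrow(plan_acc$plan), 3L) # equal splits beat one large dilution
  expect_equal(plan_acc$plan$volume_ml, rep(V0, 3), tolerance = 1e-9)

  expect_error(optimize_wash_plan(sc, budget_ml = -1), class = "invalid_budget")
  expect_error(optimize_wash_plan(sc, budget_ml = 2, step_ml = 5), class = "invalid_budget")
})

test_that("autoplot methods return ggplot objects", {
  sc <- make_scenario("mfa_expt2")
  res <- simulate_filtration(sc)
  expect_s3_class(autoplot(res), "ggplot")
  sw <- sweep_design_space(sc, list(wash1_volume_ml = c(5, 10, 20)))
  expect_s3_class(autoplot(sw), "ggplot")
  crv <- wash_curve(seq(0.01, 4, 0.05), "dispersion", peclet = 10)
  expect_s3_class(autoplot(crv), "ggplot")
})
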