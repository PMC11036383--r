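test_that("Carman-Kozeny resistance matches hand evaluation and scaling law", {
  p <- particle_population(mean_size = 100, sphericity = 1)
  expect_equal(carman_kozeny_alpha(p, 0.5, 1000), 7.2e7, tolerance = 1e-12)
  p2 <- particle_population(mean_size = 200, sphericity = 1)
  expect_equal(carman_kozeny_alpha(p2, 0.5, 1000), 7.2e7 / 4, tolerance = 1e-12)
  expect_error(carman_kozeny_alpha(p, 1.2, 1000), class = "invalid_argument")
})

test_that("Carman-Kozeny with calibrated MFA inputs sits at the measured order of magnitude", {
  # sphericity 0.4964, porosity 0.5258, mean size 94 um, vs the measured
  # 1.01e8 m/kg of the 350 mbar diglyme-water/cyclohexane run
  p <- particle_population(mean_size = 94, sphericity = 0.4964)
  a <- carman_kozeny_alpha(p, 0.5258, 1300)
  expect_gt(a / 1.01e8, 0.1)
  expect_lt(a / 1.01e8, 10)
})

test_that("compressibility power law is evaluated and fitted correctly", {
  props <- cake_properties(0.5, 0.7, compressibility_index = 0,
                           reference_pressure = 1e5, alpha_ref = 5e8)
  expect_equal(alpha_at_pressure(props, 12345), 5e8)
  props$compressibility_index <- 1
  expect_equal(alpha_at_pressure(props, 2e5), 1e9)

  # two-point slope oracle on the 100/600 mbar bench pair
  n_hand <- log(1.84e9 / 9.84e7) / log(6)
  fit <- fit_compressibility(data.frame(pressure = c(1e4, 6e4), alpha = c(9.84e7, 1.84e9)))
  expect_equal(fit$n, n_hand, tolerance = 1e-12)
  expect_identical(fit$label, "high")
  # alpha_ref at the fit's reference pressure reproduces the inputs
  pr <- cake_properties(0.5, 0.7, compressibility_index = fit$n,
                        reference_pressure = fit$reference_pressure,
                        alpha_ref = fit$alpha_ref)
  expect_equal(alpha_at_pressure(pr, 6e4), 1.84e9, tolerance = 1e-9)

  flat <- fit_compressibility(data.frame(pressure = c(1e4, 1e4), alpha = c(2e8, 2e8)))
  expect_identical(flat$n, 0)
  expect_true(flat$unidentifiable)
  expect_identical(flat$label, "low/moderate")

  # three exactly collinear points recovered to machine precision
  dp <- c(1e4, 3e4, 9e4)
  d <- data.frame(pressure = dp, alpha = 2e8 * (dp / 1e5)^0.65)
  expect_equal(fit_compressibility(d)$n, 0.65, tolerance = 1e-12)
  expect_equal(fit_compressibility(d)$alpha_ref, 2e8, tolerance = 1e-6)

  expect_error(fit_compressibility(data.frame(pressure = 1e4, alpha = 1e8)),
               class = "invalid_argument")
})

test_that("simulated filtrate curve is monotone, concave, and mass-conserving", {
  sc <- toy_scenario()
  res <- simulate_filtration(sc)
  v <- res$series$volume_m3
  expect_true(all(diff(v) >= 0))
  # concavity of V(t) on the uniform grid (flat after the dryland snap)
  expect_true(all(diff(diff(v)) <= 1e-12 * max(v)))
  expect_identical(res$stopped_at, "dryland")
  susp <- sc$suspension$solid_mass + sc$suspension$liquor_mass
  wet <- res$end_state$solid_mass + res$end_state$liquor_mass
  expect_lt(abs(susp - (res$filtrate_mass + wet)) / susp, 1e-8)
  expect_equal(res$end_state$saturation, 1)
  # filtrate carries the mother-liquor composition unchanged
  expect_equal(res$filtrate_composition, sc$suspension$liquor)
})

test_that("dryland end point is consistent with the suspension balance", {
  sc <- toy_scenario()
  res <- simulate_filtration(sc)
  st <- res$end_state
  expect_equal(st$void_volume, st$porosity * st$bulk_volume, tolerance = 1e-12)
  rho_l <- mixture_properties(sc$suspension$liquor, toy_db())$density
  expect_equal(st$liquor_mass, st$void_volume * rho_l, tolerance = 1e-10)
  expect_equal(res$filtrate_volume,
               sc$suspension$liquor_mass / rho_l - st$void_volume,
               tolerance = 1e-9)
  bad <- simulate_filtration(sc, max_time = res$series$time_s[nrow(res$series)] / 10)
  expect_identical(bad$stopped_at, "max_time")
  expect_error(dryland_state(bad), class = "invalid_state")
})

test_that("Darcy linearization round-trips the simulator's alpha and Rm", {
  sc <- toy_scenario(Rm = 5e9)
  res <- simulate_filtration(sc, n_out = 60)
  st <- cakewash:::filtration_setup(sc)
  fit <- darcy_fit(res$series, area = st$area, dP = st$dP, mu = st$mu, w = st$w)
  expect_equal(fit$alpha, res$alpha_used, tolerance = 0.01)
  expect_equal(fit$medium_resistance, res$medium_resistance, tolerance = 0.01)
  expect_false(fit$negative_rm)

  expect_error(
    darcy_fit(res$series[1:3, ], area = st$area, dP = st$dP, mu = st$mu, w = st$w),
    class = "invalid_series"
  ) # rows 1-3 include t = 0, leaving only two usable points
  non_mono <- res$series
  non_mono$volume_m3[10] <- non_mono$volume_m3[12]
  expect_error(darcy_fit(non_mono, st$area, st$dP, st$mu, st$w), class = "invalid_series")
})

test_that("Darcy fit recovers alpha within 10% (median) under 1% volume noise", {
  sc <- toy_scenario(Rm = 5e9)
  res <- simulate_filtration(sc, n_out = 50)
  st <- cakewash:::filtration_setup(sc)
  set.seed(7)
  errs <- replicate(100, {
    d <- res$series
    d$volume_m3 <- d$volume_m3 * (1 + 0.01 * rnorm(nrow(d)))
    fit <- suppressWarnings(
      darcy_fit(d, area = st$area, dP = st$dP, mu = st$mu, w = st$w, strict = FALSE)
    )
    abs(fit$alpha - res$alpha_used) / res$alpha_used
  })
  expect_lt(median(errs), 0.10)
})

test_that("negative fitted medium resistance is reported verbatim with a warning", {
  # synthesize a t/V vs V line with negative intercept (pre-settled cake)
  V <- seq(1e-6, 3e-5, length.out = 20)
  slope <- 2e6; intercept <- -5
  d <- tibble::tibble(
    time_s = (slope * V + intercept) * V * (1 + 1e-5 * sin(seq_along(V))),
    volume_m3 = V
  )
  expect_warning(
    fit <- darcy_fit(d, area = 5e-4, dP = 5e4, mu = 1e-3, w = 100),
    "negative"
  )
  expect_lt(fit$medium_resistance, 0)
  expect_true(fit$negative_rm)
  # but the forward model refuses a negative Rm
  expect_error(filter_spec(0.027, medium_resistance = -1e9), class = "invalid_argument")
})
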