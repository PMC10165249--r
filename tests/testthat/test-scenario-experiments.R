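test_that("temperature sensitivity is the two-point percent statistic", {
  expect_equal(temperature_sensitivity(5, 5, 30, 8), 0)
  expect_equal(temperature_sensitivity(5.95, 1.82, 30, 8), 10.32,
               tolerance = 1e-3)
  expect_equal(temperature_sensitivity(4.69, 2.80, 30, 8), 3.07,
               tolerance = 1e-3)
  ## ratio statistic: invariant to a uniform rescaling of the rates
  expect_equal(temperature_sensitivity(7 * 5.95, 7 * 1.82, 30, 8),
               temperature_sensitivity(5.95, 1.82, 30, 8))
  ## read in the cooling direction the statistic is positive too
  ## (rate loss per degree of cooling)
  expect_gt(temperature_sensitivity(1.82, 5.95, 8, 30), 0)
})

## a scenario so strongly reaction-saturated that the liquid boundary layer
## controls the flux: the external-film closed form is the oracle
film_limited_scenario <- function(L_LBL) {
  scenario(20, 30e-6, L_LBL, mode = "planar")
}
film_params <- kinetic_params(mu_max_AOO = 2.4, rho_X = 120000,
                              K_NH4 = 0.02)

test_that("limiting-range slope matches the boundary-layer film conductance", {
  ctrl <- list(n = 60)
  rules <- temperature_rules()
  res <- run_to_steady_state(film_limited_scenario(250e-6), film_params,
                             rules, ctrl)
  sl <- limiting_rate_slope(res)
  k_film <- water_diffusivity(rules$D_ref[["NH4"]], 20) / 250e-6
  expect_equal(sl$slope, k_film, tolerance = 0.05)
  expect_gt(sl$slope, 0)
  ## thicker boundary layer, smaller first-order coefficient
  res50 <- run_to_steady_state(film_limited_scenario(50e-6), film_params,
                               rules, ctrl)
  expect_gt(limiting_rate_slope(res50)$slope, sl$slope)
  expect_error(limiting_rate_slope(res, grid = c(0.1, 0.5)), "4 grid")
  expect_error(limiting_rate_slope(res, grid = rep(0.5, 5)), "degenerate")
})

test_that("diffusivity sensitivity separates film-controlled from kinetic regimes", {
  ctrl <- list(n = 60)
  rules <- temperature_rules()
  base <- run_to_steady_state(film_limited_scenario(250e-6), film_params,
                              rules, ctrl)
  ## film-controlled slope is proportional to D_NH4: relative sensitivity ~ 1
  s_film <- diffusivity_sensitivity(film_limited_scenario(250e-6),
                                    target = "NH4",
                                    response = "limiting_slope",
                                    params = film_params, rules = rules,
                                    control = ctrl, re_equilibrate = FALSE,
                                    base = base)
  expect_equal(s_film$sensitivity, 1, tolerance = 0.1)
  expect_equal(s_film$label, "high")

  ## kinetically limited film (thin, slow, O2-rich): rate independent of D
  p_kin <- kinetic_params(mu_max_AOO = 0.05, mu_max_NOO = 0.04, rho_X = 2000,
                          b_AOO = 0.005, b_NOO = 0.005)
  ## pure-oxygen lumen pins the O2 Monod term near 1 so the rate is set by
  ## kinetics, not by the D-dependent balance of supply and leakage
  sc_kin <- scenario(20, 15e-6, 30e-6, mode = "planar", gas_pO2 = 1)
  base_kin <- run_to_steady_state(sc_kin, p_kin, rules, ctrl)
  s_kin <- diffusivity_sensitivity(sc_kin, target = "O2",
                                   response = "rate_at_35",
                                   params = p_kin, rules = rules,
                                   control = ctrl, re_equilibrate = FALSE,
                                   base = base_kin)
  expect_lt(abs(s_kin$sensitivity), 0.05)
  expect_equal(s_kin$label, "low")
  expect_error(diffusivity_sensitivity(sc_kin, perturbation = 1.5),
               "perturbation")
})

test_that("sensitivity classification uses the published thresholds", {
  expect_equal(sensitivity_label(0.1), "low")
  expect_equal(sensitivity_label(0.35), "moderately high")
  expect_equal(sensitivity_label(0.7), "high")
})

test_that("a small simulation matrix is tidy and internally consistent", {
  m <- run_simulation_matrix(params = kinetic_params(),
                             rules = temperature_rules(),
                             temperatures = c(12, 25),
                             Lf = c(40e-6, 80e-6), L_LBL = 60e-6,
                             control = list(n = 40),
                             include_slopes = FALSE)
  expect_s3_class(m, "simulation_matrix")
  expect_equal(nrow(m$rates), 4)
  expect_true(all(m$rates$rate_35 >= 0))
  expect_equal(nrow(m$sensitivity), 2)
  ## warmer runs remove more ammonium in every geometry
  for (lf in unique(m$rates$Lf)) {
    r <- m$rates[m$rates$Lf == lf, ]
    expect_gt(r$rate_35[r$temperature == 25], r$rate_35[r$temperature == 12])
  }
  ## the sensitivity table agrees with the statistic applied to the rates
  r40 <- m$rates[m$rates$Lf == 40e-6, ]
  expect_equal(m$sensitivity$sens_rate_35[m$sensitivity$Lf == 40e-6],
               temperature_sensitivity(r40$rate_35[r40$temperature == 25],
                                       r40$rate_35[r40$temperature == 12],
                                       25, 12))
  expect_output(print(m), "Simulation matrix")
})

test_that("calibration with no free parameters reports errors unchanged", {
  targets <- data.frame(temperature = 20, Lf = 40e-6, L_LBL = 60e-6,
                        rate = 3)
  cal <- calibrate_to_matrix(targets, free = character(0),
                             control = list(n = 40))
  expect_s3_class(cal, "mabr_calibration")
  expect_equal(cal$params$mu_max_AOO, kinetic_params()$mu_max_AOO)
  expect_equal(cal$table$rel_error, cal$table$predicted / 3 - 1)
  expect_error(calibrate_to_matrix(targets, free = "K_NH4"), "subset")
})

test_that("calibration recovers a known growth rate from model-generated targets", {
  true_p <- kinetic_params(mu_max_AOO = 1.1)
  rules <- temperature_rules()
  ctrl <- list(n = 40)
  cells <- data.frame(temperature = c(10, 22), Lf = c(40e-6, 40e-6),
                      L_LBL = c(60e-6, 60e-6))
  cells$rate <- vapply(seq_len(nrow(cells)), function(i)
    run_to_steady_state(scenario(cells$temperature[i], cells$Lf[i],
                                 cells$L_LBL[i]),
                        true_p, rules, ctrl)$rate_NH4, numeric(1))
  cal <- calibrate_to_matrix(cells, free = "mu_max_AOO",
                             params = kinetic_params(mu_max_AOO = 0.7),
                             rules = rules, control = ctrl, maxit = 40)
  expect_equal(cal$params$mu_max_AOO, 1.1, tolerance = 0.05)
  expect_lt(max(abs(cal$table$rel_error)), 0.02)
})
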