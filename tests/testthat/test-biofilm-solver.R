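zero_eps <- function(n) matrix(0, n, 3, dimnames = list(NULL, guild_names()))

test_that("without biomass solutes equilibrate with the bulk and oxygen passes through", {
  g <- biofilm_geometry("planar", Lf = 100e-6, L_LBL = 100e-6)
  sol <- solve_solute_profiles(zero_eps(100), g, bulk_liquid(NH4 = 35),
                               membrane_boundary())
  ## no reaction, zero-flux wall: NH4 profile flat at the bulk value
  expect_equal(unname(range(sol$S[, "NH4"])), c(35, 35), tolerance = 1e-9)
  expect_lt(abs(sol$flux_liquid[["NH4"]]), 1e-8)
  ## oxygen enters at the membrane and leaves unconsumed at the liquid face
  expect_gt(sol$flux_membrane[["O2"]], 1)
  expect_equal(sol$flux_membrane[["O2"]], -sol$flux_liquid[["O2"]],
               tolerance = 1e-10)
})

test_that("a uniform zero-order sink reproduces the closed-form parabola", {
  ## independent oracle: D S'' = q with S(0) = S0, S(L) = SL has
  ## S(x) = S0 + (SL - S0 - q L^2 / (2 D)) x / L + q x^2 / (2 D)
  n <- 200; L <- 100e-6; D <- 1.4e-4; q <- 5e4; S0 <- 8; SL <- 2
  grid <- make_grid(biofilm_geometry("planar", Lf = L, L_LBL = 1e-6), n)
  reaction <- function(S) list(r = matrix(-q, n, 1), J = array(0, c(n, 1, 1)))
  sol <- rd_newton(matrix(5, n, 1), D, grid,
                   list(list(type = "dirichlet", value = S0)),
                   list(list(type = "dirichlet", value = SL)),
                   reaction)
  a <- (SL - S0 - q * L^2 / (2 * D)) / L
  exact <- S0 + a * grid$x + q * grid$x^2 / (2 * D)
  expect_lt(max(abs(sol$S[, 1] - exact) / abs(exact)), 1e-6)
  ## boundary fluxes match the derivative of the parabola
  expect_equal(sol$flux_left[[1]], -D * a, tolerance = 1e-8)
  expect_equal(sol$flux_right[[1]], D * (a + q * L / D), tolerance = 1e-8)
})

saturated_state <- function(g, n, eps_A = 1, eps_N = 0, eps_I = 0) {
  st <- biofilm_state(g, n, eps_AOO = eps_A, eps_NOO = eps_N, eps_I = eps_I)
  st$S <- matrix(rep(c(1e5, 1e5, 1e5, 0), each = n), n, 4,
                 dimnames = list(NULL, solute_names()))
  st
}

test_that("constant-thickness closure erodes growth exactly", {
  ## single guild filling the film, saturating substrates, negligible decay:
  ## everything grown is detached, so the biomass integral is unchanged
  g <- biofilm_geometry("planar", Lf = 50e-6, L_LBL = 50e-6)
  p <- kinetic_params(b_AOO = 1e-12, b_NOO = 1e-12)
  st <- saturated_state(g, 80)
  B0 <- sum(st$eps[, "AOO"])
  st2 <- advance_biomass(st, 0.5, p)
  expect_equal(sum(st2$eps[, "AOO"]), B0, tolerance = 1e-10)
  expect_true(all(st2$eps >= 0 & rowSums(st2$eps) <= 1 + 1e-12))
  ## detachment velocity equals the integrated growth velocity
  expect_equal(st2$u[g$Lf / st2$grid$dx + 1] / g$Lf, p$mu_max_AOO,
               tolerance = 1e-3)
})

test_that("equal net growth preserves guild proportions; a declining guild shrinks", {
  g <- biofilm_geometry("planar", Lf = 50e-6, L_LBL = 50e-6)
  p_eq <- kinetic_params(mu_max_AOO = 1, mu_max_NOO = 1,
                         b_AOO = 0.1, b_NOO = 0.1)
  ## uniform mixture: with equal local net growth the advection field moves
  ## both guilds identically, so the mixing ratio is preserved
  st <- saturated_state(g, 60, eps_A = 0.6, eps_N = 0.3)
  ratio0 <- st$eps[, "NOO"] / st$eps[, "AOO"]
  st2 <- advance_biomass(st, 1, p_eq)
  expect_equal(st2$eps[, "NOO"] / st2$eps[, "AOO"], ratio0, tolerance = 1e-4)

  ## starve the nitrite oxidisers (no NO2): their total strictly decreases
  st$S[, "NO2"] <- 0
  st3 <- advance_biomass(st, 1, p_eq)
  expect_lt(sum(st3$eps[, "NOO"]), sum(st$eps[, "NOO"]))
  expect_gt(sum(st3$eps[, "AOO"]), sum(st$eps[, "AOO"]))
})

test_that("advance_biomass validates its preconditions", {
  g <- biofilm_geometry("planar", Lf = 50e-6, L_LBL = 50e-6)
  st <- biofilm_state(g, 20)
  expect_error(advance_biomass(st, -1), "dt")
  expect_error(advance_biomass(st, 1), "profiles")
  expect_error(biofilm_state(g, 20, eps_AOO = 0.8, eps_NOO = 0.4), "sum")
})

## small, fast scenario shared by the steady-state property tests
fast_ctrl <- list(n = 60)
fast_scenario <- function(mode = "cylindrical", Lf = 50e-6, L_LBL = 50e-6,
                          temperature = 20, ...) {
  scenario(temperature, Lf, L_LBL, mode = mode, ...)
}

test_that("steady state conserves every solute and the nitrogen budget", {
  res <- run_to_steady_state(fast_scenario(), control = fast_ctrl)
  expect_lt(max(abs(res$conservation$solute_imbalance)), 1e-6)
  expect_lt(abs(res$conservation$N_balance_rel), 1e-4)
  expect_gt(res$rate_NH4, 0)
})

test_that("trivial scenarios remove nothing", {
  p_frozen <- kinetic_params(b_AOO = 1e-9, b_NOO = 1e-9)
  res0 <- run_to_steady_state(fast_scenario(bulk_NH4 = 0), p_frozen,
                              control = fast_ctrl)
  expect_equal(res0$rate_NH4, 0, tolerance = 1e-6)
  res_anox <- run_to_steady_state(fast_scenario(gas_pO2 = 0),
                                  control = fast_ctrl)
  expect_equal(res_anox$rate_NH4, 0, tolerance = 1e-6)
})

test_that("cylindrical solution approaches the planar one for a huge fibre", {
  ctrl <- list(n = 60)
  res_pl <- run_to_steady_state(fast_scenario(mode = "planar"),
                                control = ctrl)
  res_cy <- run_to_steady_state(
    fast_scenario(membrane_outer_radius = 1), control = ctrl)
  expect_lt(abs(res_cy$rate_NH4 - res_pl$rate_NH4) / res_pl$rate_NH4, 0.01)
})

test_that("grid refinement changes fluxes by less than half a percent", {
  res_c <- run_to_steady_state(fast_scenario(), control = list(n = 50))
  res_f <- run_to_steady_state(fast_scenario(), control = list(n = 100))
  expect_lt(abs(res_f$rate_NH4 - res_c$rate_NH4) / res_c$rate_NH4, 0.005)
})

test_that("removal rate is monotone in bulk ammonium and in lumen oxygen", {
  res <- run_to_steady_state(fast_scenario(), control = fast_ctrl)
  rates <- vapply(c(0, 2, 10, 35, 60), function(cb)
    evaluate_rate_at_bulk(res, cb), numeric(1))
  ## not exactly zero at zero bulk ammonium: decay releases i_N ammonium,
  ## a little of which escapes to the bulk (ammonification)
  expect_lt(abs(rates[1]), 0.01)
  expect_true(all(diff(rates) > -1e-10))
  res_lowO2 <- run_to_steady_state(
    fast_scenario(gas_pO2 = 0.5 * 0.21 * 1.248), control = fast_ctrl)
  expect_lt(res_lowO2$rate_NH4, res$rate_NH4)
})

test_that("the steady state does not depend on the starting composition", {
  sc <- fast_scenario(temperature = 25)
  res1 <- run_to_steady_state(sc, control = fast_ctrl)
  st0 <- biofilm_state(scenario_geometry(sc), 60,
                       eps_AOO = 0.05, eps_NOO = 0.45)
  res2 <- run_to_steady_state(sc, control = c(fast_ctrl, list(state0 = st0)))
  expect_equal(res2$rate_NH4, res1$rate_NH4, tolerance = 0.01)
})

test_that("membrane-area referencing applies the cylindrical area ratio", {
  mk <- function(mode, Lf) {
    structure(list(scenario = scenario(20, Lf, 50e-6, mode = mode),
                   flux_liquid = c(O2 = 0, NH4 = 2, NO2 = -1, NO3 = -1)),
              class = "biofilm_steady_state")
  }
  expect_equal(membrane_area_flux(mk("planar", 150e-6), "NH4"), 2)
  expect_equal(membrane_area_flux(mk("cylindrical", 150e-6), "NH4"),
               2 * 425 / 275)
  ## ratio tends to 1 as the film thins
  expect_equal(membrane_area_flux(mk("cylindrical", 1e-9), "NH4"), 2,
               tolerance = 1e-5)
  expect_error(membrane_area_flux(mk("planar", 1e-6), "XYZ"), "unknown")
})
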