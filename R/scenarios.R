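#' Simulation scenario
#'
#' One combination of temperature, biofilm thickness, boundary-layer
#' thickness and bulk composition to run to steady state.
#'
#' @param temperature degC.
#' @param Lf Biofilm thickness, m.
#' @param L_LBL Liquid boundary layer thickness, m.
#' @param bulk_NH4 Bulk ammonium, g N/m3 (35 = non-limiting evaluation point).
#' @param mode Geometry mode, `"cylindrical"` or `"planar"`.
#' @param gas_pO2 Lumen O2 partial pressure, bar.
#' @param membrane_outer_radius Fibre outer radius, m.
#' @return Object of class `"scenario"`.
#' @export
scenario <- function(temperature, Lf, L_LBL, bulk_NH4 = 35,
                     mode = c("cylindrical", "planar"),
                     gas_pO2 = 0.21 * (1.013 + 0.235),
                     membrane_outer_radius = 275e-6) {
  mode <- match.arg(mode)
  if (bulk_NH4 < 0)
    stop("scenario: `bulk_NH4` must be >= 0", call. = FALSE)
  sc <- list(temperature = temperature, Lf = Lf, L_LBL = L_LBL,
             bulk_NH4 = bulk_NH4, mode = mode, gas_pO2 = gas_pO2,
             membrane_outer_radius = membrane_outer_radius)
  ## geometry constructor validates Lf / L_LBL / radius
  scenario_geometry(sc)
  structure(sc, class = "scenario")
}

scenario_geometry <- function(sc) {
  biofilm_geometry(mode = sc$mode, Lf = sc$Lf, L_LBL = sc$L_LBL,
                   membrane_outer_radius = sc$membrane_outer_radius)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario: %g degC, Lf %g um, LBL %g um, bulk NH4 %g g/m3 (%s)\n",
              x$temperature, x$Lf * 1e6, x$L_LBL * 1e6, x$bulk_NH4, x$mode))
  invisible(x)
}

#' Ammonium removal rate at a given bulk concentration
#'
#' Re-solves the solute profiles with the biomass distribution frozen at a
#' scenario's steady state and the bulk ammonium replaced, and returns the
#' membrane-area-referenced NH4-N removal rate.  This is how rates are
#' evaluated both at the non-limiting point (35 g/m3) and across the
#' limiting range.
#'
#' @param result A `"biofilm_steady_state"` from [run_to_steady_state()].
#' @param bulk_NH4 Bulk ammonium concentration, g N/m3.
#' @return Removal rate, g N/(m2 membrane d).
#' @export
evaluate_rate_at_bulk <- function(result, bulk_NH4) {
  if (bulk_NH4 < 0)
    stop("evaluate_rate_at_bulk: `bulk_NH4` must be >= 0", call. = FALSE)
  sc <- result$scenario
  geometry <- scenario_geometry(sc)
  bulk <- bulk_liquid(NH4 = bulk_NH4, temperature = sc$temperature)
  membrane <- membrane_boundary(sc$gas_pO2)
  S_init <- result$state$S
  S_init[, "NH4"] <- pmin(S_init[, "NH4"], bulk_NH4 + 1e-9)
  sol <- solve_solute_profiles(result$state$eps, geometry, bulk, membrane,
                               result$params, result$rules,
                               S_init = S_init,
                               control = result$diagnostics$control,
                               decay_o2_limited = result$decay_o2_limited)
  sol$flux_liquid[["NH4"]] * liquid_to_membrane_area(geometry)
}

#' Rate-versus-concentration slope in the substrate-limited range
#'
#' Ordinary least-squares slope of the steady removal rate against bulk
#' ammonium over a grid spanning the strongly donor-limited range
#' (default 0.1-1.0 g N/m3, 10 points), with the biomass distribution fixed
#' at the scenario's steady state.  In this range the rate is nearly first
#' order in the bulk concentration and the slope is the first-order rate
#' coefficient (units (g N m-2 d-1)/(g N m-3) = m/d referenced to membrane
#' area).
#'
#' @param result A `"biofilm_steady_state"`.
#' @param grid Bulk NH4 values, g N/m3; at least 4 points.
#' @return List with `slope`, `intercept`, and the `rates` data frame.
#' @export
limiting_rate_slope <- function(result, grid = seq(0.1, 1.0, length.out = 10)) {
  if (length(grid) < 4)
    stop("limiting_rate_slope: need at least 4 grid points", call. = FALSE)
  if (stats::sd(grid) == 0)
    stop("limiting_rate_slope: degenerate concentration grid", call. = FALSE)
  rates <- vapply(grid, function(cb) evaluate_rate_at_bulk(result, cb),
                  numeric(1))
  fit <- stats::lm(rates ~ grid)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rates = data.frame(bulk_NH4 = grid, rate = rates))
}

#' Percent rate change per degree Celsius
#'
#' The two-point temperature-sensitivity statistic
#' \eqn{100 \, (R_{T1} - R_{T0}) / R_{T0} / (T_1 - T_0)} used to compare
#' reactor rates measured or simulated at two temperatures.
#'
#' @param R_hi,R_lo Rates at the higher and lower temperature (same units;
#'   `R_lo > 0`).
#' @param T_hi,T_lo Temperatures, degC (`T_hi != T_lo`).
#' @return Sensitivity in percent per degC.
#' @examples
#' temperature_sensitivity(5.95, 1.82, 30, 8)  # about 10.3 %/degC
#' @export
temperature_sensitivity <- function(R_hi, R_lo, T_hi, T_lo) {
  if (any(R_lo <= 0))
    stop("temperature_sensitivity: `R_lo` must be > 0", call. = FALSE)
  if (any(T_hi == T_lo))
    stop("temperature_sensitivity: temperatures must differ", call. = FALSE)
  100 * (R_hi - R_lo) / R_lo / (T_hi - T_lo)
}

#' @rdname temperature_sensitivity
#' @export
percent_per_degree <- temperature_sensitivity

#' Local sensitivity of the model response to a diffusivity constant
#'
#' Central relative sensitivity
#' \eqn{[R(+\delta) - R(-\delta)] / (2 \delta R(0))} of a model response to a
#' +/- fractional perturbation of the aqueous diffusivity of oxygen or
#' ammonium.  By default the biomass distribution is re-equilibrated (a fresh
#' steady state is computed) at each perturbed diffusivity;
#' `re_equilibrate = FALSE` keeps the unperturbed steady-state biomass and
#' only re-solves the solute profiles.
#'
#' Classification thresholds used in reporting: below 0.200 low, above 0.200
#' moderately high, above 0.600 high.
#'
#' @param scen A [scenario()].
#' @param target `"O2"` or `"NH4"`: which diffusivity to perturb.
#' @param perturbation Fractional perturbation in (0, 1); default 0.25.
#' @param response `"rate_at_35"` (removal rate at the scenario's bulk
#'   ammonium) or `"limiting_slope"` (see [limiting_rate_slope()]).
#' @param params,rules,control Passed to [run_to_steady_state()].
#' @param re_equilibrate Logical; see Details.
#' @param base Optional precomputed unperturbed `"biofilm_steady_state"`.
#' @return List with `sensitivity`, `label`, the three response values and
#'   the perturbation used.
#' @export
diffusivity_sensitivity <- function(scen, target = c("O2", "NH4"),
                                    perturbation = 0.25,
                                    response = c("rate_at_35",
                                                 "limiting_slope"),
                                    params = kinetic_params(),
                                    rules = temperature_rules(),
                                    control = list(),
                                    re_equilibrate = TRUE,
                                    base = NULL) {
  target <- match.arg(target)
  response <- match.arg(response)
  if (perturbation <= 0 || perturbation >= 1)
    stop("diffusivity_sensitivity: `perturbation` must lie in (0, 1)",
         call. = FALSE)
  respond <- function(res) {
    if (response == "rate_at_35") evaluate_rate_at_bulk(res, res$scenario$bulk_NH4)
    else limiting_rate_slope(res)$slope
  }
  if (is.null(base))
    base <- run_to_steady_state(scen, params, rules, control)
  R0 <- respond(base)
  if (abs(R0) < 1e-12)
    stop("diffusivity_sensitivity: unperturbed response is zero; relative ",
         "sensitivity undefined", call. = FALSE)
  perturbed <- function(sgn) {
    rules_p <- rules
    rules_p$D_ref[[target]] <- rules$D_ref[[target]] *
      (1 + sgn * perturbation)
    if (re_equilibrate) {
      res_p <- run_to_steady_state(scen, params, rules_p, control)
    } else {
      res_p <- base
      res_p$rules <- rules_p
    }
    respond(res_p)
  }
  Rp <- perturbed(+1)
  Rm <- perturbed(-1)
  sens <- (Rp - Rm) / (2 * perturbation * R0)
  list(sensitivity = sens,
       label = sensitivity_label(sens),
       R0 = R0, R_plus = Rp, R_minus = Rm,
       target = target, response = response, perturbation = perturbation)
}

sensitivity_label <- function(s) {
  a <- abs(s)
  if (a > 0.600) "high" else if (a > 0.200) "moderately high" else "low"
}

#' Run the full temperature x geometry simulation matrix
#'
#' Runs every combination of the supplied temperatures, biofilm thicknesses
#' and boundary-layer thicknesses to steady state (default: the 8-scenario
#' matrix 8/30 degC x 50/150 um x 50/250 um), evaluates the removal rate at
#' the non-limiting bulk ammonium and the limiting-range slope, and computes
#' the percent-per-degC temperature sensitivity of both responses for each
#' (Lf, LBL) pair.
#'
#' @param params,rules Kinetic parameters and temperature rules.
#' @param temperatures,Lf,L_LBL Vectors defining the matrix, degC and m.
#' @param bulk_NH4 Non-limiting evaluation concentration, g N/m3.
#' @param mode Geometry mode.
#' @param control Solver control, see [run_to_steady_state()].
#' @param include_slopes Compute limiting-range slopes too (default TRUE).
#' @param keep_results Keep the full steady-state objects (default FALSE).
#' @return Object of class `"simulation_matrix"`: list with `rates` (one row
#'   per scenario), `sensitivity` (percent per degC per (Lf, LBL) pair and
#'   response) and optionally `results`.
#' @export
run_simulation_matrix <- function(params = calibrated_params(),
                                  rules = calibrated_rules(),
                                  temperatures = c(8, 30),
                                  Lf = c(50e-6, 150e-6),
                                  L_LBL = c(50e-6, 250e-6),
                                  bulk_NH4 = 35,
                                  mode = "cylindrical",
                                  control = list(),
                                  include_slopes = TRUE,
                                  keep_results = FALSE) {
  cells <- expand.grid(temperature = temperatures, Lf = Lf, L_LBL = L_LBL,
                       KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sc <- scenario(cells$temperature[i], cells$Lf[i], cells$L_LBL[i],
                   bulk_NH4 = bulk_NH4, mode = mode)
    res <- tryCatch(run_to_steady_state(sc, params, rules, control),
                    error = function(e)
                      stop(sprintf("scenario (T=%g, Lf=%g um, LBL=%g um) failed: %s",
                                   cells$temperature[i], cells$Lf[i] * 1e6,
                                   cells$L_LBL[i] * 1e6, conditionMessage(e)),
                           call. = FALSE))
    slope <- if (include_slopes) limiting_rate_slope(res)$slope else NA_real_
    rows[[i]] <- data.frame(temperature = cells$temperature[i],
                            Lf = cells$Lf[i], L_LBL = cells$L_LBL[i],
                            rate_35 = res$rate_NH4,
                            limiting_slope = slope,
                            t_steady = res$diagnostics$t_end)
    if (keep_results) results[[i]] <- res
  }
  rates <- do.call(rbind, rows)
  sens <- matrix_sensitivity(rates)
  structure(list(rates = rates, sensitivity = sens,
                 results = if (keep_results) results,
                 bulk_NH4 = bulk_NH4),
            class = "simulation_matrix")
}

## percent-per-degC per (Lf, LBL) pair for both responses, plus means per Lf
matrix_sensitivity <- function(rates) {
  Ts <- sort(unique(rates$temperature))
  if (length(Ts) != 2) return(NULL)
  pairs <- unique(rates[, c("Lf", "L_LBL")])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- rates$Lf == pairs$Lf[i] & rates$L_LBL == pairs$L_LBL[i]
    lo <- rates[sel & rates$temperature == Ts[1], ]
    hi <- rates[sel & rates$temperature == Ts[2], ]
    data.frame(Lf = pairs$Lf[i], L_LBL = pairs$L_LBL[i],
               sens_rate_35 = temperature_sensitivity(hi$rate_35, lo$rate_35,
                                                      Ts[2], Ts[1]),
               sens_limiting = if (all(is.finite(c(hi$limiting_slope,
                                                   lo$limiting_slope))))
                 temperature_sensitivity(hi$limiting_slope,
                                         lo$limiting_slope, Ts[2], Ts[1])
               else NA_real_)
  })
  do.call(rbind, out)
}

#' @export
print.simulation_matrix <- function(x, digits = 2, ...) {
  cat("Simulation matrix: NH4-N removal at", x$bulk_NH4, "g/m3 bulk\n")
  r <- x$rates
  r$Lf <- r$Lf * 1e6; r$L_LBL <- r$L_LBL * 1e6
  names(r)[1:3] <- c("T_degC", "Lf_um", "LBL_um")
  r$rate_35 <- round(r$rate_35, digits)
  r$limiting_slope <- signif(r$limiting_slope, 3)
  print(r, row.names = FALSE)
  if (!is.null(x$sensitivity)) {
    cat("\nTemperature sensitivity (% per degC):\n")
    s <- x$sensitivity
    s$Lf <- s$Lf * 1e6; s$L_LBL <- s$L_LBL * 1e6
    names(s)[1:2] <- c("Lf_um", "LBL_um")
    s$sens_rate_35 <- round(s$sens_rate_35, 1)
    s$sens_limiting <- round(s$sens_limiting, 1)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Calibrate the kinetic parameter set against a rate matrix
#'
#' Bounded least-squares fit of selected kinetic/transport parameters so that
#' the steady-state model reproduces a table of target removal rates (one row
#' per scenario).  The objective is the sum of squared relative errors over
#' the table; optimisation is `L-BFGS-B` on log-transformed parameters.
#'
#' @param targets Data frame with columns `temperature` (degC), `Lf` (m),
#'   `L_LBL` (m) and `rate` (g N m-2 d-1).
#' @param free Character vector naming the free parameters, a subset of
#'   `mu_max_AOO`, `mu_max_NOO`, `rho_X`, `biofilm_diffusivity_ratio`.  An
#'   empty set returns the input parameters with their error report.
#' @param bounds Named list of `c(lower, upper)` per free parameter; defaults
#'   span conventional literature ranges.
#' @param params,rules Starting parameter set and temperature rules.
#' @param bulk_NH4 Evaluation concentration, g N/m3.
#' @param mode Geometry mode.
#' @param control Solver control (use a coarser grid to speed up fits).
#' @param maxit Maximum optimiser iterations.
#' @return Object of class `"mabr_calibration"`: list with fitted `params`,
#'   `rules`, the per-cell predictions and relative errors, and the `optim`
#'   diagnostics.
#' @export
calibrate_to_matrix <- function(targets,
                                free = c("mu_max_AOO", "mu_max_NOO",
                                         "rho_X",
                                         "biofilm_diffusivity_ratio"),
                                bounds = NULL,
                                params = kinetic_params(),
                                rules = temperature_rules(),
                                bulk_NH4 = 35,
                                mode = "cylindrical",
                                control = list(),
                                maxit = 60) {
  stopifnot(all(c("temperature", "Lf", "L_LBL", "rate") %in% names(targets)))
  allowed <- c("mu_max_AOO", "mu_max_NOO", "rho_X",
               "biofilm_diffusivity_ratio")
  if (!all(free %in% allowed))
    stop("calibrate_to_matrix: free parameters must be a subset of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  default_bounds <- list(mu_max_AOO = c(0.2, 2.5),
                         mu_max_NOO = c(0.2, 2.0),
                         rho_X = c(10000, 120000),
                         biofilm_diffusivity_ratio = c(0.3, 1.0))
  bounds <- utils::modifyList(default_bounds, bounds %||% list())

  apply_free <- function(theta) {
    v <- exp(theta)
    p <- params; r <- rules
    for (nm in names(v)) {
      if (nm == "biofilm_diffusivity_ratio") r[[nm]] <- v[[nm]]
      else p[[nm]] <- v[[nm]]
    }
    list(params = p, rules = r)
  }
  predict_rates <- function(p, r) {
    vapply(seq_len(nrow(targets)), function(i) {
      sc <- scenario(targets$temperature[i], targets$Lf[i],
                     targets$L_LBL[i], bulk_NH4 = bulk_NH4, mode = mode)
      run_to_steady_state(sc, p, r, control)$rate_NH4
    }, numeric(1))
  }
  report <- function(p, r, opt = NULL) {
    pred <- predict_rates(p, r)
    rel <- (pred - targets$rate) / targets$rate
    structure(list(params = p, rules = r,
                   table = cbind(targets,
                                 predicted = pred, rel_error = rel),
                   free = free, optim = opt),
              class = "mabr_calibration")
  }
  if (length(free) == 0) return(report(params, rules))

  start <- vapply(free, function(nm)
    if (nm == "biofilm_diffusivity_ratio") rules[[nm]] else params[[nm]],
    numeric(1))
  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
  obj <- function(theta) {
    names(theta) <- free
    pr <- apply_free(theta)
    pred <- tryCatch(predict_rates(pr$params, pr$rules),
                     error = function(e) rep(NA_real_, nrow(targets)))
    if (any(!is.finite(pred))) return(1e6)
    sum(((pred - targets$rate) / targets$rate)^2)
  }
  opt <- stats::optim(log(start), obj, method = "L-BFGS-B",
                      lower = log(lower), upper = log(upper),
                      control = list(maxit = maxit, factr = 1e10))
  names(opt$par) <- free
  at_bound <- opt$par <= log(lower) + 1e-8 | opt$par >= log(upper) - 1e-8
  if (any(at_bound))
    warning("calibrate_to_matrix: parameter(s) at bound: ",
            paste(free[at_bound], collapse = ", "), call. = FALSE)
  pr <- apply_free(opt$par)
  report(pr$params, pr$rules, opt)
}

#' @export
print.mabr_calibration <- function(x, ...) {
  cat("Calibration of", if (length(x$free)) paste(x$free, collapse = ", ")
      else "(no free parameters)", "\n")
  tb <- x$table
  tb$Lf <- tb$Lf * 1e6; tb$L_LBL <- tb$L_LBL * 1e6
  names(tb)[names(tb) %in% c("Lf", "L_LBL")] <- c("Lf_um", "LBL_um")
  tb$predicted <- round(tb$predicted, 3)
  tb$rel_error <- round(tb$rel_error, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("max |relative error| = %.1f%%\n",
              100 * max(abs(x$table$rel_error))))
  invisible(x)
}
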