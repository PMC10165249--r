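## Biomass dynamics: Wanner-Gujer mixed-culture 1D biofilm with
## growth-induced advection and a constant-thickness detachment closure
## (surface erosion velocity equal to the biofilm growth velocity).

#' Initial biofilm state
#'
#' Builds a biofilm state on a uniform grid: biomass volume fractions per
#' guild (AOO, NOO, inerts) at the cell centres and solute profiles (set on
#' the first solute solve).  The default start is an unbiased mixed film,
#' 15 percent of the volume each for AOO and NOO.
#'
#' @param geometry A [biofilm_geometry()].
#' @param n Number of grid cells.
#' @param eps_AOO,eps_NOO,eps_I Initial uniform volume fractions.
#' @return Object of class `"biofilm_state"`: list with `grid`, `geometry`,
#'   `eps` (n x 3), `S` (n x 4, may be `NULL` before the first solve), `u`
#'   (advection velocity at faces, m/d) and elapsed time `t` (d).
#' @export
biofilm_state <- function(geometry, n = 100,
                          eps_AOO = 0.15, eps_NOO = 0.15, eps_I = 0) {
  eps <- cbind(AOO = rep(eps_AOO, n), NOO = rep(eps_NOO, n),
               I = rep(eps_I, n))
  if (any(eps < 0) || any(rowSums(eps) > 1))
    stop("biofilm_state: volume fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  structure(list(grid = make_grid(geometry, n), geometry = geometry,
                 eps = eps, S = NULL, u = rep(0, n + 1), t = 0),
            class = "biofilm_state")
}

## Local specific rates (1/d) from current solute profiles.
local_specific_rates <- function(S, params, pT, decay_o2_limited = TRUE) {
  mO2A <- monod(S[, "O2"], params$K_O2_AOO)
  mO2N <- monod(S[, "O2"], params$K_O2_NOO)
  list(mu_A = pT$mu_AOO * monod(S[, "NH4"], params$K_NH4) * mO2A,
       mu_N = pT$mu_NOO * monod(S[, "NO2"], params$K_NO2) * mO2N *
         monod(S[, "NH4"], 0.01),
       b_A = pT$b_AOO * (if (decay_o2_limited) mO2A else 1),
       b_N = pT$b_NOO * (if (decay_o2_limited) mO2N else 1))
}

#' Advance the biomass profiles over a time step
#'
#' Explicit first-order-upwind update of the guild volume fractions under the
#' Wanner-Gujer formulation: local net production plus advection with the
#' growth-induced velocity \eqn{u(x) = \int_0^x \sum_k \sigma_k \, dz}.  The
#' biofilm surface is eroded at exactly `u(Lf)` (when positive), which keeps
#' the thickness constant.  The specific growth/decay rate fields are frozen
#' at the state's current solute profiles for the duration of the step; the
#' step is internally sub-stepped to respect the advective CFL condition and
#' the fastest local rate.
#'
#' @param state A `"biofilm_state"` whose `S` profiles are current.
#' @param dt Time step, d (> 0).
#' @param params,rules Kinetic parameters and temperature rules.
#' @param temperature Temperature, degC.
#' @param decay_o2_limited See [process_rates()].
#' @return The updated state (time advanced by `dt`).
#' @export
advance_biomass <- function(state, dt, params = kinetic_params(),
                            rules = temperature_rules(),
                            temperature = params$T_ref,
                            decay_o2_limited = TRUE) {
  if (!is.numeric(dt) || dt <= 0)
    stop("advance_biomass: `dt` must be > 0", call. = FALSE)
  if (is.null(state$S))
    stop("advance_biomass: solute profiles are not current; run ",
         "solve_solute_profiles() first", call. = FALSE)
  g <- state$grid
  pT <- params_at_temperature(params, rules, temperature)
  rates <- local_specific_rates(state$S, params, pT, decay_o2_limited)
  eps <- state$eps
  n <- g$n; dx <- g$dx
  rf <- g$r_face; rc <- g$r
  rate_scale <- max(abs(rates$mu_A - rates$b_A),
                    abs(rates$mu_N - rates$b_N), 1e-9)
  remaining <- dt
  u_face <- state$u
  while (remaining > 1e-12) {
    sigA <- (rates$mu_A - rates$b_A) * eps[, "AOO"]
    sigN <- (rates$mu_N - rates$b_N) * eps[, "NOO"]
    sigI <- params$f_I * (rates$b_A * eps[, "AOO"] + rates$b_N * eps[, "NOO"])
    v <- sigA + sigN + sigI
    ## growth-induced velocity at the faces (cylindrical: (1/r) d(ru)/dr = v)
    u_face <- c(0, cumsum(v * rc * dx)) / rf
    dt_sub <- min(remaining,
                  0.5 * dx / max(abs(u_face), 1e-12),
                  0.2 / rate_scale)
    eps <- eps + dt_sub * (cbind(AOO = sigA, NOO = sigN, I = sigI) -
                             advection_term(eps, u_face, g))
    eps[eps < 0] <- 0
    remaining <- remaining - dt_sub
  }
  state$eps <- eps
  state$u <- u_face
  state$t <- state$t + dt
  state
}

## Upwind divergence of (u * eps) per guild; zero-flux at the membrane face,
## free outflow (detachment) at the surface face.
advection_term <- function(eps, u_face, g) {
  n <- g$n; dx <- g$dx; rf <- g$r_face; rc <- g$r
  out <- 0 * eps
  for (k in seq_len(ncol(eps))) {
    e <- eps[, k]
    ## face values by upwinding (face j sits between cells j-1 and j)
    fv <- numeric(n + 1)
    up <- u_face[2:n] >= 0
    fv[2:n] <- ifelse(up, e[1:(n - 1)], e[2:n]) * u_face[2:n]
    fv[n + 1] <- if (u_face[n + 1] >= 0) u_face[n + 1] * e[n] else 0
    out[, k] <- (rf[2:(n + 1)] * fv[2:(n + 1)] - rf[1:n] * fv[1:n]) /
      (rc * dx)
  }
  out
}

#' Run a biofilm scenario to steady state
#'
#' Alternates quasi-steady solute solves with biomass advances until the
#' depth-integrated biomass of every guild and the membrane-referenced
#' ammonium removal rate stop changing (relative change below `tol_ss` over a
#' probe window of `probe` days).
#'
#' @param scenario A [scenario()] (temperature, geometry, bulk composition).
#' @param params,rules Kinetic parameters and temperature rules.
#' @param control List of settings: `n` grid cells (100), `dt0` initial
#'   macro step in d (0.25), `dt_max` (1), `tol_ss` (1e-4), `probe` window in
#'   d (5), `max_time` in d (3000), `tol` solute residual (1e-8),
#'   `decay_o2_limited` (TRUE), `state0` optional warm-start state.
#' @return Object of class `"biofilm_steady_state"`; see
#'   [membrane_area_flux()], [summary.biofilm_steady_state()].
#' @export
run_to_steady_state <- function(scenario, params = kinetic_params(),
                                rules = temperature_rules(),
                                control = list()) {
  n <- control$n %||% 100
  dt0 <- control$dt0 %||% 0.25
  dt_max <- control$dt_max %||% 1
  tol_ss <- control$tol_ss %||% 1e-4
  probe <- control$probe %||% 5
  max_time <- control$max_time %||% 3000
  decay_o2 <- control$decay_o2_limited %||% TRUE
  sol_ctrl <- list(tol = control$tol %||% 1e-8, maxit = control$maxit %||% 80)

  geometry <- scenario_geometry(scenario)
  bulk <- bulk_liquid(NH4 = scenario$bulk_NH4, temperature = scenario$temperature)
  membrane <- membrane_boundary(scenario$gas_pO2)
  state <- control$state0 %||% biofilm_state(geometry, n)
  dt <- dt0
  hist <- list(t = numeric(0), rate = numeric(0), B = NULL)
  area_ratio <- liquid_to_membrane_area(geometry)
  converged <- FALSE
  S_warm <- state$S
  sol <- NULL
  while (state$t < max_time) {
    sol <- solve_solute_profiles(state$eps, geometry, bulk, membrane,
                                 params, rules, S_init = S_warm, n = n,
                                 control = sol_ctrl,
                                 decay_o2_limited = decay_o2)
    state$S <- sol$S
    S_warm <- sol$S
    rate <- sol$flux_liquid[["NH4"]] * area_ratio
    B <- colSums(state$eps * state$grid$r * state$grid$dx)
    hist$t <- c(hist$t, state$t)
    hist$rate <- c(hist$rate, rate)
    hist$B <- rbind(hist$B, B)
    i_ref <- which(hist$t <= state$t - probe)
    if (length(i_ref) && state$t >= 2 * probe) {
      i0 <- max(i_ref)
      dB <- abs(hist$B[nrow(hist$B), ] - hist$B[i0, ]) /
        pmax(hist$B[i0, ], 1e-12)
      drate <- abs(rate - hist$rate[i0]) / max(abs(hist$rate[i0]), 1e-12)
      if (max(dB, drate) < tol_ss) { converged <- TRUE; break }
    }
    state <- advance_biomass(state, dt, params, rules,
                             temperature = scenario$temperature,
                             decay_o2_limited = decay_o2)
    dt <- min(dt * 1.2, dt_max)
  }
  if (!converged)
    stop(sprintf(paste0("run_to_steady_state: no steady state within %g ",
                        "simulated days (last rate %.4g g N/m2/d); ",
                        "trajectory attached"), max_time,
                 utils::tail(hist$rate, 1)),
         call. = FALSE)
  conv <- conservation_checks(sol, state, params, rules, scenario, decay_o2)
  structure(list(state = state, scenario = scenario,
                 params = params, rules = rules,
                 flux_membrane = sol$flux_membrane,
                 flux_liquid = sol$flux_liquid,
                 rate_NH4 = sol$flux_liquid[["NH4"]] * area_ratio,
                 Csat = sol$Csat,
                 conservation = conv,
                 diagnostics = list(t_end = state$t,
                                    iterations = sol$iterations,
                                    residual = sol$residual,
                                    history = hist,
                                    control = control),
                 decay_o2_limited = decay_o2),
            class = "biofilm_steady_state")
}

## ratio of liquid-face area to membrane-face area
liquid_to_membrane_area <- function(geometry) {
  if (geometry$mode == "cylindrical")
    (geometry$membrane_outer_radius + geometry$Lf) /
      geometry$membrane_outer_radius
  else 1
}

#' Membrane-area-referenced boundary flux
#'
#' Rescales the liquid-face flux of a solute to the membrane outer surface
#' area, the reference area for reactor rates (cylindrical: multiply by
#' `(R_m + Lf)/R_m`; planar: identity).  Removal rates are positive into the
#' biofilm.
#'
#' @param result A `"biofilm_steady_state"`.
#' @param solute One of `"O2"`, `"NH4"`, `"NO2"`, `"NO3"`.
#' @return Flux in g/(m2 membrane d).
#' @export
membrane_area_flux <- function(result, solute = "NH4") {
  if (!solute %in% solute_names())
    stop("membrane_area_flux: unknown solute `", solute, "`", call. = FALSE)
  result$flux_liquid[[solute]] *
    liquid_to_membrane_area(scenario_geometry(result$scenario))
}

## Per-solute conservation and biofilm nitrogen balance at steady state.
## All terms are expressed per unit membrane area, g/(m2 d).
conservation_checks <- function(sol, state, params, rules, scenario,
                                decay_o2_limited = TRUE) {
  g <- state$grid
  geometry <- scenario_geometry(scenario)
  pT <- params_at_temperature(params, rules, scenario$temperature)
  rx <- solute_reaction(sol$S, state$eps * params$rho_X, pT, params,
                        decay_o2_limited)
  Rm <- if (g$mode == "cylindrical") g$R0 else 1
  conv_int <- colSums(rx$r * g$r * g$dx) / Rm       # per membrane area
  fm <- sol$flux_membrane
  fl <- sol$flux_liquid * liquid_to_membrane_area(geometry)
  imbalance <- fm + fl + conv_int
  ## floor the per-solute scale at a fraction of the largest flux so inactive
  ## solutes (near-zero turnover) do not report spurious relative imbalance
  scale <- pmax(abs(fm), abs(fl), abs(conv_int),
                1e-6 * max(abs(fm), abs(fl), abs(conv_int)), 1e-9)
  ## nitrogen: NH4 in = NO2 out + NO3 out + N removed in detached biomass
  u_det <- max(state$u[g$n + 1], 0)
  det_N <- u_det * params$rho_X * sum(state$eps[g$n, ]) * params$i_N *
    liquid_to_membrane_area(geometry)
  N_in <- fl[["NH4"]]
  N_out <- -fl[["NO2"]] - fl[["NO3"]] + det_N
  list(solute_imbalance = imbalance / scale,
       N_balance_rel = (N_in - N_out) / max(abs(N_in), 1e-9),
       detached_N = det_N)
}

#' @export
print.biofilm_steady_state <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Steady-state biofilm (%s): T = %g degC, Lf = %g um, LBL = %g um, bulk NH4 = %g g/m3\n",
              sc$mode, sc$temperature, sc$Lf * 1e6, sc$L_LBL * 1e6,
              sc$bulk_NH4))
  cat(sprintf("  NH4 removal rate: %.3f g N/m2(membrane)/d\n", x$rate_NH4))
  cat(sprintf("  reached at t = %.0f d; max solute imbalance %.2g; N balance %.2g\n",
              x$diagnostics$t_end, max(abs(x$conservation$solute_imbalance)),
              abs(x$conservation$N_balance_rel)))
  invisible(x)
}

#' Summary of a steady-state biofilm solution
#'
#' @param object A `"biofilm_steady_state"`.
#' @param ... Unused.
#' @return A list with the scenario, rates, per-solute boundary fluxes,
#'   depth-integrated biomass fractions and conservation diagnostics,
#'   printed in a readable layout.
#' @export
summary.biofilm_steady_state <- function(object, ...) {
  g <- object$state$grid
  B <- colSums(object$state$eps * g$r * g$dx) / sum(g$r * g$dx)
  out <- list(scenario = object$scenario,
              rate_NH4 = object$rate_NH4,
              flux_membrane = object$flux_membrane,
              flux_liquid = object$flux_liquid,
              mean_volume_fractions = B,
              conservation = object$conservation,
              t_end = object$diagnostics$t_end)
  class(out) <- "summary.biofilm_steady_state"
  out
}

#' @export
print.summary.biofilm_steady_state <- function(x, ...) {
  print(structure(list(scenario = x$scenario, rate_NH4 = x$rate_NH4,
                       diagnostics = list(t_end = x$t_end),
                       conservation = x$conservation),
                  class = "biofilm_steady_state"))
  cat("  mean volume fractions:",
      paste(sprintf("%s %.3f", names(x$mean_volume_fractions),
                    x$mean_volume_fractions), collapse = ", "), "\n")
  cat("  membrane-face fluxes (g/m2/d):",
      paste(sprintf("%s %.3g", names(x$flux_membrane), x$flux_membrane),
            collapse = ", "), "\n")
  cat("  liquid-face fluxes (g/m2/d):",
      paste(sprintf("%s %.3g", names(x$flux_liquid), x$flux_liquid),
            collapse = ", "), "\n")
  invisible(x)
}

#' Plot solute and biomass depth profiles of a steady state
#'
#' Two panels: solute concentrations and biomass volume fractions against
#' depth from the membrane face.
#'
#' @param x A `"biofilm_steady_state"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.biofilm_steady_state <- function(x, ...) {
  g <- x$state$grid
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(g$x * 1e6, x$state$S, type = "l", lty = 1,
                    xlab = "depth from membrane (um)",
                    ylab = "concentration (g/m3)", main = "solutes", ...)
  graphics::legend("topright", legend = solute_names(), col = 1:4, lty = 1,
                   bty = "n", cex = 0.8)
  graphics::matplot(g$x * 1e6, x$state$eps, type = "l", lty = 1,
                    xlab = "depth from membrane (um)",
                    ylab = "volume fraction", main = "biomass",
                    ylim = c(0, 1))
  graphics::legend("topright", legend = guild_names(), col = 1:3, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
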