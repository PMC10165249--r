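#' Kinetic and stoichiometric parameters of two-step nitrification
#'
#' Constructs the parameter set describing growth, decay and stoichiometry of
#' the two nitrifier guilds: ammonia oxidisers (AOO), which oxidise NH4+ to
#' NO2-, and nitrite oxidisers (NOO), which oxidise NO2- to NO3-.  All rate
#' parameters refer to the reference temperature `T_ref`; temperature
#' correction is applied separately through a [temperature_rules()] object.
#'
#' Package-wide unit system: lengths in m, time in d, solutes in g/m3
#' (equivalently mg/L), biomass in g COD/m3, temperatures in degrees Celsius.
#'
#' The defaults are conventional activated-sludge-model nitrification values
#' at 20 degC.  [calibrated_params()] returns the variant tuned so that the
#' biofilm model reproduces published membrane-aerated reactor rates.
#'
#' @param mu_max_AOO,mu_max_NOO Maximum specific growth rates at `T_ref`, 1/d.
#' @param K_NH4 Ammonium half-saturation of AOO growth, g N/m3.
#' @param K_NO2 Nitrite half-saturation of NOO growth, g N/m3.
#' @param K_O2_AOO,K_O2_NOO Oxygen half-saturations, g O2/m3.
#' @param Y_AOO,Y_NOO Yields, g COD biomass per g N oxidised.  Must satisfy
#'   `Y_AOO < 3.43` and `Y_NOO < 1.14` so the oxygen stoichiometry stays
#'   negative (oxygen is consumed).
#' @param b_AOO,b_NOO Decay coefficients at `T_ref`, 1/d.
#' @param i_N Nitrogen content of biomass, g N per g COD.
#' @param f_I Inert particulate fraction produced on decay, dimensionless.
#' @param rho_X Total biofilm biomass density, g COD/m3 of biofilm.
#' @param T_ref Reference temperature, degC.
#' @return An object of class `"kinetic_params"` (a named list).
#' @seealso [temperature_rules()], [stoichiometry_matrix()], [process_rates()]
#' @examples
#' p <- kinetic_params()
#' p$mu_max_AOO
#' @export
kinetic_params <- function(mu_max_AOO = 0.9,
                           mu_max_NOO = 0.7,
                           K_NH4 = 1.0,
                           K_NO2 = 0.5,
                           K_O2_AOO = 0.5,
                           K_O2_NOO = 0.68,
                           Y_AOO = 0.15,
                           Y_NOO = 0.041,
                           b_AOO = 0.05,
                           b_NOO = 0.05,
                           i_N = 0.07,
                           f_I = 0.1,
                           rho_X = 50000,
                           T_ref = 20) {
  p <- list(mu_max_AOO = mu_max_AOO, mu_max_NOO = mu_max_NOO,
            K_NH4 = K_NH4, K_NO2 = K_NO2,
            K_O2_AOO = K_O2_AOO, K_O2_NOO = K_O2_NOO,
            Y_AOO = Y_AOO, Y_NOO = Y_NOO,
            b_AOO = b_AOO, b_NOO = b_NOO,
            i_N = i_N, f_I = f_I, rho_X = rho_X, T_ref = T_ref)
  validate_kinetic_params(p)
  class(p) <- "kinetic_params"
  p
}

validate_kinetic_params <- function(p) {
  pos <- c("mu_max_AOO", "mu_max_NOO", "K_NH4", "K_NO2", "K_O2_AOO",
           "K_O2_NOO", "Y_AOO", "Y_NOO", "b_AOO", "b_NOO", "i_N", "rho_X")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("kinetic_params: `", nm, "` must be a single positive number",
           call. = FALSE)
  }
  if (p$f_I < 0 || p$f_I >= 1)
    stop("kinetic_params: `f_I` must lie in [0, 1)", call. = FALSE)
  if (p$Y_AOO >= 3.43)
    stop("kinetic_params: `Y_AOO` must be < 3.43 g COD/g N ",
         "(oxygen demand of ammonia oxidation must stay positive)",
         call. = FALSE)
  if (p$Y_NOO >= 1.14)
    stop("kinetic_params: `Y_NOO` must be < 1.14 g COD/g N ",
         "(oxygen demand of nitrite oxidation must stay positive)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-step nitrification kinetic parameters (T_ref =",
      x$T_ref, "degC)\n")
  cat(sprintf("  AOO: mu_max %.3f 1/d, K_NH4 %.2f g N/m3, K_O2 %.2f g/m3, Y %.3f, b %.3f 1/d\n",
              x$mu_max_AOO, x$K_NH4, x$K_O2_AOO, x$Y_AOO, x$b_AOO))
  cat(sprintf("  NOO: mu_max %.3f 1/d, K_NO2 %.2f g N/m3, K_O2 %.2f g/m3, Y %.3f, b %.3f 1/d\n",
              x$mu_max_NOO, x$K_NO2, x$K_O2_NOO, x$Y_NOO, x$b_NOO))
  cat(sprintf("  i_N %.3f g N/g COD, f_I %.2f, rho_X %g g COD/m3\n",
              x$i_N, x$f_I, x$rho_X))
  invisible(x)
}

#' Temperature-correction laws for kinetics and transport
#'
#' Collects every temperature-sensitive parameter of the biofilm model and the
#' law correcting it: Arrhenius-type bases (theta) for growth and decay rates,
#' a van't Hoff law for the Henry's-law oxygen solubility, Stokes-Einstein
#' viscosity scaling for aqueous diffusivities, and an Arrhenius activation
#' energy for the membrane oxygen permeance.
#'
#' @param theta_mu_AOO,theta_mu_NOO Arrhenius base per degC for the maximum
#'   growth rates (dimensionless; around 1.0-1.15 for nitrifiers).
#' @param theta_b Arrhenius base for the decay coefficients.
#' @param henry_ref Oxygen solubility at `T_ref`, g O2/m3 per bar of O2
#'   partial pressure.
#' @param henry_vant_hoff_K van't Hoff temperature coefficient, K.
#' @param D_ref Named vector of aqueous diffusivities at `T_ref`, m2/d, for
#'   solutes `O2`, `NH4`, `NO2`, `NO3`.
#' @param biofilm_diffusivity_ratio In-biofilm to aqueous diffusivity ratio,
#'   dimensionless, in (0, 1].
#' @param perm_ref Membrane oxygen permeance at `T_ref`, m/d (flux per unit
#'   dissolved-concentration driving force).  The default is an effective
#'   module-scale value for dense PDMS hollow-fibre bundles; the ideal-wall
#'   estimate from bulk PDMS permeability (~10 m/d for a 135 um wall) is an
#'   upper bound that neglects lumen-side depletion along the fibre and
#'   contact resistances.
#' @param perm_activation_energy Activation energy of the permeance, J/mol.
#' @param T_ref Reference temperature, degC.
#' @return An object of class `"temperature_rules"`.
#' @seealso [arrhenius_correct()], [oxygen_saturation()],
#'   [water_diffusivity()], [membrane_permeance()]
#' @export
temperature_rules <- function(theta_mu_AOO = 1.095,
                              theta_mu_NOO = 1.06,
                              theta_b = 1.04,
                              henry_ref = 42.8,
                              henry_vant_hoff_K = 1700,
                              D_ref = c(O2 = 1.98e-9, NH4 = 1.8e-9,
                                        NO2 = 1.7e-9, NO3 = 1.7e-9) * 86400,
                              biofilm_diffusivity_ratio = 0.8,
                              perm_ref = 3.2,
                              perm_activation_energy = 8400,
                              T_ref = 20) {
  if (any(c(theta_mu_AOO, theta_mu_NOO, theta_b) <= 0))
    stop("temperature_rules: Arrhenius bases theta must be > 0", call. = FALSE)
  if (henry_ref <= 0 || perm_ref <= 0)
    stop("temperature_rules: `henry_ref` and `perm_ref` must be > 0",
         call. = FALSE)
  if (biofilm_diffusivity_ratio <= 0 || biofilm_diffusivity_ratio > 1)
    stop("temperature_rules: `biofilm_diffusivity_ratio` must lie in (0, 1]",
         call. = FALSE)
  D_ref <- D_ref[solute_names()]
  if (any(is.na(D_ref)) || any(D_ref <= 0))
    stop("temperature_rules: `D_ref` must give a positive diffusivity for ",
         "each of ", paste(solute_names(), collapse = ", "), call. = FALSE)
  r <- list(theta_mu_AOO = theta_mu_AOO, theta_mu_NOO = theta_mu_NOO,
            theta_b = theta_b, henry_ref = henry_ref,
            henry_vant_hoff_K = henry_vant_hoff_K, D_ref = D_ref,
            biofilm_diffusivity_ratio = biofilm_diffusivity_ratio,
            perm_ref = perm_ref,
            perm_activation_energy = perm_activation_energy, T_ref = T_ref)
  class(r) <- "temperature_rules"
  r
}

#' @export
print.temperature_rules <- function(x, ...) {
  cat("Temperature-correction rules (T_ref =", x$T_ref, "degC)\n")
  cat(sprintf("  theta: mu_AOO %.3f, mu_NOO %.3f, b %.3f per degC\n",
              x$theta_mu_AOO, x$theta_mu_NOO, x$theta_b))
  cat(sprintf("  Henry: %.1f g O2/m3/bar, van't Hoff %g K\n",
              x$henry_ref, x$henry_vant_hoff_K))
  cat("  D_ref (m2/d):",
      paste(sprintf("%s %.3g", names(x$D_ref), x$D_ref), collapse = ", "),
      "\n")
  cat(sprintf("  biofilm/aqueous D ratio %.2f; permeance %.2f m/d (Ea %g J/mol)\n",
              x$biofilm_diffusivity_ratio, x$perm_ref,
              x$perm_activation_energy))
  invisible(x)
}

solute_names <- function() c("O2", "NH4", "NO2", "NO3")
guild_names  <- function() c("AOO", "NOO", "I")
process_names <- function() c("growth_AOO", "growth_NOO",
                              "decay_AOO", "decay_NOO")

#' Stoichiometry matrix of the two-step nitrification model
#'
#' Gujer-style matrix: one row per process (AOO growth, NOO growth, AOO decay,
#' NOO decay), one column per component (S_O2, S_NH4, S_NO2, S_NO3, X_AOO,
#' X_NOO, X_I), in units of g of the component per g COD of process turnover.
#' Growth of either guild uses ammonium as nitrogen source (`i_N` per unit
#' biomass); decay routes a fraction `f_I` of the biomass to inert particulates
#' and oxidises the remainder, releasing the associated nitrogen as ammonium.
#' Nitrogen is conserved exactly in every row (biomass nitrogen counted at
#' `i_N`).
#'
#' @param params A [kinetic_params()] object.
#' @return Numeric matrix with processes as rows, components as columns.
#' @examples
#' S <- stoichiometry_matrix(kinetic_params())
#' ## nitrogen closes in every process row
#' nu_N <- S[, "S_NH4"] + S[, "S_NO2"] + S[, "S_NO3"] +
#'   kinetic_params()$i_N * (S[, "X_AOO"] + S[, "X_NOO"] + S[, "X_I"])
#' stopifnot(max(abs(nu_N)) < 1e-12)
#' @export
stoichiometry_matrix <- function(params = kinetic_params()) {
  p <- params
  m <- rbind(
    growth_AOO = c(S_O2 = -(3.43 - p$Y_AOO) / p$Y_AOO,
                   S_NH4 = -1 / p$Y_AOO - p$i_N,
                   S_NO2 = 1 / p$Y_AOO, S_NO3 = 0,
                   X_AOO = 1, X_NOO = 0, X_I = 0),
    growth_NOO = c(S_O2 = -(1.14 - p$Y_NOO) / p$Y_NOO,
                   S_NH4 = -p$i_N,
                   S_NO2 = -1 / p$Y_NOO, S_NO3 = 1 / p$Y_NOO,
                   X_AOO = 0, X_NOO = 1, X_I = 0),
    decay_AOO = c(S_O2 = -(1 - p$f_I), S_NH4 = p$i_N * (1 - p$f_I),
                  S_NO2 = 0, S_NO3 = 0,
                  X_AOO = -1, X_NOO = 0, X_I = p$f_I),
    decay_NOO = c(S_O2 = -(1 - p$f_I), S_NH4 = p$i_N * (1 - p$f_I),
                  S_NO2 = 0, S_NO3 = 0,
                  X_AOO = 0, X_NOO = -1, X_I = p$f_I))
  m
}
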