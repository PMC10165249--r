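#' Arrhenius-type temperature correction of a rate
#'
#' Applies the empirical law \eqn{R(T) = R(T_{ref}) \cdot \theta^{T - T_{ref}}}
#' used throughout wastewater engineering to move a rate parameter between
#' temperatures.
#'
#' @param value_ref Value at the reference temperature (strictly positive).
#' @param T Target temperature, degC.
#' @param T_ref Reference temperature, degC.
#' @param theta Arrhenius base per degC (strictly positive; 1 means no
#'   temperature dependence).
#' @return The corrected value `value_ref * theta^(T - T_ref)`.
#' @examples
#' arrhenius_correct(1, T = 30, T_ref = 20, theta = 1.026)  # 1.026^10
#' @export
arrhenius_correct <- function(value_ref, T, T_ref, theta) {
  if (!is.numeric(value_ref) || any(value_ref <= 0))
    stop("arrhenius_correct: `value_ref` must be positive", call. = FALSE)
  if (!is.numeric(theta) || any(theta <= 0))
    stop("arrhenius_correct: `theta` must be positive", call. = FALSE)
  value_ref * theta^(T - T_ref)
}

celsius_to_kelvin <- function(T) T + 273.15

#' Dissolved-oxygen saturation concentration
#'
#' Henry's-law equilibrium concentration of oxygen in water at a given
#' temperature and O2 partial pressure, with the solubility coefficient
#' corrected by a van't Hoff law:
#' \eqn{C^*(T) = p_{O2} \, H_{ref} \exp[K_{vH} (1/T_K - 1/T_{ref,K})]}.
#' Solubility decreases with temperature for `henry_vant_hoff_K > 0`.
#'
#' @param T Temperature, degC, within \[-5, 50\].
#' @param pO2 Oxygen partial pressure, bar (>= 0).
#' @param rules A [temperature_rules()] object.
#' @return Saturation concentration, g O2/m3.
#' @examples
#' oxygen_saturation(20, 0.2095 * 1.01325)  # about 9.1 g/m3
#' @export
oxygen_saturation <- function(T, pO2, rules = temperature_rules()) {
  if (any(T < -5) || any(T > 50))
    stop("oxygen_saturation: temperature outside the validity range ",
         "[-5, 50] degC", call. = FALSE)
  if (any(pO2 < 0))
    stop("oxygen_saturation: `pO2` must be >= 0", call. = FALSE)
  TK <- celsius_to_kelvin(T)
  TrefK <- celsius_to_kelvin(rules$T_ref)
  pO2 * rules$henry_ref * exp(rules$henry_vant_hoff_K * (1 / TK - 1 / TrefK))
}

#' Dynamic viscosity of water
#'
#' Vogel correlation \eqn{\eta(T) = 0.02939 \exp[507.88 / (T_K - 149.3)]}
#' in mPa s; accurate to well under 1 percent over 0-40 degC.
#'
#' @param T Temperature, degC.
#' @return Viscosity, mPa s.
#' @keywords internal
water_viscosity <- function(T) {
  0.02939 * exp(507.88 / (celsius_to_kelvin(T) - 149.3))
}

#' Temperature correction of an aqueous diffusivity
#'
#' Stokes-Einstein scaling
#' \eqn{D(T) = D_{ref} \, (T_K/T_{ref,K}) \, \eta(T_{ref})/\eta(T)} with the
#' Vogel water-viscosity correlation; strictly increasing in temperature.
#' Over 8-30 degC the implied per-degC factor is about 1.029.
#'
#' @param D_ref Diffusivity at `T_ref`, m2/d (any positive scale; the law is
#'   multiplicative).
#' @param T Temperature, degC.
#' @param T_ref Reference temperature, degC.
#' @return Corrected diffusivity in the units of `D_ref`.
#' @export
water_diffusivity <- function(D_ref, T, T_ref = 20) {
  if (any(D_ref <= 0))
    stop("water_diffusivity: `D_ref` must be positive", call. = FALSE)
  D_ref * (celsius_to_kelvin(T) / celsius_to_kelvin(T_ref)) *
    (water_viscosity(T_ref) / water_viscosity(T))
}

#' Temperature correction of the membrane oxygen permeance
#'
#' Arrhenius law
#' \eqn{P(T) = P_{ref} \exp[-(E_a/R)(1/T_K - 1/T_{ref,K})]}; increasing in
#' temperature for a positive activation energy.
#'
#' @param T Temperature, degC.
#' @param rules A [temperature_rules()] object supplying `perm_ref`,
#'   `perm_activation_energy` and `T_ref`.
#' @return Permeance, m/d.
#' @export
membrane_permeance <- function(T, rules = temperature_rules()) {
  R_gas <- 8.314
  TK <- celsius_to_kelvin(T)
  TrefK <- celsius_to_kelvin(rules$T_ref)
  rules$perm_ref *
    exp(-(rules$perm_activation_energy / R_gas) * (1 / TK - 1 / TrefK))
}

## All temperature-sensitive model parameters evaluated at one temperature.
## Central place so the solver, the scenario engine and the generator agree.
params_at_temperature <- function(params, rules, T) {
  list(
    T = T,
    mu_AOO = arrhenius_correct(params$mu_max_AOO, T, params$T_ref,
                               rules$theta_mu_AOO),
    mu_NOO = arrhenius_correct(params$mu_max_NOO, T, params$T_ref,
                               rules$theta_mu_NOO),
    b_AOO = arrhenius_correct(params$b_AOO, T, params$T_ref, rules$theta_b),
    b_NOO = arrhenius_correct(params$b_NOO, T, params$T_ref, rules$theta_b),
    D_w = water_diffusivity(rules$D_ref, T, rules$T_ref),
    D_f = rules$biofilm_diffusivity_ratio *
      water_diffusivity(rules$D_ref, T, rules$T_ref),
    perm = membrane_permeance(T, rules)
  )
}

monod <- function(S, K) {
  S <- pmax(S, 0)
  S / (K + S)
}

## derivative consistent with the clipped monod() (zero below S = 0)
dmonod <- function(S, K) {
  ifelse(S > 0, K / (K + S)^2, 0)
}

#' Process turnover rates of the nitrification model
#'
#' Evaluates the four process rates (AOO growth, NOO growth, AOO decay, NOO
#' decay) at given solute and biomass concentrations.  Growth follows double
#' Monod kinetics in the electron donor and oxygen; nitrite-oxidiser growth
#' additionally carries a weak ammonium limitation term (half-saturation 0.01
#' g N/m3) because ammonium is its nitrogen source.  Decay is first order in
#' biomass and, by default, limited by the same oxygen Monod term as growth so
#' that endogenous respiration cannot consume oxygen that is not there.
#'
#' @param S Named numeric vector (or matrix with named columns) of solute
#'   concentrations `O2`, `NH4`, `NO2`, `NO3`, g/m3.
#' @param X Named numeric vector (or matrix) of biomass concentrations `AOO`,
#'   `NOO`, `I`, g COD/m3.
#' @param params A [kinetic_params()] object.
#' @param T Temperature, degC (defaults to the reference temperature).
#' @param rules A [temperature_rules()] object.
#' @param decay_o2_limited Logical; if `FALSE`, decay is plain `b * X`.
#' @return Matrix (rows = states, columns = processes) of turnover rates in
#'   g COD/(m3 d); a named vector for single-state input.
#' @export
process_rates <- function(S, X, params = kinetic_params(),
                          T = params$T_ref, rules = temperature_rules(),
                          decay_o2_limited = TRUE) {
  single <- is.null(dim(S))
  S <- rbind_state(S, solute_names())
  X <- rbind_state(X, guild_names())
  if (any(S < 0))
    stop("process_rates: negative solute concentration", call. = FALSE)
  if (any(X < 0))
    stop("process_rates: negative biomass concentration", call. = FALSE)
  pT <- params_at_temperature(params, rules, T)
  mO2A <- monod(S[, "O2"], params$K_O2_AOO)
  mO2N <- monod(S[, "O2"], params$K_O2_NOO)
  mNH4 <- monod(S[, "NH4"], params$K_NH4)
  mNO2 <- monod(S[, "NO2"], params$K_NO2)
  mNsrc <- monod(S[, "NH4"], 0.01)
  dA <- if (decay_o2_limited) mO2A else 1
  dN <- if (decay_o2_limited) mO2N else 1
  r <- cbind(growth_AOO = pT$mu_AOO * mNH4 * mO2A * X[, "AOO"],
             growth_NOO = pT$mu_NOO * mNO2 * mO2N * mNsrc * X[, "NOO"],
             decay_AOO = pT$b_AOO * dA * X[, "AOO"],
             decay_NOO = pT$b_NOO * dN * X[, "NOO"])
  if (single) r[1, ] else r
}

rbind_state <- function(v, want) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
  if (is.null(colnames(v)) && ncol(v) == length(want)) colnames(v) <- want
  missing <- setdiff(want, colnames(v))
  if (length(missing))
    stop("missing components: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v[, want, drop = FALSE]
}

#' Net volumetric conversion rates per component
#'
#' Matrix product of [process_rates()] with the [stoichiometry_matrix()]:
#' the net rate of change of each solute and particulate component, in
#' g/(m3 d).  Nitrogen is conserved to machine precision by construction.
#'
#' @inheritParams process_rates
#' @return Named vector (or matrix) over components `S_O2`, `S_NH4`, `S_NO2`,
#'   `S_NO3`, `X_AOO`, `X_NOO`, `X_I`.
#' @export
net_conversion_rates <- function(S, X, params = kinetic_params(),
                                 T = params$T_ref,
                                 rules = temperature_rules(),
                                 decay_o2_limited = TRUE) {
  single <- is.null(dim(S))
  r <- process_rates(S, X, params, T, rules, decay_o2_limited)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1, dimnames = list(NULL, names(r)))
  out <- r %*% stoichiometry_matrix(params)
  if (single) out[1, ] else out
}
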