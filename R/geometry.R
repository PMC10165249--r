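#' Biofilm geometry
#'
#' Describes the one-dimensional biofilm domain.  The membrane face sits at
#' depth 0 (cylindrical mode: at the fibre outer radius) and the biofilm-bulk
#' interface at depth `Lf`.  A stagnant liquid boundary layer of thickness
#' `L_LBL` separates the biofilm surface from the completely mixed bulk.
#'
#' Defaults follow a PDMS hollow-fibre membrane with 550 um outer and 280 um
#' inner diameter (outer radius 275 um, wall 135 um).
#'
#' @param mode `"cylindrical"` (biofilm grown around a fibre; default) or
#'   `"planar"`.
#' @param Lf Biofilm thickness, m.
#' @param L_LBL Liquid boundary layer thickness, m.
#' @param membrane_outer_radius Fibre outer radius, m (cylindrical mode).
#' @param membrane_wall Membrane wall thickness, m (metadata only; the wall
#'   resistance is already folded into the permeance).
#' @return An object of class `"biofilm_geometry"`.
#' @export
biofilm_geometry <- function(mode = c("cylindrical", "planar"),
                             Lf,
                             L_LBL,
                             membrane_outer_radius = 275e-6,
                             membrane_wall = 135e-6) {
  mode <- match.arg(mode)
  if (!is.numeric(Lf) || Lf <= 0)
    stop("biofilm_geometry: `Lf` must be > 0", call. = FALSE)
  if (!is.numeric(L_LBL) || L_LBL <= 0)
    stop("biofilm_geometry: `L_LBL` must be > 0", call. = FALSE)
  if (mode == "cylindrical" &&
      (!is.numeric(membrane_outer_radius) || membrane_outer_radius <= 0))
    stop("biofilm_geometry: cylindrical mode requires ",
         "`membrane_outer_radius` > 0", call. = FALSE)
  structure(list(mode = mode, Lf = Lf, L_LBL = L_LBL,
                 membrane_outer_radius = membrane_outer_radius,
                 membrane_wall = membrane_wall),
            class = "biofilm_geometry")
}

#' @export
print.biofilm_geometry <- function(x, ...) {
  cat(sprintf("%s biofilm: Lf = %g um, LBL = %g um",
              x$mode, x$Lf * 1e6, x$L_LBL * 1e6))
  if (x$mode == "cylindrical")
    cat(sprintf(", fibre outer radius = %g um", x$membrane_outer_radius * 1e6))
  cat("\n")
  invisible(x)
}

#' Membrane-side gas boundary
#'
#' The biofilm base is connected to a completely mixed gas compartment through
#' the membrane, modelled as a diffusive link with permeance
#' [membrane_permeance()].  The default partial pressure corresponds to air at
#' 235 mbar gauge: 0.21 x (1.013 + 0.235) bar.
#'
#' @param gas_pO2 Oxygen partial pressure in the gas lumen, bar.
#' @return Object of class `"membrane_boundary"`.
#' @export
membrane_boundary <- function(gas_pO2 = 0.21 * (1.013 + 0.235)) {
  if (!is.numeric(gas_pO2) || gas_pO2 < 0)
    stop("membrane_boundary: `gas_pO2` must be >= 0", call. = FALSE)
  structure(list(gas_pO2 = gas_pO2), class = "membrane_boundary")
}

#' Bulk liquid state
#'
#' Completely mixed bulk composition and temperature seen by the biofilm
#' through the liquid boundary layer.
#'
#' @param NH4,NO2,NO3,O2 Bulk concentrations, g/m3.
#' @param temperature Bulk temperature, degC.
#' @return Object of class `"bulk_liquid"`.
#' @export
bulk_liquid <- function(NH4 = 35, NO2 = 0, NO3 = 0, O2 = 0,
                        temperature = 20) {
  S <- c(O2 = O2, NH4 = NH4, NO2 = NO2, NO3 = NO3)
  if (any(S < 0))
    stop("bulk_liquid: concentrations must be >= 0", call. = FALSE)
  structure(list(S_bulk = S, temperature = temperature),
            class = "bulk_liquid")
}

## Uniform finite-volume grid over the biofilm depth.
## Depth x runs from the membrane face (0) to the liquid face (Lf);
## cylindrical radius r = R0 + x.
make_grid <- function(geometry, n = 100) {
  dx <- geometry$Lf / n
  x <- (seq_len(n) - 0.5) * dx
  R0 <- if (geometry$mode == "cylindrical") geometry$membrane_outer_radius else NA
  list(n = n, dx = dx, x = x,
       mode = geometry$mode, R0 = R0,
       r = if (geometry$mode == "cylindrical") R0 + x else rep(1, n),
       r_face = if (geometry$mode == "cylindrical")
         R0 + c(0, seq_len(n)) * dx else rep(1, n + 1))
}
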