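## Finite-volume reaction-diffusion solver for the biofilm depth profiles.
##
## Discretisation: uniform finite volumes over [0, Lf] (membrane face at 0),
## second-order central differences inside, quadratic face extrapolation for
## the boundary conditions, so linear and parabolic exact solutions are
## reproduced to machine precision.  Cylindrical mode weighs faces and cell
## volumes by radius.  The coupled nonlinear system (Monod reactions couple
## the solutes) is solved by damped Newton iteration on the full block system
## with an analytic reaction Jacobian.

## Boundary-face flux coefficients: inward flux F = a0 + a1*S_near + a2*S_next
## (per unit face area), where S_near/S_next are the two cells adjacent to the
## face.  `type` is "flux0", "dirichlet" (value = face concentration) or
## "robin" (k = external conductance m/d, value = external concentration).
face_coefs <- function(type, D, dx, k = NULL, value = NULL) {
  switch(type,
    flux0 = c(a0 = 0, a1 = 0, a2 = 0),
    dirichlet = c(a0 = 8 * D * value / (3 * dx),
                  a1 = -3 * D / dx,
                  a2 = D / (3 * dx)),
    robin = {
      denom <- k + 8 * D / (3 * dx)
      c(a0 = k * value * (8 * D / (3 * dx)) / denom,
        a1 = -k * 3 * D / (dx * denom),
        a2 = k * D / (3 * dx * denom))
    },
    stop("unknown boundary type: ", type, call. = FALSE))
}

## Assemble the constant linear part of the residual for one solute:
## res = M %*% S + cst + reaction.  Returns triplets and constant vector.
rd_linear_part <- function(grid, D, bcL, bcR) {
  n <- grid$n; dx <- grid$dx
  rf <- grid$r_face; rc <- grid$r
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  cst <- numeric(n)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  ## interior faces f = i+1/2 between cells i and i+1 (face index i+1 in rf)
  for (i in seq_len(n - 1)) {
    w <- rf[i + 1] * D / dx           # transfer coefficient at the face
    add(i, i + 1, w / (rc[i] * dx));   add(i, i, -w / (rc[i] * dx))
    add(i + 1, i, w / (rc[i + 1] * dx)); add(i + 1, i + 1, -w / (rc[i + 1] * dx))
  }
  cl <- face_coefs(bcL$type, D, dx, bcL$k, bcL$value)
  wl <- rf[1] / (rc[1] * dx)
  cst[1] <- cst[1] + wl * cl[["a0"]]
  add(1, 1, wl * cl[["a1"]]); add(1, 2, wl * cl[["a2"]])
  cr <- face_coefs(bcR$type, D, dx, bcR$k, bcR$value)
  wr <- rf[n + 1] / (rc[n] * dx)
  cst[n] <- cst[n] + wr * cr[["a0"]]
  add(n, n, wr * cr[["a1"]]); add(n, n - 1, wr * cr[["a2"]])
  list(i = ii, j = jj, x = xx, cst = cst, coefL = cl, coefR = cr)
}

## Inward boundary fluxes (per unit face area) for a converged profile.
boundary_fluxes <- function(S, lin) {
  n <- nrow(S)
  FL <- FR <- numeric(ncol(S))
  for (s in seq_len(ncol(S))) {
    cl <- lin[[s]]$coefL; cr <- lin[[s]]$coefR
    FL[s] <- cl[["a0"]] + cl[["a1"]] * S[1, s] + cl[["a2"]] * S[2, s]
    FR[s] <- cr[["a0"]] + cr[["a1"]] * S[n, s] + cr[["a2"]] * S[n - 1, s]
  }
  names(FL) <- names(FR) <- colnames(S)
  list(left = FL, right = FR)
}

## Damped Newton solve of the coupled reaction-diffusion system.
## S0: n x m initial guess; D: length-m diffusivities; bc_left/bc_right:
## per-solute lists (type/k/value); reaction(S) -> list(r = n x m rates,
## J = n x m x m Jacobian d r_s / d S_s').
rd_newton <- function(S0, D, grid, bc_left, bc_right, reaction,
                      tol = 1e-8, maxit = 80, neg_tol = 1e-6) {
  n <- grid$n; m <- ncol(S0)
  D <- unname(D)
  bc_left <- lapply(bc_left, lapply, unname)
  bc_right <- lapply(bc_right, lapply, unname)
  lin <- vector("list", m)
  ii <- jj <- xx <- list()
  cst <- numeric(n * m)
  for (s in seq_len(m)) {
    lp <- rd_linear_part(grid, D[s], bc_left[[s]], bc_right[[s]])
    off <- (s - 1L) * n
    ii[[s]] <- lp$i + off; jj[[s]] <- lp$j + off; xx[[s]] <- lp$x
    cst[off + seq_len(n)] <- lp$cst
    lin[[s]] <- lp
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n * m, n * m))
  ## per-solute residual scales for the relative convergence test
  sc_ext <- vapply(seq_len(m), function(s) {
    v <- c(bc_left[[s]]$value, bc_right[[s]]$value, abs(S0[, s]))
    max(abs(v), 1e-3)
  }, numeric(1))
  scale_s <- D / grid$dx^2 * sc_ext
  scale_vec <- rep(scale_s, each = n)

  S <- S0
  resid_of <- function(S) {
    rx <- reaction(S)
    list(F = as.numeric(A %*% as.numeric(S)) + cst + as.numeric(rx$r),
         rx = rx)
  }
  cur <- resid_of(S)
  fnorm <- function(F) max(abs(F) / scale_vec)
  f0 <- fnorm(cur$F)
  it <- 0L
  while (f0 > tol && it < maxit) {
    it <- it + 1L
    J <- A
    if (!is.null(cur$rx$J)) {
      tri <- reaction_jac_triplets(cur$rx$J, n, m)
      if (length(tri$x))
        J <- J + Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                                      dims = c(n * m, n * m))
    }
    step <- tryCatch(as.numeric(Matrix::solve(J, -cur$F)),
                     error = function(e) NULL)
    if (is.null(step))
      stop("solute solver: singular Jacobian at iteration ", it,
           call. = FALSE)
    lambda <- 1
    repeat {
      S_try <- S + lambda * matrix(step, n, m)
      nxt <- resid_of(S_try)
      if (fnorm(nxt$F) <= (1 - 0.25 * lambda) * f0 || lambda <= 1 / 256)
        break
      lambda <- lambda / 2
    }
    S <- S_try; cur <- nxt; f0 <- fnorm(cur$F)
  }
  if (f0 > tol) {
    ## pseudo-transient continuation: regularise the Newton system with a
    ## diagonal 1/tau term (implicit Euler towards steady state) and grow tau
    ## as the iteration stabilises; rescues sharp-front cases where plain
    ## damped Newton stalls
    tau <- 1e-7
    for (pt in seq_len(300)) {
      if (f0 <= tol) break
      J <- A
      if (!is.null(cur$rx$J)) {
        tri <- reaction_jac_triplets(cur$rx$J, n, m)
        if (length(tri$x))
          J <- J + Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                                        dims = c(n * m, n * m))
      }
      J <- J - Matrix::Diagonal(n * m, 1 / tau)
      step <- tryCatch(as.numeric(Matrix::solve(J, -cur$F)),
                       error = function(e) NULL)
      if (is.null(step)) { tau <- tau / 4; next }
      S_try <- S + matrix(step, n, m)
      nxt <- resid_of(S_try)
      if (fnorm(nxt$F) < f0 * 1.001) {
        S <- S_try; cur <- nxt; f0 <- fnorm(cur$F); tau <- tau * 2
      } else {
        tau <- tau / 4
        if (tau < 1e-14) break
      }
    }
  }
  if (f0 > tol)
    stop(sprintf(paste0("solute solver did not converge: relative residual ",
                        "%.3g after %d iterations"), f0, it), call. = FALSE)
  ## polish: a few extra full Newton steps drive the residual to the round-off
  ## floor so that discrete flux conservation holds essentially exactly
  for (extra in 1:4) {
    J <- A
    if (!is.null(cur$rx$J)) {
      tri <- reaction_jac_triplets(cur$rx$J, n, m)
      if (length(tri$x))
        J <- J + Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                                      dims = c(n * m, n * m))
    }
    step <- tryCatch(as.numeric(Matrix::solve(J, -cur$F)),
                     error = function(e) NULL)
    if (is.null(step)) break
    S_try <- S + matrix(step, n, m)
    nxt <- resid_of(S_try)
    if (fnorm(nxt$F) >= 0.5 * f0) break
    S <- S_try; cur <- nxt; f0 <- fnorm(cur$F)
  }
  if (any(S < -neg_tol * rep(sc_ext, each = n)))
    stop("solute solver: negative concentrations beyond tolerance",
         call. = FALSE)
  S[S < 0] <- 0
  fl <- boundary_fluxes(S, lin)
  list(S = S, flux_left = fl$left, flux_right = fl$right,
       iterations = it, residual = f0)
}

## Triplets of the block-diagonal reaction Jacobian d r_s / d S_s'.
reaction_jac_triplets <- function(Jarr, n, m) {
  idx_i <- idx_j <- idx_x <- vector("list", m * m)
  k <- 0L
  for (s in seq_len(m)) for (sp in seq_len(m)) {
    v <- Jarr[, s, sp]
    if (any(v != 0)) {
      k <- k + 1L
      idx_i[[k]] <- (s - 1L) * n + seq_len(n)
      idx_j[[k]] <- (sp - 1L) * n + seq_len(n)
      idx_x[[k]] <- v
    }
  }
  list(i = unlist(idx_i[seq_len(k)]), j = unlist(idx_j[seq_len(k)]),
       x = unlist(idx_x[seq_len(k)]))
}

## Net solute conversion rates and analytic Jacobian for the biofilm solve.
## S: n x 4 solute matrix; X: n x 3 biomass (g COD/m3); pT: output of
## params_at_temperature(); p: kinetic_params.
solute_reaction <- function(S, X, pT, p, decay_o2_limited = TRUE) {
  n <- nrow(S)
  nu <- stoichiometry_matrix(p)[, paste0("S_", solute_names())]
  mO2A <- monod(S[, 1], p$K_O2_AOO); dO2A <- dmonod(S[, 1], p$K_O2_AOO)
  mO2N <- monod(S[, 1], p$K_O2_NOO); dO2N <- dmonod(S[, 1], p$K_O2_NOO)
  mNH4 <- monod(S[, 2], p$K_NH4);    dNH4 <- dmonod(S[, 2], p$K_NH4)
  mNO2 <- monod(S[, 3], p$K_NO2);    dNO2 <- dmonod(S[, 3], p$K_NO2)
  mNs  <- monod(S[, 2], 0.01);       dNs  <- dmonod(S[, 2], 0.01)
  XA <- X[, 1]; XN <- X[, 2]
  rho <- cbind(pT$mu_AOO * mNH4 * mO2A * XA,
               pT$mu_NOO * mNO2 * mO2N * mNs * XN,
               pT$b_AOO * (if (decay_o2_limited) mO2A else 1) * XA,
               pT$b_NOO * (if (decay_o2_limited) mO2N else 1) * XN)
  r <- rho %*% nu
  ## d rho_p / d S_s' (n x 4 processes x 4 solutes)
  drho <- array(0, c(n, 4, 4))
  drho[, 1, 1] <- pT$mu_AOO * mNH4 * dO2A * XA
  drho[, 1, 2] <- pT$mu_AOO * dNH4 * mO2A * XA
  drho[, 2, 1] <- pT$mu_NOO * mNO2 * dO2N * mNs * XN
  drho[, 2, 2] <- pT$mu_NOO * mNO2 * mO2N * dNs * XN
  drho[, 2, 3] <- pT$mu_NOO * dNO2 * mO2N * mNs * XN
  if (decay_o2_limited) {
    drho[, 3, 1] <- pT$b_AOO * dO2A * XA
    drho[, 4, 1] <- pT$b_NOO * dO2N * XN
  }
  J <- array(0, c(n, 4, 4))
  for (s in 1:4) for (sp in 1:4) {
    J[, s, sp] <- drho[, 1, sp] * nu[1, s] + drho[, 2, sp] * nu[2, s] +
      drho[, 3, sp] * nu[3, s] + drho[, 4, sp] * nu[4, s]
  }
  list(r = r, J = J, rho = rho)
}

#' Solve the quasi-steady solute profiles of the biofilm
#'
#' Solves, for each solute (O2, NH4, NO2, NO3), the steady diffusion-reaction
#' equation across the biofilm depth with the biomass profile frozen.
#' Boundary conditions: at the membrane face, oxygen enters through the
#' diffusive membrane link with flux `perm(T) * (C_sat - S)` and all other
#' solutes see a zero-flux wall; at the liquid face every solute exchanges
#' with the bulk through the stagnant boundary-layer film with conductance
#' `D_w / L_LBL`.
#'
#' @param eps n x 3 matrix of biomass volume fractions (columns AOO, NOO, I)
#'   on the cell-centre grid.
#' @param geometry A [biofilm_geometry()].
#' @param bulk A [bulk_liquid()] (supplies bulk concentrations and
#'   temperature).
#' @param membrane A [membrane_boundary()].
#' @param params,rules Kinetic parameters and temperature rules.
#' @param S_init Optional n x 4 matrix of initial profiles (warm start).
#' @param n Number of grid cells (used when `S_init` is absent).
#' @param control List of solver settings: `tol` (relative residual,
#'   default 1e-8), `maxit`.
#' @param decay_o2_limited Passed to the rate model; see [process_rates()].
#' @return List with `S` (n x 4 profile matrix), `flux_membrane` and
#'   `flux_liquid` (named inward fluxes per unit of the respective face area,
#'   g/(m2 d)), `grid`, `iterations`, `residual`.
#' @export
solve_solute_profiles <- function(eps, geometry, bulk, membrane,
                                  params = kinetic_params(),
                                  rules = temperature_rules(),
                                  S_init = NULL, n = 100,
                                  control = list(),
                                  decay_o2_limited = TRUE) {
  tol <- control$tol %||% 1e-8
  maxit <- control$maxit %||% 80
  if (!is.null(S_init)) n <- nrow(S_init)
  if (!is.matrix(eps) || ncol(eps) != 3 || nrow(eps) != n)
    stop("solve_solute_profiles: `eps` must be an n x 3 matrix matching the ",
         "grid", call. = FALSE)
  grid <- make_grid(geometry, n)
  T <- bulk$temperature
  pT <- params_at_temperature(params, rules, T)
  Csat <- oxygen_saturation(T, membrane$gas_pO2, rules)
  sn <- solute_names()
  bc_left <- lapply(sn, function(s) {
    if (s == "O2") list(type = "robin", k = pT$perm, value = Csat)
    else list(type = "flux0", k = NULL, value = NULL)
  })
  bc_right <- lapply(sn, function(s)
    list(type = "robin", k = pT$D_w[[s]] / geometry$L_LBL,
         value = bulk$S_bulk[[s]]))
  if (is.null(S_init)) {
    S_init <- matrix(rep(bulk$S_bulk, each = n), n, 4,
                     dimnames = list(NULL, sn))
    S_init[, "O2"] <- Csat * (1 - grid$x / geometry$Lf) +
      bulk$S_bulk[["O2"]] * grid$x / geometry$Lf
  }
  colnames(S_init) <- sn
  X <- eps * params$rho_X
  reaction <- function(S) solute_reaction(S, X, pT, params, decay_o2_limited)
  sol <- rd_newton(S_init, pT$D_f[sn], grid, bc_left, bc_right, reaction,
                   tol = tol, maxit = maxit)
  colnames(sol$S) <- sn
  list(S = sol$S,
       flux_membrane = sol$flux_left,
       flux_liquid = sol$flux_right,
       grid = grid, Csat = Csat,
       iterations = sol$iterations, residual = sol$residual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
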