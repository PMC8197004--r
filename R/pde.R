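# Thomas algorithm for a tridiagonal system. lower[i] multiplies c[i-1] in
# row i, upper[i] multiplies c[i+1]; lower[1] and upper[n] are ignored.
solve_tridiag <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Harmonic-mean face transmissibilities (units of K per metre) for a cell
# conductivity field K. Returns length n-1 (interior faces).
face_transmissibility <- function(k_cell, grid) {
  n <- grid$n
  d_left <- grid$x_f[2:n] - grid$x_c[1:(n - 1)]    # centre i to face
  d_right <- grid$x_c[2:n] - grid$x_f[2:n]         # face to centre i+1
  1 / (d_left / k_cell[1:(n - 1)] + d_right / k_cell[2:n])
}

# Volumetric charge-transfer source s(x) [A/m3 of geometric volume] and its
# derivative w.r.t. u = phi_m - phi_s, including the planar external-surface
# contributions at the first and last REM cells. u, eps_s are per REM cell.
charge_source <- function(u, eps_s, config) {
  e <- config$electro
  rc <- reaction_currents(u, e, config$numerics$exp_cap)
  i_sum <- rc$i_ho + rc$i_o2
  di_sum <- rc$di_ho + rc$di_o2
  s <- eps_s * e$a_v * i_sum
  ds <- eps_s * e$a_v * di_sum
  ext <- numeric(length(u)); dext <- numeric(length(u))
  if (isTRUE(config$numerics$external_faces)) {
    m <- (1 - config$gas$eps_p) * config$numerics$external_face_multiplier
    ext[c(1, length(u))] <- m * i_sum[c(1, length(u))]          # A/m2
    dext[c(1, length(u))] <- m * di_sum[c(1, length(u))]
  }
  list(s = s, ds = ds, ext = ext, dext = dext, rc = rc)
}

#' Solve the dual-phase secondary current distribution
#'
#' Newton solve of the coupled nonlinear system for the solution-phase
#' potential \eqn{\phi_s} (whole domain) and matrix-phase potential
#' \eqn{\phi_m} (REM only): Ohm's law in each phase, charge conservation
#' \eqn{\partial(i_s + i_m)/\partial x = 0}, and Butler-Volmer transfer
#' current \eqn{\partial i_s/\partial x} per REM cell. Boundary conditions:
#' \eqn{\phi_s(-\delta) = 0}; all current in the solution phase at the feed
#' side (\eqn{i_m = 0} at \eqn{x = 0}); all current in the matrix at the
#' permeate face (\eqn{i_m = i_{tot}} at \eqn{x = d}). At convergence the
#' galvanostatic closure \eqn{|\int \varepsilon_s a_v (i_{HO} + i_{O2}) dx|
#' = |i_{tot}|} holds to the Newton tolerance.
#'
#' At \eqn{i_{tot} = 0} the single-branch Tafel kinetics admit no finite
#' zero-current potential; the physical zero-current limit is returned
#' directly (\eqn{\phi_s \equiv 0}, zero reaction currents).
#'
#' @param eps_g gas-fraction profile on the full grid
#' @param i_tot signed total current density, A/m2
#' @param config validated configuration
#' @param grid a [build_grid()] grid
#' @param init optional warm start, list with \code{phi_s}, \code{phi_m}
#' @return list with \code{phi_s}, \code{phi_m} (NA in the diffusion layer),
#'   reaction-current magnitudes \code{i_ho}, \code{i_o2} (A/m2, 0 in the
#'   DL), signed face currents \code{i_s}, \code{i_m}, the volumetric charge
#'   source \code{q} (A/m3), closure residual \code{closure}, and Newton
#'   iteration count
#' @export
solve_potentials <- function(eps_g, i_tot, config, grid, init = NULL) {
  n <- grid$n; n_rem <- grid$n_rem
  ir <- grid$i_rem
  e <- config$electro
  eps_s_full <- ifelse(grid$in_rem, config$gas$eps_p - eps_g, 1)
  zero <- list(phi_s = numeric(n),
               phi_m = ifelse(grid$in_rem, 0, NA_real_),
               i_ho = numeric(n), i_o2 = numeric(n),
               i_s = rep(0, n + 1), i_m = rep(0, n + 1),
               q = numeric(n), closure = 0, iterations = 0L)
  if (i_tot == 0) return(zero)
  I <- abs(i_tot)

  k_s <- eps_s_full * e$kappa_s
  k_m_rem <- rep((1 - config$gas$eps_p) * e$kappa_m, n_rem)
  ts <- face_transmissibility(k_s, grid)          # n-1 interior faces
  tb_s <- k_s[1] / (grid$x_c[1] - grid$x_f[1])    # Dirichlet at x = -delta
  # phi_m faces inside the REM (n_rem - 1 of them)
  d_l <- grid$x_f[ir[-1]] - grid$x_c[ir[-n_rem]]
  d_r <- grid$x_c[ir[-1]] - grid$x_f[ir[-1]]
  tm <- 1 / (d_l / k_m_rem[-n_rem] + d_r / k_m_rem[-1])

  dx <- grid$dx
  eps_s_rem <- eps_s_full[ir]

  residual <- function(z) {
    phi_s <- z[1:n]; phi_m <- z[n + 1:n_rem]
    u <- phi_m - phi_s[ir]
    cs <- charge_source(u, eps_s_rem, config)
    q <- cs$s + cs$ext / dx[ir]                   # A/m3
    # solution phase: G = -K dphi/dx; residual = G_r - G_l - q dx (REM)
    g_int <- -ts * diff(phi_s)
    g_l <- c(-tb_s * phi_s[1], g_int)             # left-face flux per cell
    g_r <- c(g_int, 0)                            # zero flux at x = d
    r_s <- g_r - g_l
    r_s[ir] <- r_s[ir] - (cs$s * dx[ir] + cs$ext)
    # matrix phase: residual = Gm_r - Gm_l + s dx; Gm(d) = -I
    gm_int <- -tm * diff(phi_m)
    gm_l <- c(0, gm_int)
    gm_r <- c(gm_int, -I)
    r_m <- gm_r - gm_l + (cs$s * dx[ir] + cs$ext)
    list(r = c(r_s, r_m), cs = cs, q = q)
  }

  jacobian <- function(z, cs) {
    ntot <- n + n_rem
    J <- matrix(0, ntot, ntot)
    # solution-phase Laplacian
    for (f in 1:(n - 1)) {
      J[f, f] <- J[f, f] + ts[f];       J[f, f + 1] <- J[f, f + 1] - ts[f]
      J[f + 1, f + 1] <- J[f + 1, f + 1] + ts[f]; J[f + 1, f] <- J[f + 1, f] - ts[f]
    }
    J[1, 1] <- J[1, 1] + tb_s
    # matrix-phase Laplacian
    for (f in seq_len(n_rem - 1)) {
      a <- n + f; b <- n + f + 1
      J[a, a] <- J[a, a] + tm[f]; J[a, b] <- J[a, b] - tm[f]
      J[b, b] <- J[b, b] + tm[f]; J[b, a] <- J[b, a] - tm[f]
    }
    # reaction coupling, diagonal in the cell index
    dq <- cs$ds * dx[grid$i_rem] + cs$dext        # d(total source)/du per cell
    for (j in seq_len(n_rem)) {
      is_ <- grid$i_rem[j]; im_ <- n + j
      J[is_, is_] <- J[is_, is_] + dq[j]          # -d(-q dx)/dphi_s
      J[is_, im_] <- J[is_, im_] - dq[j]
      J[im_, im_] <- J[im_, im_] + dq[j]
      J[im_, is_] <- J[im_, is_] - dq[j]
    }
    J
  }

  init_guess <- function() {
    # scalar closure for a uniform u, then ohmic reconstruction
    tot <- function(u0) {
      cs <- charge_source(rep(u0, n_rem), eps_s_rem, config)
      sum(cs$s * dx[ir]) + sum(cs$ext) - I
    }
    lo <- min(e$e0_ho, e$e0_o2) - 2; hi <- max(e$e0_ho, e$e0_o2) + 2
    u0 <- tryCatch(stats::uniroot(tot, c(lo, hi), tol = 1e-10)$root,
                   error = function(e2) min(e$e0_ho, e$e0_o2) + 0.3)
    cs <- charge_source(rep(u0, n_rem), eps_s_rem, config)
    qdx <- cs$s * dx[ir] + cs$ext
    j_face_rem <- I - cumsum(qdx)                 # solution current at right faces
    j_cell <- I - cumsum(qdx) + qdx / 2
    phi_s <- numeric(n)
    # march from the feed boundary
    grad <- rep(I, n); grad[ir] <- j_cell
    grad <- grad / k_s
    phi_face <- cumsum(c(0, grad * dx))
    phi_s <- (phi_face[-1] + phi_face[-(n + 1)]) / 2
    list(phi_s = phi_s, phi_m = phi_s[ir] + u0)
  }

  start <- if (!is.null(init) && all(is.finite(init$phi_s)) &&
               all(is.finite(init$phi_m[ir]))) {
    list(phi_s = init$phi_s, phi_m = init$phi_m[ir])
  } else init_guess()

  z <- c(start$phi_s, start$phi_m)
  tol <- config$numerics$newton_tol * I
  res <- residual(z)
  rn <- max(abs(res$r))
  iter <- 0L
  while (rn > tol && iter < config$numerics$newton_max_iter) {
    J <- jacobian(z, res$cs)
    dz <- tryCatch(solve(J, -res$r), error = function(e2) NULL)
    if (is.null(dz)) break
    lambda <- 1
    repeat {
      z_try <- z + lambda * dz
      res_try <- residual(z_try)
      rn_try <- max(abs(res_try$r))
      if (is.finite(rn_try) && rn_try < rn) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
    z <- z_try; res <- res_try; rn <- rn_try
    iter <- iter + 1L
  }
  if (rn > tol) {
    # retry once from the fresh scalar-closure guess
    if (!is.null(init)) {
      return(solve_potentials(eps_g, i_tot, config, grid, init = NULL))
    }
    stop(sprintf("solve_potentials: Newton failed, residual %.3e (tol %.3e)",
                 rn, tol), call. = FALSE)
  }

  phi_s <- z[1:n]
  phi_m_rem <- z[n + 1:n_rem]
  cs <- res$cs
  qdx <- cs$s * dx[ir] + cs$ext                   # A/m2 transferred per cell
  closure <- (sum(qdx) - I) / I
  # face currents signed like the configured total: i_s + i_m = i_tot
  j_faces <- c(rep(I, grid$n_dl + 1), I - cumsum(qdx))  # solution current magnitude
  i_s <- sign(i_tot) * j_faces
  i_m <- i_tot - i_s
  i_ho <- numeric(n); i_o2 <- numeric(n)
  i_ho[ir] <- cs$rc$i_ho; i_o2[ir] <- cs$rc$i_o2
  q <- numeric(n); q[ir] <- qdx / dx[ir]
  phi_m <- rep(NA_real_, n)
  phi_m[ir] <- phi_m_rem
  list(phi_s = phi_s,
       phi_m = phi_m,
       i_ho = i_ho, i_o2 = i_o2,
       i_s = i_s, i_m = i_m, q = q,
       closure = closure, iterations = iter)
  }

#' Implicit advection-diffusion-reaction step for one species
#'
#' Backward-Euler finite-volume step of
#' \eqn{\varepsilon_s \partial c/\partial t = -\partial J/\partial x +
#' \varepsilon_s (P - L c)} with flux
#' \eqn{J = -\varepsilon_s D \, \partial c/\partial x + c v}, first-order
#' upwind convection and harmonic-mean face diffusivities weighted by
#' \eqn{\varepsilon_s}. Inlet (\eqn{x = -\delta}): Dirichlet \code{c_in};
#' outlet (\eqn{x = d}): zero diffusive gradient with advective outflow.
#' The linear source splitting \eqn{P - L c} (production explicit, loss
#' linearized in the species' own concentration) keeps the matrix an
#' M-matrix, so non-negative inputs give a non-negative solution.
#'
#' @param c_old concentration profile, mol/m3
#' @param v superficial velocity, m/s
#' @param eps_s solution volume fraction per cell
#' @param d_k molecular diffusion coefficient, m2/s
#' @param p_src production per solution volume, mol/m3/s
#' @param l_src first-order loss rate, 1/s
#' @param c_in inlet Dirichlet value, mol/m3
#' @param dt time step, s
#' @param grid grid object
#' @return list with \code{c} (updated profile) and \code{audit} (relative
#'   mass-balance residual of the step, an identity check of the assembly)
#' @export
species_step <- function(c_old, v, eps_s, d_k, p_src, l_src, c_in, dt, grid) {
  if (dt <= 0) stop("species_step: dt must be > 0", call. = FALSE)
  n <- grid$n
  kd <- eps_s * d_k
  td <- face_transmissibility(kd, grid)
  lower <- numeric(n); upper <- numeric(n); diag <- numeric(n); rhs <- numeric(n)

  cap <- eps_s * grid$dx / dt
  diag <- cap + eps_s * grid$dx * l_src
  rhs <- cap * c_old + eps_s * grid$dx * p_src

  # interior faces: diffusion + upwind advection
  for_idx <- 1:(n - 1)
  # diffusion
  diag[for_idx] <- diag[for_idx] + td
  upper[for_idx] <- upper[for_idx] - td
  diag[for_idx + 1] <- diag[for_idx + 1] + td
  lower[for_idx + 1] <- lower[for_idx + 1] - td
  # advection, upwind
  if (v >= 0) {
    diag[for_idx] <- diag[for_idx] + v        # outflow from i at right face
    lower[for_idx + 1] <- lower[for_idx + 1] - v
  } else {
    upper[for_idx] <- upper[for_idx] + v
    diag[for_idx + 1] <- diag[for_idx + 1] - v
  }
  # inlet boundary (Dirichlet + advective inflow)
  tb <- kd[1] / (grid$x_c[1] - grid$x_f[1])
  diag[1] <- diag[1] + tb
  rhs[1] <- rhs[1] + tb * c_in
  if (v >= 0) rhs[1] <- rhs[1] + v * c_in else diag[1] <- diag[1] - v
  # outlet boundary: zero diffusive gradient; advective outflow if v > 0
  if (v >= 0) diag[n] <- diag[n] + v

  c_new <- solve_tridiag(lower, diag, upper, rhs)

  # discrete mass-balance audit (identity check of the assembly)
  flux_in <- tb * (c_in - c_new[1]) + v * (if (v >= 0) c_in else c_new[1])
  flux_out <- v * (if (v >= 0) c_new[n] else c_in)
  lhs <- sum(eps_s * grid$dx * (c_new - c_old)) / dt
  rhs_bal <- flux_in - flux_out + sum(eps_s * grid$dx * (p_src - l_src * c_new))
  gross <- sum(eps_s * grid$dx * (abs(p_src) + l_src * abs(c_new)))
  scale <- max(abs(lhs), abs(rhs_bal), gross,
               sum(eps_s * grid$dx * abs(c_new)) / dt, 1e-30)
  list(c = c_new, audit = abs(lhs - rhs_bal) / scale)
}

#' Initial state of the system
#'
#' Feed concentration of paracetamol everywhere; no radicals, dissolved
#' electro-generated oxygen, byproducts or gas before electrolysis; potential
#' fields from the zero-current limit; velocity from the bubble-free
#' pressure-driven solve.
#'
#' @param config validated configuration
#' @param grid optional pre-built grid
#' @return a \code{rem_state} list
#' @export
initial_state <- function(config, grid = build_grid(config$geometry)) {
  n <- grid$n
  pot <- solve_potentials(numeric(n), 0, config, grid)
  vel <- solve_velocity(numeric(n), pot$phi_s, grid, config)
  st <- list(
    t = 0,
    c_pct = rep(config$species$c0, n),
    c_bp = numeric(n), c_ho = numeric(n), c_o2 = numeric(n),
    eps_g = numeric(n),
    phi_s = pot$phi_s, phi_m = pot$phi_m,
    i_s = pot$i_s, i_m = pot$i_m,
    i_ho = pot$i_ho, i_o2 = pot$i_o2,
    p = vel$p, v = vel$v
  )
  class(st) <- "rem_state"
  st
}

#' External-surface reaction sources at the electrode faces
#'
#' The REM's two external interfaces (x = 0 and x = d) carry a planar
#' electrode reaction in addition to the internal pore-wall area: per-area
#' Butler-Volmer currents weighted by the geometric solid-area fraction
#' (1 - porosity) and a configurable multiplier, converted to volumetric
#' sources in the adjacent boundary cells (divided by the cell width).
#' Controlled by \code{numerics$external_faces} (default on) and
#' \code{numerics$external_face_multiplier} (default 1).
#'
#' @param state a simulation state with solved potentials
#' @param config validated configuration
#' @param grid grid object
#' @return data.frame with one row per REM cell: \code{x_m}, extra volumetric
#'   current \code{q_extra_A_m3}, and extra production rates
#'   \code{s_ho_mol_m3_s}, \code{s_o2_mol_m3_s} (per geometric volume);
#'   all zero except in the two boundary cells (or everywhere when the
#'   feature is off)
#' @export
external_surface_sources <- function(state, config, grid) {
  ir <- grid$i_rem
  n_rem <- grid$n_rem
  out <- data.frame(x_m = grid$x_c[ir],
                    q_extra_A_m3 = numeric(n_rem),
                    s_ho_mol_m3_s = numeric(n_rem),
                    s_o2_mol_m3_s = numeric(n_rem))
  if (!isTRUE(config$numerics$external_faces)) return(out)
  u <- state$phi_m[ir] - state$phi_s[ir]
  if (any(!is.finite(u[c(1, n_rem)]))) return(out)
  rc <- reaction_currents(u, config$electro, config$numerics$exp_cap)
  m <- (1 - config$gas$eps_p) * config$numerics$external_face_multiplier
  b <- c(1, n_rem)
  dxb <- grid$dx[ir][b]
  out$q_extra_A_m3[b] <- m * (rc$i_ho[b] + rc$i_o2[b]) / dxb
  out$s_ho_mol_m3_s[b] <- m * rc$i_ho[b] / dxb / (config$electro$n_ho * FARADAY)
  out$s_o2_mol_m3_s[b] <- m * rc$i_o2[b] / dxb / (config$electro$n_o2 * FARADAY)
  out
}
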