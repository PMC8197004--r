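#' Electroosmotic velocity (Helmholtz-Smoluchowski)
#'
#' \deqn{v_{EO} = -\frac{\varepsilon_r \varepsilon_0 \zeta}{\mu}
#'       \frac{\partial \phi_s}{\partial x}.}
#' The solution-phase potential rises toward the permeate side while the
#' current is on, so with a negative zeta potential this orientation makes the
#' electroosmotic contribution augment the permeate flux at current-on and
#' vanish at current-off, the experimentally observed behaviour.
#'
#' @param dphis_dx solution-phase potential gradient, V/m
#' @param flow the \code{flow} section of a configuration
#' @return electroosmotic velocity, m/s (positive toward the permeate)
#' @export
electroosmotic_velocity <- function(dphis_dx, flow) {
  -flow$eps_r * flow$eps0 * flow$zeta / flow$mu * dphis_dx
}

#' Gas-blockage factor of the Darcy permeability
#'
#' Power-law reduction of the effective permeability when gas bubbles occupy
#' part of the pore volume: \eqn{f = (\varepsilon_s/\varepsilon_p)^e}, equal
#' to 1 in the bubble-free state.
#'
#' @param eps_s solution volume fraction
#' @param eps_p porosity
#' @param exponent power-law exponent
#' @return blockage factor in (0, 1]
#' @export
blockage_factor <- function(eps_s, eps_p, exponent) {
  if (any(eps_s <= 0)) {
    stop("blockage_factor: eps_s <= 0 (pore fully closed)", call. = FALSE)
  }
  if (any(eps_s > eps_p + 1e-12)) {
    stop("blockage_factor: eps_s cannot exceed eps_p", call. = FALSE)
  }
  (eps_s / eps_p)^exponent
}

#' Superficial velocity and pressure profile
#'
#' The liquid is incompressible and the flow quasi-steady, so the superficial
#' velocity is spatially uniform at each instant. At every REM cell Darcy's
#' law with electroosmosis holds,
#' \eqn{v = f(x)\,(\sigma/\mu)\,(-dp/dx) + v_{EO}(x)}, and the pressure drop
#' across the REM equals the transmembrane pressure (the diffusion layer is
#' free solution and contributes no hydraulic resistance). Summing the series
#' resistances gives
#' \deqn{v = \frac{TMP\,\sigma/\mu + \sum_i v_{EO,i}\,\Delta x_i / f_i}
#'                {\sum_i \Delta x_i / f_i}.}
#'
#' @param eps_g gas-fraction profile on the full grid
#' @param phi_s solution-phase potential profile on the full grid, V
#' @param grid a [build_grid()] object
#' @param config validated configuration
#' @return list with \code{v} (m/s), \code{p} (Pa, per cell; TMP at the feed
#'   boundary, 0 at the permeate), and \code{v_eo} (m/s per REM cell)
#' @export
solve_velocity <- function(eps_g, phi_s, grid, config) {
  flow <- config$flow
  gas <- config$gas
  ir <- grid$i_rem
  eps_s <- pmax(gas$eps_p - eps_g[ir], gas$eps_p - gas$eps_g_cap)
  f <- blockage_factor(eps_s, gas$eps_p, flow$blockage_exponent)

  # cell-centred potential gradient from neighbouring centres (one-sided at
  # the REM ends)
  v_eo <- numeric(length(ir))
  if (abs(flow$zeta) > 0) {
    grad <- cell_gradient(phi_s, grid)[ir]
    v_eo <- electroosmotic_velocity(grad, flow)
  }

  res <- grid$dx[ir] / f                     # local resistance weight, m
  v <- (flow$tmp * flow$sigma / flow$mu + sum(v_eo * res)) / sum(res)

  # pressure: TMP at the feed boundary, no DL resistance, 0 at the permeate
  dpdx <- -(v - v_eo) * flow$mu / (flow$sigma * f)
  p <- numeric(grid$n)
  p[grid$i_dl] <- flow$tmp
  drop_to_face <- cumsum(dpdx * grid$dx[ir])          # p change up to right face
  p[ir] <- flow$tmp + drop_to_face - dpdx * grid$dx[ir] / 2
  list(v = v, p = p, v_eo = v_eo)
}

#' Gas-fraction growth rate
#'
#' Relaxation of the gas volume fraction toward the local solubility
#' equilibrium with the dissolved O2:
#' \deqn{d\varepsilon_g/dt = k_v(\varepsilon_s c_{O2} k_g - \varepsilon_g).}
#'
#' @param eps_s solution volume fraction
#' @param c_o2 dissolved O2 concentration, mol/m3
#' @param eps_g gas volume fraction
#' @param gas the \code{gas} section of a configuration
#' @return rate, 1/s
#' @export
gas_rate <- function(eps_s, c_o2, eps_g, gas) {
  if (any(!is.finite(c(eps_s, c_o2, eps_g)))) {
    stop("gas_rate: non-finite input", call. = FALSE)
  }
  gas$k_v * (eps_s * c_o2 * gas$k_g - eps_g)
}

#' Advance the gas fraction over one time step (exact per-cell update)
#'
#' With \eqn{\varepsilon_s = \varepsilon_p - \varepsilon_g} substituted, the
#' gas equation is linear in \eqn{\varepsilon_g} at frozen \eqn{c_{O2}}:
#' \eqn{d\varepsilon_g/dt = k_v(\varepsilon_p c k_g - (1 + c k_g)\varepsilon_g)},
#' an exponential relaxation at rate \eqn{k_v (1 + c k_g)} toward
#' \eqn{\varepsilon_p c k_g / (1 + c k_g)}. The update is therefore exact for
#' any step size and unconditionally stable; the result is clipped into
#' \eqn{[0, \varepsilon_{g,cap}]}.
#'
#' @param eps_g gas-fraction profile on REM cells
#' @param c_o2 dissolved O2 on the same cells, mol/m3
#' @param dt time step, s
#' @param config validated configuration
#' @return updated gas-fraction profile
#' @export
step_gas <- function(eps_g, c_o2, dt, config) {
  if (dt <= 0) stop("step_gas: dt must be > 0", call. = FALSE)
  gas <- config$gas
  c_o2 <- pmax(c_o2, 0)
  rate <- gas$k_v * (1 + c_o2 * gas$k_g)
  target <- gas$eps_p * c_o2 * gas$k_g / (1 + c_o2 * gas$k_g)
  out <- target + (eps_g - target) * exp(-rate * dt)
  pmin(pmax(out, 0), gas$eps_g_cap)
}
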