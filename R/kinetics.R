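#' Homogeneous hydroxyl-radical reaction rates
#'
#' Second-order rate laws for radical recombination (four HO* consumed per O2
#' produced), paracetamol oxidation, and lumped-byproduct oxidation:
#' \deqn{r_{HO} = k_{HO} c_{HO}^2,\quad r_{PCT} = k_{PCT} c_{PCT} c_{HO},\quad
#'       r_{BP} = k_{BP} c_{BP} c_{HO}.}
#' Negative concentrations from numerical undershoot are clipped to zero with
#' a warning before the rates are evaluated.
#'
#' @param c_ho,c_pct,c_bp concentrations, mol/m3 (vectors of equal length)
#' @param kin the \code{kinetics} section of a configuration
#' @return list with elements \code{r_ho}, \code{r_pct}, \code{r_bp}
#'   (mol m-3 s-1)
#' @export
homogeneous_rates <- function(c_ho, c_pct, c_bp, kin) {
  if (any(!is.finite(c(c_ho, c_pct, c_bp)))) {
    stop("homogeneous_rates: non-finite concentration", call. = FALSE)
  }
  if (any(c(c_ho, c_pct, c_bp) < 0)) {
    warning("homogeneous_rates: negative concentration clipped to 0")
    c_ho <- pmax(c_ho, 0); c_pct <- pmax(c_pct, 0); c_bp <- pmax(c_bp, 0)
  }
  list(
    r_ho = kin$k_ho * c_ho^2,
    r_pct = kin$k_pct * c_pct * c_ho,
    r_bp = kin$k_bp * c_bp * c_ho
  )
}

#' Butler-Volmer electrode current density
#'
#' Tafel-type single-branch kinetics for the two anodic reactions
#' (HO* generation from water discharge; O2 evolution), with overpotential
#' \eqn{\eta = \phi_m - \phi_s - E^0}. Two conventions are supported:
#' \describe{
#'   \item{\code{"anodic"} (default)}{\eqn{i = |i_0| \exp(+\beta n F \eta / RT)},
#'     currents positive, magnitude grows with positive overpotential.}
#'   \item{\code{"printed"}}{\eqn{i = i_0 \exp(-\beta n F \eta / RT)} applied
#'     exactly as written with signed \eqn{i_0}; the magnitude grows as the
#'     overpotential decreases.}
#' }
#' The exponent argument is capped at \code{exp_cap} (with a warning) to guard
#' against overflow during nonlinear iteration.
#'
#' @param phi_m,phi_s matrix- and solution-phase potentials, V
#' @param e0 formal potential, V
#' @param i0 exchange current density, A/m2 (sign as configured)
#' @param beta symmetry coefficient
#' @param n number of electrons
#' @param temperature K
#' @param sign_convention \code{"anodic"} or \code{"printed"}
#' @param exp_cap cap on the exponent argument
#' @return current density, A/m2 (same sign behaviour as \code{i0})
#' @export
butler_volmer <- function(phi_m, phi_s, e0, i0, beta, n, temperature,
                          sign_convention = "anodic", exp_cap = 200) {
  if (any(temperature <= 0)) stop("butler_volmer: temperature must be > 0", call. = FALSE)
  eta <- phi_m - phi_s - e0
  s <- if (identical(sign_convention, "printed")) -1 else 1
  arg <- s * beta * n * FARADAY * eta / (GAS_CONSTANT * temperature)
  if (any(arg > exp_cap)) {
    warning("butler_volmer: exponent capped at exp_cap")
    arg <- pmin(arg, exp_cap)
  }
  mag <- abs(i0) * exp(arg)
  if (identical(sign_convention, "printed")) sign(i0) * mag else mag
}

# Internal: positive reaction-current magnitudes for both reactions at a
# matrix-solution potential difference u = phi_m - phi_s, plus their
# derivatives d|i|/du. Used by the secondary-current-distribution solver.
reaction_currents <- function(u, electro, exp_cap = 200) {
  rt <- GAS_CONSTANT * electro$temperature
  s <- if (identical(electro$sign_convention, "printed")) -1 else 1
  a_ho <- s * electro$beta * electro$n_ho * FARADAY / rt
  a_o2 <- s * electro$beta * electro$n_o2 * FARADAY / rt
  arg_ho <- pmin(a_ho * (u - electro$e0_ho), exp_cap)
  arg_o2 <- pmin(a_o2 * (u - electro$e0_o2), exp_cap)
  i_ho <- abs(electro$i0_ho) * exp(arg_ho)
  i_o2 <- abs(electro$i0_o2) * exp(arg_o2)
  list(i_ho = i_ho, i_o2 = i_o2,
       di_ho = ifelse(arg_ho < exp_cap, a_ho * i_ho, 0),
       di_o2 = ifelse(arg_o2 < exp_cap, a_o2 * i_o2, 0))
}

#' Net volumetric source terms for the four species
#'
#' Combines the homogeneous rates with the electrode production terms and the
#' O2 volatilization exchange:
#' \deqn{R_{HO} = -4 r_{HO} - r_{PCT} - z_{BP} r_{BP} + S_{HO},\quad
#'       R_{PCT} = -r_{PCT},\quad R_{BP} = r_{PCT} - r_{BP},}
#' \deqn{R_{O2} = r_{HO} - k_v(\varepsilon_s c_{O2} - \varepsilon_g / k_g)
#'       + S_{O2},}
#' where the electrode production \eqn{S_k = |i_k| a_v / (n_k F)} is applied
#' only where \eqn{a_v > 0} (inside the REM; the diffusion layer has
#' \eqn{a_v = 0}). \code{i_ho} and \code{i_o2} are reaction-current
#' magnitudes, A/m2. Units of all terms are mol per m3 of solution per s.
#'
#' @param rates list from [homogeneous_rates()]
#' @param i_ho,i_o2 electrode current magnitudes per cell, A/m2
#' @param c_o2 dissolved O2 concentration, mol/m3
#' @param eps_s,eps_g solution and gas volume fractions
#' @param a_v specific surface area per cell, 1/m (0 outside the REM)
#' @param in_rem logical vector, TRUE for REM cells (volatilization is active
#'   only where a gas phase can exist)
#' @param config validated configuration
#' @return list with \code{r_ho}, \code{r_pct}, \code{r_bp}, \code{i_ho},
#'   \code{i_o2}, \code{R_ho}, \code{R_pct}, \code{R_bp}, \code{R_o2}
#' @export
species_sources <- function(rates, i_ho, i_o2, c_o2, eps_s, eps_g, a_v,
                            in_rem, config) {
  if (any(!is.finite(c(i_ho, i_o2, c_o2, eps_s, eps_g)))) {
    stop("species_sources: non-finite input", call. = FALSE)
  }
  if (any(eps_s <= 0)) stop("species_sources: eps_s must be > 0", call. = FALSE)
  kin <- config$kinetics
  gas <- config$gas
  s_ho <- i_ho * a_v / (config$electro$n_ho * FARADAY)
  s_o2 <- i_o2 * a_v / (config$electro$n_o2 * FARADAY)
  volat <- ifelse(in_rem, gas$k_v * (eps_s * c_o2 - eps_g / gas$k_g), 0)
  list(
    r_ho = rates$r_ho, r_pct = rates$r_pct, r_bp = rates$r_bp,
    i_ho = i_ho, i_o2 = i_o2,
    R_ho = -4 * rates$r_ho - rates$r_pct - kin$z_bp * rates$r_bp + s_ho,
    R_pct = -rates$r_pct,
    R_bp = rates$r_pct - rates$r_bp,
    R_o2 = rates$r_ho - volat + s_o2
  )
}
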