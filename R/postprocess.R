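#' Convert a superficial velocity to a permeate flux
#'
#' @param v superficial velocity, m/s
#' @return flux in L m-2 h-1 (1 m/s = 3.6e6 L m-2 h-1)
#' @export
permeate_flux_lmh <- function(v) {
  if (any(!is.finite(v))) stop("permeate_flux_lmh: non-finite v", call. = FALSE)
  v * LMH_PER_M_S
}

#' Depth of 99 percent degradation
#'
#' Smallest depth \eqn{x \ge 0} inside the porous electrode at which the
#' concentration falls to 1 percent of the reference, linearly interpolated
#' between cell centres (ties broken toward the smaller depth). The search
#' starts from the location of the reference value: for paracetamol the
#' reference is the feed concentration and the search starts at the REM
#' inlet; for the byproducts - which enter at zero, build up to an interior
#' maximum and are then destroyed - the reference is the profile maximum and
#' the search starts there, so the rising flank near the inlet is not
#' mistaken for degradation.
#'
#' @param profile concentrations on the REM cells, mol/m3
#' @param grid grid object (the REM part is used)
#' @param reference reference concentration, mol/m3; default: profile maximum
#' @param threshold degraded fraction of the reference (default 0.99)
#' @return depth in m, or \code{NA} with attribute \code{reason} if the
#'   criterion is not reached within the electrode
#' @export
depth_99 <- function(profile, grid, reference = max(profile), threshold = 0.99) {
  if (!is.finite(reference) || reference <= 0) {
    stop("depth_99: reference must be > 0", call. = FALSE)
  }
  x <- grid$x_c[grid$i_rem]
  c_rem <- profile
  if (length(c_rem) == grid$n) c_rem <- profile[grid$i_rem]
  if (length(c_rem) != grid$n_rem) {
    stop("depth_99: profile must cover the REM cells", call. = FALSE)
  }
  target <- (1 - threshold) * reference
  if (all(c_rem <= target)) return(0)
  start <- which.max(c_rem >= target)       # first cell at/above target
  i_max <- which.max(c_rem)
  from <- max(start, if (abs(max(c_rem) - reference) <= 1e-9 * reference) i_max else start)
  below <- which(c_rem[from:length(c_rem)] <= target)
  if (length(below) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "not reached within d"
    return(out)
  }
  j <- from + below[1] - 1                  # first cell at/below target
  if (j == 1) return(max(x[1], 0))
  x0 <- x[j - 1]; x1 <- x[j]
  c0 <- c_rem[j - 1]; c1 <- c_rem[j]
  if (c0 == c1) return(x0)                  # tie: smaller depth
  x0 + (target - c0) / (c1 - c0) * (x1 - x0)
}

#' Solution-phase potential drop across the electrode
#'
#' Absolute difference of the solution-phase potential between the REM inlet
#' face (\eqn{x = 0}, interpolated between the adjacent cell centres) and the
#' permeate face (\eqn{x = d}; zero solution current there, so the last cell
#' value applies).
#'
#' @param state a simulation state
#' @param grid grid object
#' @return potential difference, V
#' @export
potential_drop <- function(state, grid) {
  phi <- state$phi_s
  i0 <- grid$n_dl          # last DL cell
  i1 <- grid$n_dl + 1L     # first REM cell
  w <- (0 - grid$x_c[i0]) / (grid$x_c[i1] - grid$x_c[i0])
  phi_at_0 <- phi[i0] + w * (phi[i1] - phi[i0])
  abs(phi_at_0 - phi[grid$n])
}

#' Degradation fraction at the outlet
#'
#' @param result a \code{rem_result}
#' @param t time, s (nearest recorded time is used)
#' @return \eqn{1 - c_{PCT,out}(t)/c_0}
#' @export
degradation_fraction <- function(result, t) {
  c0 <- result$config$species$c0
  if (!is.finite(c0) || c0 <= 0) {
    stop("degradation_fraction: undefined for c0 = 0", call. = FALSE)
  }
  s <- result$series
  if (t < min(s$t_s) - 1e-9 || t > max(s$t_s) + 1e-9) {
    stop("degradation_fraction: t outside the run", call. = FALSE)
  }
  i <- which.min(abs(s$t_s - t))
  1 - s$c_pct_out[i] / c0
}

#' Degradation report for one run
#'
#' One row per species (paracetamol, byproducts) at a reference time:
#' 99-percent-degradation depth, outlet degradation fraction (relative to the
#' feed concentration for PCT; relative to the profile maximum for BP),
#' potential drop, flux and mean gas fraction at that time.
#'
#' @param result a \code{rem_result} with a snapshot at time \code{t}
#' @param t snapshot time, s
#' @return data.frame, one row per species
#' @export
degradation_report <- function(result, t) {
  key <- sprintf("t=%g", t)
  if (!key %in% names(result$snapshots)) {
    stop(sprintf("degradation_report: no snapshot at t = %g s", t), call. = FALSE)
  }
  st <- result$snapshots[[key]]
  grid <- result$grid
  c0 <- result$config$species$c0
  s <- result$series
  i <- which.min(abs(s$t_s - t))
  pct_depth <- if (c0 > 0) {
    depth_99(st$c_pct, grid, reference = c0)
  } else NA_real_
  bp_max <- max(st$c_bp[grid$i_rem])
  bp_depth <- if (bp_max > 0) depth_99(st$c_bp, grid) else 0
  data.frame(
    species = c("PCT", "BP"),
    depth_99_m = c(pct_depth, bp_depth),
    outlet_fraction = c(
      if (c0 > 0) 1 - st$c_pct[grid$n] / c0 else NA_real_,
      if (bp_max > 0) 1 - st$c_bp[grid$n] / bp_max else NA_real_),
    dphi_V = rep(s$dphi_V[i], 2),
    flux_lmh = rep(s$flux_L_m2_h[i], 2),
    eps_g_mean = rep(s$eps_g_mean[i], 2),
    t_s = rep(s$t_s[i], 2)
  )
}
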