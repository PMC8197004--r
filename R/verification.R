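#' Well-mixed (0D) reference integration
#'
#' Integrates the homogeneous reaction system with all spatial transport
#' removed, using an independent stiff integrator (\code{deSolve::lsoda}; no
#' code shared with the finite-volume core):
#' \deqn{dc_k/dt = R_k, \qquad
#'       d\varepsilon_g/dt = k_v(\varepsilon_s c_{O2} k_g - \varepsilon_g),}
#' with a prescribed volumetric HO* source standing in for the electrode
#' term and \eqn{\varepsilon_s = \varepsilon_p - \varepsilon_g}. Serves as
#' the oracle for the reaction coupling of the PDE core: a PDE run with
#' transport switched off (zero velocity, vanishing diffusivities) must
#' reproduce these trajectories cell by cell.
#'
#' @param config validated configuration
#' @param ho_source prescribed HO* source, mol/m3/s
#' @param t_end end time, s
#' @param times output times, s
#' @param c_init optional named initial concentrations
#'   (\code{c_pct}, \code{c_bp}, \code{c_ho}, \code{c_o2}, \code{eps_g})
#' @return data.frame with columns \code{time}, \code{c_pct}, \code{c_bp},
#'   \code{c_ho}, \code{c_o2}, \code{eps_g}
#' @export
batch_oracle <- function(config, ho_source, t_end,
                         times = seq(0, t_end, length.out = 101),
                         c_init = NULL) {
  kin <- config$kinetics; gas <- config$gas
  y0 <- c(c_pct = config$species$c0, c_bp = 0, c_ho = 0, c_o2 = 0, eps_g = 0)
  if (!is.null(c_init)) y0[names(c_init)] <- unlist(c_init)
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    eps_s <- gas$eps_p - y["eps_g"]
    r_ho <- kin$k_ho * y["c_ho"]^2
    r_pct <- kin$k_pct * y["c_pct"] * y["c_ho"]
    r_bp <- kin$k_bp * y["c_bp"] * y["c_ho"]
    volat <- gas$k_v * (eps_s * y["c_o2"] - y["eps_g"] / gas$k_g)
    list(c(
      -r_pct,
      r_pct - r_bp,
      -4 * r_ho - r_pct - kin$z_bp * r_bp + ho_source,
      r_ho - volat,
      gas$k_v * (eps_s * y["c_o2"] * gas$k_g - y["eps_g"])
    ))
  }
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-14, maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0) {
    stop("batch_oracle: integrator failure", call. = FALSE)
  }
  df <- as.data.frame(out)
  names(df) <- c("time", "c_pct", "c_bp", "c_ho", "c_o2", "eps_g")
  df
}

#' Summarize the per-step conservation audits of a run
#'
#' Collects the per-step audit rows recorded during [run_simulation()] (audit
#' hooks are on by default) and reports the worst-case residuals: discrete
#' species mass balances, galvanostatic charge closure, carbon balance
#' (paracetamol-to-byproduct conversion conserves carbon; byproduct
#' destruction is mineralization), and the gas/solution O2 exchange.
#'
#' @param result a \code{rem_result}
#' @return list of class \code{rem_audit} with \code{max} (named worst-case
#'   residuals), \code{n_steps}, \code{failures} (names exceeding tolerance),
#'   and the tolerances applied (1e-8 for the linear per-step identities,
#'   1e-3 for the split-step balances)
#' @export
conservation_audit <- function(result) {
  a <- result$audit
  if (is.null(a)) {
    stop("conservation_audit: run was executed without audit hooks", call. = FALSE)
  }
  linear_tol <- 1e-8
  split_tol <- 1e-3
  mx <- c(
    charge_closure = max(a$charge_closure),
    mass_ho = max(a$mass_ho), mass_pct = max(a$mass_pct),
    mass_bp = max(a$mass_bp), mass_o2 = max(a$mass_o2),
    carbon = max(a$carbon), gas_exchange = max(a$gas_exchange)
  )
  tol <- c(charge_closure = linear_tol, mass_ho = linear_tol,
           mass_pct = linear_tol, mass_bp = linear_tol, mass_o2 = linear_tol,
           carbon = split_tol, gas_exchange = split_tol)
  out <- list(max = mx, tolerances = tol,
              failures = names(mx)[mx > tol], n_steps = nrow(a))
  class(out) <- "rem_audit"
  out
}

#' @export
print.rem_audit <- function(x, ...) {
  cat("<rem_audit>", x$n_steps, "steps\n")
  for (nm in names(x$max)) {
    cat(sprintf("  %-15s max %.3e (tol %.0e)%s\n", nm, x$max[[nm]],
                x$tolerances[[nm]],
                if (nm %in% x$failures) "  FAIL" else ""))
  }
  invisible(x)
}

#' Write an audit report as JSON
#'
#' @param audit a \code{rem_audit} from [conservation_audit()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_audit_json <- function(audit, path) {
  jsonlite::write_json(
    list(n_steps = audit$n_steps,
         max_residuals = as.list(audit$max),
         tolerances = as.list(audit$tolerances),
         failures = audit$failures,
         pass = length(audit$failures) == 0),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
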