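# One operator-split step from state$t to state$t + dt. The split order is
# potentials -> velocity -> implicit species (Gauss-Seidel with Picard sweeps
# on the radical balance) -> exact gas update. Returns the new state plus an
# audit row. `pot_init` is a warm start for the Newton solve.
rem_step <- function(state, dt, config, grid, pot_init = NULL) {
  t_new <- state$t + dt
  i_tot <- current_at(config, t_new)
  n <- grid$n; ir <- grid$i_rem
  gas <- config$gas; kin <- config$kinetics; num <- config$numerics
  eps_s <- ifelse(grid$in_rem, gas$eps_p - state$eps_g, 1)

  pot <- solve_potentials(state$eps_g, i_tot, config, grid, init = pot_init)
  vel <- solve_velocity(state$eps_g, pot$phi_s, grid, config)
  v <- vel$v

  # electrode production, mol per m3 of solution per s
  q_ho <- numeric(n); q_o2 <- numeric(n)
  q_ho[ir] <- (eps_s[ir] * config$electro$a_v * pot$i_ho[ir] +
                 ifelse(seq_along(ir) %in% c(1, length(ir)) &
                          isTRUE(num$external_faces),
                        (1 - gas$eps_p) * num$external_face_multiplier *
                          pot$i_ho[ir] / grid$dx[ir], 0)) /
    (config$electro$n_ho * FARADAY) / eps_s[ir]
  q_o2[ir] <- (eps_s[ir] * config$electro$a_v * pot$i_o2[ir] +
                 ifelse(seq_along(ir) %in% c(1, length(ir)) &
                          isTRUE(num$external_faces),
                        (1 - gas$eps_p) * num$external_face_multiplier *
                          pot$i_o2[ir] / grid$dx[ir], 0)) /
    (config$electro$n_o2 * FARADAY) / eps_s[ir]
  if (num$extra_source_ho != 0) q_ho[ir] <- q_ho[ir] + num$extra_source_ho

  # --- hydroxyl radicals: Picard sweeps on the linearized self-sink
  c_ho <- state$c_ho
  for (k in seq_len(max(1L, num$ho_picard_iter))) {
    l_ho <- 4 * kin$k_ho * c_ho + kin$k_pct * state$c_pct +
      kin$z_bp * kin$k_bp * state$c_bp
    st <- species_step(state$c_ho, v, eps_s, config$species$d_ho,
                       q_ho, l_ho, 0, dt, grid)
    c_ho <- st$c
  }
  audit_ho <- st$audit

  # --- paracetamol
  st_p <- species_step(state$c_pct, v, eps_s, config$species$d_pct,
                       numeric(n), kin$k_pct * c_ho, config$species$c0,
                       dt, grid)
  c_pct <- st_p$c

  # --- byproducts: produced by the PCT oxidation just computed
  p_bp <- kin$k_pct * c_pct * c_ho
  st_b <- species_step(state$c_bp, v, eps_s, config$species$d_bp,
                       p_bp, kin$k_bp * c_ho, 0, dt, grid)
  c_bp <- st_b$c

  # --- dissolved oxygen: recombination + electrode + volatilization exchange
  p_o2 <- kin$k_ho * c_ho^2 + q_o2
  l_o2 <- numeric(n)
  p_o2[ir] <- p_o2[ir] + gas$k_v * state$eps_g[ir] / gas$k_g
  l_o2[ir] <- gas$k_v * eps_s[ir]
  st_o <- species_step(state$c_o2, v, eps_s, config$species$d_o2,
                       p_o2, l_o2, 0, dt, grid)
  c_o2 <- st_o$c

  # --- gas fraction, exact exponential update (REM only)
  eps_g <- state$eps_g
  eps_g[ir] <- step_gas(state$eps_g[ir], c_o2[ir], dt, config)
  cap_hit <- any(eps_g[ir] >= gas$eps_g_cap - 1e-12)

  audit <- NULL
  if (isTRUE(num$audit)) {
    # carbon balance of the step (mol C, relative to domain inventory)
    nc <- kin$n_carbon_pct
    c_inv_new <- nc * sum(eps_s * grid$dx * (c_pct + c_bp))
    c_inv_old <- nc * sum(eps_s * grid$dx * (state$c_pct + state$c_bp))
    c_in <- nc * (v * config$species$c0 +
                    (eps_s[1] * config$species$d_pct /
                       (grid$x_c[1] - grid$x_f[1])) *
                    (config$species$c0 - c_pct[1]) +
                    (eps_s[1] * config$species$d_bp /
                       (grid$x_c[1] - grid$x_f[1])) * (0 - c_bp[1]))
    c_out <- nc * v * (c_pct[n] + c_bp[n])
    c_mineralized <- nc * sum(eps_s * grid$dx * kin$k_bp * c_bp * c_ho)
    c_resid <- abs((c_inv_new - c_inv_old) / dt -
                     (c_in - c_out - c_mineralized)) /
      max(c_inv_new / dt, abs(c_in), 1e-30)
    # O2 moles moved to gas vs k_g-weighted gas inventory change
    gas_gain <- sum(grid$dx[ir] * (eps_g[ir] - state$eps_g[ir])) / gas$k_g
    o2_sink <- dt * sum(grid$dx[ir] * eps_s[ir] * gas$k_v *
                          (eps_s[ir] * c_o2[ir] - state$eps_g[ir] / gas$k_g))
    o2_inventory <- sum(eps_s * grid$dx * c_o2) +
      sum(grid$dx[ir] * eps_g[ir]) / gas$k_g
    gas_resid <- abs(gas_gain - o2_sink) / max(o2_inventory, 1e-30)
    audit <- data.frame(
      t = t_new, dt = dt,
      charge_closure = abs(pot$closure),
      mass_ho = audit_ho, mass_pct = st_p$audit,
      mass_bp = st_b$audit, mass_o2 = st_o$audit,
      carbon = c_resid, gas_exchange = gas_resid,
      newton_iter = pot$iterations, cap_hit = cap_hit
    )
  }

  new_state <- state
  new_state$t <- t_new
  new_state$c_pct <- c_pct; new_state$c_bp <- c_bp
  new_state$c_ho <- c_ho; new_state$c_o2 <- c_o2
  new_state$eps_g <- eps_g
  new_state$phi_s <- pot$phi_s; new_state$phi_m <- pot$phi_m
  new_state$i_s <- pot$i_s; new_state$i_m <- pot$i_m
  new_state$i_ho <- pot$i_ho; new_state$i_o2 <- pot$i_o2
  new_state$p <- vel$p; new_state$v <- v
  list(state = new_state, audit = audit, i_tot = i_tot)
}

# Scalar observables of a state.
observe <- function(state, config, grid, i_tot) {
  ir <- grid$i_rem; n <- grid$n
  w <- grid$dx[ir]
  data.frame(
    t_s = state$t,
    flux_L_m2_h = permeate_flux_lmh(state$v),
    c_pct_out = state$c_pct[n],
    c_bp_out = state$c_bp[n],
    c_o2_out = state$c_o2[n],
    eps_g_mean = sum(state$eps_g[ir] * w) / sum(w),
    eps_g_max = max(state$eps_g[ir]),
    dphi_V = potential_drop(state, grid),
    i_tot_A_m2 = i_tot
  )
}

#' Run the full transient simulation
#'
#' Orchestrates the operator-split loop from the initial state to
#' \code{t_end}: galvanostatic current from the configured schedule, adaptive
#' time step (reset to \code{dt_init} at every schedule discontinuity, grown
#' geometrically to \code{dt_max}, halved on solver failure), scalar
#' observables recorded at every accepted step (thinned to at most
#' \code{max_records}), full profile snapshots at the requested times.
#' The model is deterministic: identical inputs give identical outputs.
#'
#' @param config validated configuration
#' @param t_end end time, s (default: end of the current schedule)
#' @param snapshot_times times (s) at which to store full spatial profiles
#' @param max_records cap on the number of recorded time-series rows
#' @param verbose print a progress line every 200 accepted steps
#' @return a \code{rem_result} list: \code{series} (data.frame of
#'   observables), \code{snapshots} (named list of states), \code{audit}
#'   (per-step conservation audit), \code{config}, \code{grid}
#' @export
run_simulation <- function(config, t_end = NULL,
                           snapshot_times = c(100, 5300),
                           max_records = 1e4, verbose = FALSE) {
  config <- validate_config(config)
  grid <- build_grid(config$geometry)
  sch <- config$electro$i_tot_schedule
  if (is.null(t_end)) t_end <- sch$t_end[nrow(sch)]
  if (t_end <= 0) stop("run_simulation: t_end must be > 0", call. = FALSE)
  snapshot_times <- snapshot_times[snapshot_times <= t_end]
  events <- sort(unique(c(
    sch$t_start[sch$t_start > 0 & sch$t_start < t_end],
    sch$t_end[sch$t_end > 0 & sch$t_end < t_end],
    snapshot_times, t_end)))

  num <- config$numerics
  state <- initial_state(config, grid)
  series <- vector("list", 4096)
  audits <- vector("list", 4096)
  snaps <- list()
  nrec <- 0L
  record_every <- 1L
  dt_cur <- num$dt_init
  pot_init <- NULL
  step_count <- 0L
  if (any(abs(snapshot_times) < 1e-12)) {
    snaps[["t=0"]] <- state
  }

  while (state$t < t_end - 1e-9) {
    next_event <- events[events > state$t + 1e-9][1]
    # keep the operator-split gas/O2 exchange well resolved: the gas
    # relaxation rate is k_v (1 + c_O2 k_g), which grows with supersaturation
    gas_rate_max <- config$gas$k_v *
      (1 + max(state$c_o2[grid$i_rem], 0) * config$gas$k_g)
    dt_gas <- (num$gas_dt_safety %||% 0.1) / gas_rate_max
    dt <- min(dt_cur, dt_gas, next_event - state$t)
    out <- NULL
    repeat {
      out <- tryCatch(rem_step(state, dt, config, grid, pot_init),
                      error = function(e) e)
      # accept only steps whose split-step gas/O2 exchange error is well
      # inside the audit tolerance; otherwise retry at half the step
      ok <- !inherits(out, "error") &&
        (is.null(out$audit) || out$audit$gas_exchange <= 8e-4 ||
           dt <= 4 * num$dt_min)
      if (ok) break
      dt <- dt / 2
      if (dt < num$dt_min) {
        stop(sprintf("run_simulation: step failed at t = %.6g s (%s)",
                     state$t,
                     if (inherits(out, "error")) conditionMessage(out)
                     else "gas-exchange error not reducible"), call. = FALSE)
      }
    }
    state <- out$state
    pot_init <- list(phi_s = state$phi_s, phi_m = state$phi_m)
    step_count <- step_count + 1L
    if (step_count %% record_every == 0L) {
      nrec <- nrec + 1L
      if (nrec > length(series)) {
        series <- c(series, vector("list", length(series)))
        audits <- c(audits, vector("list", length(audits)))
      }
      series[[nrec]] <- observe(state, config, grid, out$i_tot)
      audits[[nrec]] <- out$audit
      if (nrec >= max_records) record_every <- record_every * 2L
    }
    if (verbose && step_count %% 200L == 0L) {
      message(sprintf("  t = %8.1f s  dt = %6.3g  flux = %6.3f LMH  max eps_g = %.3f",
                      state$t, dt, permeate_flux_lmh(state$v),
                      max(state$eps_g)))
    }
    hit <- which(abs(snapshot_times - state$t) < 1e-9)
    if (length(hit)) snaps[[sprintf("t=%g", snapshot_times[hit[1]])]] <- state
    at_event <- abs(state$t - next_event) < 1e-9
    schedule_break <- at_event &&
      any(abs(c(sch$t_start, sch$t_end) - state$t) < 1e-9) &&
      state$t < t_end - 1e-9
    dt_cur <- if (schedule_break) num$dt_init else min(dt * num$dt_growth, num$dt_max)
  }

  res <- list(
    series = do.call(rbind, series[seq_len(nrec)]),
    snapshots = snaps,
    audit = if (isTRUE(num$audit)) do.call(rbind, audits[seq_len(nrec)]) else NULL,
    config = config, grid = grid
  )
  class(res) <- "rem_result"
  res
}

#' @export
print.rem_result <- function(x, ...) {
  s <- x$series
  cat("<rem_result>\n")
  cat(sprintf("  %d recorded steps, t in [%g, %g] s; %d snapshot(s)\n",
              nrow(s), min(s$t_s), max(s$t_s), length(x$snapshots)))
  cat(sprintf("  final flux %.3f L/m2/h | final mean eps_g %.4f | final dphi %.3f V\n",
              s$flux_L_m2_h[nrow(s)], s$eps_g_mean[nrow(s)], s$dphi_V[nrow(s)]))
  invisible(x)
}

#' Sweep over transmembrane pressures
#'
#' One full simulation per TMP value; per-run errors are collected rather
#' than fatal to the sweep.
#'
#' @param config validated configuration
#' @param tmp_values transmembrane pressures, Pa
#' @param ... passed to [run_simulation()]
#' @return named list of \code{rem_result} (or condition objects for failed
#'   runs), names \code{tmp=<Pa>}
#' @export
sweep_tmp <- function(config, tmp_values, ...) {
  if (length(tmp_values) == 0) stop("sweep_tmp: empty tmp_values", call. = FALSE)
  if (any(tmp_values < 0)) stop("sweep_tmp: TMP must be >= 0", call. = FALSE)
  out <- lapply(tmp_values, function(tmp) {
    cfg <- config
    cfg$flow$tmp <- tmp
    tryCatch(run_simulation(validate_config(cfg), ...), error = function(e) e)
  })
  names(out) <- sprintf("tmp=%g", tmp_values)
  out
}

#' Sweep over feed concentrations
#'
#' @param config validated configuration
#' @param toc_values feed TOC values, mgC/L
#' @param ... passed to [run_simulation()]
#' @return named list of \code{rem_result}, names \code{toc=<mgC/L>}
#' @export
sweep_toc <- function(config, toc_values, ...) {
  if (length(toc_values) == 0) stop("sweep_toc: empty toc_values", call. = FALSE)
  out <- lapply(toc_values, function(toc) {
    cfg <- config
    cfg$species$c0_toc <- toc
    tryCatch(run_simulation(validate_config(cfg), ...), error = function(e) e)
  })
  names(out) <- sprintf("toc=%g", toc_values)
  out
}
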