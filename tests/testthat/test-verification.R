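# Transport-free configuration: every cell becomes an isolated well-mixed
# reactor, which is exactly the system the 0D oracle integrates.
batch_config <- function(toc = 141, source = 2e-3) {
  cfg <- coarse_config(toc = toc)
  cfg$flow$tmp <- 0
  cfg$flow$zeta <- 0
  cfg$species$d_pct <- cfg$species$d_bp <- 1e-30
  cfg$species$d_ho <- cfg$species$d_o2 <- 1e-30
  cfg$electro$i_tot_schedule <- data.frame(t_start = 0, t_end = 4000, i_tot = 0)
  cfg$numerics$extra_source_ho <- source
  cfg$numerics$dt_max <- 2
  validate_config(cfg)
}

test_that("the oracle stays put without a radical source", {
  cfg <- batch_config(source = 0)
  orc <- batch_oracle(cfg, 0, 100, times = c(0, 50, 100))
  expect_equal(orc$c_pct, rep(cfg$species$c0, 3))
  expect_equal(orc$c_ho, rep(0, 3))
  expect_equal(orc$eps_g, rep(0, 3))
})

test_that("pure recombination reaches the square-root quasi-steady state", {
  cfg <- batch_config(toc = 0, source = 1e-6)
  orc <- batch_oracle(cfg, 1e-6, 2e4, times = c(0, 2e4))
  expect_equal(tail(orc$c_ho, 1),
               sqrt(1e-6 / (4 * cfg$kinetics$k_ho)), tolerance = 1e-3)
})

test_that("the PDE core reproduces the well-mixed oracle trajectories", {
  cfg <- batch_config(toc = 141, source = 2e-3)
  times <- seq(150, 1500, by = 150)
  res <- run_simulation(cfg, t_end = 1500, snapshot_times = times)
  orc <- batch_oracle(cfg, 2e-3, 1500, times = c(0, times))
  g <- res$grid
  mid <- g$i_rem[ceiling(g$n_rem / 2)]
  rel <- function(a, b, scale) abs(a - b) / max(scale, 1e-30)
  for (k in seq_along(times)) {
    st <- res$snapshots[[sprintf("t=%g", times[k])]]
    o <- orc[k + 1, ]
    expect_lt(rel(st$c_pct[mid], o$c_pct, cfg$species$c0), 0.01)
    expect_lt(rel(st$c_bp[mid], o$c_bp, max(orc$c_bp)), 0.01)
    expect_lt(rel(st$c_ho[mid], o$c_ho, max(orc$c_ho)), 0.01)
    expect_lt(rel(st$c_o2[mid], o$c_o2, max(orc$c_o2)), 0.01)
    expect_lt(rel(st$eps_g[mid], o$eps_g, max(orc$eps_g)), 0.01)
  }
})

test_that("limiting parameter values recover the simpler models", {
  # vanishing mass transfer: no gas ever forms
  cfg <- coarse_config(toc = 0)
  cfg$gas$k_v <- 1e-12
  cfg <- validate_config(cfg)
  res <- run_simulation(cfg, t_end = 200, snapshot_times = numeric(0))
  expect_lt(max(res$series$eps_g_max), 1e-8)

  # zero zeta: no flux jump at switch-on
  cfg2 <- coarse_config(toc = 0)
  cfg2$flow$zeta <- 0
  cfg2 <- validate_config(cfg2)
  res2 <- run_simulation(cfg2, t_end = 30, snapshot_times = numeric(0))
  expect_equal(res2$series$flux_L_m2_h[1],
               permeate_flux_lmh(plane_darcy_v(cfg2)), tolerance = 1e-9)

  # vanishing PCT reactivity decouples the organics from the gas budget
  cfg3 <- coarse_config(toc = 141)
  cfg3$kinetics$k_pct <- 1e-12
  cfg3$kinetics$k_bp <- 1e-12
  cfg3 <- validate_config(cfg3)
  res3 <- run_simulation(cfg3, t_end = 400, snapshot_times = numeric(0))
  res0 <- run_simulation(coarse_config(toc = 0), t_end = 400,
                         snapshot_times = numeric(0))
  expect_equal(tail(res3$series$eps_g_mean, 1),
               tail(res0$series$eps_g_mean, 1), tolerance = 1e-3)
  expect_equal(tail(res3$series$c_pct_out, 1) / cfg3$species$c0, 1,
               tolerance = 1e-3)
})

test_that("audit summaries flag nothing on a healthy run", {
  cfg <- coarse_config(toc = 141)
  cfg <- with_schedule(cfg, 120, 60)
  res <- run_simulation(cfg, t_end = 180, snapshot_times = numeric(0))
  audit <- conservation_audit(res)
  expect_length(audit$failures, 0)
  expect_lt(audit$max[["charge_closure"]], 1e-8)
  expect_lt(audit$max[["carbon"]], 1e-3)
  path <- tempfile(fileext = ".json")
  write_audit_json(audit, path)
  j <- jsonlite::read_json(path)
  expect_true(j$pass)
  unlink(path)
})
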