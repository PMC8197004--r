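# Coarse, fast configuration for unit tests: minimum admissible grid and a
# moderate step ceiling. Physics parameters stay at the reference defaults.
coarse_config <- function(toc = 141, tmp_mbar = 40) {
  cfg <- default_config(c0_toc = toc, tmp_mbar = tmp_mbar)
  cfg$geometry$n_cells_dl <- 4L
  cfg$geometry$n_cells_rem <- 24L
  cfg$numerics$dt_max <- 5
  validate_config(cfg)
}

# Short galvanostatic schedule for on/off behaviour tests.
with_schedule <- function(cfg, t_on, t_off, i_on = -300) {
  cfg$electro$i_tot_schedule <- data.frame(
    t_start = c(0, t_on), t_end = c(t_on, t_on + t_off), i_tot = c(i_on, 0))
  validate_config(cfg)
}

# Closed-form bubble-free pressure-driven superficial velocity.
plane_darcy_v <- function(cfg) {
  cfg$flow$sigma * cfg$flow$tmp / (cfg$flow$mu * cfg$geometry$d)
}
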