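test_that("electroosmotic velocity follows Helmholtz-Smoluchowski", {
  flow <- default_config()$flow
  flow$zeta <- 0
  expect_equal(electroosmotic_velocity(250, flow), 0)
  flow$zeta <- -20e-3
  # 0.5 V across 2 mm with -20 mV zeta gives ~3.98e-6 m/s toward the permeate
  v <- electroosmotic_velocity(0.5 / 2e-3, flow)
  expect_equal(v, 3.98e-6, tolerance = 1e-3)
  expect_gt(v, 0)
  # linear in zeta and in the potential gradient
  flow2 <- flow; flow2$zeta <- 3 * flow$zeta
  expect_equal(electroosmotic_velocity(250, flow2),
               3 * electroosmotic_velocity(250, flow))
  expect_equal(electroosmotic_velocity(500, flow),
               2 * electroosmotic_velocity(250, flow))
})

test_that("the blockage factor is a power law in the saturation", {
  expect_equal(blockage_factor(0.41, 0.41, 1.5), 1)
  expect_equal(blockage_factor(0.205, 0.41, 1.5), 0.5^1.5, tolerance = 1e-12)
  expect_equal(blockage_factor(0.205, 0.41, 1.5), 0.3536, tolerance = 2e-4)
  eps <- seq(0.05, 0.41, length.out = 20)
  expect_true(all(diff(blockage_factor(eps, 0.41, 2 / 3)) > 0))
  expect_error(blockage_factor(0, 0.41, 1.5), "closed")
  expect_error(blockage_factor(0.5, 0.41, 1.5), "exceed")
})

test_that("the velocity solve reduces to plane Darcy without gas or EO", {
  cfg <- coarse_config()
  cfg$flow$zeta <- 0
  cfg <- validate_config(cfg)
  g <- build_grid(cfg$geometry)
  out <- solve_velocity(numeric(g$n), numeric(g$n), g, cfg)
  expect_equal(out$v, plane_darcy_v(cfg), tolerance = 1e-12)
  # pressure spans TMP across the REM, flat in the diffusion layer
  expect_equal(out$p[g$i_dl], rep(cfg$flow$tmp, g$n_dl))
  expect_lt(abs(out$p[g$n] - 0), cfg$flow$tmp * 0.1)

  cfg0 <- cfg; cfg0$flow$tmp <- 0
  expect_equal(solve_velocity(numeric(g$n), numeric(g$n), g, cfg0)$v, 0)

  # uniform half-saturation scales the flux by exactly the blockage factor
  cfg15 <- cfg; cfg15$flow$blockage_exponent <- 1.5
  eps_g <- ifelse(g$in_rem, cfg$gas$eps_p / 2, 0)
  out2 <- solve_velocity(eps_g, numeric(g$n), g, cfg15)
  expect_equal(out2$v, 0.5^1.5 * plane_darcy_v(cfg), tolerance = 1e-12)
})

test_that("more gas never increases the permeate flux", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  set.seed(7)
  eps_g <- ifelse(g$in_rem, runif(g$n, 0, 0.3), 0)
  phi <- cumsum(rep(0.5 / g$n, g$n))          # a monotone potential profile
  v0 <- solve_velocity(eps_g, phi, g, cfg)$v
  for (j in sample(g$i_rem, 5)) {
    bumped <- eps_g
    bumped[j] <- min(bumped[j] + 0.05, cfg$gas$eps_g_cap)
    expect_lte(solve_velocity(bumped, phi, g, cfg)$v, v0 + 1e-15)
  }
})

test_that("bubble-free flux is Darcy plus the mean electroosmotic term", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  phi <- g$x_c * 250                          # uniform 250 V/m gradient
  out <- solve_velocity(numeric(g$n), phi, g, cfg)
  v_eo_mean <- sum(out$v_eo * g$dx[g$i_rem]) / sum(g$dx[g$i_rem])
  expect_equal(out$v, plane_darcy_v(cfg) + v_eo_mean, tolerance = 1e-10)
})

test_that("gas kinetics relax exponentially toward solubility equilibrium", {
  gas <- default_config()$gas
  # fixed point of the relaxation
  expect_equal(gas_rate(0.41, 2, 0.41 * 2 * gas$k_g, gas), 0)
  expect_equal(gas_rate(0.41, 1, 0, gas), 1.722e-5, tolerance = 1e-4)
  expect_error(gas_rate(0.41, NaN, 0, gas), "non-finite")

  cfg <- default_config()
  # pure decay at rate k_v when no dissolved oxygen remains
  out <- step_gas(0.1, 0, 1 / gas$k_v, cfg)
  expect_equal(out, 0.1 * exp(-1), tolerance = 1e-12)
  expect_equal(step_gas(0, 0, 100, cfg), 0)
  # enormous supersaturation plateaus exactly at the cap
  expect_equal(step_gas(0.2, 1e9, 1e6, cfg), gas$eps_g_cap)

  # the exact per-cell update agrees with an independent stiff integration
  # of d(eps_g)/dt = k_v((eps_p - eps_g) c k_g - eps_g) at fixed c
  c_o2 <- 12
  ode <- deSolve::lsoda(c(e = 0.05), c(0, 900), function(t, y, p) {
    list(gas$k_v * ((gas$eps_p - y) * c_o2 * gas$k_g - y))
  }, parms = NULL, rtol = 1e-12, atol = 1e-14)
  expect_equal(step_gas(0.05, c_o2, 900, cfg), unname(ode[2, "e"]),
               tolerance = 1e-6)
  # semigroup property: one exact step equals two half steps
  expect_equal(step_gas(0.05, c_o2, 900, cfg),
               step_gas(step_gas(0.05, c_o2, 450, cfg), c_o2, 450, cfg),
               tolerance = 1e-14)
})
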