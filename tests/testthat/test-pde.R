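test_that("a uniform field with no forcing is a steady state", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  eps_s <- ifelse(g$in_rem, cfg$gas$eps_p, 1)
  c0 <- rep(3.2, g$n)
  out <- species_step(c0, 0, eps_s, 1e-9, numeric(g$n), numeric(g$n),
                      3.2, 10, g)
  expect_equal(out$c, c0, tolerance = 1e-12)
  expect_lt(out$audit, 1e-10)
})

test_that("an inert tracer front arrives after the advective residence time", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  eps_s <- ifelse(g$in_rem, cfg$gas$eps_p, 1)
  v <- 1e-5
  t_res <- sum(eps_s * g$dx) / v
  c <- numeric(g$n)
  dt <- t_res / 400
  for (k in 1:400) {
    c <- species_step(c, v, eps_s, 1e-12, numeric(g$n), numeric(g$n),
                      1, dt, g)$c
  }
  # first-order upwinding smears the front; coarse tolerance
  expect_gt(c[g$n], 0.25)
  expect_lt(c[g$n], 0.75)
})

test_that("each implicit step conserves mass discretely", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  eps_s <- ifelse(g$in_rem, cfg$gas$eps_p, 1)
  set.seed(11)
  c <- runif(g$n, 0, 2)
  p_src <- runif(g$n, 0, 1e3)
  l_src <- runif(g$n, 0, 1e5)
  out <- species_step(c, 3e-6, eps_s, 2.2e-9, p_src, l_src, 1.4, 2, g)
  expect_lt(out$audit, 1e-8)
  expect_true(all(out$c >= 0))
})

test_that("the zero-current limit has flat potentials and no reaction", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  pot <- solve_potentials(numeric(g$n), 0, cfg, g)
  expect_equal(pot$phi_s, numeric(g$n))
  expect_equal(pot$i_ho, numeric(g$n))
  expect_equal(pot$i_m, rep(0, g$n + 1))
})

test_that("the galvanostatic solve closes the charge balance", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  pot <- solve_potentials(numeric(g$n), -300, cfg, g)
  expect_lt(abs(pot$closure), 1e-8)
  # both phases share the total current at every face
  expect_equal(pot$i_s + pot$i_m, rep(-300, g$n + 1), tolerance = 1e-10)
  # the reported face currents agree with the solved potential gradients
  ir_f <- (g$n_dl + 1):(g$n - 1)               # interior faces inside the REM
  ts <- remoxsim:::face_transmissibility(
    ifelse(g$in_rem, cfg$gas$eps_p, 1) * cfg$electro$kappa_s, g)
  i_s_from_phi <- -ts[ir_f] * diff(pot$phi_s)[ir_f]
  expect_equal(-i_s_from_phi, abs(pot$i_s[ir_f + 1]), tolerance = 1e-6)
  # the feed boundary of the solution phase is grounded
  expect_lt(abs(pot$phi_s[1]), 0.02)
})

test_that("doubling both conductivities halves the ohmic drop", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  p1 <- solve_potentials(numeric(g$n), -300, cfg, g)
  cfg2 <- cfg
  cfg2$electro$kappa_s <- 2 * cfg$electro$kappa_s
  cfg2$electro$kappa_m <- 2 * cfg$electro$kappa_m
  p2 <- solve_potentials(numeric(g$n), -300, cfg2, g)
  d1 <- abs(p1$phi_s[g$n] - p1$phi_s[g$n_dl + 1])
  d2 <- abs(p2$phi_s[g$n] - p2$phi_s[g$n_dl + 1])
  # the redistribution of the reaction current with the changed ohmic
  # resistance shifts the ratio a few percent away from exact halving
  expect_equal(d2 / d1, 0.5, tolerance = 0.05)
})

test_that("external face reactions boost the boundary cells", {
  cfg <- coarse_config()
  g <- build_grid(cfg$geometry)
  pot <- solve_potentials(numeric(g$n), -300, cfg, g)
  st <- initial_state(cfg, g)
  st$phi_s <- pot$phi_s; st$phi_m <- pot$phi_m
  ext <- external_surface_sources(st, cfg, g)
  expect_true(all(ext$q_extra_A_m3[c(1, g$n_rem)] > 0))
  expect_equal(sum(ext$q_extra_A_m3 != 0), 2)
  # linear in the configured multiplier
  cfg3 <- cfg; cfg3$numerics$external_face_multiplier <- 3
  ext3 <- external_surface_sources(st, cfg3, g)
  expect_equal(ext3$q_extra_A_m3, 3 * ext$q_extra_A_m3)
  cfg0 <- cfg; cfg0$numerics$external_faces <- FALSE
  expect_equal(external_surface_sources(st, cfg0, g)$q_extra_A_m3,
               numeric(g$n_rem))
  # with faces on, the boundary generation density exceeds the interior's
  mid <- ceiling(g$n_rem / 2)
  q_rem <- pot$q[g$i_rem]
  expect_gt(q_rem[1], q_rem[mid])
  expect_gt(q_rem[g$n_rem], q_rem[mid])
})

test_that("the initial state matches the pristine feed conditions", {
  cfg <- coarse_config(toc = 141)
  st <- initial_state(cfg)
  expect_equal(max(abs(st$c_ho)), 0)
  expect_equal(max(abs(st$c_o2)), 0)
  expect_equal(max(abs(st$c_bp)), 0)
  expect_equal(max(abs(st$eps_g)), 0)
  expect_equal(st$c_pct, rep(toc_to_molar(141, 8), length(st$c_pct)))
  expect_equal(st$v, plane_darcy_v(cfg), tolerance = 1e-12)
})
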