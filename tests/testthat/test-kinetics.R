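kin <- default_config()$kinetics

test_that("homogeneous rates follow the second-order laws", {
  expect_equal(homogeneous_rates(0, 5, 3, kin),
               list(r_ho = 0, r_pct = 0, r_bp = 0))
  r <- homogeneous_rates(1e-3, 0.1842, 0, kin)
  expect_equal(r$r_ho, 5.5, tolerance = 1e-12)           # k_ho * (1e-3)^2
  expect_equal(r$r_pct, 1.842e3, tolerance = 1e-12)      # k_pct * c_pct * c_ho
  expect_equal(r$r_bp, 0)
  # reaction orders: doubling c_ho quadruples recombination, doubles oxidation
  r2 <- homogeneous_rates(2e-3, 0.1842, 0.05, kin)
  expect_equal(r2$r_ho / r$r_ho, 4)
  expect_equal(r2$r_pct / r$r_pct, 2)
  expect_warning(homogeneous_rates(-1e-9, 1, 1, kin), "clipped")
  expect_error(homogeneous_rates(NaN, 1, 1, kin), "non-finite")
})

test_that("Butler-Volmer kinetics are exponential in the overpotential", {
  e <- default_config()$electro
  # zero overpotential returns the exchange current in both conventions
  expect_equal(butler_volmer(e$e0_ho, 0, e$e0_ho, -1e-6, 0.5, 1, 298.15),
               1e-6)
  expect_equal(butler_volmer(e$e0_ho, 0, e$e0_ho, -1e-6, 0.5, 1, 298.15,
                             sign_convention = "printed"), -1e-6)
  expect_equal(butler_volmer(2, 0, 1.7, 0, 0.5, 1, 298.15), 0)
  # one decade per ln10 * RT / (beta n F) = 118.3 mV for beta*n = 0.5
  decade <- log(10) * 8.314 * 298.15 / (0.5 * 96485.33)
  expect_equal(decade, 0.11831, tolerance = 1e-4)
  i1 <- butler_volmer(2.0, 0, 1.7, -1e-6, 0.5, 1, 298.15)
  i2 <- butler_volmer(2.0 + decade, 0, 1.7, -1e-6, 0.5, 1, 298.15)
  expect_equal(i2 / i1, 10, tolerance = 1e-12)
  # strict monotonicity and exact exponentiality (midpoint identity)
  eta <- c(0.1, 0.25, 0.4)
  iv <- butler_volmer(1.7 + eta, 0, 1.7, -1e-6, 0.5, 1, 298.15)
  expect_true(all(diff(iv) > 0))
  expect_equal(iv[1] * iv[3], iv[2]^2, tolerance = 1e-12)
  # the printed convention grows in the opposite direction
  ip <- butler_volmer(1.7 + eta, 0, 1.7, -1e-6, 0.5, 1, 298.15, "printed")
  expect_true(all(diff(abs(ip)) < 0))
  expect_warning(butler_volmer(1e4, 0, 1.7, -1e-6, 0.5, 1, 298.15), "capped")
  expect_error(butler_volmer(2, 0, 1.7, -1e-6, 0.5, 1, -5), "temperature")
})

test_that("net source terms respect the reaction stoichiometry", {
  cfg <- default_config()
  n <- 5
  zero <- species_sources(list(r_ho = numeric(n), r_pct = numeric(n),
                               r_bp = numeric(n)),
                          numeric(n), numeric(n), numeric(n),
                          rep(0.41, n), numeric(n), numeric(n),
                          rep(TRUE, n), cfg)
  for (f in c("R_ho", "R_pct", "R_bp", "R_o2")) expect_equal(zero[[f]], rep(0, n))
  # four radicals recombine into one O2
  s <- species_sources(list(r_ho = 1, r_pct = 0, r_bp = 0),
                       0, 0, 0, 0.41, 0, 0, TRUE, cfg)
  expect_equal(s$R_o2, 1)
  expect_equal(s$R_ho, -4)
  # each oxidized PCT molecule becomes one byproduct molecule
  s2 <- species_sources(list(r_ho = 0, r_pct = 2, r_bp = 0),
                        0, 0, 0, 0.41, 0, 0, TRUE, cfg)
  expect_equal(s2$R_bp, 2)
  expect_equal(s2$R_pct, -2)
})

test_that("radical and carbon bookkeeping hold for random states", {
  cfg <- default_config()
  set.seed(42)
  for (rep in 1:20) {
    c_ho <- runif(1, 0, 1e-2); c_pct <- runif(1, 0, 2); c_bp <- runif(1, 0, 2)
    i_ho <- runif(1, 0, 0.05); i_o2 <- runif(1, 0, 0.05)
    eps_g <- runif(1, 0, 0.3); eps_s <- 0.41 - eps_g
    r <- homogeneous_rates(c_ho, c_pct, c_bp, cfg$kinetics)
    s <- species_sources(r, i_ho, i_o2, runif(1, 0, 50), eps_s, eps_g,
                         cfg$electro$a_v, TRUE, cfg)
    s_ho <- i_ho * cfg$electro$a_v / (cfg$electro$n_ho * 96485.33)
    resid <- s$R_ho + 4 * r$r_ho + r$r_pct + cfg$kinetics$z_bp * r$r_bp - s_ho
    expect_lt(abs(resid) / max(abs(s$R_ho), s_ho, 1e-30), 1e-12)
    # byproduct creation exactly matches PCT destruction
    expect_equal(s$R_bp - (r$r_pct - r$r_bp), 0)
    expect_equal(s$R_pct, -r$r_pct)
    expect_lte(s$R_pct, 0)
  }
})
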