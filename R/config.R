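#' Default model configuration
#'
#' Builds the full model configuration with the reference parameter set used
#' throughout: second-order rate constants for the hydroxyl-radical reactions,
#' diffusion coefficients of the four transported species, membrane geometry,
#' dual-phase conductivities, Butler-Volmer parameters, Darcy permeability,
#' electroosmotic (zeta) parameters, and the gas-fraction coefficients. All
#' values are stored in SI units; the galvanostatic schedule defaults to
#' -300 A/m2 for 90 min followed by 50 min at zero current.
#'
#' Two entries of the printed reference table required interpretation and are
#' therefore deliberately exposed as plain config values: the Darcy
#' permeability defaults to \code{sigma = 1.6e-14} m2 (the printed mantissa
#' 1.6 with its exponent restored from a Hagen-Poiseuille estimate for the
#' membrane's 1.4 um pores at porosity 0.41) and the gas-blockage exponent
#' defaults to 2/3. The methods vignette discusses both choices and their
#' sensitivity.
#'
#' @param c0_toc feed total organic carbon, mgC/L (default 141)
#' @param tmp_mbar transmembrane pressure, mbar (default 40)
#' @return an object of class \code{rem_config} (a validated nested list)
#' @export
default_config <- function(c0_toc = 141, tmp_mbar = 40) {
  cfg <- list(
    geometry = list(
      delta = 30e-6,          # diffusion-layer thickness, m
      d = 2e-3,               # REM thickness, m
      n_cells_dl = 8L,
      n_cells_rem = 60L,
      refine_ratio_dl = 1.3,  # geometric refinement toward x = 0
      refine_ratio_rem = 1.18 # refinement toward both REM faces
    ),
    kinetics = list(
      k_pct = 1e7,            # m3/mol/s
      k_bp = 1.2e7,           # m3/mol/s (hydroquinone as lumped byproduct)
      k_ho = 5.5e6,           # m3/mol/s (radical recombination, lumped)
      z_bp = 27L,             # HO* consumed per byproduct molecule
      n_carbon_pct = 8L       # carbons per paracetamol molecule (C8H9NO2)
    ),
    electro = list(
      kappa_s = 1.3,          # S/m, solution phase
      kappa_m = 1.3,          # S/m, anode matrix phase
      a_v = 1.7e8,            # 1/m specific surface area
      i0_ho = -1e-6,          # A/m2 exchange current density, HO* generation
      i0_o2 = -1e-6,          # A/m2 exchange current density, O2 evolution
      e0_ho = 1.7,            # V formal potential, HO* generation
      e0_o2 = 2.05,           # V formal potential, O2 evolution
      beta = 0.5,             # symmetry coefficient
      n_ho = 1L,
      n_o2 = 4L,
      temperature = 298.15,   # K
      sign_convention = "anodic",  # "anodic" or "printed", see vignette
      i_tot_schedule = data.frame(
        t_start = c(0, 90 * 60),
        t_end = c(90 * 60, 140 * 60),
        i_tot = c(-300, 0)    # A/m2, galvanostatic
      )
    ),
    flow = list(
      sigma = 1.6e-14,        # m2, Darcy permeability (see vignette: exponent
                              # restored via Hagen-Poiseuille for 1.4 um pores)
      mu = 8.9e-4,            # Pa s
      tmp = tmp_mbar * 100,   # Pa (feed-minus-permeate driving pressure)
      eps_r = 80,             # relative permittivity
      eps0 = VACUUM_PERMITTIVITY,
      zeta = -22e-3,          # V
      blockage_exponent = 2 / 3
    ),
    gas = list(
      k_v = 6e-4,             # 1/s, gas/solution mass-transfer coefficient
      k_g = 0.07,             # m3/mol, volatility coefficient
      eps_p = 0.41,           # REM porosity
      eps_g_cap = 0.95 * 0.41 # maximum allowed gas fraction
    ),
    species = list(
      d_pct = 0.65e-9,        # m2/s
      d_bp = 2.7e-10,         # m2/s (hydroquinone)
      d_ho = 2.2e-9,          # m2/s
      d_o2 = 2.2e-9,          # m2/s
      c0_toc = c0_toc,        # mgC/L
      c0 = NA_real_           # mol/m3, derived in validate_config()
    ),
    numerics = list(
      dt_init = 1e-2,         # s, after a schedule discontinuity
      dt_max = 10,            # s
      dt_min = 1e-6,          # s
      dt_growth = 1.3,
      newton_tol = 1e-11,     # relative residual, potential solve
      newton_max_iter = 60L,
      exp_cap = 200,          # cap on Butler-Volmer exponent argument
      ho_picard_iter = 3L,    # Picard sweeps on the radical balance per step
      gas_dt_safety = 0.004,  # dt cap as a fraction of the gas relaxation time
      external_faces = TRUE,  # planar electrode reaction at x = 0 and x = d
      external_face_multiplier = 1,
      extra_source_ho = 0,    # mol/m3/s prescribed HO* source (testing hook)
      audit = TRUE
    )
  )
  validate_config(cfg)
}

#' Convert a TOC load to a molar concentration
#'
#' TOC in mgC/L is numerically gC/m3; dividing by the molar mass of carbon
#' and the number of carbon atoms per molecule gives mol/m3.
#'
#' @param toc total organic carbon, mgC/L
#' @param n_carbon carbon atoms per molecule
#' @return concentration in mol/m3
#' @export
toc_to_molar <- function(toc, n_carbon) {
  if (any(!is.finite(toc)) || any(toc < 0)) {
    stop("toc_to_molar: 'toc' must be finite and non-negative", call. = FALSE)
  }
  if (any(n_carbon < 1)) {
    stop("toc_to_molar: 'n_carbon' must be >= 1", call. = FALSE)
  }
  toc / CARBON_MOLAR_MASS / n_carbon
}

#' CO2 that complete mineralization of a TOC load could release
#'
#' Every organic carbon atom ends as one CO2 molecule, so the ceiling on the
#' dissolved CO2 concentration is TOC divided by the molar mass of carbon.
#'
#' @param toc total organic carbon, mgC/L
#' @return CO2 concentration in mmol/L
#' @export
co2_mineralization_yield <- function(toc) {
  if (any(!is.finite(toc)) || any(toc < 0)) {
    stop("co2_mineralization_yield: 'toc' must be finite and non-negative",
         call. = FALSE)
  }
  toc / CARBON_MOLAR_MASS
}

#' Validate a model configuration
#'
#' Checks every invariant of the configuration (positivity of physical
#' parameters, porosity and gas-cap ranges, non-overlapping contiguous current
#' schedule, minimum cell counts) and populates derived quantities: the feed
#' molar concentration \code{species$c0} from \code{species$c0_toc}.
#' Each violation produces a named, human-readable error.
#'
#' @param config a configuration list as produced by [default_config()]
#' @return the validated configuration, class \code{rem_config}
#' @export
validate_config <- function(config) {
  fail <- function(name, msg) stop(sprintf("[%s] %s", name, msg), call. = FALSE)
  g <- config$geometry
  if (!is.numeric(g$delta) || g$delta <= 0) fail("geometry", "delta must be > 0")
  if (!is.numeric(g$d) || g$d <= 0) fail("geometry", "d must be > 0")
  if (g$n_cells_dl < 4) fail("geometry", "n_cells_dl must be >= 4")
  if (g$n_cells_rem < 20) fail("geometry", "n_cells_rem must be >= 20")

  k <- config$kinetics
  if (any(c(k$k_pct, k$k_bp, k$k_ho) <= 0)) fail("kinetics", "rate constants must be > 0")
  if (k$z_bp < 1 || k$z_bp != round(k$z_bp)) fail("kinetics", "z_bp must be an integer >= 1")

  e <- config$electro
  if (any(c(e$kappa_s, e$kappa_m, e$a_v) <= 0)) {
    fail("electro", "kappa_s, kappa_m and a_v must be > 0")
  }
  if (e$beta <= 0 || e$beta >= 1) fail("electro", "beta must lie in (0, 1)")
  if (e$temperature <= 0) fail("electro", "temperature must be > 0 K")
  if (!e$sign_convention %in% c("anodic", "printed")) {
    fail("electro", "sign_convention must be 'anodic' or 'printed'")
  }
  sch <- e$i_tot_schedule
  if (!is.data.frame(sch) || nrow(sch) < 1 ||
      !all(c("t_start", "t_end", "i_tot") %in% names(sch))) {
    fail("schedule", "i_tot_schedule needs columns t_start, t_end, i_tot")
  }
  sch <- sch[order(sch$t_start), , drop = FALSE]
  if (any(sch$t_end <= sch$t_start)) fail("schedule", "intervals must have t_end > t_start")
  if (nrow(sch) > 1 && any(abs(sch$t_start[-1] - sch$t_end[-nrow(sch)]) > 1e-9)) {
    fail("schedule", "intervals must be contiguous and non-overlapping")
  }
  config$electro$i_tot_schedule <- sch

  f <- config$flow
  if (f$sigma <= 0) fail("flow", "sigma (permeability) must be > 0")
  if (f$mu <= 0) fail("flow", "mu (viscosity) must be > 0")
  if (f$tmp < 0) fail("flow", "tmp must be >= 0")
  if (f$blockage_exponent <= 0) fail("flow", "blockage_exponent must be > 0")

  gs <- config$gas
  if (gs$k_v <= 0 || gs$k_g <= 0) fail("gas", "k_v and k_g must be > 0")
  if (gs$eps_p <= 0 || gs$eps_p >= 1) fail("gas", "porosity eps_p must lie in (0, 1)")
  if (gs$eps_g_cap <= 0 || gs$eps_g_cap >= gs$eps_p) {
    fail("gas", "eps_g_cap must lie in (0, eps_p)")
  }

  s <- config$species
  if (any(c(s$d_pct, s$d_bp, s$d_ho, s$d_o2) <= 0)) {
    fail("species", "diffusion coefficients must be > 0")
  }
  if (s$c0_toc < 0) fail("species", "c0_toc must be >= 0")
  config$species$c0 <- toc_to_molar(s$c0_toc, config$kinetics$n_carbon_pct)

  class(config) <- "rem_config"
  config
}

#' @export
print.rem_config <- function(x, ...) {
  cat("<rem_config>\n")
  cat(sprintf("  feed TOC: %g mgC/L (c0 = %.4g mol/m3)\n",
              x$species$c0_toc, x$species$c0))
  cat(sprintf("  TMP: %g mbar | sigma = %g m2 | zeta = %g mV\n",
              x$flow$tmp / 100, x$flow$sigma, x$flow$zeta * 1e3))
  cat(sprintf("  geometry: delta = %g um, d = %g mm, cells %d + %d\n",
              x$geometry$delta * 1e6, x$geometry$d * 1e3,
              x$geometry$n_cells_dl, x$geometry$n_cells_rem))
  sch <- x$electro$i_tot_schedule
  cat("  schedule (A/m2):",
      paste(sprintf("[%g, %g] min: %g", sch$t_start / 60, sch$t_end / 60,
                    sch$i_tot), collapse = "; "), "\n")
  invisible(x)
}

#' Current density at a given time from the galvanostatic schedule
#'
#' @param config validated configuration
#' @param t time, s
#' @return signed total current density, A/m2 (0 beyond the schedule)
#' @export
current_at <- function(config, t) {
  sch <- config$electro$i_tot_schedule
  hit <- which(t >= sch$t_start & t < sch$t_end)
  if (length(hit) == 0) {
    # the exact end instant of the last interval belongs to it
    if (abs(t - sch$t_end[nrow(sch)]) < 1e-12) return(sch$i_tot[nrow(sch)])
    return(0)
  }
  sch$i_tot[hit[1]]
}

#' Read a model configuration from a YAML file
#'
#' Keys are SI except a few explicitly suffixed convenience keys:
#' \code{flow$tmp_mbar}, \code{flow$zeta_mV}, \code{species$toc_mgC_per_L},
#' and schedule columns \code{t_start_min}/\code{t_end_min}. Any key absent
#' from the file keeps its default.
#'
#' @param path path to a YAML configuration file
#' @return validated \code{rem_config}
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  for (section in intersect(names(user), names(cfg))) {
    sec <- user[[section]]
    if (section == "electro" && !is.null(sec$i_tot_schedule)) {
      sch <- as.data.frame(do.call(rbind, lapply(sec$i_tot_schedule, as.data.frame)))
      if (all(c("t_start_min", "t_end_min") %in% names(sch))) {
        sch$t_start <- sch$t_start_min * 60
        sch$t_end <- sch$t_end_min * 60
        sch$t_start_min <- sch$t_end_min <- NULL
      }
      cfg$electro$i_tot_schedule <- sch[, c("t_start", "t_end", "i_tot")]
      sec$i_tot_schedule <- NULL
    }
    # convenience unit-suffixed keys
    if (section == "flow") {
      if (!is.null(sec$tmp_mbar)) { sec$tmp <- sec$tmp_mbar * 100; sec$tmp_mbar <- NULL }
      if (!is.null(sec$zeta_mV)) { sec$zeta <- sec$zeta_mV * 1e-3; sec$zeta_mV <- NULL }
    }
    if (section == "species" && !is.null(sec$toc_mgC_per_L)) {
      sec$c0_toc <- sec$toc_mgC_per_L
      sec$toc_mgC_per_L <- NULL
    }
    for (key in intersect(names(sec), names(cfg[[section]]))) {
      cfg[[section]][[key]] <- sec[[key]]
    }
  }
  validate_config(cfg)
}

#' Write a model configuration to a YAML file
#'
#' Round-trips through [read_config()]: all fields are written in SI.
#'
#' @param config validated configuration
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  sch <- cfg$electro$i_tot_schedule
  cfg$electro$i_tot_schedule <- lapply(seq_len(nrow(sch)), function(i) {
    list(t_start = sch$t_start[i], t_end = sch$t_end[i], i_tot = sch$i_tot[i])
  })
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}
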