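#' Write the observable time series of a run as CSV
#'
#' Plain CSV, '.' decimal separator, header row with units embedded in the
#' column names.
#'
#' @param result a \code{rem_result}
#' @param path output path
#' @return `path`, invisibly
#' @export
write_series_csv <- function(result, path) {
  utils::write.csv(result$series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# One snapshot state as a per-cell data.frame.
snapshot_frame <- function(state, grid) {
  n <- grid$n
  data.frame(
    x_m = grid$x_c,
    c_pct = state$c_pct, c_bp = state$c_bp,
    c_ho = state$c_ho, c_o2 = state$c_o2,
    eps_g = state$eps_g,
    phi_s = state$phi_s, phi_m = state$phi_m,
    i_s = (state$i_s[1:n] + state$i_s[2:(n + 1)]) / 2,
    i_m = (state$i_m[1:n] + state$i_m[2:(n + 1)]) / 2,
    p = state$p
  )
}

#' Write profile snapshots as CSV files
#'
#' One file per stored snapshot (\code{snapshot_<t>s.csv}), one row per
#' cell: coordinate, the four concentrations, gas fraction, both potentials,
#' cell-averaged phase currents and pressure.
#'
#' @param result a \code{rem_result}
#' @param dir output directory (created if needed)
#' @return character vector of written paths, invisibly
#' @export
write_snapshot_csv <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (key in names(result$snapshots)) {
    t <- sub("^t=", "", key)
    p <- file.path(dir, sprintf("snapshot_%ss.csv", t))
    utils::write.csv(snapshot_frame(result$snapshots[[key]], result$grid),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# MD5 of a configuration via its serialized YAML form.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' Records the configuration hash, package version, wall-clock interval,
#' output paths and the audit summary. Written atomically (temp file then
#' rename) after a successful run.
#'
#' @param result a \code{rem_result}
#' @param path output JSON path
#' @param outputs character vector of output file paths
#' @param started POSIXct start time of the run
#' @param overrides named list of CLI/config overrides applied (may be empty)
#' @return `path`, invisibly
#' @export
write_manifest <- function(result, path, outputs = character(0),
                           started = Sys.time(), overrides = list()) {
  audit <- tryCatch(conservation_audit(result), error = function(e) NULL)
  manifest <- list(
    config_hash = config_hash(result$config),
    package_version = as.character(utils::packageVersion("remoxsim")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs),
    overrides = overrides,
    audit = if (!is.null(audit)) {
      list(max_residuals = as.list(audit$max),
           failures = audit$failures,
           pass = length(audit$failures) == 0)
    }
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}
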