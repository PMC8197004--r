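# Geometric cell widths for one region. refine = "end" makes the last cell
# the finest, "both" refines toward both ends, "none" is uniform. ratio is
# the growth factor between neighbouring cells (1 -> uniform).
geometric_widths <- function(length_m, n, ratio, refine = c("none", "end", "both")) {
  refine <- match.arg(refine)
  if (ratio <= 0) stop("refinement ratio must be > 0", call. = FALSE)
  if (refine == "none" || abs(ratio - 1) < 1e-12) {
    return(rep(length_m / n, n))
  }
  if (refine == "end") {
    w <- ratio^((n - 1):0)          # widths shrink toward the end
    return(w / sum(w) * length_m)
  }
  # "both": two mirrored geometric halves (n may be odd)
  n1 <- ceiling(n / 2); n2 <- n - n1
  w1 <- ratio^(0:(n1 - 1))          # grow away from the left face
  w2 <- if (n2 > 0) ratio^((n2 - 1):0) else numeric(0)
  w <- c(w1, w2)
  w / sum(w) * length_m
}

#' Build the two-region finite-volume grid
#'
#' The domain spans \eqn{[-\delta, d]}: a free-solution diffusion layer on
#' \eqn{[-\delta, 0]} and the porous electrode (REM) on \eqn{[0, d]}, with a
#' cell face exactly at \eqn{x = 0}. By default the mesh is refined toward
#' \eqn{x = 0} in the diffusion layer and toward both faces of the REM, where
#' the reaction-rate and concentration gradients are steepest.
#'
#' @param geometry the \code{geometry} section of a configuration
#' @return a \code{rem_grid} list: face/centre coordinates, cell widths,
#'   region flags, per-cell porosity and specific surface area
#' @export
build_grid <- function(geometry) {
  n_dl <- as.integer(geometry$n_cells_dl)
  n_rem <- as.integer(geometry$n_cells_rem)
  if (n_dl < 4 || n_rem < 20) {
    stop("build_grid: need n_cells_dl >= 4 and n_cells_rem >= 20", call. = FALSE)
  }
  w_dl <- geometric_widths(geometry$delta, n_dl,
                           geometry$refine_ratio_dl %||% 1, "end")
  w_rem <- geometric_widths(geometry$d, n_rem,
                            geometry$refine_ratio_rem %||% 1, "both")
  dx <- c(w_dl, w_rem)
  x_f <- -geometry$delta + c(0, cumsum(dx))
  x_f[n_dl + 1] <- 0                      # face at the region boundary, exactly
  x_f[length(x_f)] <- geometry$d
  x_c <- (x_f[-1] + x_f[-length(x_f)]) / 2
  n <- n_dl + n_rem
  region <- c(rep("dl", n_dl), rep("rem", n_rem))
  g <- list(
    n = n, n_dl = n_dl, n_rem = n_rem,
    x_f = x_f, x_c = x_c, dx = dx,
    region = region,
    i_dl = seq_len(n_dl), i_rem = n_dl + seq_len(n_rem),
    in_rem = region == "rem",
    face0 = n_dl + 1L                      # index of the face at x = 0
  )
  class(g) <- "rem_grid"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cell-centred gradient of a cell field, from neighbouring centres
# (one-sided at the domain ends).
cell_gradient <- function(phi, grid) {
  n <- grid$n
  g <- numeric(n)
  if (n >= 3) {
    g[2:(n - 1)] <- (phi[3:n] - phi[1:(n - 2)]) /
      (grid$x_c[3:n] - grid$x_c[1:(n - 2)])
  }
  g[1] <- (phi[2] - phi[1]) / (grid$x_c[2] - grid$x_c[1])
  g[n] <- (phi[n] - phi[n - 1]) / (grid$x_c[n] - grid$x_c[n - 1])
  g
}
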