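species_values <- function(state, species = NULL) {
  if (is.null(species)) total_density(state)
  else matrix(state$rho[, , species], nrow = state$grid$nx)
}

outermost_crossing <- function(pos, val, threshold) {
  above <- which(val >= threshold)
  if (length(above) == 0) return(NA_real_)
  i <- max(above)
  if (i == length(val)) return(pos[i])  # front not contained in the domain
  pos[i] + (val[i] - threshold) / (val[i] - val[i + 1]) * (pos[i + 1] - pos[i])
}

#' Angularly averaged radial density profile
#'
#' Averages a 2D field over annuli of width `h` about `center`; for radial
#' grids the stored profile is returned directly. The mass of the binned
#' profile, computed as `sum(density * n_cells * h^2)`, equals the field
#' mass exactly, since every cell contributes to exactly one annulus.
#'
#' @param state A [tissue_state()].
#' @param center Centre of the annuli (mm), cartesian grids only; must lie
#'   inside the domain.
#' @param species Species index, or `NULL` for the total density.
#' @return A data.frame with columns `radius` (bin centre, mm), `density`
#'   (mean cells mm^-2) and `n_cells`.
#' @export
radial_profile <- function(state, center = NULL, species = NULL) {
  stopifnot(inherits(state, "tissue_state"))
  g <- state$grid
  v <- species_values(state, species)
  if (g$mode == "radial1d") {
    return(data.frame(radius = grid_coords(g)$r, density = as.numeric(v),
                      n_cells = 1L))
  }
  co <- grid_coords(g)
  if (is.null(center)) center <- c(mean(range(co$x)), mean(range(co$y)))
  if (center[1] < co$x[1] - g$h / 2 || center[1] > co$x[g$nx] + g$h / 2 ||
      center[2] < co$y[1] - g$h / 2 || center[2] > co$y[g$ny] + g$h / 2)
    stop("center lies outside the domain")
  rr <- sqrt(outer(co$x - center[1], rep(1, g$ny))^2 +
             outer(rep(1, g$nx), co$y - center[2])^2)
  bin <- pmax(1L, ceiling(rr / g$h))
  dens <- as.numeric(tapply(as.numeric(v), bin, mean))
  cnt <- as.integer(table(bin))
  data.frame(radius = (as.integer(names(table(bin))) - 0.5) * g$h,
             density = dens, n_cells = cnt)
}

#' Position of the expansion front
#'
#' The outermost location at which the (linearly interpolated) density
#' profile crosses `threshold`. Radial states use the stored profile;
#' planar 1D states (`ny = 1`) use the profile along x; full 2D states are
#' first reduced with [radial_profile()] about `center`.
#'
#' @param state A [tissue_state()].
#' @param threshold Density threshold (cells mm^-2), `> 0`; default 10, a
#'   conventional visualisation cutoff for monolayer densities.
#' @param species Species index, or `NULL` for the total density.
#' @param center Profile centre for 2D states (see [radial_profile()]).
#' @return Front position (mm), or `NA` when the field nowhere reaches
#'   `threshold`.
#' @export
front_position <- function(state, threshold = 10, species = NULL, center = NULL) {
  stopifnot(inherits(state, "tissue_state"), threshold > 0)
  g <- state$grid
  if (g$mode == "radial1d") {
    outermost_crossing(grid_coords(g)$r, as.numeric(species_values(state, species)),
                       threshold)
  } else if (g$ny == 1L) {
    outermost_crossing(grid_coords(g)$x, as.numeric(species_values(state, species)),
                       threshold)
  } else {
    pr <- radial_profile(state, center = center, species = species)
    outermost_crossing(pr$radius, pr$density, threshold)
  }
}

#' Front propagation speed from a trajectory
#'
#' Least-squares slope of [front_position()] against time. In the
#' travelling-wave regime this estimates the invasion speed, to be compared
#' with the classical \eqn{2\sqrt{Dr}} (Fisher-KPP) or the sharp-front
#' \eqn{\sqrt{DKr/2}} (Porous-Fisher, `m = 2`) wave speeds.
#'
#' @param trajectory A list of [tissue_state()] snapshots (>= 3), or `NULL`
#'   when `times` and `positions` are given directly.
#' @param threshold Front threshold (cells mm^-2).
#' @param species,center Passed to [front_position()].
#' @param times,positions Precomputed front positions, as an alternative to
#'   `trajectory`.
#' @return Speed (mm h^-1).
#' @export
wave_speed_estimate <- function(trajectory = NULL, threshold = 10,
                                species = NULL, center = NULL,
                                times = NULL, positions = NULL) {
  if (is.null(times)) {
    stopifnot(length(trajectory) >= 3)
    times <- trajectory_times(trajectory)
    positions <- vapply(trajectory, front_position, numeric(1),
                        threshold = threshold, species = species, center = center)
  }
  stopifnot(length(times) == length(positions), length(times) >= 3)
  if (any(is.na(positions))) stop("front undefined at some requested times")
  unname(stats::coef(stats::lm(positions ~ times))[2])
}
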