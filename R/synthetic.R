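voxel_lattice <- function(corner, Lx, Ly, voxel_mm) {
  nvx <- floor(Lx / voxel_mm + 1e-9)
  nvy <- floor(Ly / voxel_mm + 1e-9)
  list(corner = corner, v = voxel_mm, nvx = nvx, nvy = nvy,
       x = corner[1] + voxel_mm * (seq_len(nvx) - 0.5),
       y = corner[2] + voxel_mm * (seq_len(nvy) - 0.5))
}

# exact interval-overlap weights: rows = voxels, cols = grid cells
overlap_weights <- function(vox_centres, v, cell_centres, h) {
  a <- outer(vox_centres - v / 2, cell_centres - h / 2, pmax)
  b <- outer(vox_centres + v / 2, cell_centres + h / 2, pmin)
  pmax(b - a, 0) / v
}

# deterministic per-(time, voxel) standard normals, independent of
# iteration order so that voxel subsets are reproducible
counter_normal <- function(seed, time_index, voxel_index) {
  n <- length(voxel_index)
  z <- numeric(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (k in seq_len(n)) {
    s <- (abs(seed) * 1000003 + time_index * 499979 + voxel_index[k]) %% 2147483647
    s <- (s * 2654435761) %% 2147483647  # scramble consecutive counters
    set.seed(as.integer(s))
    z[k] <- stats::rnorm(8)[8]  # skip the first draws after reseeding
  }
  z
}

new_observation_set <- function(data, voxel, sigma, seed, lattice) {
  structure(list(data = data, voxel = voxel, sigma = sigma, seed = seed,
                 lattice = lattice, times = sort(unique(data$t))),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d values | %d voxels (%g um) x %d times (%s h)\n",
              nrow(x$data), x$lattice$nvx * x$lattice$nvy, x$voxel,
              length(x$times), paste(x$times, collapse = ", ")))
  if (is.finite(x$sigma)) cat(sprintf("  synthetic, sigma_true = %g, seed = %d\n",
                                      x$sigma, x$seed))
  invisible(x)
}

#' Voxelised noisy observations of a simulated trajectory
#'
#' Emulates the experimental measurement protocol: the model density is
#' averaged over square voxels (voxel centres on a lattice anchored at the
#' domain corner) and perturbed with additive i.i.d. Gaussian noise of
#' standard deviation `sigma` per voxel and time. Negative noisy values are
#' retained, matching the unbounded additive error model assumed by the
#' likelihood. Noise is seeded per (time, voxel) counter, so observations
#' are reproducible independently of iteration order.
#'
#' Cartesian fields are voxel-averaged with exact overlap weights; radially
#' symmetric fields are averaged by supersampling each voxel and
#' interpolating the radial profile (the voxel lattice covers the square
#' circumscribing the radial domain, centred on the tissue).
#'
#' @param trajectory List of [tissue_state()] snapshots containing all
#'   requested times.
#' @param times Observation times (h).
#' @param voxel Voxel side (um); must be at least the grid spacing.
#' @param sigma Noise s.d. (cells mm^-2), `>= 0`.
#' @param seed Integer seed.
#' @param ss Supersampling factor per axis for radial fields.
#' @return An `observation_set`: a data.frame (`x`, `y`, `t`, `value`) plus
#'   lattice and noise metadata.
#' @export
observe <- function(trajectory, times, voxel = 115, sigma = 0, seed = 1L,
                    ss = 6L) {
  stopifnot(length(trajectory) >= 1, sigma >= 0)
  tt <- trajectory_times(trajectory)
  g <- trajectory[[1]]$grid
  v <- voxel * 1e-3
  if (v < g$h - 1e-12) stop("voxel must be at least the grid spacing")
  lat <- observation_lattice(g, v)
  rows <- vector("list", length(times))
  for (j in seq_along(times)) {
    k <- which(abs(tt - times[j]) < 1e-8)
    if (length(k) == 0) stop(sprintf("time %g h absent from trajectory", times[j]))
    mu <- voxel_average(trajectory[[k[1]]], lat, ss)
    val <- mu
    if (sigma > 0)
      val <- mu + sigma * counter_normal(seed, j, seq_along(mu))
    rows[[j]] <- data.frame(x = rep(lat$x, times = lat$nvy),
                            y = rep(lat$y, each = lat$nvx),
                            t = times[j], value = val)
  }
  new_observation_set(do.call(rbind, rows), voxel,
                      if (sigma > 0) sigma else 0, as.integer(seed), lat)
}

observation_lattice <- function(grid, v_mm) {
  if (grid$mode == "cartesian2d") {
    corner <- grid$origin - grid$h / 2
    voxel_lattice(corner, grid$nx * grid$h, grid$ny * grid$h, v_mm)
  } else {
    L <- grid$nx * grid$h
    voxel_lattice(c(-L, -L), 2 * L, 2 * L, v_mm)
  }
}

# mean model density over each voxel, in lattice column-major (x fastest) order
voxel_average <- function(state, lat, ss = 6L) {
  g <- state$grid
  if (g$mode == "cartesian2d") {
    co <- grid_coords(g)
    Wx <- overlap_weights(lat$x, lat$v, co$x, g$h)
    Wy <- overlap_weights(lat$y, lat$v, co$y, g$h)
    as.numeric(Wx %*% total_density(state) %*% t(Wy))
  } else {
    prof <- as.numeric(total_density(state))
    r_grid <- grid_coords(g)$r
    off <- ((seq_len(ss) - 0.5) / ss - 0.5) * lat$v
    xs <- rep(lat$x, each = ss) + off
    ys <- rep(lat$y, each = ss) + off
    R <- sqrt(outer(xs^2, rep(1, length(ys))) + outer(rep(1, length(xs)), ys^2))
    vals <- matrix(stats::approx(r_grid, prof, xout = as.numeric(R),
                                 rule = 2)$y, nrow = length(xs))
    as.numeric(block_mean(vals, lat$nvx, lat$nvy, ss))
  }
}

#' Average replicate observation sets
#'
#' Value-wise mean of observation sets sharing one lattice and one set of
#' times (replicate tissues with the same initial condition); the residual
#' noise s.d. shrinks as the square root of the number of replicates.
#'
#' @param obs_list List of `observation_set` objects.
#' @return An `observation_set` with averaged values; `sigma` is the
#'   single-replicate `sigma` divided by `sqrt(n)`.
#' @export
average_observations <- function(obs_list) {
  stopifnot(length(obs_list) >= 1)
  o <- obs_list[[1]]
  vals <- rowMeans(vapply(obs_list, function(z) z$data$value,
                          numeric(nrow(o$data))))
  o$data$value <- vals
  o$sigma <- o$sigma / sqrt(length(obs_list))
  o
}

#' Synthetic single-tissue expansion experiment
#'
#' Generates an observation set with the structure of a circular epithelial
#' expansion assay: a uniform circular tissue of diameter `diameter` is
#' seeded, the model is run for a `burnin` period (emulating the discarded
#' post-stencil-removal transient; the state at the end of the burn-in
#' plays the role of the measured initial profile), and voxelised noisy
#' observations are returned at the requested times. The simulation runs on
#' a radially symmetric grid, which is exact for this geometry.
#'
#' @param params A [model_params()] object.
#' @param sigma Observation noise s.d. (cells mm^-2).
#' @param seed Integer seed (controls noise only; the dynamics are
#'   deterministic).
#' @param density0 Seeding density (cells mm^-2).
#' @param diameter Initial tissue diameter (mm).
#' @param times Observation times (h), on the clock that starts at seeding.
#' @param voxel Voxel side (um).
#' @param burnin Discarded transient (h).
#' @param h Radial grid spacing (mm).
#' @param domain_radius Radial domain size (mm).
#' @param replicates Number of replicate tissues to average (1 = single
#'   tissue).
#' @param cfl Solver stability factor.
#' @return An `observation_set`; attributes `initial_state` (the
#'   [tissue_state()] at the end of the burn-in, the inference initial
#'   condition) and `trajectory` (snapshots at the observation times).
#' @export
expansion_protocol <- function(params, sigma, seed = 1L, density0 = 2600,
                               diameter = 3.4, times = c(16, 26, 36, 46),
                               voxel = 115, burnin = 6, h = 0.01,
                               domain_radius = 3.5, replicates = 1,
                               cfl = 0.4) {
  stopifnot(inherits(params, "model_params"), all(times > burnin))
  grid <- fv_grid_radial(h, domain_radius)
  state0 <- build_state(list(tissue_spec("circle", c(0, 0), diameter / 2,
                                         density0, 0L)), grid)
  traj <- fv_solve(state0, params, c(burnin, times), cfl = cfl)
  init <- traj[[1]]
  obs_traj <- traj[-1]
  reps <- lapply(seq_len(replicates), function(k)
    observe(obs_traj, times, voxel = voxel, sigma = sigma,
            seed = as.integer(seed) + k - 1L))
  obs <- if (replicates == 1) reps[[1]] else average_observations(reps)
  attr(obs, "initial_state") <- init
  attr(obs, "trajectory") <- obs_traj
  obs
}
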