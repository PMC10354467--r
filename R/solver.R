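#' @useDynLib epigrowth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

fam_code <- function(params) if (params$family == "linear") 0L else 1L
mode_code <- function(grid) if (grid$mode == "cartesian2d") 0L else 1L

#' Largest admissible explicit time step
#'
#' The stability restriction of the explicit scheme:
#' `CFL * h^2 / (2 * dim * Dmax)` with `Dmax` the largest diffusivity over
#' the current state, combined with the reaction bound `0.1 / r` that keeps
#' the explicit logistic update accurate.
#'
#' @param state A [tissue_state()].
#' @param params A [model_params()].
#' @param cfl Safety factor in (0, 1]; default 0.4.
#' @return Admissible step (h); `Inf` for a zero state with `r = 0`.
#' @export
fv_dt_bound <- function(state, params, cfl = 0.4) {
  stopifnot(inherits(state, "tissue_state"), inherits(params, "model_params"))
  g <- state$grid
  fv_dt_bound_cpp(as.numeric(state$rho), c(g$nx, g$ny, n_species(state)),
                  mode_code(g), g$h, fam_code(params), params$D_int,
                  params$r, params$K, params$m, cfl)
}

#' One explicit finite-volume step
#'
#' Advances a (multi-species) state by one conservative explicit step.
#' Species fluxes are Fickian (`-D grad rho_i`) for the linear family; for
#' the porous family each species moves down the gradient of the common
#' pressure `P = D (sum_j rho_j)^(m-1)` with its own upwinded mobility
#' `rho_i`, which preserves positivity and keeps vacuum regions exactly
#' empty. The logistic reaction `r rho_i (1 - sum_j rho_j / K)` is applied
#' explicitly in the same step. All boundaries are no-flux.
#'
#' @param state A [tissue_state()].
#' @param params A [model_params()].
#' @param dt Time step (h); must not exceed [fv_dt_bound()].
#' @param cfl Safety factor used for the admissibility check.
#' @return The updated `tissue_state` at `state$time + dt`.
#' @export
fv_step <- function(state, params, dt, cfl = 0.4) {
  stopifnot(inherits(state, "tissue_state"), inherits(params, "model_params"),
            is.numeric(dt), length(dt) == 1, dt > 0)
  bound <- fv_dt_bound(state, params, cfl)
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stability bound; admissible dt <= %g", dt, bound))
  g <- state$grid
  out <- fv_step_cpp(as.numeric(state$rho), c(g$nx, g$ny, n_species(state)),
                     mode_code(g), g$h, fam_code(params), params$D_int,
                     params$r, params$K, params$m, dt)
  state$rho <- array(out, dim = dim(state$rho))
  state$time <- state$time + dt
  state
}

#' Solve the model forward in time
#'
#' Integrates the single- or multi-species model from `state0` and returns
#' snapshots exactly at the requested output times. The internal step is
#' chosen adaptively from the stability bound, so the trajectory is
#' deterministic for fixed inputs.
#'
#' @param state0 Initial [tissue_state()].
#' @param params A [model_params()].
#' @param t_out Strictly increasing output times (h), all `>= state0$time`.
#' @param cfl Stability safety factor; default 0.4.
#' @return A list of `tissue_state` snapshots (class `tissue_trajectory`),
#'   one per requested time; attribute `n_steps` records the number of
#'   internal steps taken.
#' @export
fv_solve <- function(state0, params, t_out, cfl = 0.4) {
  stopifnot(inherits(state0, "tissue_state"), inherits(params, "model_params"),
            is.numeric(t_out), length(t_out) >= 1)
  if (any(diff(t_out) <= 0)) stop("t_out must be strictly increasing")
  if (t_out[1] < state0$time - 1e-12) stop("t_out must start at or after state0$time")
  g <- state0$grid
  res <- fv_solve_cpp(as.numeric(state0$rho), c(g$nx, g$ny, n_species(state0)),
                      mode_code(g), g$h, fam_code(params), params$D_int,
                      params$r, params$K, params$m, state0$time,
                      as.numeric(t_out), cfl)
  traj <- vector("list", length(t_out))
  for (k in seq_along(t_out)) {
    s <- state0
    s$rho <- array(res$snapshots[[k]], dim = dim(state0$rho))
    s$time <- t_out[k]
    traj[[k]] <- s
  }
  structure(traj, n_steps = res$n_steps, class = c("tissue_trajectory", "list"))
}

#' Times of a trajectory
#' @param trajectory A list of [tissue_state()] snapshots.
#' @return Numeric vector of time stamps (h).
#' @export
trajectory_times <- function(trajectory)
  vapply(trajectory, function(s) s$time, numeric(1))
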