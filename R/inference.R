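#' Log-uniform prior box
#'
#' Independent priors for theta = (D, r, K, sigma), uniform on the log10
#' scale between per-parameter bounds (both bounds `> 0`, natural units as
#' in [model_params()], sigma in cells mm^-2).
#'
#' @param D,r,K,sigma Length-2 vectors `c(lower, upper)`.
#' @return An object of class `prior_box`.
#' @export
prior_box <- function(D, r, K, sigma) {
  b <- list(D = D, r = r, K = K, sigma = sigma)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || any(v <= 0) || v[1] >= v[2])
      stop(sprintf("invalid bounds for %s: need 0 < lower < upper", nm))
  }
  structure(b, class = "prior_box")
}

#' Default prior boxes per model family
#'
#' Log-uniform boxes wide enough to contain the biologically plausible
#' range for MDCK-like epithelia with comfortable margin around the
#' calibrated reference estimates (linear: D = 1073 um^2/h, porous:
#' D = 1.18 um^2 (cells h)^-1; r ~ 0.2 /h; K ~ 5100-5300 cells mm^-2;
#' sigma ~ 400-500 cells mm^-2).
#'
#' @param family `"linear"` or `"porous"`.
#' @return A [prior_box()].
#' @export
default_priors <- function(family = c("linear", "porous")) {
  family <- match.arg(family)
  D <- if (family == "linear") 10^c(2.5, 4.5) else 10^c(-2.5, 1.5)
  prior_box(D = D, r = 10^c(-2.5, 1), K = 10^c(3, 4), sigma = 10^c(1, 3.5))
}

prior_contains <- function(priors, theta) {
  all(theta >= unlist(lapply(priors, `[`, 1)) &
      theta <= unlist(lapply(priors, `[`, 2)))
}

#' Likelihood configuration for an observation set
#'
#' Precomputes everything the likelihood needs besides theta: the solver
#' initial condition, the model family and pressure exponent, and the
#' voxel-averaging operators mapping the model field onto the observation
#' lattice.
#'
#' @param obs An `observation_set`.
#' @param initial_state The [tissue_state()] used as the solver initial
#'   condition (for synthetic protocols, the end-of-burn-in state; its time
#'   stamp must precede all observation times).
#' @param family Model family, `"linear"` or `"porous"`.
#' @param m Pressure exponent for the porous family.
#' @param cfl Solver stability factor.
#' @param ss Voxel supersampling factor (radial grids).
#' @return An object of class `likelihood_config`.
#' @export
likelihood_config <- function(obs, initial_state, family = c("linear", "porous"),
                              m = 2, cfl = 0.4, ss = 6L) {
  family <- match.arg(family)
  stopifnot(inherits(obs, "observation_set"), inherits(initial_state, "tissue_state"))
  if (any(obs$times <= initial_state$time))
    stop("all observation times must be after the initial-state time")
  g <- initial_state$grid
  lat <- obs$lattice
  # align each observation row to its voxel and time, so the likelihood is
  # invariant to the storage order of the rows
  ix <- round((obs$data$x - lat$corner[1]) / lat$v + 0.5)
  iy <- round((obs$data$y - lat$corner[2]) / lat$v + 0.5)
  if (any(ix < 1 | ix > lat$nvx | iy < 1 | iy > lat$nvy))
    stop("observation positions do not lie on the voxel lattice")
  vox_idx <- (iy - 1L) * lat$nvx + ix
  t_idx <- match(obs$data$t, obs$times)
  pre <- if (g$mode == "cartesian2d") {
    co <- grid_coords(g)
    list(Wx = overlap_weights(lat$x, lat$v, co$x, g$h),
         Wy = overlap_weights(lat$y, lat$v, co$y, g$h))
  } else {
    off <- ((seq_len(ss) - 0.5) / ss - 0.5) * lat$v
    xs <- rep(lat$x, each = ss) + off
    ys <- rep(lat$y, each = ss) + off
    list(R = sqrt(outer(xs^2, rep(1, length(ys))) +
                  outer(rep(1, length(xs)), ys^2)),
         r_grid = grid_coords(g)$r, ss = ss, nvx = lat$nvx, nvy = lat$nvy)
  }
  structure(list(initial_state = initial_state, family = family, m = m,
                 cfl = cfl, times = obs$times, pre = pre,
                 n_vox = lat$nvx * lat$nvy, vox_idx = vox_idx,
                 t_idx = t_idx),
            class = "likelihood_config")
}

predict_voxels <- function(state, config) {
  pre <- config$pre
  if (!is.null(pre$Wx)) {
    as.numeric(pre$Wx %*% total_density(state) %*% t(pre$Wy))
  } else {
    prof <- as.numeric(total_density(state))
    vals <- matrix(stats::approx(pre$r_grid, prof, xout = as.numeric(pre$R),
                                 rule = 2)$y, nrow = nrow(pre$R))
    as.numeric(block_mean(vals, pre$nvx, pre$nvy, pre$ss))
  }
}

#' Gaussian observation log-likelihood
#'
#' For theta = (D, r, K, sigma), solves the model from the configured
#' initial condition, voxel-averages the solution at every observation
#' position and time, and evaluates
#' \deqn{\ell(\theta) = -\tfrac12 \sum_{i,j}\left[\log(2\pi\sigma^2) +
#'   \left(\frac{\rho(x_i,t_j) - \rho_D(x_i,t_j)}{\sigma}\right)^2\right].}
#'
#' @param theta Numeric vector `c(D, r, K, sigma)` in natural units.
#' @param obs An `observation_set`.
#' @param config A [likelihood_config()].
#' @return The log-likelihood (scalar); `-Inf` with attribute `"reason"` if
#'   the solver fails at `theta`.
#' @export
log_likelihood <- function(theta, obs, config) {
  stopifnot(length(theta) == 4, all(is.finite(theta)), all(theta > 0))
  if (nrow(obs$data) == 0) return(0)  # empty data: posterior = prior
  params <- model_params(config$family, D = theta[1], r = theta[2],
                         K = theta[3], m = config$m)
  sigma <- theta[4]
  traj <- tryCatch(fv_solve(config$initial_state, params, config$times,
                            cfl = config$cfl),
                   error = function(e) e)
  if (inherits(traj, "error")) {
    out <- -Inf
    attr(out, "reason") <- conditionMessage(traj)
    return(out)
  }
  mu <- vapply(traj, predict_voxels, numeric(config$n_vox), config = config)
  resid <- mu[cbind(config$vox_idx, config$t_idx)] - obs$data$value
  -0.5 * sum(log(2 * pi * sigma^2) + (resid / sigma)^2)
}

#' Multistart maximum-likelihood fit
#'
#' Maximises [log_likelihood()] over theta = (D, r, K, sigma) with
#' bound-constrained local optimisation (`L-BFGS-B`) on the log10 scale,
#' started from `n_starts` points sampled uniformly on the log scale within
#' the prior box. The best optimum is returned together with the full
#' multistart table sorted by log-likelihood.
#'
#' @param obs An `observation_set`.
#' @param config A [likelihood_config()].
#' @param priors A [prior_box()] providing the optimisation bounds.
#' @param n_starts Number of starts, `>= 1`.
#' @param seed Integer seed for the start sampling.
#' @param maxit Iteration cap per start.
#' @return An object of class `ml_fit`: `theta` (named vector), `logLik`,
#'   and `starts` (the multistart table).
#' @export
ml_fit <- function(obs, config, priors, n_starts = 10, seed = 1L, maxit = 200) {
  stopifnot(inherits(priors, "prior_box"), n_starts >= 1)
  lo <- log10(vapply(priors, `[`, 0, 1))
  hi <- log10(vapply(priors, `[`, 0, 2))
  nll <- function(lp) {
    ll <- log_likelihood(10^lp, obs, config)
    if (!is.finite(ll)) 1e10 else -ll
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  starts <- matrix(stats::runif(4 * n_starts, lo, hi), ncol = 4, byrow = TRUE)
  fits <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    fits[[k]] <- tryCatch(
      stats::optim(starts[k, ], nll, method = "L-BFGS-B", lower = lo,
                   upper = hi, control = list(maxit = maxit)),
      error = function(e) list(par = rep(NA_real_, 4), value = NA_real_,
                               convergence = -1L, message = conditionMessage(e)))
  }
  tab <- data.frame(start_D = 10^starts[, 1], start_r = 10^starts[, 2],
                    start_K = 10^starts[, 3], start_sigma = 10^starts[, 4],
                    D = 10^vapply(fits, function(f) f$par[1], 0),
                    r = 10^vapply(fits, function(f) f$par[2], 0),
                    K = 10^vapply(fits, function(f) f$par[3], 0),
                    sigma = 10^vapply(fits, function(f) f$par[4], 0),
                    logLik = -vapply(fits, function(f) f$value, 0),
                    convergence = vapply(fits, function(f) f$convergence, 0L))
  tab <- tab[order(-tab$logLik), ]
  if (all(is.na(tab$logLik))) stop("all optimisation starts failed")
  best <- tab[1, ]
  theta <- c(D = best$D, r = best$r, K = best$K, sigma = best$sigma)
  structure(list(theta = theta, logLik = best$logLik, starts = tab),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("<ml_fit> maximum-likelihood estimate\n")
  print(signif(x$theta, 6))
  cat(sprintf("  logLik = %.3f over %d starts (%d converged)\n", x$logLik,
              nrow(x$starts), sum(x$starts$convergence == 0, na.rm = TRUE)))
  invisible(x)
}
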