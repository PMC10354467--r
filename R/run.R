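#' Read and validate a run configuration
#'
#' Run configurations are flat YAML files with blocks mirroring the
#' package's building blocks: `model` ([model_params()] fields), `solver`
#' (grid mode, spacing `h` in mm, `cfl`, optional `margin` in mm around the
#' seeded shapes), `geometry` (a list of [tissue_spec()] entries),
#' `output_times`, `protocol` (synthetic-observation settings for
#' [expansion_protocol()]) and `inference` (prior bounds, `n_starts`,
#' `n_iter`, `n_chains`, `n_retain`, `seed`).
#'
#' @param path YAML file path.
#' @return The configuration as a named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  m <- cfg$model
  if (is.null(m)) stop("config is missing the 'model' block")
  for (f in c("family", "D", "r", "K"))
    if (is.null(m[[f]])) stop(sprintf("model block is missing '%s'", f))
  model_params(m$family, D = m$D, r = m$r, K = m$K,
               m = if (is.null(m$m)) 2 else m$m)
}

config_specs <- function(cfg) {
  lapply(seq_along(cfg$geometry), function(k) {
    sp <- cfg$geometry[[k]]
    for (f in c("shape", "center", "size", "density"))
      if (is.null(sp[[f]])) stop(sprintf("geometry entry %d is missing '%s'", k, f))
    tissue_spec(sp$shape, center = unlist(sp$center), size = unlist(sp$size),
                density = sp$density,
                species = if (is.null(sp$species)) 0L else sp$species)
  })
}

config_grid <- function(cfg, specs) {
  sv <- cfg$solver
  if (is.null(sv$h)) stop("solver block is missing 'h'")
  margin <- if (is.null(sv$margin)) 1 else sv$margin
  bbs <- do.call(rbind, lapply(specs, spec_bbox))
  xr <- c(min(bbs[, 1]) - margin, max(bbs[, 2]) + margin)
  yr <- c(min(bbs[, 3]) - margin, max(bbs[, 4]) + margin)
  nx <- ceiling((xr[2] - xr[1]) / sv$h)
  ny <- ceiling((yr[2] - yr[1]) / sv$h)
  fv_grid("cartesian2d", h = sv$h, nx = nx, ny = ny,
          origin = c(xr[1], yr[1]) + sv$h / 2)
}

write_manifest <- function(cfg, outdir, extra = list()) {
  man <- list(config = unclass(cfg),
              package = "epigrowth",
              version = as.character(utils::packageVersion("epigrowth")))
  man <- c(man, extra)
  yaml::write_yaml(man, file.path(outdir, "manifest.yaml"))
}

#' Run a configured simulation
#'
#' Builds the initial condition from the `geometry` block, integrates the
#' configured model, and writes one snapshot file per requested output
#' time, a `manifest.yaml` echoing the configuration, and (for 2-species
#' runs) the interface track. Deterministic: the same configuration
#' produces byte-identical numeric outputs.
#'
#' @param config A `run_config` (from [read_run_config()]) or a config
#'   list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `status` (0 on success) and the written
#'   file paths.
#' @export
run_simulate <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  params <- config_params(config)
  specs <- config_specs(config)
  if (length(specs) == 0) stop("geometry block is empty")
  grid <- config_grid(config, specs)
  state0 <- build_state(specs, grid)
  t_out <- unlist(config$output_times)
  if (is.null(t_out)) stop("config is missing 'output_times'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  traj <- if (all(t_out == state0$time)) list(state0) else
    fv_solve(state0, params, t_out[t_out > state0$time],
             cfl = if (is.null(config$solver$cfl)) 0.4 else config$solver$cfl)
  files <- character(0)
  if (any(t_out == state0$time)) traj <- c(list(state0), traj)
  for (s in traj) {
    f <- file.path(outdir, sprintf("snapshot_t%g.txt", s$time))
    write_snapshot(s, f)
    files <- c(files, f)
  }
  if (n_species(state0) == 2) {
    tr <- track_interface(traj)
    f <- file.path(outdir, "interface_track.txt")
    utils::write.table(format(tr$track, digits = 17, trim = TRUE), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  write_manifest(config, outdir)
  invisible(list(status = 0L, files = files))
}

#' Run configured parameter inference
#'
#' Generates (or reads) observations, runs the multistart maximum-
#' likelihood fit and the adaptive MCMC sampler, and writes the multistart
#' table, the chains, per-parameter Gelman-Rubin statistics, the posterior
#' summary and a manifest. Chains whose Rhat exceeds 1.1 are reported with
#' a warning without failing the run.
#'
#' @param config A `run_config` or config list. Requires a `protocol`
#'   block (synthetic observations via [expansion_protocol()]) or an
#'   `observations` file path plus an `initial_state` snapshot path.
#' @param outdir Output directory.
#' @return Invisibly, a list with `status`, the [ml_fit()], the
#'   [chain_set()] and the posterior summary.
#' @export
run_infer <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  inf <- config$inference
  if (is.null(inf)) stop("config is missing the 'inference' block")
  priors <- if (is.null(inf$priors)) {
    default_priors(config$model$family)
  } else {
    pb <- lapply(inf$priors, unlist)
    prior_box(D = pb$D, r = pb$r, K = pb$K, sigma = pb$sigma)
  }
  seed <- if (is.null(inf$seed)) 1L else as.integer(inf$seed)

  if (!is.null(config$observations)) {
    obs <- read_observations(config$observations)
    if (is.null(config$initial_state))
      stop("file-based observations require an 'initial_state' snapshot path")
    init_state <- read_snapshot(config$initial_state)
  } else if (!is.null(config$protocol)) {
    pr <- config$protocol
    params <- config_params(config)
    obs <- do.call(expansion_protocol, c(list(params = params),
      pr[intersect(names(pr), names(formals(expansion_protocol)))]))
    init_state <- attr(obs, "initial_state")
  } else {
    stop("config needs either an 'observations' path or a 'protocol' block")
  }
  cfgL <- likelihood_config(obs, init_state, family = config$model$family,
                            m = if (is.null(config$model$m)) 2 else config$model$m)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  fit <- ml_fit(obs, cfgL, priors,
                n_starts = if (is.null(inf$n_starts)) 10 else inf$n_starts,
                seed = seed)
  utils::write.table(format(fit$starts, digits = 17, trim = TRUE),
                     file.path(outdir, "multistart.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cs <- mcmc_sample(obs, cfgL, priors,
                    n_iter = if (is.null(inf$n_iter)) 12000 else inf$n_iter,
                    n_chains = if (is.null(inf$n_chains)) 3 else inf$n_chains,
                    seed = seed, init = fit$theta,
                    n_retain = inf$n_retain)
  write_chains(cs, file.path(outdir, "chains.txt"))
  rhat <- gelman_rubin(cs)
  if (any(rhat > 1.1))
    warning(sprintf("chains may not have converged: max Rhat = %.3f", max(rhat)))
  summ <- posterior_summary(cs)

  con <- file(file.path(outdir, "summary.txt"), "w")
  writeLines(c("# epigrowth inference summary",
               paste("logLik_ML:", fmt_num(fit$logLik)),
               paste("accept_rate:", paste(fmt_num(cs$accept_rate), collapse = " "))),
             con)
  for (p in rownames(summ))
    writeLines(sprintf(
      "%s: ML %.8g | mode %.8g | mean %.8g | sd %.3g | CI95 [%.8g, %.8g] | Rhat %.4f",
      p, fit$theta[p], summ[p, "mode"], summ[p, "mean"], summ[p, "sd"],
      summ[p, "lower"], summ[p, "upper"], rhat[p]), con)
  close(con)
  write_manifest(config, outdir, extra = list(seed = seed))
  invisible(list(status = 0L, fit = fit, chains = cs, summary = summ,
                 rhat = rhat))
}
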