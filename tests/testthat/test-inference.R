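pp <- model_params("porous", D = 1.18, r = 0.214, K = 5319)
# coarse, fast synthetic expansion shared across tests
obs_small <- expansion_protocol(pp, sigma = 50, seed = 7, h = 0.04, voxel = 230)
cfg_small <- likelihood_config(obs_small, attr(obs_small, "initial_state"),
                               family = "porous")

test_that("log-likelihood matches its closed forms and a summation oracle", {
  N <- nrow(obs_small$data)
  # model == data (sigma = 0 observations): -N/2 log(2 pi sigma^2)
  obs0 <- expansion_protocol(pp, sigma = 0, seed = 1, h = 0.04, voxel = 230)
  cfg0 <- likelihood_config(obs0, attr(obs0, "initial_state"), "porous")
  s <- 123
  expect_equal(log_likelihood(c(1.18, 0.214, 5319, s), obs0, cfg0),
               -N / 2 * log(2 * pi * s^2), tolerance = 1e-10)
  # every residual equal to sigma: extra -N/2
  obs_s <- obs0
  obs_s$data$value <- obs_s$data$value + s
  expect_equal(log_likelihood(c(1.18, 0.214, 5319, s), obs_s, cfg0),
               -N / 2 * log(2 * pi * s^2) - N / 2, tolerance = 1e-10)
  # brute-force term-by-term summation on a random subset
  set.seed(21)
  idx <- sample(N, 30)
  obs_sub <- obs_small
  obs_sub$data <- obs_small$data[idx, ]
  cfg_sub <- likelihood_config(obs_sub, attr(obs_small, "initial_state"), "porous")
  theta <- c(1.3, 0.2, 5000, 80)
  prm <- model_params("porous", theta[1], theta[2], theta[3])
  traj <- fv_solve(attr(obs_small, "initial_state"), prm, obs_sub$times)
  ll <- 0
  for (k in seq_len(30)) {
    row <- obs_sub$data[k, ]
    ti <- which(obs_sub$times == row$t)
    mu_all <- epigrowth:::predict_voxels(traj[[ti]], cfg_sub)
    ix <- round((row$x - obs_sub$lattice$corner[1]) / obs_sub$lattice$v + 0.5)
    iy <- round((row$y - obs_sub$lattice$corner[2]) / obs_sub$lattice$v + 0.5)
    mu <- mu_all[(iy - 1) * obs_sub$lattice$nvx + ix]
    ll <- ll - 0.5 * (log(2 * pi * theta[4]^2) + ((mu - row$value) / theta[4])^2)
  }
  expect_equal(log_likelihood(theta, obs_sub, cfg_sub), ll, tolerance = 1e-12)
})

test_that("the likelihood is invariant to observation-row order", {
  set.seed(5)
  perm <- sample(nrow(obs_small$data))
  obs_perm <- obs_small
  obs_perm$data <- obs_small$data[perm, ]
  cfg_perm <- likelihood_config(obs_perm, attr(obs_small, "initial_state"), "porous")
  theta <- c(1.18, 0.214, 5319, 50)
  expect_equal(log_likelihood(theta, obs_perm, cfg_perm),
               log_likelihood(theta, obs_small, cfg_small), tolerance = 1e-12)
})

test_that("prior boxes validate bounds and defaults contain the estimates", {
  expect_error(prior_box(D = c(2, 1), r = c(0.01, 1), K = c(1e3, 1e4),
                         sigma = c(10, 100)), "D")
  expect_error(prior_box(D = c(-1, 1), r = c(0.01, 1), K = c(1e3, 1e4),
                         sigma = c(10, 100)), "D")
  for (fam in c("linear", "porous")) {
    pb <- default_priors(fam)
    est <- if (fam == "linear") c(1073, 0.289, 5113, 492) else c(1.18, 0.214, 5319, 427)
    expect_true(all(est > vapply(pb, `[`, 0, 1) & est < vapply(pb, `[`, 0, 2)))
  }
})

test_that("multistart ML recovers generating parameters on synthetic data", {
  fit <- ml_fit(obs_small, cfg_small, default_priors("porous"),
                n_starts = 4, seed = 1)
  truth <- c(1.18, 0.214, 5319, 50)
  # the optimum dominates the generating parameters
  expect_gte(fit$logLik, log_likelihood(truth, obs_small, cfg_small))
  expect_lt(max(abs(fit$theta[1:3] - truth[1:3]) / truth[1:3]), 0.05)
  # multistart table is sorted by log-likelihood
  expect_true(all(diff(fit$starts$logLik) <= 1e-9))
  # with sigma fixed, the ML point also minimises the mean squared error:
  # refitting at two sigma values leaves (D, r, K) unchanged
  th_a <- fit$theta
  ll_a <- log_likelihood(c(th_a[1:3], 200), obs_small, cfg_small)
  ll_b <- log_likelihood(c(th_a[1:3] * 1.02, 200), obs_small, cfg_small)
  expect_gt(ll_a, ll_b)
})

test_that("adaptive MH samples toy targets correctly", {
  # 2-parameter correlated Gaussian
  mu <- c(1, -2); S <- matrix(c(1, 0.6, 0.6, 0.5), 2)
  Sinv <- solve(S)
  lt <- function(x) -0.5 * t(x - mu) %*% Sinv %*% (x - mu)
  set.seed(1)
  run <- adaptive_mh(lt, c(0, 0), n_iter = 20000, sigma0 = 0.5,
                     adapt_start = 200)
  draws <- run$samples[5001:20000, ]
  n_eff <- 300  # conservative effective sample size for 3 s.e. bands
  expect_lt(max(abs(colMeans(draws) - mu)), 3 * sqrt(diag(S) / n_eff)[1])
  expect_lt(max(abs(cov(draws) - S)), 3 * max(S) * sqrt(2 / n_eff))
  expect_gt(run$accept_rate, 0.1)
  expect_lt(run$accept_rate, 0.5)
  expect_error(adaptive_mh(function(x) -Inf, c(0, 0), 1000), "zero target")
})

test_that("with empty data the sampler reproduces the log-uniform prior", {
  obs_empty <- obs_small
  obs_empty$data <- obs_small$data[0, ]
  cfg_e <- likelihood_config(obs_empty, attr(obs_small, "initial_state"), "porous")
  pb <- default_priors("porous")
  cs <- mcmc_sample(obs_empty, cfg_e, pb, n_iter = 8000, n_chains = 2,
                    seed = 3, sigma0 = 0.5)
  pooled <- log10(do.call(rbind, epigrowth:::retained(cs)))
  lo <- log10(vapply(pb, `[`, 0, 1)); hi <- log10(vapply(pb, `[`, 0, 2))
  n_eff <- 200
  for (j in 1:4) {
    width <- hi[j] - lo[j]
    expect_lt(abs(mean(pooled[, j]) - (lo[j] + hi[j]) / 2),
              3 * width / sqrt(12 * n_eff))
    expect_lt(abs(sd(pooled[, j]) - width / sqrt(12)), 3 * width / sqrt(12 * n_eff))
  }
})

test_that("chains are reproducible for a fixed seed", {
  pb <- default_priors("porous")
  a <- mcmc_sample(obs_small, cfg_small, pb, n_iter = 150, n_chains = 2,
                   seed = 11, init = c(1.18, 0.214, 5319, 50))
  b <- mcmc_sample(obs_small, cfg_small, pb, n_iter = 150, n_chains = 2,
                   seed = 11, init = c(1.18, 0.214, 5319, 50))
  expect_identical(a$chains, b$chains)
})

test_that("Gelman-Rubin statistic behaves at its reference points", {
  set.seed(8)
  base <- matrix(rnorm(4000), 1000, 4)
  colnames(base) <- c("D", "r", "K", "sigma")
  # identical chains: Rhat exactly 1 (unsplit)
  cs_same <- chain_set(list(base, base, base), n_retain = 1000)
  expect_equal(unname(gelman_rubin(cs_same, split = FALSE)), rep(1, 4),
               tolerance = 1e-12)
  # independent draws from one distribution: near 1
  cs_iid <- chain_set(list(base, matrix(rnorm(4000), 1000, 4),
                           matrix(rnorm(4000), 1000, 4)), n_retain = 1000)
  expect_true(all(gelman_rubin(cs_iid) < 1.05))
  # chains offset by 10 sd: far above 1, and matching the brute-force formula
  off <- base + 10
  cs_off <- chain_set(list(base, off), n_retain = 1000)
  r <- gelman_rubin(cs_off, split = FALSE)
  expect_true(all(r > 1.5))
  n <- 1000
  means <- c(mean(base[, 1]), mean(off[, 1]))
  W <- mean(c(var(base[, 1]), var(off[, 1])))
  Bn <- var(means)
  expect_equal(unname(r[1]), sqrt(1 + n * Bn / ((n - 1) * W)), tolerance = 1e-12)
  expect_error(gelman_rubin(chain_set(list(base))), "2 chains")
})

test_that("posterior summaries report modes, moments and intervals", {
  const <- matrix(rep(c(1.18, 0.214, 5319, 50), each = 500), 500, 4)
  colnames(const) <- c("D", "r", "K", "sigma")
  cs_const <- chain_set(list(const, const), n_retain = 500)
  s <- posterior_summary(cs_const)
  expect_equal(s$mode, c(1.18, 0.214, 5319, 50))
  expect_equal(s$sd, rep(0, 4))
  set.seed(9)
  g1 <- matrix(rnorm(8000, mean = 5, sd = 2), 2000, 4)
  colnames(g1) <- c("D", "r", "K", "sigma")
  cs_g <- chain_set(list(g1, matrix(rnorm(8000, 5, 2), 2000, 4)),
                    n_retain = 2000)
  sg <- posterior_summary(cs_g)
  n <- 4000
  expect_lt(max(abs(sg$mean - 5)), 3 * 2 / sqrt(n))
  expect_lt(max(abs(sg$sd - 2)), 3 * 2 / sqrt(2 * n))
  expect_lt(max(abs(sg$mode - 5)), 0.5)
  expect_error(posterior_summary(cs_g, n_retain = 5000), "insufficient")
  bv <- posterior_bivariate(cs_g, c("D", "r"), nbins = 10)
  expect_equal(sum(bv$z), n)
})

test_that("chain files round-trip", {
  set.seed(2)
  ch <- lapply(1:2, function(i) {
    m <- matrix(runif(400, 1, 10), 100, 4)
    colnames(m) <- c("D", "r", "K", "sigma")
    m
  })
  cs <- chain_set(ch, log_post = matrix(rnorm(200), 100, 2),
                  accept_rate = c(0.3, 0.4), n_retain = 40)
  f <- tempfile(fileext = ".tsv")
  write_chains(cs, f)
  back <- read_chains(f)
  expect_equal(back$chains, cs$chains, tolerance = 1e-12)
  expect_equal(back$n_retain, cs$n_retain)
  expect_equal(back$accept_rate, cs$accept_rate)
})
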