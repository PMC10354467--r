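#' Adaptive Metropolis random-walk sampler
#'
#' Metropolis-Hastings with Gaussian proposals whose covariance adapts to
#' the running sample covariance of the chain (scaled by `2.38^2 / d`, with
#' a small diagonal jitter), together with a decaying global scale
#' adaptation targeting the standard 23.4% acceptance rate — the usual
#' adaptive-Metropolis recipe. A move from `x` to `x*` is accepted with
#' probability `min(1, exp(log_target(x*) - log_target(x)))`.
#'
#' @param log_target Function returning the (unnormalised) log target
#'   density at a numeric vector.
#' @param init Starting point; must have finite target density.
#' @param n_iter Number of iterations, `>= 100`.
#' @param sigma0 Initial per-coordinate proposal s.d. (scalar or vector).
#' @param adapt_start Iteration after which the proposal covariance starts
#'   adapting (scale adaptation runs from the start).
#' @param adapt_every Adaptation cadence (iterations).
#' @param accept_target Target acceptance rate for the scale adaptation.
#' @param jitter Diagonal jitter added to the adapted covariance.
#' @return A list with `samples` (`n_iter` x d matrix, including the
#'   initial point replicated on rejection), `log_post` and `accept_rate`.
#' @export
adaptive_mh <- function(log_target, init, n_iter, sigma0 = 0.05,
                        adapt_start = 500, adapt_every = 50,
                        accept_target = 0.234, jitter = 1e-10) {
  stopifnot(n_iter >= 100)
  d <- length(init)
  lp <- log_target(init)
  if (!is.finite(lp)) stop("starting point has zero target probability")
  samples <- matrix(NA_real_, n_iter, d)
  lps <- numeric(n_iter)
  x <- as.numeric(init)
  chol_S <- diag(rep(sigma0, length.out = d), d)
  log_scale <- 0
  n_acc <- 0L; n_acc_win <- 0L; n_adapt <- 0L
  for (i in seq_len(n_iter)) {
    prop <- x + exp(log_scale) * as.numeric(chol_S %*% stats::rnorm(d))
    lp_prop <- log_target(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      x <- prop; lp <- lp_prop
      n_acc <- n_acc + 1L; n_acc_win <- n_acc_win + 1L
    }
    samples[i, ] <- x
    lps[i] <- lp
    if (i %% adapt_every == 0) {
      n_adapt <- n_adapt + 1L
      gain <- 1 / sqrt(n_adapt)
      log_scale <- log_scale + gain * (n_acc_win / adapt_every - accept_target)
      n_acc_win <- 0L
      if (i > adapt_start) {
        S <- stats::cov(samples[(i %/% 2):i, , drop = FALSE])
        S <- 2.38^2 / d * S + jitter * diag(d)
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(ch)) chol_S <- t(ch)
      }
    }
  }
  list(samples = samples, log_post = lps, accept_rate = n_acc / n_iter)
}

#' Construct a chain set
#'
#' Container for multi-chain MCMC output on theta = (D, r, K, sigma).
#'
#' @param chains List of equal-size `n_iter` x 4 matrices (natural units).
#' @param log_post Optional `n_iter` x `n_chains` matrix.
#' @param accept_rate Optional per-chain acceptance rates.
#' @param n_retain Burn-in convention: number of trailing iterations that
#'   [posterior_summary()] and [gelman_rubin()] retain per chain.
#' @return An object of class `chain_set`.
#' @export
chain_set <- function(chains, log_post = NULL, accept_rate = NA_real_,
                      n_retain = NULL) {
  stopifnot(is.list(chains), length(chains) >= 1)
  n <- nrow(chains[[1]])
  for (ch in chains) stopifnot(is.matrix(ch), nrow(ch) == n)
  if (is.null(colnames(chains[[1]])))
    chains <- lapply(chains, `colnames<-`, c("D", "r", "K", "sigma")[seq_len(ncol(chains[[1]]))])
  if (is.null(n_retain)) n_retain <- min(5000L, n %/% 2L)
  structure(list(chains = chains, log_post = log_post,
                 accept_rate = accept_rate, n_iter = n,
                 n_retain = as.integer(n_retain)),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("<chain_set> %d chains x %d iterations (retaining last %d)\n",
              length(x$chains), x$n_iter, x$n_retain))
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%.2f", x$accept_rate), collapse = " ")))
  invisible(x)
}

retained <- function(cs, n_retain = NULL) {
  n_retain <- if (is.null(n_retain)) cs$n_retain else as.integer(n_retain)
  if (n_retain > cs$n_iter) stop("insufficient retained draws")
  idx <- (cs$n_iter - n_retain + 1):cs$n_iter
  lapply(cs$chains, function(ch) ch[idx, , drop = FALSE])
}

#' Posterior sampling by adaptive Metropolis-Hastings
#'
#' Samples the posterior of theta = (D, r, K, sigma) under the Gaussian
#' observation likelihood and a log-uniform prior box. Chains move on the
#' log10-parameter scale, on which the prior is flat inside the box and
#' zero outside, with [adaptive_mh()] proposals.
#'
#' @param obs An `observation_set`.
#' @param config A [likelihood_config()].
#' @param priors A [prior_box()].
#' @param n_iter Iterations per chain, `>= 100` (12000 reproduces the
#'   reference analysis scale).
#' @param n_chains Number of chains.
#' @param seed Integer seed.
#' @param init Optional starting theta (natural units): a single vector, or
#'   a list of one per chain; each chain's start is jittered. `NULL` draws
#'   starts uniformly on the log scale within the prior box.
#' @param sigma0 Initial proposal s.d. on the log10 scale.
#' @param n_retain Burn-in convention for the returned [chain_set()]
#'   (default: last 5000 iterations, or half the chain if shorter).
#' @param adapt_start,adapt_every Adaptation schedule.
#' @return A [chain_set()].
#' @export
mcmc_sample <- function(obs, config, priors, n_iter = 12000, n_chains = 3,
                        seed = 1L, init = NULL, sigma0 = 0.005,
                        n_retain = NULL, adapt_start = 500, adapt_every = 50) {
  stopifnot(inherits(priors, "prior_box"), n_iter >= 100)
  lo <- log10(vapply(priors, `[`, 0, 1))
  hi <- log10(vapply(priors, `[`, 0, 2))
  log_target <- function(lp) {
    if (any(lp < lo) || any(lp > hi)) return(-Inf)
    log_likelihood(10^lp, obs, config)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  chains <- vector("list", n_chains)
  lpost <- matrix(NA_real_, n_iter, n_chains)
  acc <- numeric(n_chains)
  for (c in seq_len(n_chains)) {
    set.seed(as.integer(seed) + 1000L * (c - 1L))
    start <- if (is.null(init)) {
      stats::runif(4, lo, hi)
    } else {
      th <- if (is.list(init)) init[[c]] else init
      pmin(pmax(log10(th) + stats::rnorm(4, 0, sigma0), lo), hi)
    }
    run <- adaptive_mh(log_target, start, n_iter, sigma0 = sigma0,
                       adapt_start = adapt_start, adapt_every = adapt_every)
    ch <- 10^run$samples
    colnames(ch) <- c("D", "r", "K", "sigma")
    chains[[c]] <- ch
    lpost[, c] <- run$log_post
    acc[c] <- run$accept_rate
  }
  chain_set(chains, log_post = lpost, accept_rate = acc, n_retain = n_retain)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Per-parameter potential scale reduction factor from between- and
#' within-chain variances over the retained draws. With `split = TRUE`
#' (default) each chain is halved first (split-Rhat), which also detects
#' within-chain drift. Values near 1 indicate convergence.
#'
#' @param cs A [chain_set()] with at least 2 chains.
#' @param n_retain Number of trailing draws per chain to use (default: the
#'   chain set's convention).
#' @param split Halve each chain before computing the statistic.
#' @return Named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(cs, n_retain = NULL, split = TRUE) {
  stopifnot(inherits(cs, "chain_set"))
  if (length(cs$chains) < 2) stop("at least 2 chains are required")
  chains <- retained(cs, n_retain)
  if (split) {
    half <- nrow(chains[[1]]) %/% 2
    chains <- unlist(lapply(chains, function(ch)
      list(ch[seq_len(half), , drop = FALSE],
           ch[(nrow(ch) - half + 1):nrow(ch), , drop = FALSE])), recursive = FALSE)
  }
  n <- nrow(chains[[1]])
  p <- ncol(chains[[1]])
  rhat <- numeric(p)
  for (j in seq_len(p)) {
    means <- vapply(chains, function(ch) mean(ch[, j]), 0)
    vars <- vapply(chains, function(ch) stats::var(ch[, j]), 0)
    W <- mean(vars)
    B_over_n <- stats::var(means)  # = B / n
    # normalised so that identical chains give exactly 1; differs from the
    # (n-1)/n-weighted textbook form by O(1/n)
    rhat[j] <- if (W == 0) 1 else sqrt(1 + n * B_over_n / ((n - 1) * W))
  }
  stats::setNames(rhat, colnames(chains[[1]]))
}

#' Posterior summaries from pooled chains
#'
#' Pools the retained draws of all chains and reports, per parameter, the
#' univariate mode (Gaussian-kernel density argmax, Silverman bandwidth),
#' mean, standard deviation and central credible interval.
#'
#' @param cs A [chain_set()].
#' @param n_retain Trailing draws per chain to pool (default: the chain
#'   set's convention, i.e. the last 5000 of a full-length run).
#' @param level Credible level (default 0.95).
#' @return A data.frame with rows per parameter and columns `mode`, `mean`,
#'   `sd`, `lower`, `upper`; the pooled draws are attached as attribute
#'   `"draws"`.
#' @export
posterior_summary <- function(cs, n_retain = NULL, level = 0.95) {
  stopifnot(inherits(cs, "chain_set"))
  pooled <- do.call(rbind, retained(cs, n_retain))
  a <- (1 - level) / 2
  out <- do.call(rbind, lapply(seq_len(ncol(pooled)), function(j) {
    x <- pooled[, j]
    mode <- if (stats::sd(x) == 0) x[1] else {
      de <- stats::density(x, bw = "nrd0")
      de$x[which.max(de$y)]
    }
    data.frame(mode = mode, mean = mean(x), sd = stats::sd(x),
               lower = unname(stats::quantile(x, a)),
               upper = unname(stats::quantile(x, 1 - a)))
  }))
  rownames(out) <- colnames(pooled)
  attr(out, "draws") <- pooled
  out
}

#' Bivariate posterior density grid
#'
#' 2D histogram of pooled retained draws for one parameter pair, ready for
#' plot-matrix style displays of parameter correlations.
#'
#' @param cs A [chain_set()].
#' @param pars Character vector of two parameter names.
#' @param nbins Bins per axis.
#' @param n_retain Trailing draws per chain to pool.
#' @return A list with bin midpoints `x`, `y` and the count matrix `z`.
#' @export
posterior_bivariate <- function(cs, pars, nbins = 40, n_retain = NULL) {
  pooled <- do.call(rbind, retained(cs, n_retain))
  stopifnot(all(pars %in% colnames(pooled)), length(pars) == 2)
  u <- pooled[, pars[1]]; v <- pooled[, pars[2]]
  bx <- seq(min(u), max(u), length.out = nbins + 1)
  by <- seq(min(v), max(v), length.out = nbins + 1)
  iu <- pmin(pmax(findInterval(u, bx, rightmost.closed = TRUE), 1), nbins)
  iv <- pmin(pmax(findInterval(v, by, rightmost.closed = TRUE), 1), nbins)
  z <- matrix(0, nbins, nbins)
  for (k in seq_along(iu)) z[iu[k], iv[k]] <- z[iu[k], iv[k]] + 1
  list(x = (bx[-1] + bx[-length(bx)]) / 2,
       y = (by[-1] + by[-length(by)]) / 2, z = z)
}
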