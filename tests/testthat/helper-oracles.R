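# Independent dense re-implementations used as oracles for the compiled
# finite-volume kernels, plus closed-form reference solutions.

# one explicit step on a planar 1D grid (no-flux), densities as ncell x ns
oracle_step_1d <- function(rho, h, family, D, r, K, m, dt) {
  n <- nrow(rho); ns <- ncol(rho)
  tot <- rowSums(rho)
  P <- if (family == "porous") D * tot^(m - 1) else NULL
  out <- rho + dt * r * rho * (1 - tot / K)
  for (s in seq_len(ns)) for (i in seq_len(n - 1)) {
    if (family == "porous") {
      dP <- P[i + 1] - P[i]
      M <- if (dP < 0) rho[i, s] else rho[i + 1, s]
      FF <- -M * dP / h
    } else {
      FF <- -D * (rho[i + 1, s] - rho[i, s]) / h
    }
    out[i, s] <- out[i, s] - dt * FF / h
    out[i + 1, s] <- out[i + 1, s] + dt * FF / h
  }
  out
}

# one explicit step on the radial grid: face i at r = i h, centre (i - 1/2) h
oracle_step_radial <- function(rho, h, family, D, r, K, m, dt) {
  n <- nrow(rho); ns <- ncol(rho)
  tot <- rowSums(rho)
  P <- if (family == "porous") D * tot^(m - 1) else NULL
  out <- rho + dt * r * rho * (1 - tot / K)
  rc <- (seq_len(n) - 0.5) * h
  for (s in seq_len(ns)) for (i in seq_len(n - 1)) {
    if (family == "porous") {
      dP <- P[i + 1] - P[i]
      M <- if (dP < 0) rho[i, s] else rho[i + 1, s]
      FF <- -M * dP / h
    } else {
      FF <- -D * (rho[i + 1, s] - rho[i, s]) / h
    }
    rf <- i * h
    out[i, s] <- out[i, s] - dt * rf * FF / (rc[i] * h)
    out[i + 1, s] <- out[i + 1, s] + dt * rf * FF / (rc[i + 1] * h)
  }
  out
}

# heat kernel evolution of a Gaussian bump (planar 1D, D in mm^2/h)
gaussian_bump <- function(x, amp, s) amp * exp(-x^2 / (2 * s^2))
heat_gaussian <- function(x, t, amp, s0, D) {
  s2 <- s0^2 + 2 * D * t
  amp * s0 / sqrt(s2) * exp(-x^2 / (2 * s2))
}

# source-type self-similar solution of rho_t = D (rho rho_x)_x, i.e. the
# porous-medium equation for v = (D/2) rho with v_t = (v^2)_xx:
# v(x,t) = t^(-1/3) (C - x^2 / (12 t^(2/3)))_+
barenblatt_m2 <- function(x, t, C, D) {
  (2 / D) * pmax(C - x^2 / (12 * t^(2 / 3)), 0) / t^(1 / 3)
}

make_state_1d <- function(values, h = 0.02, time = 0) {
  g <- fv_grid("cartesian2d", h = h, nx = if (is.matrix(values)) nrow(values) else length(values), ny = 1)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  tissue_state(g, array(values, dim = c(nrow(values), 1, ncol(values))), time = time)
}

make_state_radial <- function(values, h = 0.01, time = 0) {
  g <- fv_grid("radial1d", h = h, nr = if (is.matrix(values)) nrow(values) else length(values))
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  tissue_state(g, array(values, dim = c(nrow(values), 1, ncol(values))), time = time)
}

# standard two-rectangle collision setup (2D; ny controls the lateral size)
rect_collision_state <- function(h = 0.05, dens = c(2600, 2600),
                                 widths = c(1, 1), gap = 0.3, height = 1.5,
                                 margin = 1) {
  Lx <- margin + widths[1] + gap + widths[2] + margin
  Ly <- 2 * margin + height
  g <- fv_grid("cartesian2d", h = h, nx = round(Lx / h), ny = round(Ly / h))
  c1 <- margin + widths[1] / 2
  c2 <- margin + widths[1] + gap + widths[2] / 2
  build_state(list(
    tissue_spec("rectangle", c(c1, Ly / 2), c(widths[1], height), dens[1], 0L),
    tissue_spec("rectangle", c(c2, Ly / 2), c(widths[2], height), dens[2], 1L)), g)
}
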