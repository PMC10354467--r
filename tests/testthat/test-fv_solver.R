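por <- model_params("porous", D = 1.18, r = 0.214, K = 5319)
por0 <- model_params("porous", D = 1.18, r = 0, K = 5319)
lin <- model_params("linear", D = 1073, r = 0.289, K = 5113)
lin0 <- model_params("linear", D = 1073, r = 0, K = 5113)

test_that("one step matches an independent dense oracle on tiny grids", {
  set.seed(42)
  vals <- matrix(stats::runif(10, 0, 4000), 5, 2)
  for (fam in list(por, lin)) {
    st <- make_state_1d(vals, h = 0.02)
    dt <- 0.5 * fv_dt_bound(st, fam)
    got <- fv_step(st, fam, dt)
    want <- oracle_step_1d(vals, 0.02, fam$family, fam$D_int, fam$r, fam$K,
                           fam$m, dt)
    expect_equal(matrix(got$rho, 5, 2), want, tolerance = 1e-13)

    str <- make_state_radial(vals, h = 0.01)
    dtr <- 0.5 * fv_dt_bound(str, fam)
    gotr <- fv_step(str, fam, dtr)
    wantr <- oracle_step_radial(vals, 0.01, fam$family, fam$D_int, fam$r,
                                fam$K, fam$m, dtr)
    expect_equal(matrix(gotr$rho, 5, 2), wantr, tolerance = 1e-13)
  }
})

test_that("uniform state at carrying capacity is a steady state", {
  for (fam in list(por, lin)) {
    g <- fv_grid("cartesian2d", h = 0.05, nx = 12, ny = 9)
    st <- tissue_state(g, fam$K)
    out <- fv_step(st, fam, 0.9 * fv_dt_bound(st, fam))
    expect_equal(as.numeric(out$rho), rep(fam$K, 12 * 9), tolerance = 1e-13)
  }
})

test_that("inadmissible time steps are rejected with the admissible bound", {
  st <- make_state_1d(c(0, 100, 3000, 100, 0))
  b <- fv_dt_bound(st, por0)
  expect_error(fv_step(st, por0, 2 * b), "admissible")
  expect_silent(fv_step(st, por0, b))
})

test_that("mass is conserved without proliferation and positivity holds", {
  set.seed(7)
  # both families x both grid modes, >= 1000 explicit steps
  cases <- list(
    list(p = por0, st = make_state_radial(2600 * (grid_coords(fv_grid("radial1d", h = 0.02, nr = 60))$r < 0.6), h = 0.02)),
    list(p = lin0, st = make_state_radial(2600 * (grid_coords(fv_grid("radial1d", h = 0.02, nr = 60))$r < 0.6), h = 0.02)),
    list(p = por0, st = {
      g <- fv_grid("cartesian2d", h = 0.05, nx = 25, ny = 20)
      tissue_state(g, array(stats::runif(25 * 20 * 2, 0, 3000), c(25, 20, 2)))
    }),
    list(p = lin0, st = {
      g <- fv_grid("cartesian2d", h = 0.05, nx = 25, ny = 20)
      tissue_state(g, array(stats::runif(25 * 20 * 2, 0, 3000), c(25, 20, 2)))
    }))
  for (cs in cases) {
    st <- cs$st
    m0 <- state_mass(st)
    for (i in 1:1000) st <- fv_step(st, cs$p, fv_dt_bound(st, cs$p))
    expect_lt(max(abs(state_mass(st) - m0) / m0), 1e-10)
    expect_true(all(st$rho >= 0))
  }
})

test_that("linear family converges to the heat kernel under refinement", {
  err <- sapply(c(0.04, 0.02), function(h) {
    n <- round(8 / h)
    g <- fv_grid("cartesian2d", h = h, nx = n, ny = 1, origin = c(-4 + h / 2, 0))
    x <- grid_coords(g)$x
    st <- tissue_state(g, gaussian_bump(x, 2000, 0.3))
    out <- fv_solve(st, lin0, 20)[[1]]
    exact <- heat_gaussian(x, 20, 2000, 0.3, lin0$D_int)
    sum(abs(as.numeric(out$rho) - exact)) * h
  })
  expect_lt(err[2], err[1])          # L1 error decreases under refinement
  expect_lt(err[2] / (2000 * 0.3 * sqrt(2 * pi)), 0.01)  # < 1% of mass
})

test_that("porous family without growth follows the Barenblatt solution", {
  C <- 2.2e-3  # gives peak density ~ 3700 cells/mm^2 at t0 = 1
  err <- sapply(c(0.02, 0.01), function(h) {
    n <- round(4 / h)
    g <- fv_grid("cartesian2d", h = h, nx = n, ny = 1, origin = c(-2 + h / 2, 0))
    x <- grid_coords(g)$x
    st <- tissue_state(g, barenblatt_m2(x, 1, C, por0$D_int))
    out <- fv_solve(st, por0, 40)[[1]]  # solver time 40 = self-similar t = 41
    exact <- barenblatt_m2(x, 41, C, por0$D_int)
    sum(abs(as.numeric(out$rho) - exact)) * h
  })
  mass <- sum(barenblatt_m2(seq(-2, 2, 0.01), 1, C, por0$D_int)) * 0.01
  expect_lt(err[2], err[1])
  expect_lt(err[2] / mass, 0.02)
})

test_that("front positions and travelling-wave speeds match theory", {
  # step profile
  disc <- make_state_radial(2600 * (grid_coords(fv_grid("radial1d", h = 0.01, nr = 300))$r <= 1.7), h = 0.01)
  expect_equal(front_position(disc, 10), 1.7, tolerance = 0.011)
  expect_true(is.na(front_position(make_state_radial(rep(0, 50)), 10)))
  # exact line through synthetic front positions
  expect_equal(wave_speed_estimate(times = 1:5, positions = 2 + 0.25 * (1:5)), 0.25)

  # Fisher-KPP pulled front: c = 2 sqrt(D r); h resolves the exponential
  # tail and the window sits past the slow O(1/t) front relaxation
  g <- fv_grid("cartesian2d", h = 0.01, nx = 600, ny = 1)
  p <- model_params("linear", D = 1000, r = 0.5, K = 5000)
  st <- tissue_state(g, 5000 * (grid_coords(g)$x < 0.5))
  traj <- fv_solve(st, p, seq(60, 100, by = 10))
  c_hat <- wave_speed_estimate(traj, threshold = 50)
  expect_equal(c_hat, 2 * sqrt(1e-3 * 0.5), tolerance = 0.05)

  # Porous-Fisher sharp front: c = sqrt(D K r / 2)
  pp <- model_params("porous", D = 1.18, r = 0.214, K = 5319)
  st2 <- tissue_state(g, 5319 * (grid_coords(g)$x < 0.5))
  traj2 <- fv_solve(st2, pp, seq(60, 140, by = 20))
  c_hat2 <- wave_speed_estimate(traj2, threshold = 50)
  expect_equal(c_hat2, sqrt(1.18e-6 * 5319 * 0.214 / 2), tolerance = 0.05)
})

test_that("two species with one empty reduce to the single-species solve", {
  g <- fv_grid("cartesian2d", h = 0.05, nx = 30, ny = 1)
  x <- grid_coords(g)$x
  one <- tissue_state(g, 2600 * (x < 0.6))
  two <- tissue_state(g, array(c(2600 * (x < 0.6), rep(0, 30)), c(30, 1, 2)))
  t1 <- fv_solve(one, por, c(10, 30))
  t2 <- fv_solve(two, por, c(10, 30))
  for (k in 1:2) {
    expect_equal(as.numeric(t2[[k]]$rho[, , 1]), as.numeric(t1[[k]]$rho),
                 tolerance = 1e-12)
    expect_equal(max(t2[[k]]$rho[, , 2]), 0)
  }
})

test_that("summed porous two-species system solves the single-species equation", {
  st <- rect_collision_state(h = 0.05, gap = 0.2, height = 0.5, margin = 0.6)
  tot0 <- tissue_state(st$grid, total_density(st))
  t2 <- fv_solve(st, por, c(20, 57))
  t1 <- fv_solve(tot0, por, c(20, 57))
  for (k in 1:2)
    expect_equal(as.numeric(total_density(t2[[k]])), as.numeric(t1[[k]]$rho),
                 tolerance = 1e-10)
})

test_that("ordered initial data stay ordered (linear family, no growth)", {
  g <- fv_grid("cartesian2d", h = 0.05, nx = 40, ny = 1)
  x <- grid_coords(g)$x
  lowv <- 1500 * exp(-(x - 1)^2)
  hiv <- lowv + 500 + 400 * sin(3 * x)^2
  a <- tissue_state(g, lowv); b <- tissue_state(g, hiv)
  for (i in 1:200) {
    dt <- min(fv_dt_bound(a, lin0), fv_dt_bound(b, lin0))
    a <- fv_step(a, lin0, dt); b <- fv_step(b, lin0, dt)
  }
  expect_true(all(b$rho >= a$rho - 1e-12))
})

test_that("radial and 2D solves of a circular expansion agree", {
  pr <- model_params("porous", D = 1.18, r = 0.214, K = 5319)
  gr <- fv_grid_radial(0.02, 2.4)
  s_r <- build_state(list(tissue_spec("circle", c(0, 0), 0.8, 2600, 0L)), gr)
  g2 <- fv_grid("cartesian2d", h = 0.04, nx = 120, ny = 120,
                origin = c(-2.4 + 0.02, -2.4 + 0.02))
  s_2 <- build_state(list(tissue_spec("circle", c(0, 0), 0.8, 2600, 0L)), g2)
  out_r <- fv_solve(s_r, pr, 30)[[1]]
  out_2 <- fv_solve(s_2, pr, 30)[[1]]
  pr_r <- radial_profile(out_r)
  pr_2 <- radial_profile(out_2, center = c(0, 0))
  common <- pr_2$radius[pr_2$radius < 2]
  v_r <- approx(pr_r$radius, pr_r$density, xout = common)$y
  v_2 <- approx(pr_2$radius, pr_2$density, xout = common)$y
  expect_lt(max(abs(v_r - v_2)) / 5319, 0.08)
  expect_equal(front_position(out_r), front_position(out_2, center = c(0, 0)),
               tolerance = 0.06)
})

test_that("radial profile matches a direct per-annulus averaging oracle", {
  set.seed(11)
  g <- fv_grid("cartesian2d", h = 0.1, nx = 21, ny = 17)
  vals <- matrix(stats::runif(21 * 17, 0, 1000), 21, 17)
  st <- tissue_state(g, vals)
  ctr <- c(1.05, 0.85)
  pr <- radial_profile(st, center = ctr)
  co <- grid_coords(g)
  rr <- sqrt(outer(co$x - ctr[1], rep(1, 17))^2 + outer(rep(1, 21), co$y - ctr[2])^2)
  bins <- pmax(1, ceiling(rr / g$h))
  for (k in seq_len(nrow(pr))) {
    b <- round(pr$radius[k] / g$h + 0.5)
    expect_equal(pr$density[k], mean(vals[bins == b]), tolerance = 1e-12)
  }
  # binned mass accounts for the field mass
  expect_equal(sum(pr$density * pr$n_cells) * g$h^2, sum(vals) * g$h^2,
               tolerance = 1e-12)
  # uniform disc: plateau then zero
  st2 <- build_state(list(tissue_spec("circle", c(1.05, 0.85), 0.4, 1000, 0L)), g)
  pr2 <- radial_profile(st2, center = ctr)
  expect_equal(pr2$density[pr2$radius < 0.3],
               rep(1000, sum(pr2$radius < 0.3)), tolerance = 1e-9)
  expect_equal(pr2$density[pr2$radius > 0.6],
               rep(0, sum(pr2$radius > 0.6)))
  expect_error(radial_profile(st, center = c(99, 0)), "outside")
})

test_that("snapshot files round-trip states exactly", {
  st <- rect_collision_state(h = 0.1, height = 0.5, margin = 0.4)
  f <- tempfile(fileext = ".txt")
  write_snapshot(st, f)
  back <- read_snapshot(f)
  expect_equal(back$rho, st$rho)
  expect_equal(back$grid$h, st$grid$h)
  expect_equal(back$time, st$time)
  sr <- make_state_radial(stats::runif(40, 0, 100), h = 0.05, time = 3.5)
  f2 <- tempfile(fileext = ".txt")
  write_snapshot(sr, f2)
  br <- read_snapshot(f2)
  expect_equal(br$rho, sr$rho)
  expect_equal(br$grid$mode, "radial1d")
})
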