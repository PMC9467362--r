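test_that("shape parameter follows the prolate-spheroid formula", {
  expect_equal(shape_parameter(1, 1), 0)
  expect_gt(shape_parameter(1, 1e-6), 1 - 1e-6)
  expect_equal(shape_parameter(0.25, 0.15), (1 - 0.36) / (1 + 0.36))
  expect_equal(shape_parameter(0.25, 0.15), 0.470588, tolerance = 1e-6)
  expect_error(shape_parameter(0.15, 0.25), "a >= b")
})

test_that("larval velocity is flow plus swimming along the major axis", {
  expect_equal(larval_velocity(10, 0, pi / 2, 3), tibble::tibble(vx = 10, vy = 3),
               tolerance = 1e-12)
  expect_equal(larval_velocity(0, 0, 0, 3)$vx, 3)
  v <- larval_velocity(-4, 1, pi, 3)
  expect_equal(c(v$vx, v$vy), c(-7, 1), tolerance = 1e-12)
})

test_that("larval rotation: vorticity half plus shape-weighted strain", {
  expect_equal(larval_rotation(0.7, 0, list(s11 = 0, s12 = 0, s22 = 0), 0.47), 0)
  # simple shear u = gamma y, gamma = 1: omega_z = -1, S12 = 1/2
  S <- list(s11 = 0, s12 = 0.5, s22 = 0)
  for (th in seq(0, 2 * pi, by = 0.37)) {
    expect_equal(larval_rotation(th, -1, S, 0), -0.5)
  }
  a <- 0.470588
  expect_equal(larval_rotation(0, -1, S, a), -0.5 + a * 0.5, tolerance = 1e-9)
  expect_equal(larval_rotation(0, -1, S, a), -0.264706, tolerance = 1e-6)
  Sm <- matrix(c(1, 0.5, 0.5, -1), 2, 2)
  expect_equal(larval_rotation(0.3, 2, Sm, 0.2),
               larval_rotation(0.3, 2, list(s11 = 1, s12 = 0.5, s22 = -1), 0.2))
  expect_error(larval_rotation(0, 0, matrix(c(0, 1, 0, 0), 2, 2), 0.2),
               "symmetric")
})

test_that("the seeding lattice is the exact deterministic cross product", {
  lat <- seed_lattice(sim_config(), domain_length = 40, period = 5.5)
  expect_equal(nrow(lat), 19200)
  expect_equal(dplyr::n_distinct(lat$x0), 30)
  expect_equal(dplyr::n_distinct(lat$theta0), 32)
  expect_equal(dplyr::n_distinct(lat$t0), 20)
  expect_true(all(lat$y0 == 10))
  one <- seed_lattice(sim_config(n_positions = 1, n_orientations = 1,
                                 n_phases = 1), 40, 5.5)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$x0, one$y0, one$theta0, one$t0), c(0, 10, 0, 0))
  four <- seed_lattice(sim_config(n_positions = 1, n_orientations = 4,
                                  n_phases = 1), 40, 5.5)
  expect_equal(sort(four$theta0), c(0, pi / 2, pi, 3 * pi / 2))
})

test_that("settlement needs both surface contact and the speed gate", {
  sub <- substrate_profile("flat")
  p <- larva_params()
  expect_equal(check_settlement(1, 0.1, 3.5, sub, p, 30), "settled")
  expect_equal(check_settlement(1, 0.1, 5.0, sub, p, 30), "swimming")
  expect_equal(check_settlement(1, 0.1, 4.0, sub, p, 30), "swimming") # gate is strict
  expect_equal(check_settlement(1, 31, 3.0, sub, p, 30), "exited")
  expect_equal(check_settlement(1, 5, 3.0, sub, p, 30), "swimming")
})

test_that("engine limit cases: still fluid and uniform downward flows", {
  p0 <- larva_params(u_ell = 0, sd_u = 4)   # passive agents, speed gate 4 mm/s
  cfg <- sim_config(n_positions = 2, n_orientations = 4, n_phases = 2,
                    max_time = 10)
  still <- make_uniform_field(0, 0, L = 30, dx = 5)
  sim <- run_simulation(still, p0, cfg)
  expect_equal(sim$unresolved, sim$n)
  # slow downward flow: every passive agent reaches the floor under the gate
  down2 <- make_uniform_field(0, -2, L = 30, dx = 5)
  sim2 <- run_simulation(down2, p0, cfg)
  expect_equal(sim2$settled, sim2$n)
  # fast downward flow: contact always exceeds the gate; agents slide forever
  down6 <- make_uniform_field(0, -6, L = 30, dx = 5)
  sim6 <- run_simulation(down6, p0, cfg)
  expect_equal(sim6$settled, 0)
  expect_equal(sim6$unresolved, sim6$n)
  expect_true(all(tidy(sim6)$y_final < 0.5))
})

test_that("a sphere in solid-body rotation orbits at omega/2 with conserved radius", {
  om <- 0.25                       # explicit Euler grows r by ~exp(pi om dt)/rev
  rot <- make_rotation_field(omega = om, L = 10, dx = 0.25)
  p <- larva_params(a = 0.2, b = 0.2, u_ell = 0)   # passive sphere
  cfg <- sim_config(dt = 0.01, max_time = 2 * pi / om)  # one revolution
  ag <- tibble::tibble(agent = 1, x0 = 7, y0 = 5, theta0 = 0, t0 = 0)
  sim <- run_simulation(rot, p, cfg, agents = ag)
  res <- tidy(sim)
  r_end <- sqrt((res$x_final - 5)^2 + (res$y_final - 5)^2)
  expect_equal(r_end, 2, tolerance = 0.01)
  # orientation advances at omega_z / 2 = om: one full turn per revolution
  expect_equal(res$theta_final %% (2 * pi), 0, tolerance = 0.02)
})

test_that("Jeffery tumbling period is recovered within 1% at dt = 0.01", {
  # closed form for an ellipse of aspect ratio r in shear gamma:
  # T_J = (2 pi / gamma) (r + 1/r)
  gam <- 1
  r <- (5 / 3)
  alpha <- (1 - (1 / r)^2) / (1 + (1 / r)^2)
  S <- list(s11 = 0, s12 = gam / 2, s22 = 0)
  dt <- 0.01
  th <- 0; tt <- 0
  turns <- 0
  T_J <- (2 * pi / gam) * (r + 1 / r)
  while (tt < 3 * T_J) {
    th <- th + dt * larval_rotation(th, -gam, S, alpha)
    tt <- tt + dt
    if (th <= -2 * pi * (turns + 1)) turns <- turns + 1
  }
  # time per full tumble, averaged over the completed turns
  expect_gte(turns, 2)
  t_turn <- tt * (3 * T_J / tt) # total time is 3 T_J by construction
  period_est <- NA
  # re-integrate recording the exact crossing times for precision
  th <- 0; tt <- 0; crossings <- c()
  while (length(crossings) < 3 && tt < 5 * T_J) {
    th_new <- th + dt * larval_rotation(th, -gam, S, alpha)
    tt <- tt + dt
    k <- length(crossings) + 1
    if (th_new <= -2 * pi * k) {
      frac <- (-2 * pi * k - th) / (th_new - th)
      crossings <- c(crossings, tt - dt + frac * dt)
    }
    th <- th_new
  }
  periods <- diff(c(0, crossings))
  expect_equal(mean(periods), T_J, tolerance = 0.01)
})

test_that("the simulation is bitwise deterministic", {
  r <- ridged_cavity_field()
  cfg <- sim_config(n_positions = 3, n_orientations = 4, n_phases = 2,
                    max_time = 15)
  s1 <- run_simulation(r, config = cfg)
  s2 <- run_simulation(r, config = cfg)
  expect_identical(tidy(s1), tidy(s2))
})

test_that("raising the speed gate never loses settlers", {
  r <- ridged_cavity_field()
  cfg <- sim_config(n_positions = 4, n_orientations = 8, n_phases = 2,
                    max_time = 30)
  lo <- run_simulation(r, larva_params(sd_u = 1), cfg)
  hi <- run_simulation(r, larva_params(sd_u = 2), cfg)
  expect_gte(hi$settled, lo$settled)
  set_lo <- tidy(lo)$agent[tidy(lo)$status == "settled"]
  set_hi <- tidy(hi)$agent[tidy(hi)$status == "settled"]
  expect_true(all(set_lo %in% set_hi))
})

test_that("the passive limit matches RK4 tracer advection", {
  f <- stokes_layer_field()
  start <- c(10, 3, 0, 0)
  cfg <- sim_config(dt = 0.01, max_time = 1)
  tr_euler <- simulate_trajectory(f, start, larva_params(u_ell = 0), cfg)
  tr_rk <- advect_tracers(f, duration = 1, dt = 0.01,
                          release = tibble::tibble(x = 10, y = 3))
  n <- nrow(tr_rk)
  expect_equal(tail(tr_euler$x, 1), tail(tr_rk$x, 1), tolerance = 0.02)
  expect_equal(tail(tr_euler$y, 1), tail(tr_rk$y, 1), tolerance = 0.02)
})

test_that("R stepping on a gridded field matches the compiled analytic path", {
  f <- stokes_layer_field(domain_length = 8, domain_height = 8)
  g <- sample_field(f, dx = 0.1, nt = 32, xlim = c(0, 8), ylim = c(0, 8))
  ag <- seed_lattice(sim_config(n_positions = 2, n_orientations = 4,
                                n_phases = 1, seed_height = 5), 8, 5.5)
  cfg <- sim_config(n_positions = 2, n_orientations = 4, n_phases = 1,
                    seed_height = 5, max_time = 1)
  sim_r <- run_simulation(g, config = cfg, agents = ag)
  sim_c <- run_simulation(f, config = cfg, agents = ag)
  res_r <- tidy(sim_r); res_c <- tidy(sim_c)
  expect_equal(res_r$status, res_c$status)
  expect_equal(res_r$x_final, res_c$x_final, tolerance = 0.05)
  expect_equal(res_r$y_final, res_c$y_final, tolerance = 0.05)
})

test_that("trajectory diagnostics: relative speed, Q, and active windows", {
  uf <- make_uniform_field(6, 0, L = 30, dx = 5)   # flow at 2 u_ell
  ag <- tibble::tibble(x = c(10, 10.1), y = c(15, 15.2),
                       t = c(0, 0.01))
  d <- trajectory_diagnostics(ag, uf, u_ell = 3)
  expect_equal(d$trajectory$rel_speed, rep(2, 2))
  expect_equal(d$trajectory$q, rep(0, 2))
  expect_equal(nrow(d$active_windows), 0)
  still <- make_uniform_field(0, 0, L = 30, dx = 5)
  d0 <- trajectory_diagnostics(ag, still, u_ell = 3)
  expect_equal(nrow(d0$active_windows), 1)
  expect_equal(d0$active_windows$duration, 0.01)
  # crossing the cavity cell: engine-recorded Q matches the analytic
  # streamfunction derivatives evaluated independently in this test
  r <- ridged_cavity_field()
  tr <- simulate_trajectory(r, c(6.25, 3, 3 * pi / 2, 1.0),
                            larva_params(sd_u = -3 + 1e-9), # gate ~ 0: no settling
                            sim_config(max_time = 3))
  dg <- trajectory_diagnostics(tr, u_ell = 3)
  inside <- dg$trajectory$y < 2.4 & dg$trajectory$y > 0.1
  expect_gt(sum(inside), 10)
  p <- r$pars
  qa <- vapply(which(inside), function(i) {
    X <- dg$trajectory$x[i] %% p$pitch - p$w
    Y <- dg$trajectory$y[i]
    A <- p$A0 * sin(p$omega * (dg$trajectory$t[i] - p$phase_lag))
    pis <- pi / p$sg; pih <- pi / p$H
    uy <- A * sin(pis * X)^2 * 2 * pih^2 * cos(2 * pih * Y)
    ux <- A * pis * sin(2 * pis * X) * pih * sin(2 * pih * Y)
    vx <- -A * 2 * pis^2 * cos(2 * pis * X) * sin(pih * Y)^2
    omz <- vx - uy
    0.5 * (omz^2 / 2 - (ux^2 + ux^2 + 0.5 * (uy + vx)^2))
  }, numeric(1))
  expect_equal(max(dg$trajectory$q[inside]), max(qa), tolerance = 0.1)
})
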