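test_that("velocity gradients recover hand-differentiated fields", {
  uf <- make_uniform_field(5, -2)
  g <- velocity_gradients(uf, 0)
  for (nm in c("dudx", "dudy", "dvdx", "dvdy")) {
    expect_lt(max(abs(g[[nm]])), 1e-12)
  }
  sh <- make_shear_field(gamma = 1)
  gs <- velocity_gradients(sh, 0)
  expect_equal(max(abs(gs$dudy - 1)), 0, tolerance = 1e-12)
  expect_lt(max(abs(gs$dudx)), 1e-12)
  expect_equal(gs$omega_z, matrix(-1, nrow(gs$omega_z), ncol(gs$omega_z)),
               tolerance = 1e-12)
  rot <- make_rotation_field(omega = 2)
  gr <- velocity_gradients(rot, 0)
  expect_equal(max(abs(gr$dudy + 2)), 0, tolerance = 1e-10)
  expect_equal(max(abs(gr$dvdx - 2)), 0, tolerance = 1e-10)
  # strain vanishes for solid-body rotation
  expect_lt(max(abs(gr$s11)), 1e-10)
  expect_lt(max(abs(gr$s12)), 1e-10)
  expect_error(velocity_gradients(make_uniform_field(1, 0, L = 0.5, dx = 0.5), 0),
               "3 fluid nodes")
})

test_that("Q-criterion: rotation gives omega^2, shear and uniform flow give 0", {
  rot <- make_rotation_field(omega = 3)
  Q <- q_criterion(velocity_gradients(rot, 0))
  expect_equal(Q, matrix(9, nrow(Q), ncol(Q)), tolerance = 1e-10)
  Qs <- q_criterion(velocity_gradients(make_shear_field(1), 0))
  expect_lt(max(abs(Qs)), 1e-12)
  Qu <- q_criterion(velocity_gradients(make_uniform_field(7, 1), 0))
  expect_lt(max(abs(Qu)), 1e-12)
})

test_that("Q equals det(grad U) for divergence-free fields (independent oracle)", {
  for (seed in 1:3) {
    f <- make_random_psi_field(seed = seed)
    g <- velocity_gradients(f, 0)
    Q <- q_criterion(g)
    detJ <- g$dudx * g$dvdy - g$dudy * g$dvdx
    # compare away from one-sided boundary stencils
    ii <- 3:(nrow(Q) - 2); jj <- 3:(ncol(Q) - 2)
    num <- max(abs(Q[ii, jj] - detJ[ii, jj]))
    den <- max(abs(Q[ii, jj]))
    expect_lt(num / den, 1e-10)
  }
})

test_that("Q is Galilean- and rotation-invariant", {
  f <- make_random_psi_field(seed = 5)
  Q1 <- q_criterion(velocity_gradients(f, 0))
  f2 <- f; f2$u <- f$u + 11.3; f2$v <- f$v - 4.2
  Q2 <- q_criterion(velocity_gradients(f2, 0))
  expect_equal(Q1, Q2, tolerance = 1e-12)
  # rotation invariance at the tensor level: Q(R J R^T) = Q(J)
  qq <- function(J) 0.5 * ((J[2, 1] - J[1, 2])^2 / 2 -
                             (J[1, 1]^2 + J[2, 2]^2 + (J[1, 2] + J[2, 1])^2 / 2))
  set.seed(8)
  for (k in 1:20) {
    J <- matrix(rnorm(4), 2, 2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(qq(R %*% J %*% t(R)), qq(J), tolerance = 1e-12)
  }
})

test_that("vortex labeling agrees with an independent image-analysis oracle", {
  skip_if_not_installed("EBImage")
  set.seed(12)
  Q <- matrix(rnorm(900), 30, 30)
  thr <- 0.8
  ours <- vortex_regions(Q, q_thresh = thr, min_area = 1, connectivity = 4)
  lab <- EBImage::bwlabel(Q > thr)
  expect_equal(nrow(ours), max(lab))
  areas_oracle <- sort(tabulate(lab[lab > 0]))
  expect_equal(sort(ours$area), areas_oracle)
})

test_that("Q threshold is the population SD and flat fields stay sub-threshold", {
  expect_equal(q_threshold(matrix(5, 4, 4)), 0)
  Q <- c(rep(2, 50), rep(-2, 50))
  expect_equal(q_threshold(Q), 2)
  flat <- sample_field(stokes_layer_field(), dx = 0.1, nt = 8,
                       xlim = c(0, 2), ylim = c(0, 6))
  qa <- q_analysis(flat)
  expect_lt(qa$q_thresh, 1e-6)
  expect_equal(nrow(vortex_regions(qa)), 0)
})

test_that("the ridged cavity develops one supra-threshold region per cavity", {
  rid <- sample_field(ridged_cavity_field(), dx = 0.1, nt = 8,
                      xlim = c(0, 20), ylim = c(0, 5))  # two pitches
  qa <- q_analysis(rid)
  vr <- vortex_regions(qa, t = 5.5 / 4)
  expect_gte(nrow(vr), 2)          # at least one region in each of 2 cavities
  expect_true(any(vr$x > 2.5 & vr$x < 10))
  expect_true(any(vr$x > 12.5 & vr$x < 20))
  # single seeded supra-threshold blob -> exactly one region
  Q <- matrix(0, 40, 40)
  Q[15:20, 8:13] <- 3
  expect_equal(nrow(vortex_regions(Q, q_thresh = 1, min_area = 4)), 1)
})

test_that("band speed averages the near-substrate region", {
  uf <- make_uniform_field(10, 0)
  bs <- band_speed(uf, band_height = 1.5)
  expect_equal(bs$speed, 10)
  z <- make_uniform_field(0, 0)
  expect_equal(band_speed(z, 1.5)$speed, 0)
  flat <- sample_field(stokes_layer_field(), dx = 0.1, nt = 16,
                       xlim = c(0, 2), ylim = c(0, 6))
  bsf <- band_speed(flat, 1.5)
  sp <- bsf$speed
  # slower near the turning point than at the peak phase
  expect_lt(sp[which.min(abs(bsf$t - 5.5 / 2))], sp[which.min(abs(bsf$t - 5.5 / 4))])
  expect_error(band_speed(uf, -1), "positive")
  expect_error(band_speed(uf, 1.5, cavity_only = TRUE), "ridged")
})

test_that("settling windows: constants, closed-form sine inversion, monotonicity", {
  mkband <- function(v, t) {
    b <- tibble::tibble(t = t, speed = v)
    attr(b, "period") <- 5.5
    b
  }
  t <- seq(0, 5.5, length.out = 4001)[-4001]
  swa <- settling_windows(mkband(rep(2, length(t)), t))
  expect_equal(swa$n_windows, 1)
  expect_equal(swa$period_fraction, 1)
  swb <- settling_windows(mkband(rep(10, length(t)), t))
  expect_equal(swb$n_windows, 0)
  expect_equal(swb$period_fraction, 0)
  # 15 |sin(2 pi t / 5.5)| dips below 4 twice, for asin(4/15)/pi * T/2 * 2 each
  v <- 15 * abs(sin(2 * pi * t / 5.5))
  sw <- settling_windows(mkband(v, t))
  dur_expect <- 2 * asin(4 / 15) / (2 * pi / 5.5)
  expect_equal(sw$n_windows, 2)
  expect_equal(sw$intervals$duration, rep(dur_expect, 2), tolerance = 1e-3)
  expect_equal(sw$period_fraction, 2 * dur_expect / 5.5, tolerance = 1e-3)
  expect_equal(round(dur_expect, 3), 0.473)
  # fraction non-increasing as the threshold decreases
  fr <- vapply(c(6, 4, 3, 2, 1), function(thr) {
    settling_windows(mkband(v, t), threshold = thr)$period_fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
  expect_error(settling_windows(mkband(v, t), threshold = -1), "positive")
})

test_that("points are classified by the Q-criterion column above them", {
  rid <- sample_field(ridged_cavity_field(), dx = 0.1, nt = 8,
                      xlim = c(0, 10), ylim = c(0, 5))
  qa <- q_analysis(rid)
  pts <- tibble::tibble(x = c(6.25, 1.0), y = c(0, 2.5))
  cl <- classify_points_by_q(pts, qa)
  expect_true(cl$under_vortex[1])    # cavity floor sits under the cell
  expect_false(cl$under_vortex[2])   # ridge top under pure shear
  cl0 <- classify_points_by_q(pts, qa, column_height = 0)
  expect_false(any(cl0$under_vortex))
  expect_error(classify_points_by_q(tibble::tibble(x = 99, y = 0), qa),
               "outside")
  flat <- sample_field(stokes_layer_field(), dx = 0.1, nt = 4,
                       xlim = c(0, 2), ylim = c(0, 5))
  qf <- q_analysis(flat)
  expect_false(classify_points_by_q(tibble::tibble(x = 1, y = 0), qf)$under_vortex)
})

test_that("turbulent energy fraction isolates off-fundamental power", {
  Tp <- 5.5; dt <- Tp / 64
  t <- seq(0, 8 * Tp - dt, by = dt)
  pure <- sin(2 * pi * t / Tp)
  expect_lt(turbulent_energy_fraction(pure, dt, Tp), 1e-3)
  expect_equal(turbulent_energy_fraction(rep(3, length(t)), dt, Tp), 0)
  # Parseval check: noise variance fraction recovered within 10%
  set.seed(99)
  fracs <- vapply(1:20, function(i) {
    x <- 3 * sin(2 * pi * t / Tp) + rnorm(length(t), sd = 1)
    turbulent_energy_fraction(x, dt, Tp)
  }, numeric(1))
  sig2 <- 3^2 / 2
  expect_equal(mean(fracs), 1 / (sig2 + 1), tolerance = 0.1)
  expect_error(turbulent_energy_fraction(pure[1:100], dt, Tp), "4 forcing periods")
})
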