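ps <- 0.031

one_spot_stack <- function(x_px, y_px, nframes = 2) {
  tr <- tibble::tibble(particle = 1L, t = (seq_len(nframes) - 1) / 90,
                       x = x_px * ps, y = y_px * ps)
  render_frames(tr, ptv_optics(noise_level = 0),
                xlim = c(0, 40 * ps), ylim = c(0, 40 * ps))
}

test_that("detection finds a rendered Gaussian spot to sub-pixel accuracy", {
  fs <- one_spot_stack(10.0, 20.0)
  det <- detect_particles(fs[, , 1])
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 10.0), 0.1)
  expect_lt(abs(det$y - 20.0), 0.1)
})

test_that("blank frames give an empty (not failing) detection table", {
  det <- detect_particles(matrix(0, 20, 20))
  expect_equal(nrow(det), 0)
  expect_tibble_cols(det, c("x", "y", "intensity"))
})

test_that("two separated spots give two centroids", {
  tr <- tibble::tibble(particle = c(1L, 2L), t = 0,
                       x = c(8, 28) * ps, y = c(20, 20) * ps)
  tr2 <- tr; tr2$t <- 1 / 90
  fs <- render_frames(dplyr::bind_rows(tr, tr2), ptv_optics(noise_level = 0),
                      xlim = c(0, 40 * ps), ylim = c(0, 40 * ps))
  det <- detect_particles(fs[, , 1])
  expect_equal(nrow(det), 2)
  expect_equal(sort(round(det$x)), c(8, 28))
})

test_that("detection is translation-equivariant under integer pixel shifts", {
  fs <- one_spot_stack(12.3, 17.8)
  fr <- fs[, , 1]
  shifted <- matrix(0, nrow(fr), ncol(fr))
  shifted[, 4:ncol(fr)] <- fr[, 1:(ncol(fr) - 3)]   # shift +3 px in x
  d0 <- detect_particles(fr)
  d1 <- detect_particles(shifted)
  expect_equal(d1$x, d0$x + 3, tolerance = 1e-9)
  expect_equal(d1$y, d0$y, tolerance = 1e-9)
})

test_that("linking follows one moving particle and converts to mm/s", {
  det <- purrr::map_dfr(1:10, function(f) {
    tibble::tibble(frame = f, x = 5 + 2 * (f - 1), y = 10)
  })
  tracks <- link_tracks(det, linking_params(max_disp = 5),
                        fps = 90, pixel_size = ps)
  expect_equal(dplyr::n_distinct(tracks$particle), 1)
  expect_equal(nrow(tracks), 10)
  sp <- sqrt(diff(tracks$x)^2 + diff(tracks$y)^2) / diff(tracks$t)
  expect_equal(unique(round(sp, 9)), 2 * ps * 90)  # 5.58 mm/s
  expect_equal(2 * ps * 90, 5.58)
})

test_that("linking never makes a link longer than max_disp (crossing tracks split)", {
  # two particles approach, cross, and separate; max_disp below the frame step
  det <- purrr::map_dfr(1:11, function(f) {
    tibble::tibble(frame = f,
                   x = c(0 + 4 * (f - 1), 40 - 4 * (f - 1)),
                   y = c(10, 10))
  })
  tracks <- link_tracks(det, linking_params(max_disp = 3), fps = 90,
                        pixel_size = 1)
  jumps <- dplyr::group_by(tracks, particle) |>
    dplyr::reframe(d = sqrt(diff(x)^2 + diff(y)^2))
  expect_true(all(jumps$d <= 3 + 1e-9))
  expect_gt(dplyr::n_distinct(tracks$particle), 2)
})

test_that("gridding reproduces uniform and zero flows exactly", {
  fld <- make_uniform_field(10, 0, L = 20, dx = 1)
  tr <- advect_tracers(fld, n = 40, duration = 0.5, seed = 9)
  pav <- grid_velocities(tr, dx = 2)
  expect_lt(max(abs(pav$u - 10), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(pav$v), na.rm = TRUE), 1e-9)
  still <- advect_tracers(make_uniform_field(0, 0), n = 10, duration = 0.2,
                          seed = 2)
  pav0 <- grid_velocities(still, dx = 2)
  expect_lt(max(abs(pav0$u), na.rm = TRUE), 1e-12)
})

test_that("phase windows are 40 frames centred on the forcing extremum and reversal", {
  fc <- oscillatory_forcing()
  pw <- phase_windows(fc)
  expect_equal(pw$t_end - pw$t_start, rep(40 / 90, 2))
  expect_equal(pw$t_center, c(5.5 / 4, 5.5 / 2))
  expect_equal(free_stream(fc, pw$t_center[1]), 45)
  expect_equal(free_stream(fc, pw$t_center[2]), 0, tolerance = 1e-12)
})

test_that("the full PTV chain recovers a Stokes-layer field within 5% RMS", {
  # a 0.44 s record centred on the peak phase, where the flow varies by <2%;
  # 360 fps keeps frame-to-frame displacements well below the particle
  # spacing so greedy nearest-neighbour linking stays unambiguous
  fc <- oscillatory_forcing()
  f <- stokes_layer_field(fc)
  fps <- 360
  tpk <- 5.5 / 4
  dur <- 40 / 90
  set.seed(31)
  # seed an upstream strip so the field of view stays populated while the
  # peak flow sweeps particles through it
  rel <- tibble::tibble(x = runif(400, -16, 16), y = runif(400, 0.3, 6.5))
  tracks <- advect_tracers(f, duration = dur, dt = 1 / fps, release = rel,
                           t0 = tpk - dur / 2)
  fs <- render_frames(tracks,
                      ptv_optics(fps = fps, noise_level = 0.02,
                                 spot_sigma = 0.047),
                      seed = 8, xlim = c(4, 16), ylim = c(0, 7))
  det <- detect_particles(fs, detection_params())
  expect_gt(nrow(det) / dim(fs)[3], 25)
  linked <- link_tracks(det, linking_params(max_disp = 5), fps = fps,
                        pixel_size = ps)
  # positions are relative to the rendered field of view
  linked$x <- linked$x + 4
  pav <- grid_velocities(linked, dx = 0.5, min_track_length = 5)
  truth <- field_eval(f, rep(pav$x, each = length(pav$y)),
                      rep(pav$y, times = length(pav$x)), tpk)
  ok <- pav$n[, , 1] >= 5 & !is.na(pav$u[, , 1])
  expect_gt(sum(ok), 50)
  err <- (pav$u[, , 1] - matrix(truth$u, length(pav$y)))[ok]
  scale <- sqrt(mean(matrix(truth$u, length(pav$y))[ok]^2))
  expect_lt(sqrt(mean(err^2)) / scale, 0.05)
})
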