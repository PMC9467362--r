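#' Advect passive tracer particles through a flow field
#'
#' Integrates passive tracers (the swimming-speed-zero limit of the larval
#' equations of motion) with a fixed-step 4th-order Runge-Kutta scheme.
#' Used as the ground truth for the particle tracking velocimetry chain.
#'
#' @param field A `larvaflow_field`.
#' @param n Number of tracers (ignored when `release` is given).
#' @param duration Integration time, s.
#' @param dt Time step, s; default 1/90 so positions align with 90 fps
#'   imaging.
#' @param seed RNG seed for the release positions.
#' @param release Optional tibble/matrix of release positions (`x`, `y` in
#'   mm); must lie in the fluid.
#' @param t0 Release time, s (e.g. to centre the record on a flow phase).
#' @return A `particle_tracks` tibble `(particle, t, x, y)` with attributes
#'   `origin = "synthetic"`, `dt` and `fps`.
#' @export
advect_tracers <- function(field, n = 50, duration = 1, dt = 1 / 90,
                           seed = 1, release = NULL, t0 = 0) {
  stopifnot(inherits(field, "larvaflow_field"))
  if (is.null(release)) {
    if (n <= 0) abort("`n` must be positive.")
    set.seed(seed)
    Lx <- field$domain$length; Ly <- field$domain$height
    xs <- ys <- numeric(0)
    while (length(xs) < n) {
      xc <- runif(2 * n, 0, Lx)
      yc <- runif(2 * n, 0, 0.9 * Ly)
      ok <- yc > elevation(field$substrate, xc) + 0.1
      xs <- c(xs, xc[ok]); ys <- c(ys, yc[ok])
    }
    release <- tibble(x = xs[seq_len(n)], y = ys[seq_len(n)])
  } else {
    release <- as_tibble(as.data.frame(release))
    if (any(release$y <= elevation(field$substrate, release$x))) {
      abort("tracer released inside the solid mask.")
    }
    n <- nrow(release)
  }
  nsteps <- max(1L, round(duration / dt))
  Lx <- field$domain$length
  x <- release$x; y <- release$y
  X <- matrix(NA_real_, n, nsteps + 1); Y <- X
  X[, 1] <- x; Y[, 1] <- y
  vel <- function(x, y, t) {
    ev <- field_eval(field, x %% Lx, y, t)
    list(u = ev$u, v = ev$v)
  }
  for (k in seq_len(nsteps)) {
    tk <- t0 + (k - 1) * dt
    k1 <- vel(x, y, tk)
    k2 <- vel(x + dt / 2 * k1$u, y + dt / 2 * k1$v, tk + dt / 2)
    k3 <- vel(x + dt / 2 * k2$u, y + dt / 2 * k2$v, tk + dt / 2)
    k4 <- vel(x + dt * k3$u, y + dt * k3$v, tk + dt)
    x <- x + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
    y <- y + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
    y <- pmax(y, elevation(field$substrate, x %% Lx) + 1e-9)
    X[, k + 1] <- x; Y[, k + 1] <- y
  }
  out <- tibble(
    particle = rep(seq_len(n), each = nsteps + 1),
    t = rep(t0 + dt * (0:nsteps), times = n),
    x = as.vector(t(X)),
    y = as.vector(t(Y)))
  attr(out, "origin") <- "synthetic"
  attr(out, "dt") <- dt
  attr(out, "fps") <- 1 / dt
  class(out) <- c("particle_tracks", class(out))
  out
}

#' Imaging parameters for synthetic particle frames
#'
#' @param pixel_size Image resolution, mm per pixel (31 um default).
#' @param fps Frame rate, frames per second.
#' @param spot_sigma Gaussian spot width (standard deviation), mm.
#' @param noise_level Mean of the additive non-negative image noise
#'   (0 disables noise).
#' @return A list of class `ptv_optics`.
#' @export
ptv_optics <- function(pixel_size = 0.031, fps = 90, spot_sigma = 0.062,
                       noise_level = 0) {
  stopifnot(pixel_size > 0, fps > 0, spot_sigma > 0, noise_level >= 0)
  structure(list(pixel_size = pixel_size, fps = fps,
                 spot_sigma = spot_sigma, noise_level = noise_level),
            class = "ptv_optics")
}

#' Render particle tracks into a synthetic image stack
#'
#' Each particle is drawn as a Gaussian spot centred on its position in each
#' frame; optional additive noise (non-negative, mean `noise_level`) is
#' applied per pixel. Pixel `(r, c)` is centred at
#' `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)` relative to the lower-
#' left corner of the field of view, with row 1 at the bottom.
#'
#' @param tracks A `particle_tracks` tibble; sampling interval must equal
#'   `1/fps`.
#' @param optics A [ptv_optics()] object.
#' @param seed RNG seed for the noise.
#' @param xlim,ylim Field of view in mm; defaults to a tight box around the
#'   tracks.
#' @return A `frame_stack`: numeric array `(rows, cols, frames)` with
#'   attributes `pixel_size`, `fps`, `origin_mm` and `times`.
#' @export
render_frames <- function(tracks, optics = ptv_optics(), seed = 1,
                          xlim = NULL, ylim = NULL) {
  times <- sort(unique(tracks$t))
  if (length(times) < 2) abort("need at least 2 frames of track samples.")
  dts <- diff(times)
  if (max(abs(dts - 1 / optics$fps)) > 1e-6) {
    abort("track sampling interval is inconsistent with `fps`.")
  }
  pad <- 6 * optics$spot_sigma
  xlim <- xlim %||% c(min(tracks$x) - pad, max(tracks$x) + pad)
  ylim <- ylim %||% c(min(tracks$y) - pad, max(tracks$y) + pad)
  ps <- optics$pixel_size
  ncol_px <- max(2L, ceiling((xlim[2] - xlim[1]) / ps))
  nrow_px <- max(2L, ceiling((ylim[2] - ylim[1]) / ps))
  sig <- optics$spot_sigma / ps
  win <- ceiling(4 * sig)
  frames <- array(0, c(nrow_px, ncol_px, length(times)))
  for (k in seq_along(times)) {
    det <- tracks[abs(tracks$t - times[k]) < 1e-9, ]
    img <- matrix(0, nrow_px, ncol_px)
    for (i in seq_len(nrow(det))) {
      px <- (det$x[i] - xlim[1]) / ps
      py <- (det$y[i] - ylim[1]) / ps
      c0 <- max(1L, floor(px - win)); c1 <- min(ncol_px, ceiling(px + win))
      r0 <- max(1L, floor(py - win)); r1 <- min(nrow_px, ceiling(py + win))
      if (c0 > c1 || r0 > r1) next
      cc <- c0:c1; rr <- r0:r1
      gx <- exp(-((cc - 0.5) - px)^2 / (2 * sig^2))
      gy <- exp(-((rr - 0.5) - py)^2 / (2 * sig^2))
      img[rr, cc] <- img[rr, cc] + outer(gy, gx)
    }
    frames[, , k] <- img
  }
  if (optics$noise_level > 0) {
    set.seed(seed)
    frames <- frames + pmax(0, rnorm(length(frames),
                                     mean = optics$noise_level,
                                     sd = optics$noise_level / 4))
  }
  structure(frames, pixel_size = ps, fps = optics$fps,
            origin_mm = c(xlim[1], ylim[1]), times = times,
            class = "frame_stack")
}

#' Write / read a frame stack as a multi-page TIFF
#'
#' Frames are scaled to \[0, 1\] by the stack maximum and stored as 16-bit
#' TIFF pages, so round-trips are quantised to 16-bit precision.
#'
#' @param frames A `frame_stack`.
#' @param path File path (`.tif`).
#' @return `read_frames()` returns a `frame_stack`.
#' @export
write_frames <- function(frames, path) {
  mx <- max(frames, 1e-12)
  pages <- lapply(seq_len(dim(frames)[3]), function(k) {
    frames[dim(frames)[1]:1, , k] / mx   # TIFF row 1 is the image top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames
#' @param pixel_size,fps Imaging metadata to attach on read (mm/px, 1/s).
#' @export
read_frames <- function(path, pixel_size = 0.031, fps = 90) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    frames[, , k] <- pages[[k]][nrow(pages[[k]]):1, ]
  }
  structure(frames, pixel_size = pixel_size, fps = fps,
            origin_mm = c(0, 0),
            times = (seq_along(pages) - 1) / fps,
            class = "frame_stack")
}

#' Write / read particle tracks as CSV
#'
#' @param tracks A `particle_tracks` tibble.
#' @param path File path (`.csv`).
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks[, c("particle", "t", "x", "y")], path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           particle = readr::col_integer(),
                           t = readr::col_double(),
                           x = readr::col_double(),
                           y = readr::col_double()))
  class(out) <- c("particle_tracks", class(out))
  out
}
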