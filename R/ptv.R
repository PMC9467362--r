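#' Particle detection parameters
#'
#' @param intensity_threshold Detection threshold as a fraction of the frame
#'   maximum (0 < threshold < 1).
#' @param min_area Minimum connected-component area in pixels.
#' @param connectivity Pixel connectivity for components (8 or 4).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(intensity_threshold = 0.5, min_area = 2,
                             connectivity = 8) {
  if (intensity_threshold <= 0 || intensity_threshold >= 1) {
    abort("`intensity_threshold` must be in (0, 1).")
  }
  if (min_area < 1) abort("`min_area` must be >= 1.")
  structure(list(intensity_threshold = intensity_threshold,
                 min_area = min_area,
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Detect tracer particles in a frame
#'
#' Thresholds the frame at a fraction of its maximum, labels connected
#' components, discards components below the minimum area, and returns
#' intensity-weighted centroids in (continuous) pixel coordinates — pixel
#' `(r, c)` is centred at `(c - 0.5, r - 0.5)`.
#'
#' @param frame A numeric matrix (one image; row 1 = bottom), or a
#'   `frame_stack` (all frames are processed, with a `frame` column added).
#' @param params A [detection_params()] object.
#' @return A tibble with columns `x`, `y` (px), `intensity` (summed), and
#'   `area` (px). An all-zero frame yields zero rows.
#' @export
detect_particles <- function(frame, params = detection_params()) {
  if (inherits(frame, "frame_stack")) {
    nf <- dim(frame)[3]
    return(purrr::map_dfr(seq_len(nf), function(k) {
      d <- detect_particles(frame[, , k], params)
      if (nrow(d)) d$frame <- k
      d
    }))
  }
  stopifnot(is.matrix(frame))
  if (length(frame) == 0) abort("`frame` is empty.")
  mx <- max(frame)
  if (mx <= 0) {
    return(tibble(x = double(), y = double(),
                  intensity = double(), area = integer()))
  }
  mask <- frame > params$intensity_threshold * mx
  lab <- label_components_cpp(mask, params$connectivity)
  nlab <- max(lab)
  if (nlab == 0) {
    return(tibble(x = double(), y = double(),
                  intensity = double(), area = integer()))
  }
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= params$min_area)
  if (!length(keep)) {
    return(tibble(x = double(), y = double(),
                  intensity = double(), area = integer()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  iv <- frame[lab > 0]
  sel <- lv %in% keep
  lv <- lv[sel]; iv <- iv[sel]; idx <- idx[sel, , drop = FALSE]
  wsum <- tapply(iv, lv, sum)
  xs <- tapply(iv * (idx[, 2] - 0.5), lv, sum) / wsum
  ys <- tapply(iv * (idx[, 1] - 0.5), lv, sum) / wsum
  tibble(x = as.numeric(xs), y = as.numeric(ys),
         intensity = as.numeric(wsum),
         area = as.integer(areas[keep][match(names(wsum), as.character(keep))]))
}

#' Track-linking parameters
#'
#' @param max_disp Maximum allowed displacement between consecutive frames,
#'   px.
#' @return A list of class `linking_params`.
#' @export
linking_params <- function(max_disp = 5) {
  if (max_disp <= 0) abort("`max_disp` must be positive.")
  structure(list(max_disp = max_disp, conflict_rule = "greedy"),
            class = "linking_params")
}

#' Link per-frame detections into particle tracks
#'
#' Nearest-neighbour linking between consecutive frames with a greedy
#' assignment by ascending pair distance; candidate pairs farther than
#' `max_disp` are never linked (crossing particles therefore terminate and
#' restart rather than swap). Unmatched detections start new tracks.
#' Positions are converted to mm.
#'
#' @param detections A tibble with columns `frame`, `x`, `y` (px), e.g. from
#'   [detect_particles()] on a `frame_stack`.
#' @param params A [linking_params()] object.
#' @param fps Frame rate, 1/s.
#' @param pixel_size mm per pixel.
#' @return A `particle_tracks` tibble `(particle, t, x, y)` in mm with
#'   attribute `origin = "detected"`.
#' @export
link_tracks <- function(detections, params = linking_params(), fps = 90,
                        pixel_size = 0.031) {
  if (nrow(detections) == 0) {
    out <- tibble(particle = integer(), t = double(), x = double(), y = double())
    attr(out, "origin") <- "detected"
    class(out) <- c("particle_tracks", class(out))
    return(out)
  }
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2) abort("need detections from at least 2 frames.")
  next_id <- 0L
  rows <- list()
  active <- NULL  # tibble: particle, x, y (px) from the previous frame
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- detections[detections$frame == f, c("x", "y")]
    nd <- nrow(det)
    assigned <- rep(NA_integer_, nd)
    contiguous <- fi > 1 && (f - frames[fi - 1]) == 1
    if (!is.null(active) && contiguous && nd > 0) {
      dmat <- outer(active$x, det$x, `-`)^2 + outer(active$y, det$y, `-`)^2
      cand <- which(dmat <= params$max_disp^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand])
        used_a <- rep(FALSE, nrow(active)); used_d <- rep(FALSE, nd)
        for (ci in ord) {
          a <- cand[ci, 1]; d <- cand[ci, 2]
          if (used_a[a] || used_d[d]) next
          used_a[a] <- TRUE; used_d[d] <- TRUE
          assigned[d] <- active$particle[a]
        }
      }
    }
    new <- which(is.na(assigned))
    if (length(new)) {
      assigned[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    if (nd > 0) {
      rows[[length(rows) + 1]] <- tibble(
        particle = assigned, frame = f, x = det$x, y = det$y)
      active <- tibble(particle = assigned, x = det$x, y = det$y)
    } else {
      active <- NULL
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- tibble(particle = out$particle,
                t = (out$frame - 1) / fps,
                x = out$x * pixel_size,
                y = out$y * pixel_size)
  out <- dplyr::arrange(out, .data$particle, .data$t)
  attr(out, "origin") <- "detected"
  attr(out, "fps") <- fps
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("particle_tracks", class(out))
  out
}

#' Phase windows of an oscillatory forcing
#'
#' Time windows of `n_frames` consecutive frames centred on the named phases
#' of the forcing: `"peak"` (first free-stream maximum) and `"turning"`
#' (the following reversal). With 40 frames at 90 fps each window spans
#' 0.44 s.
#'
#' @param forcing An [oscillatory_forcing()].
#' @param fps Frame rate, 1/s.
#' @param n_frames Window length in frames.
#' @param phases Character vector of named phases, or a numeric vector of
#'   centre times (s), optionally named.
#' @return A tibble `(window, t_center, t_start, t_end)`.
#' @export
phase_windows <- function(forcing, fps = 90, n_frames = 40,
                          phases = c("peak", "turning")) {
  half <- n_frames / (2 * fps)
  if (is.numeric(phases)) {
    centers <- phases
    nm <- names(phases) %||% paste0("w", seq_along(phases))
  } else {
    centers <- vapply(phases, function(p) {
      switch(p,
             peak = (pi / 2 - forcing$phase0) / forcing$omega,
             turning = (pi - forcing$phase0) / forcing$omega,
             abort(sprintf("unknown phase '%s'", p)))
    }, numeric(1))
    nm <- phases
  }
  tibble(window = unname(nm), t_center = unname(centers),
         t_start = unname(centers) - half, t_end = unname(centers) + half)
}

#' Grid phase-averaged velocities from particle tracks
#'
#' Finite-difference velocities between consecutive track positions are
#' placed at the link midpoint, folded by the forcing period when supplied,
#' assigned to phase windows, and averaged per grid cell. Cells without
#' samples are `NA` (missing, not zero); per-cell sample counts are kept.
#'
#' @param tracks A `particle_tracks` tibble (positions in mm).
#' @param dx Grid cell size, mm (PTV output is coarser than simulation
#'   grids; default 0.5 mm).
#' @param windows A tibble from [phase_windows()]; default one window
#'   spanning all samples.
#' @param fold_period Optional period (s) used to fold sample times before
#'   window assignment (phase averaging across repeated cycles).
#' @param xlim,ylim Grid extents, mm; default the track bounding box.
#' @param min_track_length Minimum track length in samples; shorter tracks
#'   (typically spurious links) contribute no velocities. Default 2 keeps
#'   every link.
#' @return A `phase_averaged_field`: arrays `u`, `v`, `n` of dim
#'   `(ny, nx, n_windows)` plus grid centres.
#' @export
grid_velocities <- function(tracks, dx = 0.5, windows = NULL,
                            fold_period = NULL, xlim = NULL, ylim = NULL,
                            min_track_length = 2) {
  tr <- dplyr::arrange(as_tibble(tracks), .data$particle, .data$t)
  if (min_track_length > 2) {
    len <- dplyr::count(tr, .data$particle)
    tr <- dplyr::semi_join(tr, len[len$n >= min_track_length, ],
                           by = "particle")
  }
  tr <- dplyr::group_by(tr, .data$particle)
  links <- dplyr::reframe(
    tr,
    mt = (head(.data$t, -1) + tail(.data$t, -1)) / 2,
    mx = (head(.data$x, -1) + tail(.data$x, -1)) / 2,
    my = (head(.data$y, -1) + tail(.data$y, -1)) / 2,
    u = diff(.data$x) / diff(.data$t),
    v = diff(.data$y) / diff(.data$t))
  if (is.null(windows)) {
    windows <- tibble(window = "all",
                      t_center = mean(range(links$mt %||% 0)),
                      t_start = -Inf, t_end = Inf)
  }
  tfold <- if (is.null(fold_period)) links$mt else links$mt %% fold_period
  xlim <- xlim %||% range(links$mx)
  ylim <- ylim %||% range(links$my)
  xb <- seq(xlim[1], xlim[2] + dx, by = dx)
  yb <- seq(ylim[1], ylim[2] + dx, by = dx)
  nx <- length(xb) - 1; ny <- length(yb) - 1
  nw <- nrow(windows)
  U <- array(NA_real_, c(ny, nx, nw)); V <- U
  N <- array(0L, c(ny, nx, nw))
  for (wi in seq_len(nw)) {
    inw <- tfold >= windows$t_start[wi] & tfold <= windows$t_end[wi]
    li <- links[inw, ]
    if (!nrow(li)) next
    ci <- findInterval(li$mx, xb, rightmost.closed = TRUE)
    ri <- findInterval(li$my, yb, rightmost.closed = TRUE)
    ok <- ci >= 1 & ci <= nx & ri >= 1 & ri <= ny
    li <- li[ok, ]; ci <- ci[ok]; ri <- ri[ok]
    if (!nrow(li)) next
    cell <- (ci - 1L) * ny + ri
    us <- tapply(li$u, cell, mean)
    vs <- tapply(li$v, cell, mean)
    ns <- tapply(li$u, cell, length)
    id <- as.integer(names(us))
    Uk <- matrix(NA_real_, ny, nx); Vk <- Uk; Nk <- matrix(0L, ny, nx)
    Uk[id] <- us; Vk[id] <- vs; Nk[id] <- as.integer(ns)
    U[, , wi] <- Uk; V[, , wi] <- Vk; N[, , wi] <- Nk
  }
  structure(
    list(x = xb[-length(xb)] + dx / 2, y = yb[-length(yb)] + dx / 2,
         windows = windows, u = U, v = V, n = N, dx = dx),
    class = "phase_averaged_field")
}

#' @export
print.phase_averaged_field <- function(x, ...) {
  cat(sprintf("<phase_averaged_field> %d x %d cells (%g mm), %d window(s), %d samples\n",
              length(x$y), length(x$x), x$dx, nrow(x$windows), sum(x$n)))
  invisible(x)
}

#' @export
as_tibble.phase_averaged_field <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$windows)), function(wi) {
    tibble(window = x$windows$window[wi],
           x = rep(x$x, each = length(x$y)),
           y = rep(x$y, times = length(x$x)),
           u = as.vector(x$u[, , wi]),
           v = as.vector(x$v[, , wi]),
           n = as.vector(x$n[, , wi]))
  })
}
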