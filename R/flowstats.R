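#' Velocity gradients of a field at one instant
#'
#' Computes the four velocity-gradient components on the grid with
#' second-order central differences, falling back to one-sided second-order
#' (or first-order where only one neighbour exists) next to solid nodes and
#' domain edges. Gradients are never differenced across the solid mask;
#' solid nodes carry `NA`. For analytic providers the closed-form gradients
#' are evaluated on a grid of spacing `dx`.
#'
#' @param field A `larvaflow_field`.
#' @param t Time (s).
#' @param dx Grid spacing used when `field` is analytic.
#' @return A `gradient_field`: matrices `dudx`, `dudy`, `dvdx`, `dvdy`,
#'   vorticity `omega_z` and strain components `s11`, `s12`, `s22` (1/s).
#' @export
velocity_gradients <- function(field, t, dx = 0.05) {
  if (inherits(field, "analytic_field")) {
    x <- seq(0, field$domain$length, by = dx)
    y <- seq(0, field$domain$height, by = dx)
    ev <- field_eval(field,
                     x = rep(x, each = length(y)),
                     y = rep(y, times = length(x)),
                     t = t, gradients = TRUE)
    fluid <- !outer(y, elevation(field$substrate, x), `<=`)
    g <- list(dudx = matrix(ev$dudx, length(y), length(x)),
              dudy = matrix(ev$dudy, length(y), length(x)),
              dvdx = matrix(ev$dvdx, length(y), length(x)),
              dvdy = matrix(ev$dvdy, length(y), length(x)))
    return(new_gradient_field(g, x, y, t, fluid))
  }
  stopifnot(inherits(field, "gridded_field"))
  fluid <- !field$solid_mask
  if (sum(colSums(fluid) > 0) < 3 || sum(rowSums(fluid) > 0) < 3) {
    abort("grid must have at least 3 fluid nodes along each axis.")
  }
  tw <- time_weights(field, t)
  u <- (1 - tw$w) * field$u[, , tw$k0] + tw$w * field$u[, , tw$k1]
  v <- (1 - tw$w) * field$v[, , tw$k0] + tw$w * field$v[, , tw$k1]
  g <- slice_gradients(u, v, field$dx, fluid)
  new_gradient_field(g, field$x, field$y, t, fluid)
}

new_gradient_field <- function(g, x, y, t, fluid) {
  g$omega_z <- g$dvdx - g$dudy
  g$s11 <- g$dudx
  g$s22 <- g$dvdy
  g$s12 <- 0.5 * (g$dudy + g$dvdx)
  structure(c(g, list(x = x, y = y, t = t, fluid = fluid)),
            class = "gradient_field")
}

# one-axis masked finite difference; axis 2 = x (columns), 1 = y (rows)
masked_diff <- function(M, h, fluid, axis) {
  if (axis == 1) {
    t(masked_diff(t(M), h, t(fluid), 2))
  } else {
    nc <- ncol(M)
    pad <- function(A, fill) matrix(fill, nrow(A), 1)
    Mleft <- cbind(pad(M, NA), M[, -nc, drop = FALSE])
    Mright <- cbind(M[, -1, drop = FALSE], pad(M, NA))
    Mright2 <- cbind(M[, -(1:2), drop = FALSE], pad(M, NA), pad(M, NA))
    Mleft2 <- cbind(pad(M, NA), pad(M, NA), M[, -((nc - 1):nc), drop = FALSE])
    fl <- cbind(pad(fluid, FALSE) == 1, fluid[, -nc, drop = FALSE])
    fr <- cbind(fluid[, -1, drop = FALSE], pad(fluid, FALSE) == 1)
    fl2 <- cbind(matrix(FALSE, nrow(M), 2), fluid[, -((nc - 1):nc), drop = FALSE])
    fr2 <- cbind(fluid[, -(1:2), drop = FALSE], matrix(FALSE, nrow(M), 2))
    out <- matrix(NA_real_, nrow(M), nc)
    cc <- fl & fr
    out[cc] <- (Mright[cc] - Mleft[cc]) / (2 * h)
    fwd2 <- !fl & fr & fr2
    out[fwd2] <- (-3 * M[fwd2] + 4 * Mright[fwd2] - Mright2[fwd2]) / (2 * h)
    fwd1 <- !fl & fr & !fr2
    out[fwd1] <- (Mright[fwd1] - M[fwd1]) / h
    bwd2 <- fl & !fr & fl2
    out[bwd2] <- (3 * M[bwd2] - 4 * Mleft[bwd2] + Mleft2[bwd2]) / (2 * h)
    bwd1 <- fl & !fr & !fl2
    out[bwd1] <- (M[bwd1] - Mleft[bwd1]) / h
    out[!fluid] <- NA_real_
    out
  }
}

slice_gradients <- function(u, v, h, fluid) {
  list(dudx = masked_diff(u, h, fluid, 2),
       dudy = masked_diff(u, h, fluid, 1),
       dvdx = masked_diff(v, h, fluid, 2),
       dvdy = masked_diff(v, h, fluid, 1))
}

#' Q-criterion of a velocity-gradient field
#'
#' `Q = (|Omega|^2 - |S|^2) / 2` with Frobenius norms of the vorticity
#' (antisymmetric) and rate-of-strain (symmetric) parts of the velocity
#' gradient tensor. Positive where rotation dominates strain — the signature
#' of true recirculation as opposed to parallel shear. In 2D, for a
#' divergence-free field, Q equals the determinant of the velocity-gradient
#' tensor.
#'
#' @param grad A `gradient_field` from [velocity_gradients()].
#' @return Matrix of Q values (1/s^2), `NA` at solid nodes.
#' @export
q_criterion <- function(grad) {
  stopifnot(inherits(grad, "gradient_field"))
  0.5 * (grad$omega_z^2 / 2 -
           (grad$s11^2 + grad$s22^2 + 2 * grad$s12^2))
}

#' Q-criterion threshold: the standard deviation of Q
#'
#' The population standard deviation of Q over all fluid-node space-time
#' samples of (at least) one forcing period. Used as the detection threshold
#' for true vortex regions.
#'
#' @param Q A numeric array/matrix of Q samples (NAs ignored), or a
#'   `q_field`.
#' @return Threshold in 1/s^2.
#' @export
q_threshold <- function(Q) {
  if (inherits(Q, "q_field")) return(Q$q_thresh)
  q <- as.vector(Q)
  q <- q[!is.na(q)]
  if (!length(q)) abort("no fluid samples: cannot compute a Q threshold.")
  sqrt(mean((q - mean(q))^2))
}

#' Q-criterion analysis of a field over one period
#'
#' Computes Q on every stored time slice, the SD-based threshold, and the
#' per-node maximum of Q over the period.
#'
#' @param field A `gridded_field` (sample analytic providers first with
#'   [sample_field()]).
#' @param min_area Minimum vortex-region area in cells (see
#'   [vortex_regions()]).
#' @param connectivity 4 or 8, for region labeling.
#' @return A `q_field`: Q array `(ny, nx, nt)`, `q_thresh`, `max_q_map`.
#' @export
q_analysis <- function(field, min_area = 4, connectivity = 4) {
  stopifnot(inherits(field, "gridded_field"))
  nt <- length(field$times)
  Q <- array(NA_real_, c(length(field$y), length(field$x), nt))
  fluid <- !field$solid_mask
  for (k in seq_len(nt)) {
    g <- slice_gradients(field$u[, , k], field$v[, , k], field$dx, fluid)
    gf <- new_gradient_field(g, field$x, field$y, field$times[k], fluid)
    Q[, , k] <- q_criterion(gf)
  }
  structure(
    list(Q = Q, q_thresh = q_threshold(Q),
         max_q_map = apply(Q, c(1, 2), function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)),
         x = field$x, y = field$y, times = field$times,
         fluid = fluid, substrate = field$substrate, dx = field$dx,
         min_area = min_area, connectivity = connectivity),
    class = "q_field")
}

#' @export
print.q_field <- function(x, ...) {
  cat(sprintf("<q_field> %d x %d grid, %d slices, Q_thresh = %.4g 1/s^2\n",
              length(x$y), length(x$x), length(x$times), x$q_thresh))
  invisible(x)
}

#' Label supra-threshold vortex regions
#'
#' Connected components (default 4-connectivity) of `Q > Q_thresh`,
#' discarding components smaller than `min_area` cells.
#'
#' @param q A `q_field`, or a numeric Q matrix.
#' @param t Time(s) of the slice(s) to label (default: all stored slices);
#'   ignored when `q` is a matrix.
#' @param q_thresh Threshold; defaults to the `q_field`'s own.
#' @param min_area Minimum component size in cells.
#' @param connectivity 4 or 8.
#' @return A tibble with one row per region: `t`, `region`, `area` (cells),
#'   centroid `x`, `y` (mm, Q-weighted), and `q_max`.
#' @export
vortex_regions <- function(q, t = NULL, q_thresh = NULL, min_area = 4,
                           connectivity = 4) {
  if (is.matrix(q)) {
    if (is.null(q_thresh)) abort("`q_thresh` is required for a plain Q matrix.")
    return(label_regions(q, q_thresh, min_area, connectivity,
                         x = seq_len(ncol(q)), y = seq_len(nrow(q)), t = NA_real_))
  }
  stopifnot(inherits(q, "q_field"))
  q_thresh <- q_thresh %||% q$q_thresh
  ks <- if (is.null(t)) seq_along(q$times) else
    vapply(t, function(ti) which.min(abs(q$times - ti)), integer(1))
  purrr::map_dfr(ks, function(k) {
    label_regions(q$Q[, , k], q_thresh, min_area, connectivity,
                  x = q$x, y = q$y, t = q$times[k])
  })
}

label_regions <- function(Q, q_thresh, min_area, connectivity, x, y, t) {
  mask <- !is.na(Q) & Q > q_thresh
  lab <- label_components_cpp(mask, as.integer(connectivity))
  if (max(lab) == 0) {
    return(tibble(t = double(), region = integer(), area = integer(),
                  x = double(), y = double(), q_max = double()))
  }
  keep <- which(tabulate(lab[lab > 0]) >= min_area)
  purrr::map_dfr(seq_along(keep), function(i) {
    idx <- which(lab == keep[i], arr.ind = TRUE)
    qv <- Q[lab == keep[i]]
    tibble(t = t, region = i, area = nrow(idx),
           x = sum(x[idx[, 2]] * qv) / sum(qv),
           y = sum(y[idx[, 1]] * qv) / sum(qv),
           q_max = max(qv))
  })
}

#' Mean near-substrate flow speed over time
#'
#' Spatial mean of the speed magnitude within a band of height `band_height`
#' measured normal to the local surface (piecewise-constant elevation for
#' ridged substrates), per stored time slice.
#'
#' @param field A `gridded_field`.
#' @param band_height Band height above the local surface, mm.
#' @param cavity_only For ridged substrates, restrict the band to the
#'   inter-ridge cavities (columns between ridges).
#' @return A tibble `(t, speed, n_nodes)` with the forcing period and band
#'   parameters in attributes.
#' @export
band_speed <- function(field, band_height = 1.5, cavity_only = FALSE) {
  stopifnot(inherits(field, "gridded_field"))
  if (band_height <= 0) abort("`band_height` must be positive.")
  elev <- elevation(field$substrate, field$x)
  rel <- outer(field$y, elev, `-`)
  band <- rel > 0 & rel <= band_height & !field$solid_mask
  if (cavity_only) {
    if (field$substrate$kind != "ridged") {
      abort("`cavity_only = TRUE` needs a ridged substrate.")
    }
    band <- band & rep(elev == 0, each = length(field$y))
  }
  if (!any(band)) abort("the band contains no fluid nodes.")
  sp <- vapply(seq_along(field$times), function(k) {
    mean(sqrt(field$u[, , k][band]^2 + field$v[, , k][band]^2))
  }, numeric(1))
  out <- tibble(t = field$times, speed = sp, n_nodes = sum(band))
  attr(out, "period") <- field$forcing$period
  attr(out, "band_height") <- band_height
  attr(out, "cavity_only") <- cavity_only
  out
}

# maximal sub-threshold intervals of a sampled series, boundaries by linear
# interpolation; periodic series get their wrap-around interval merged
threshold_intervals <- function(t, v, threshold, period = NULL) {
  stopifnot(length(t) == length(v), !is.unsorted(t))
  if (!is.null(period)) {
    t <- c(t, t[1] + period)
    v <- c(v, v[1])
  }
  below <- v < threshold
  starts <- c(); ends <- c()
  open <- FALSE
  for (i in seq_along(t)) {
    if (below[i] && !open) {
      open <- TRUE
      starts <- c(starts, if (i == 1) t[1] else
        t[i - 1] + (threshold - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1]))
    } else if (!below[i] && open) {
      open <- FALSE
      ends <- c(ends, t[i - 1] + (threshold - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1]))
    }
  }
  if (open) ends <- c(ends, t[length(t)])
  iv <- tibble(t_start = starts %||% double(), t_end = ends %||% double())
  if (!is.null(period) && nrow(iv) >= 2) {
    wraps <- abs(iv$t_start[1] - t[1]) < 1e-12 &&
      abs(iv$t_end[nrow(iv)] - (t[1] + period)) < 1e-12
    if (wraps) {
      iv$t_end[nrow(iv)] <- iv$t_end[1] + period
      iv <- iv[-1, ]
    }
  }
  iv$duration <- iv$t_end - iv$t_start
  iv
}

#' Settling windows from a near-substrate speed series
#'
#' Settling windows are the maximal time intervals during which the
#' band-averaged flow speed falls below the larval threshold — by default
#' the mean larval swimming speed plus one standard deviation
#' (3 + 1 = 4 mm/s). The series is treated as periodic over one forcing
#' period; window boundaries are located by linear interpolation.
#'
#' @param band A tibble `(t, speed)` as returned by [band_speed()], covering
#'   one period.
#' @param u_ell Larval swimming speed, mm/s.
#' @param sd_u Standard deviation of the swimming speed, mm/s.
#' @param threshold Speed threshold, mm/s; default `u_ell + sd_u`. Set
#'   `threshold = u_ell` for the stricter cutoff.
#' @param period Forcing period (s); taken from `band`'s attributes when
#'   present.
#' @return A `settling_windows` object: interval tibble plus total duration
#'   and period fraction.
#' @export
settling_windows <- function(band, u_ell = 3, sd_u = 1,
                             threshold = u_ell + sd_u, period = NULL) {
  period <- period %||% attr(band, "period")
  if (is.null(period)) abort("`period` is required (not found in attributes).")
  if (threshold <= 0) abort("`threshold` must be positive.")
  t <- band$t
  v <- band$speed
  iv <- threshold_intervals(t, v, threshold, period = period)
  structure(
    list(intervals = iv,
         n_windows = nrow(iv),
         total_duration = sum(iv$duration),
         period_fraction = sum(iv$duration) / period,
         threshold = threshold, period = period,
         band = band),
    class = "settling_windows")
}

#' @export
print.settling_windows <- function(x, ...) {
  cat(sprintf("<settling_windows> %d window(s), total %.3f s (%.1f%% of the %g s period), threshold %g mm/s\n",
              x$n_windows, x$total_duration, 100 * x$period_fraction,
              x$period, x$threshold))
  invisible(x)
}

#' @export
tidy.settling_windows <- function(x, ...) x$intervals

#' @export
glance.settling_windows <- function(x, ...) {
  tibble(n_windows = x$n_windows, total_duration = x$total_duration,
         period_fraction = x$period_fraction, threshold = x$threshold,
         period = x$period)
}

#' Classify surface points by the Q-criterion overhead
#'
#' A point "lies under a vortex region" if any fluid node in the one-cell-
#' wide vertical column above it, up to `column_height`, exceeds the Q
#' threshold at any sampled time of the period.
#'
#' @param points A data frame with columns `x`, `y` (mm), points on or near
#'   the substrate surface.
#' @param q A `q_field` from [q_analysis()].
#' @param column_height Height of the interrogation column, mm.
#' @param q_thresh Threshold; defaults to the `q_field`'s own.
#' @return `points` with a logical `under_vortex` column added.
#' @export
classify_points_by_q <- function(points, q, column_height = 1.5,
                                 q_thresh = NULL) {
  stopifnot(inherits(q, "q_field"))
  q_thresh <- q_thresh %||% q$q_thresh
  xr <- range(q$x); yr <- range(q$y)
  under <- vapply(seq_len(nrow(points)), function(i) {
    xi <- points$x[i]; yi <- points$y[i]
    if (xi < xr[1] - q$dx / 2 || xi > xr[2] + q$dx / 2 ||
        yi < yr[1] - q$dx / 2 || yi > yr[2] + q$dx / 2) {
      abort("point outside the analysed domain.")
    }
    if (column_height <= 0) return(FALSE)
    j <- which.min(abs(q$x - xi))
    rows <- which(q$y > yi & q$y <= yi + column_height & q$fluid[, j])
    if (!length(rows)) return(FALSE)
    any(q$Q[rows, j, ] > q_thresh, na.rm = TRUE)
  }, logical(1))
  dplyr::mutate(as_tibble(points), under_vortex = under)
}

#' Turbulent energy fraction of a velocity time series
#'
#' Fraction of periodogram power outside the DC bin and the fundamental
#' (forcing) frequency bin plus/minus one bin. A clean sinusoidal record
#' yields ~0; broadband fluctuations raise the fraction toward their share
#' of the variance.
#'
#' @param v Velocity samples, uniformly spaced.
#' @param dt Sampling interval, s.
#' @param period Forcing period, s. The record must cover at least 4
#'   periods.
#' @return Dimensionless fraction in \[0, 1\].
#' @export
turbulent_energy_fraction <- function(v, dt, period) {
  n <- length(v)
  if (n * dt < 4 * period - 1e-9) {
    abort("the series must cover at least 4 forcing periods.")
  }
  P <- Mod(fft(v))^2
  kf <- round(n * dt / period)
  drop0 <- 1L                              # DC (R index 1)
  kfund <- kf + c(-1L, 0L, 1L)
  kfund <- kfund[kfund >= 1 & kfund <= n - 1]
  drop <- unique(c(drop0, kfund + 1L, n + 1L - kfund))
  keep <- setdiff(seq_len(n), drop)
  tot <- sum(P[-drop0])
  if (tot <= 0) return(0)
  sum(P[keep]) / tot
}
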