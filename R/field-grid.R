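#' Materialise an analytic field on a uniform grid
#'
#' Samples an analytic provider onto a uniform grid (default spacing 0.05 mm)
#' at `nt` evenly spaced instants over one period. Velocities are obtained as
#' central differences of the sampled streamfunction, so the discrete
#' (central) divergence at interior fluid nodes cancels identically;
#' velocities at solid nodes are exactly zero.
#'
#' @param field An analytic `larvaflow_field`.
#' @param dx Grid spacing in mm (`dx = dy`).
#' @param nt Number of stored time slices per period.
#' @param xlim,ylim Optional sub-domain extents (mm); default the full domain.
#' @return A `gridded_field` object.
#' @export
sample_field <- function(field, dx = 0.05, nt = 64, xlim = NULL, ylim = NULL) {
  stopifnot(inherits(field, "analytic_field"))
  if (dx <= 0) abort("`dx` must be positive.")
  xlim <- xlim %||% c(0, field$domain$length)
  ylim <- ylim %||% c(0, field$domain$height)
  x <- seq(xlim[1], xlim[2], by = dx)
  y <- seq(ylim[1], ylim[2], by = dx)
  if (field$substrate$kind == "ridged") {
    ncav <- field$substrate$ridge_spacing / dx
    if (ncav < 8) abort("fewer than 8 grid nodes across a cavity; use a smaller `dx`.")
  }
  times <- seq(0, field$forcing$period, length.out = nt + 1)[seq_len(nt)]
  nx <- length(x); ny <- length(y)
  xg <- c(x[1] - dx, x, x[nx] + dx)
  yg <- c(y[1] - dx, y, y[ny] + dx)
  elev <- elevation(field$substrate, x)
  solid <- outer(y, elev, `<=`)
  XX <- matrix(rep(xg, each = ny + 2), ny + 2, nx + 2)
  YY <- matrix(rep(yg, times = nx + 2), ny + 2, nx + 2)
  u <- array(0, c(ny, nx, nt))
  v <- array(0, c(ny, nx, nt))
  for (k in seq_len(nt)) {
    psi <- matrix(field_psi(field, as.vector(XX), as.vector(YY), times[k]),
                  ny + 2, nx + 2)
    uk <- (psi[3:(ny + 2), 2:(nx + 1)] - psi[1:ny, 2:(nx + 1)]) / (2 * dx)
    vk <- -(psi[2:(ny + 1), 3:(nx + 2)] - psi[2:(ny + 1), 1:nx]) / (2 * dx)
    uk[solid] <- 0
    vk[solid] <- 0
    u[, , k] <- uk
    v[, , k] <- vk
  }
  gridded_field(x, y, times, u, v, solid,
                forcing = field$forcing, fluid = field$fluid,
                substrate = field$substrate, kind = field$kind)
}

#' Construct a gridded velocity field
#'
#' Container for a time-resolved 2D velocity field on a uniform grid with a
#' solid mask. Times must cover one forcing period; evaluation wraps time
#' periodically and interpolates linearly between stored slices.
#'
#' @param x,y Grid coordinates (mm), uniform spacing.
#' @param times Sampled instants (s) within one period.
#' @param u,v Arrays of dim `(length(y), length(x), length(times))`, mm/s.
#' @param solid_mask Logical matrix `(length(y), length(x))`.
#' @param forcing,fluid,substrate Metadata objects (see
#'   [oscillatory_forcing()], [fluid_properties()], [substrate_profile()]).
#' @param kind Label for the provenance of the field.
#' @return A `gridded_field` object.
#' @export
gridded_field <- function(x, y, times, u, v, solid_mask,
                          forcing, fluid = fluid_properties(),
                          substrate = substrate_profile("flat"),
                          kind = "gridded") {
  dims <- c(length(y), length(x), length(times))
  if (!all(dim(u) == dims) || !all(dim(v) == dims)) {
    abort("`u` and `v` must have dim (length(y), length(x), length(times)).")
  }
  if (!all(dim(solid_mask) == dims[1:2])) {
    abort("`solid_mask` must have dim (length(y), length(x)).")
  }
  dxs <- diff(x)
  if (length(dxs) && max(abs(dxs - dxs[1])) > 1e-9 * max(abs(dxs))) {
    abort("`x` must be uniformly spaced.")
  }
  structure(
    list(provider = "gridded", kind = kind,
         x = x, y = y, times = times, dx = if (length(dxs)) dxs[1] else NA_real_,
         u = u, v = v, solid_mask = solid_mask,
         forcing = forcing, fluid = fluid, substrate = substrate,
         domain = list(length = diff(range(x)), height = max(y))),
    class = c("gridded_field", "larvaflow_field")
  )
}

# periodic linear time interpolation weights for stored slices
time_weights <- function(field, t) {
  Tp <- field$forcing$period
  nt <- length(field$times)
  dtt <- Tp / nt
  tau <- (t - field$times[1]) %% Tp
  k0 <- floor(tau / dtt + 1e-12)
  w <- tau / dtt - k0
  w[w < 1e-12] <- 0
  k0 <- (k0 %% nt) + 1
  k1 <- (k0 %% nt) + 1
  list(k0 = k0, k1 = k1, w = w)
}

# bilinear interpolation of one matrix slice at scattered points
interp_slice <- function(field, M, xp, yp) {
  xp <- pmin(pmax(xp, min(field$x)), max(field$x))
  yp <- pmin(pmax(yp, min(field$y)), max(field$y))
  pracma::interp2(field$x, field$y, M, xp, yp, method = "linear")
}

#' @export
field_eval.gridded_field <- function(field, x, y, t, gradients = FALSE) {
  n <- max(length(x), length(y), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  tw <- time_weights(field, t)
  out <- tibble(x = x, y = y, t = t, u = NA_real_, v = NA_real_)
  if (gradients) {
    out$dudx <- NA_real_; out$dudy <- NA_real_
    out$dvdx <- NA_real_; out$dvdy <- NA_real_
  }
  grads_k <- list()
  get_grads <- function(k) {
    key <- as.character(k)
    if (is.null(grads_k[[key]])) {
      g <- slice_gradients(field$u[, , k], field$v[, , k],
                           field$dx, !field$solid_mask)
      grads_k[[key]] <<- g
    }
    grads_k[[key]]
  }
  for (k in unique(c(tw$k0, tw$k1))) {
    for (side in 1:2) {
      idx <- if (side == 1) which(tw$k0 == k) else which(tw$k1 == k & tw$w > 0)
      if (!length(idx)) next
      wgt <- if (side == 1) 1 - tw$w[idx] else tw$w[idx]
      uu <- interp_slice(field, field$u[, , k], x[idx], y[idx])
      vv <- interp_slice(field, field$v[, , k], x[idx], y[idx])
      out$u[idx] <- ifelse(is.na(out$u[idx]), 0, out$u[idx]) + wgt * uu
      out$v[idx] <- ifelse(is.na(out$v[idx]), 0, out$v[idx]) + wgt * vv
      if (gradients) {
        g <- get_grads(k)
        for (nm in c("dudx", "dudy", "dvdx", "dvdy")) {
          gg <- interp_slice(field, g[[nm]], x[idx], y[idx])
          out[[nm]][idx] <- ifelse(is.na(out[[nm]][idx]), 0, out[[nm]][idx]) + wgt * gg
        }
      }
    }
  }
  out
}

#' Resample a gridded field onto a new uniform spacing
#'
#' Bilinear resampling of `u` and `v`; the solid mask is resampled
#' conservatively (a target node is solid if its grid cell overlaps any solid
#' source cell). Analytic providers are sampled directly at the requested
#' spacing.
#'
#' @param field A `larvaflow_field`.
#' @param dx Target grid spacing in mm.
#' @return A `gridded_field`.
#' @export
regrid_field <- function(field, dx) {
  if (dx <= 0) abort("`dx` must be positive.")
  if (inherits(field, "analytic_field")) return(sample_field(field, dx = dx))
  if (dx > field$domain$length || dx > field$domain$height) {
    abort("`dx` is larger than the domain extent.")
  }
  x2 <- seq(min(field$x), max(field$x), by = dx)
  y2 <- seq(min(field$y), max(field$y), by = dx)
  nt <- length(field$times)
  nx2 <- length(x2); ny2 <- length(y2)
  solid2 <- resample_mask_conservative(field$x, field$y, field$solid_mask,
                                       field$dx, x2, y2, dx)
  u2 <- array(0, c(ny2, nx2, nt))
  v2 <- array(0, c(ny2, nx2, nt))
  XP <- rep(x2, each = ny2)
  YP <- rep(y2, times = nx2)
  for (k in seq_len(nt)) {
    uk <- matrix(interp_slice(field, field$u[, , k], XP, YP), ny2, nx2)
    vk <- matrix(interp_slice(field, field$v[, , k], XP, YP), ny2, nx2)
    uk[solid2] <- 0; vk[solid2] <- 0
    u2[, , k] <- uk; v2[, , k] <- vk
  }
  gridded_field(x2, y2, field$times, u2, v2, solid2,
                forcing = field$forcing, fluid = field$fluid,
                substrate = field$substrate, kind = field$kind)
}

resample_mask_conservative <- function(xs, ys, mask, dxs, x2, y2, dx2) {
  n_solid <- matrix(0L, nrow(mask) + 1, ncol(mask) + 1)
  n_solid[-1, -1] <- apply(apply(mask * 1L, 2, cumsum), 1, cumsum) |> t()
  eps <- 1e-9
  col_rng <- function(x0, x1, grid, half) {
    lo <- findInterval(x0 - half + eps, grid) + 1L
    hi <- findInterval(x1 + half - eps, grid)
    c(lo, hi)
  }
  ny2 <- length(y2); nx2 <- length(x2)
  out <- matrix(FALSE, ny2, nx2)
  hs <- dxs / 2; h2 <- dx2 / 2
  for (j in seq_len(nx2)) {
    cr <- col_rng(x2[j] - h2, x2[j] + h2, xs, hs)
    if (cr[1] > cr[2]) next
    for (i in seq_len(ny2)) {
      rr <- col_rng(y2[i] - h2, y2[i] + h2, ys, hs)
      if (rr[1] > rr[2]) next
      cnt <- n_solid[rr[2] + 1, cr[2] + 1] - n_solid[rr[1], cr[2] + 1] -
        n_solid[rr[2] + 1, cr[1]] + n_solid[rr[1], cr[1]]
      out[i, j] <- cnt > 0
    }
  }
  out
}

#' @export
as_tibble.gridded_field <- function(x, ..., times = NULL) {
  ks <- if (is.null(times)) seq_along(x$times) else match(times, x$times)
  if (anyNA(ks)) abort("`times` must match stored time slices.")
  purrr::map_dfr(ks, function(k) {
    tibble(t = x$times[k],
           x = rep(x$x, each = length(x$y)),
           y = rep(x$y, times = length(x$x)),
           u = as.vector(x$u[, , k]),
           v = as.vector(x$v[, , k]),
           solid = as.vector(x$solid_mask))
  })
}

#' @export
as_tibble.analytic_field <- function(x, ..., dx = 0.5, nt = 8) {
  as_tibble(sample_field(x, dx = dx, nt = nt))
}
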