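#' Ellipsoidal shape parameter
#'
#' `alpha = (1 - (b/a)^2) / (1 + (b/a)^2)`: 0 for a sphere, approaching 1
#' for a needle. Weights the strain contribution to the rotation of an
#' ellipsoid in shear (Jeffery dynamics).
#'
#' @param a Semi-major axis, mm.
#' @param b Semi-minor axis, mm (`0 < b <= a`).
#' @return Dimensionless shape parameter in \[0, 1).
#' @examples
#' shape_parameter(0.25, 0.15)
#' @export
shape_parameter <- function(a, b) {
  if (any(b <= 0) || any(b > a)) abort("need a >= b > 0.")
  r2 <- (b / a)^2
  (1 - r2) / (1 + r2)
}

#' Larval swimmer parameters
#'
#' Neutrally buoyant prolate-spheroid swimmer with constant swimming speed
#' along its major axis. Defaults: semi-axes 0.25 x 0.15 mm (a 0.5 mm long,
#' 0.3 mm wide larva) and a species-averaged swimming speed of 3 +/- 1 mm/s.
#' The standard deviation enters only the settlement criterion (the speed
#' gate `u_ell + sd_u`).
#'
#' @param a,b Semi-major/minor axes, mm.
#' @param u_ell Swimming speed, mm/s.
#' @param sd_u Standard deviation of the swimming speed, mm/s.
#' @return A list of class `larva_params` (with derived `alpha`).
#' @export
larva_params <- function(a = 0.25, b = 0.15, u_ell = 3, sd_u = 1) {
  structure(list(a = a, b = b, u_ell = u_ell, sd_u = sd_u,
                 alpha = shape_parameter(a, b)),
            class = "larva_params")
}

#' Simulation configuration
#'
#' The default seeding lattice is 30 positions x 32 orientations x 20
#' release phases = 19,200 agents, released 10 mm above the substrate and
#' integrated with a 0.01 s time step (0.18% of the default period) for at
#' most `max_time` seconds. Boundaries: periodic in x, rigid substrate
#' below, open (absorbing) top.
#'
#' @param dt Time step, s.
#' @param n_positions,n_orientations,n_phases Lattice dimensions.
#' @param seed_height Release height above the substrate base, mm.
#' @param max_time Maximum simulated time per agent, s; agents still
#'   swimming then are reported `unresolved`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, n_positions = 30, n_orientations = 32,
                       n_phases = 20, seed_height = 10, max_time = 120) {
  if (dt <= 0) abort("`dt` must be positive.")
  structure(list(dt = dt, n_positions = n_positions,
                 n_orientations = n_orientations, n_phases = n_phases,
                 seed_height = seed_height, max_time = max_time),
            class = "sim_config")
}

#' Total larval velocity
#'
#' `rdot = U + u_ell * n_hat`, with `n_hat = (cos(theta), sin(theta))` the
#' unit vector along the larva's major axis.
#'
#' @param u,v Local flow velocity components, mm/s.
#' @param theta Orientation of the major axis, rad.
#' @param u_ell Swimming speed, mm/s.
#' @return A tibble `(vx, vy)` in mm/s.
#' @export
larval_velocity <- function(u, v, theta, u_ell = 3) {
  tibble(vx = u + u_ell * cos(theta), vy = v + u_ell * sin(theta))
}

#' Total larval angular velocity
#'
#' `thetadot = omega_z / 2 + alpha * g_hat . (S n_hat)`, where `omega_z` is
#' the vorticity, `S` the (symmetric) rate-of-strain tensor, `n_hat` the
#' major-axis direction and `g_hat = (-sin(theta), cos(theta))` the
#' minor-axis direction. A sphere (`alpha = 0`) rotates at exactly
#' `omega_z / 2`.
#'
#' @param theta Orientation, rad (vectorised).
#' @param omega_z Vorticity, 1/s.
#' @param S Rate-of-strain tensor: a 2x2 symmetric matrix, or a list with
#'   components `s11`, `s12`, `s22` (vectorised).
#' @param alpha Shape parameter.
#' @return Angular velocity, rad/s.
#' @export
larval_rotation <- function(theta, omega_z, S, alpha) {
  if (is.matrix(S)) {
    if (max(abs(S - t(S))) > 1e-9 * max(1, max(abs(S)))) {
      abort("`S` must be symmetric.")
    }
    S <- list(s11 = S[1, 1], s12 = S[1, 2], s22 = S[2, 2])
  }
  gSn <- (S$s22 - S$s11) * sin(theta) * cos(theta) +
    S$s12 * (cos(theta)^2 - sin(theta)^2)
  omega_z / 2 + alpha * gSn
}

#' Deterministic seeding lattice of initial larval states
#'
#' The full cross product of evenly spaced streamwise positions (at
#' `seed_height`), orientations in \[0, 2 pi), and release times in one
#' forcing period. Contains no randomness.
#'
#' @param config A [sim_config()].
#' @param domain_length Periodic domain length, mm.
#' @param period Forcing period, s.
#' @return A tibble `(agent, x0, y0, theta0, t0)` with
#'   `n_positions * n_orientations * n_phases` rows.
#' @export
seed_lattice <- function(config = sim_config(), domain_length = 40,
                         period = 5.5) {
  if (domain_length <= 0) abort("`domain_length` must be positive.")
  xs <- domain_length * (seq_len(config$n_positions) - 1) / config$n_positions
  ths <- 2 * pi * (seq_len(config$n_orientations) - 1) / config$n_orientations
  t0s <- period * (seq_len(config$n_phases) - 1) / config$n_phases
  g <- expand.grid(x0 = xs, theta0 = ths, t0 = t0s, KEEP.OUT.ATTRS = FALSE)
  tibble(agent = seq_len(nrow(g)), x0 = g$x0, y0 = config$seed_height,
         theta0 = g$theta0, t0 = g$t0)
}

#' Settlement / exit check for larval states
#'
#' A larva settles when its centre is within one semi-minor axis `b` of a
#' solid surface while its total speed is below the speed gate
#' `u_ell + sd_u` (default 4 mm/s); it exits when above the domain top.
#'
#' @param x,y Position, mm.
#' @param speed Total speed `|rdot|`, mm/s.
#' @param substrate A [substrate_profile()].
#' @param params A [larva_params()].
#' @param domain_height Domain top, mm.
#' @return Character vector: `"settled"`, `"exited"` or `"swimming"`.
#' @export
check_settlement <- function(x, y, speed, substrate, params = larva_params(),
                             domain_height = 30) {
  gate <- params$u_ell + params$sd_u
  d <- surface_distance(substrate, x, y)
  dplyr::case_when(
    d <= params$b & speed < gate ~ "settled",
    y > domain_height ~ "exited",
    .default = "swimming")
}

#' Run the agent-based settlement simulation
#'
#' Advances every agent of the seeding lattice with the explicit-Euler
#' update of the larval equations of motion (translation by the local flow
#' plus swimming; rotation by vorticity plus the shape-weighted strain) at a
#' fixed time step, until it settles (surface contact under the speed gate),
#' exits the open top, or `max_time` elapses. Fully deterministic: repeated
#' runs give identical results. Analytic field providers use a compiled
#' fast path; gridded fields use interpolated gradients in R.
#'
#' @param field A `larvaflow_field`.
#' @param params A [larva_params()].
#' @param config A [sim_config()].
#' @param agents Optional tibble of initial states (`x0`, `y0`, `theta0`,
#'   `t0`); default [seed_lattice()] across the field's domain and period.
#' @return A `settlement_sim` object; see [tidy.settlement_sim()] and
#'   [glance.settlement_sim()].
#' @export
run_simulation <- function(field, params = larva_params(),
                           config = sim_config(), agents = NULL) {
  agents <- agents %||% seed_lattice(config, field$domain$length,
                                     field$forcing$period)
  if (!all(c("x0", "y0", "theta0", "t0") %in% names(agents))) {
    abort("`agents` needs columns x0, y0, theta0, t0.")
  }
  if (!"agent" %in% names(agents)) agents$agent <- seq_len(nrow(agents))
  if (inherits(field, "analytic_field")) {
    m <- engine_run(cbind(agents$x0, agents$y0, agents$theta0, agents$t0),
                    field$pars,
                    list(dt = config$dt, max_time = config$max_time,
                         u_ell = params$u_ell,
                         gate = params$u_ell + params$sd_u,
                         alpha = params$alpha, b = params$b))
    status <- c("settled", "exited", "unresolved")[m[, "status"]]
    res <- dplyr::mutate(agents, status = status,
                         t_final = m[, "t_final"], x_final = m[, "x_final"],
                         y_final = m[, "y_final"],
                         theta_final = m[, "theta_final"])
  } else {
    x <- agents$x0; y <- agents$y0; th <- agents$theta0; tt <- agents$t0
    status <- rep("swimming", length(x))
    nmax <- ceiling(config$max_time / config$dt - 1e-9)
    top <- field$domain$height
    dt <- config$dt
    Lx <- field$domain$length
    sub <- field$substrate
    gate <- params$u_ell + params$sd_u
    for (k in seq_len(nmax)) {
      act <- which(status == "swimming")
      if (!length(act)) break
      ev <- field_eval(field, x[act], y[act], tt[act], gradients = TRUE)
      vx <- ev$u + params$u_ell * cos(th[act])
      vy <- ev$v + params$u_ell * sin(th[act])
      spd <- sqrt(vx^2 + vy^2)
      settle <- surface_distance(sub, x[act], y[act]) <= params$b & spd < gate
      exit <- !settle & y[act] > top
      status[act[settle]] <- "settled"
      status[act[exit]] <- "exited"
      mv <- !settle & !exit
      if (!any(mv)) next
      i <- act[mv]
      thdot <- larval_rotation(th[i], ev$dvdx[mv] - ev$dudy[mv],
                               list(s11 = ev$dudx[mv],
                                    s12 = 0.5 * (ev$dudy[mv] + ev$dvdx[mv]),
                                    s22 = ev$dvdy[mv]),
                               params$alpha)
      xn <- (x[i] + dt * vx[mv]) %% Lx
      yn <- y[i] + dt * vy[mv]
      pen <- yn < elevation(sub, xn)
      if (any(pen)) {
        from_above <- pen & y[i] >= elevation(sub, xn)
        yn[from_above] <- y[i][from_above]
        wall <- pen & !from_above
        xn[wall] <- x[i][wall]
        still_pen <- wall & yn < elevation(sub, xn)
        yn[still_pen] <- y[i][still_pen]
      }
      x[i] <- xn; y[i] <- yn
      th[i] <- (th[i] + dt * thdot) %% (2 * pi)
      tt[i] <- tt[i] + dt
    }
    status[status == "swimming"] <- "unresolved"
    res <- dplyr::mutate(agents, status = status,
                         t_final = tt, x_final = x, y_final = y,
                         theta_final = th)
  }
  n <- nrow(res)
  counts <- table(factor(res$status,
                         levels = c("settled", "exited", "unresolved")))
  structure(
    list(agents = res, n = n,
         settled = unname(counts["settled"]),
         exited = unname(counts["exited"]),
         unresolved = unname(counts["unresolved"]),
         settlement_pct = 100 * unname(counts["settled"]) / n,
         params = params, config = config,
         substrate = field$substrate, forcing = field$forcing,
         field_kind = field$kind),
    class = "settlement_sim")
}

#' @export
print.settlement_sim <- function(x, ...) {
  cat(sprintf("<settlement_sim> %s substrate, %d agents: %.1f%% settled, %.1f%% exited, %.1f%% unresolved\n",
              x$substrate$kind, x$n, x$settlement_pct,
              100 * x$exited / x$n, 100 * x$unresolved / x$n))
  invisible(x)
}

#' Per-agent outcomes of a settlement simulation
#' @param x A `settlement_sim`.
#' @param ... Unused.
#' @return A tibble with one row per agent.
#' @export
tidy.settlement_sim <- function(x, ...) x$agents

#' One-row summary of a settlement simulation
#' @param x A `settlement_sim`.
#' @param ... Unused.
#' @export
glance.settlement_sim <- function(x, ...) {
  tibble(n = x$n, settled = x$settled, exited = x$exited,
         unresolved = x$unresolved,
         settlement_pct = x$settlement_pct,
         exited_pct = 100 * x$exited / x$n,
         unresolved_pct = 100 * x$unresolved / x$n,
         substrate = x$substrate$kind, field = x$field_kind)
}

#' Record a single larval trajectory
#'
#' Integrates one larva with the same scheme as [run_simulation()] and
#' records its state and the local flow every `save_every` steps.
#'
#' @param field An analytic `larvaflow_field`.
#' @param start Numeric `c(x, y, theta, t0)` initial state.
#' @param params A [larva_params()].
#' @param config A [sim_config()].
#' @param save_every Recording stride in steps.
#' @return A tibble `(t, x, y, theta, u, v, dudx, dudy, dvdx, dvdy)` with
#'   attribute `status`.
#' @export
simulate_trajectory <- function(field, start, params = larva_params(),
                                config = sim_config(), save_every = 1) {
  stopifnot(inherits(field, "analytic_field"))
  tr <- engine_trajectory(as.numeric(start), field$pars,
                          list(dt = config$dt, max_time = config$max_time,
                               u_ell = params$u_ell,
                               gate = params$u_ell + params$sd_u,
                               alpha = params$alpha, b = params$b),
                          as.integer(save_every))
  out <- tibble(t = tr$t, x = tr$x, y = tr$y, theta = tr$theta,
                u = tr$u, v = tr$v,
                dudx = tr$dudx, dudy = tr$dudy,
                dvdx = tr$dvdx, dvdy = tr$dvdy)
  attr(out, "status") <- c("settled", "exited", "unresolved")[tr$status]
  out
}

#' Along-trajectory hydrodynamic diagnostics
#'
#' Samples the instantaneous Q-criterion and relative flow speed
#' `|U| / u_ell` along a larval trajectory and identifies the larval active
#' windows — maximal intervals with `|U| / u_ell < 1`, during which the
#' larva can out-swim the local flow.
#'
#' @param trajectory A tibble with columns `t`, `x`, `y` (e.g. from
#'   [simulate_trajectory()]; gradient columns are reused if present).
#' @param field The `larvaflow_field` the trajectory was computed in
#'   (required if the trajectory lacks flow columns).
#' @param u_ell Larval swimming speed, mm/s.
#' @return A list of class `trajectory_diagnostics`: the annotated
#'   trajectory (`q`, `rel_speed` columns) and the `active_windows` tibble.
#' @export
trajectory_diagnostics <- function(trajectory, field = NULL, u_ell = 3) {
  tr <- as_tibble(trajectory)
  need <- c("u", "v", "dudx", "dudy", "dvdx", "dvdy")
  if (!all(need %in% names(tr))) {
    if (is.null(field)) abort("`field` is required when the trajectory has no flow columns.")
    ev <- field_eval(field, tr$x, tr$y, tr$t, gradients = TRUE)
    tr[need] <- ev[need]
  }
  omz <- tr$dvdx - tr$dudy
  tr$q <- 0.5 * (omz^2 / 2 -
                   (tr$dudx^2 + tr$dvdy^2 + 0.5 * (tr$dudy + tr$dvdx)^2))
  tr$rel_speed <- sqrt(tr$u^2 + tr$v^2) / u_ell
  aw <- threshold_intervals(tr$t, tr$rel_speed, 1)
  structure(list(trajectory = tr, active_windows = aw, u_ell = u_ell),
            class = "trajectory_diagnostics")
}

#' @export
print.trajectory_diagnostics <- function(x, ...) {
  cat(sprintf("<trajectory_diagnostics> %d samples, %d active window(s) totalling %.2f s\n",
              nrow(x$trajectory), nrow(x$active_windows),
              sum(x$active_windows$duration)))
  invisible(x)
}
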