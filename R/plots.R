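#' Plot a velocity-field snapshot
#'
#' Speed-magnitude heatmap of one time slice, with solid regions greyed
#' out. Analytic providers are sampled at `dx` first.
#'
#' @param object A `larvaflow_field`.
#' @param t Time of the snapshot, s.
#' @param dx Sampling resolution for analytic providers, mm.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.larvaflow_field <- function(object, t = NULL, dx = 0.1, ...) {
  t <- t %||% object$forcing$period / 4
  if (inherits(object, "analytic_field")) {
    object <- sample_field(object, dx = dx, nt = 8)
  }
  tw <- time_weights(object, t)
  u <- (1 - tw$w) * object$u[, , tw$k0] + tw$w * object$u[, , tw$k1]
  v <- (1 - tw$w) * object$v[, , tw$k0] + tw$w * object$v[, , tw$k1]
  df <- tibble(x = rep(object$x, each = length(object$y)),
               y = rep(object$y, times = length(object$x)),
               speed = as.vector(sqrt(u^2 + v^2)),
               solid = as.vector(object$solid_mask))
  df$speed[df$solid] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$speed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey40", name = "|U| (mm/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("t = %.2f s", t))
}

#' Plot settling windows over one forcing period
#'
#' Band-averaged near-substrate speed with the larval threshold and the
#' settling windows shaded.
#'
#' @param object A `settling_windows` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.settling_windows <- function(object, ...) {
  iv <- object$intervals
  p <- ggplot2::ggplot(object$band, ggplot2::aes(.data$t, .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "t (s)", y = "band speed (mm/s)")
  if (nrow(iv)) {
    iv2 <- iv
    iv2$t_end <- pmin(iv2$t_end, object$period)
    wrap <- iv$t_end > object$period
    if (any(wrap)) {
      iv2 <- dplyr::bind_rows(iv2, tibble(
        t_start = 0, t_end = iv$t_end[wrap] - object$period,
        duration = NA_real_))
    }
    p <- p + ggplot2::geom_rect(
      data = iv2, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.2, fill = "gold")
  }
  p
}

#' Plot settlement-simulation outcomes
#'
#' Outcome fractions per release phase (settled / exited / unresolved).
#'
#' @param object A `settlement_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.settlement_sim <- function(object, ...) {
  df <- dplyr::count(object$agents, .data$t0, .data$status)
  ggplot2::ggplot(df, ggplot2::aes(factor(round(.data$t0, 3)), .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = "release phase t0 (s)", y = "fraction", fill = NULL)
}

#' Plot the maximum Q-criterion map of a period
#'
#' @param object A `q_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.q_field <- function(object, ...) {
  df <- tibble(x = rep(object$x, each = length(object$y)),
               y = rep(object$y, times = length(object$x)),
               q = as.vector(object$max_q_map))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$q)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey40",
                                  name = "max Q (1/s²)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  subtitle = sprintf("Q_thresh = %.3g 1/s²", object$q_thresh))
}

#' Plot along-trajectory diagnostics
#'
#' Relative flow speed and instantaneous Q along a larval trajectory, with
#' active windows shaded.
#'
#' @param object A `trajectory_diagnostics` object.
#' @param ... Unused.
#' @return A ggplot (two stacked facets).
#' @export
autoplot.trajectory_diagnostics <- function(object, ...) {
  tr <- object$trajectory
  df <- tidyr::pivot_longer(tr[, c("t", "q", "rel_speed")],
                            cols = c("q", "rel_speed"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "t (s)", y = NULL)
  if (nrow(object$active_windows)) {
    p <- p + ggplot2::geom_rect(
      data = object$active_windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.2, fill = "gold")
  }
  p
}
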