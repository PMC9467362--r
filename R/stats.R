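#' Settlement fraction per group
#'
#' `100 * settled / total` per group. Accepts a `settlement_sim` (grouping
#' optional, e.g. by release phase) or a tibble of per-run counts.
#'
#' @param x A `settlement_sim`, or a data frame with columns `settled` and
#'   `total` (counts).
#' @param by Optional grouping column name(s) (for `settlement_sim`: any
#'   column of its agent table, e.g. `"t0"`).
#' @return A tibble with `settled`, `total` and `settlement_pct` per group.
#' @export
settlement_fraction <- function(x, by = NULL) {
  if (inherits(x, "settlement_sim")) {
    ag <- x$agents
    if (is.null(by)) {
      return(tibble(settled = x$settled, total = x$n,
                    settlement_pct = 100 * x$settled / x$n))
    }
    out <- dplyr::summarise(
      dplyr::group_by(ag, dplyr::across(dplyr::all_of(by))),
      settled = sum(.data$status == "settled"),
      total = dplyr::n(), .groups = "drop")
    return(dplyr::mutate(out, settlement_pct = 100 * .data$settled / .data$total))
  }
  x <- as_tibble(x)
  if (!all(c("settled", "total") %in% names(x))) {
    abort("need columns `settled` and `total`.")
  }
  if (any(x$total <= 0)) abort("`total` must be positive.")
  dplyr::mutate(x, settlement_pct = 100 * .data$settled / .data$total)
}

#' Arcsine-square-root (angular) transform of proportions
#'
#' `asin(sqrt(p))`, the classical variance-stabilising transform applied to
#' settlement proportions before ANOVA.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed value(s) in radians.
#' @examples
#' arcsine_transform(c(0, 0.25, 1))
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  asin(sqrt(p))
}

#' Fixed-effects ANOVA with Tukey HSD contrasts
#'
#' One- or two-factor fixed-effects analysis of variance with post-hoc
#' Tukey Honestly Significant Difference comparisons, at significance level
#' `alpha`. Two factors are crossed (`y ~ f1 * f2`).
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param factors Character vector of 1 or 2 factor column names.
#' @param alpha Significance level for the Tukey comparisons.
#' @return A `larvaflow_anova` object; `tidy()` gives the ANOVA table,
#'   `glance()` a one-row summary, and `$tukey` the pairwise comparisons
#'   with a `significant` flag.
#' @export
anova_tukey <- function(data, response, factors, alpha = 0.05) {
  stopifnot(length(factors) %in% 1:2, response %in% names(data),
            all(factors %in% names(data)))
  d <- as.data.frame(data)
  for (f in factors) d[[f]] <- factor(d[[f]])
  if (any(table(d[factors]) < 1)) abort("every factor combination needs data.")
  vr <- stats::var(d[[response]])
  if (!is.na(vr) && vr == 0) {
    warn("response has zero variance everywhere; F statistics are undefined.")
  }
  fml <- stats::reformulate(paste(factors, collapse = " * "), response)
  fit <- aov(fml, data = d)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)
  tukey <- purrr::map_dfr(names(tk), function(term) {
    m <- tk[[term]]
    tibble(term = term, contrast = rownames(m),
           estimate = m[, "diff"], conf.low = m[, "lwr"],
           conf.high = m[, "upr"], adj.p.value = m[, "p adj"],
           significant = m[, "p adj"] < alpha)
  })
  structure(list(fit = fit, anova = broom::tidy(fit), tukey = tukey,
                 alpha = alpha, factors = factors, response = response),
            class = "larvaflow_anova")
}

#' @export
print.larvaflow_anova <- function(x, ...) {
  cat(sprintf("<larvaflow_anova> %s ~ %s (alpha = %g)\n", x$response,
              paste(x$factors, collapse = " * "), x$alpha))
  print(x$anova)
  cat("Tukey HSD:\n")
  print(x$tukey)
  invisible(x)
}

#' @export
tidy.larvaflow_anova <- function(x, ...) x$anova

#' @export
glance.larvaflow_anova <- function(x, ...) {
  main <- x$anova[x$anova$term != "Residuals", ]
  tibble(n_terms = nrow(main),
         min_p = min(main$p.value, na.rm = TRUE),
         df_residual = x$anova$df[x$anova$term == "Residuals"],
         alpha = x$alpha,
         n_significant_contrasts = sum(x$tukey$significant))
}

#' Distances of settlement locations to the nearest ridge base
#'
#' Horizontal distance from each settler to the nearest ridge flank at
#' floor level, and the fraction of settlers within `d` of a flank.
#'
#' @param x Settler x-positions (mm), or a `settlement_sim` over a ridged
#'   substrate (settled agents are used).
#' @param substrate A ridged [substrate_profile()] (taken from the
#'   `settlement_sim` when omitted).
#' @param d Distance bound for the summary fraction, mm.
#' @return A list of class `ridge_distances`: per-settler tibble and the
#'   `fraction_within` summary.
#' @export
ridge_distance_histogram <- function(x, substrate = NULL, d = 1) {
  if (inherits(x, "settlement_sim")) {
    substrate <- substrate %||% x$substrate
    x <- x$agents$x_final[x$agents$status == "settled"]
  }
  if (is.null(substrate) || substrate$kind != "ridged") {
    abort("ridge distances require a ridged substrate.")
  }
  p <- substrate$pitch; w <- substrate$ridge_width
  xm <- x %% p
  # flanks at xm = 0, w (ridge edges) and p (next ridge), measured along the floor
  dist <- pmin(abs(xm - 0), abs(xm - w), abs(xm - p))
  structure(
    list(distances = tibble(x = x, distance = dist),
         fraction_within = if (length(dist)) mean(dist <= d) else NA_real_,
         d = d, substrate = substrate),
    class = "ridge_distances")
}

#' @export
print.ridge_distances <- function(x, ...) {
  cat(sprintf("<ridge_distances> %d settlers, %.1f%% within %g mm of a ridge base\n",
              nrow(x$distances), 100 * x$fraction_within, x$d))
  invisible(x)
}

#' @export
tidy.ridge_distances <- function(x, ...) x$distances

#' Two-factor settlement table by Q-criterion class
#'
#' Arranges per-settler vortex classifications (above/below the Q
#' threshold) into per-run percentages crossed with a second factor
#' (species), ready for the two-way fixed-effects ANOVA. Runs without
#' settlers are dropped with a warning (missing data, not zeros).
#'
#' @param classified A data frame with columns `run`, `species` and logical
#'   `under_vortex` (e.g. from [classify_points_by_q()], one row per
#'   settler).
#' @return A tibble `(run, species, q_class, n, pct)` with two `q_class`
#'   rows per run ("above", "below").
#' @export
settlement_q_table <- function(classified) {
  need <- c("run", "species", "under_vortex")
  if (!all(need %in% names(classified))) {
    abort("need columns `run`, `species`, `under_vortex`.")
  }
  if (anyNA(classified$under_vortex)) abort("missing vortex classification.")
  cl <- as_tibble(classified)
  runs <- dplyr::distinct(cl[, c("run", "species")])
  empty <- dplyr::anti_join(runs, cl[!is.na(cl$under_vortex), c("run", "species")],
                            by = c("run", "species"))
  per_run <- dplyr::summarise(
    dplyr::group_by(cl, .data$run, .data$species),
    above = sum(.data$under_vortex), total = dplyr::n(), .groups = "drop")
  zero <- per_run$total == 0
  if (any(zero)) {
    warn(sprintf("%d run(s) without settlers dropped.", sum(zero)))
    per_run <- per_run[!zero, ]
  }
  tidyr::pivot_longer(
    dplyr::mutate(per_run,
                  above_pct = 100 * .data$above / .data$total,
                  below_pct = 100 * (.data$total - .data$above) / .data$total),
    cols = c("above_pct", "below_pct"),
    names_to = "q_class", values_to = "pct") |>
    dplyr::mutate(q_class = sub("_pct$", "", .data$q_class),
                  n = ifelse(.data$q_class == "above", .data$above,
                             .data$total - .data$above)) |>
    dplyr::select("run", "species", "q_class", "n", "pct")
}
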