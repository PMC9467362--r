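test_that("settlement fractions are percentages of group totals", {
  tb <- tibble::tibble(group = c("a", "b"), settled = c(3, 1),
                       total = c(10, 10))
  out <- settlement_fraction(tb)
  expect_equal(out$settlement_pct, c(30, 10))
  expect_equal(settlement_fraction(
    tibble::tibble(settled = 1420, total = 10000))$settlement_pct, 14.2)
  expect_equal(settlement_fraction(
    tibble::tibble(settled = 0, total = 50))$settlement_pct, 0)
  expect_error(settlement_fraction(tibble::tibble(settled = 1, total = 0)),
               "positive")
})

test_that("simulation outcome percentages sum to 100", {
  sim <- run_simulation(stokes_layer_field(),
                        config = sim_config(n_positions = 3,
                                            n_orientations = 4, n_phases = 2,
                                            max_time = 20))
  g <- glance(sim)
  expect_equal(g$settlement_pct + g$exited_pct + g$unresolved_pct, 100)
  per_phase <- settlement_fraction(sim, by = "t0")
  expect_equal(nrow(per_phase), 2)
  expect_equal(sum(per_phase$total), sim$n)
})

test_that("arcsine-square-root transform: endpoints, closed form, round-trip", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.25), asin(0.5))
  expect_equal(arcsine_transform(0.25), 0.5236, tolerance = 1e-4)
  p <- seq(0, 1, by = 0.01)
  expect_equal(sin(arcsine_transform(p))^2, p, tolerance = 1e-12)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
})

test_that("one-way ANOVA F matches brute-force sums of squares", {
  set.seed(21)
  for (rep in 1:5) {
    d <- tibble::tibble(
      g = rep(letters[1:3], each = 7),
      y = rnorm(21, mean = rep(c(0, 0.5, 2), each = 7)))
    fit <- anova_tukey(d, "y", "g")
    tab <- tidy(fit)
    # brute force from sums of squares
    gm <- mean(d$y)
    means <- tapply(d$y, d$g, mean)
    ssb <- sum(7 * (means - gm)^2)
    ssw <- sum((d$y - means[d$g])^2)
    F_brute <- (ssb / 2) / (ssw / 18)
    expect_equal(tab$statistic[tab$term == "g"], F_brute, tolerance = 1e-9)
  }
})

test_that("ANOVA degenerate and trivial cases behave", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 5), y = rep(c(1, 1), each = 5))
  expect_warning(anova_tukey(d, "y", "g"), "zero variance")
  d2 <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                       y = c(0, 0, 0, 10, 10, 10) + rnorm(6, sd = 1e-6))
  fit <- anova_tukey(d2, "y", "g")
  expect_lt(tidy(fit)$p.value[1], 1e-6)
  expect_true(all(fit$tukey$significant))
  # identical groups: tiny F, p near 1
  set.seed(4)
  base <- rnorm(6)
  d3 <- tibble::tibble(g = rep(c("a", "b"), each = 6), y = rep(base, 2))
  fit3 <- anova_tukey(d3, "y", "g")
  expect_equal(tidy(fit3)$statistic[1], 0, tolerance = 1e-12)
  expect_equal(tidy(fit3)$p.value[1], 1, tolerance = 1e-9)
})

test_that("balanced two-factor design with additive effects has no interaction", {
  eff_a <- c(a1 = 0, a2 = 3)
  eff_b <- c(b1 = 0, b2 = 1)
  d <- expand.grid(a = names(eff_a), b = names(eff_b), rep = 1:4,
                   KEEP.OUT.ATTRS = FALSE)
  d$y <- eff_a[d$a] + eff_b[d$b]
  set.seed(5)
  d$y <- d$y + rep(rnorm(4, sd = 1e-8), each = 4)  # additive replicate noise
  fit <- anova_tukey(d, "y", c("a", "b"))
  tab <- tidy(fit)
  expect_true("a:b" %in% tab$term)
  Fint <- tab$statistic[tab$term == "a:b"]
  Fmain <- tab$statistic[tab$term == "a"]
  expect_lt(Fint / Fmain, 1e-6)
})

test_that("ridge distances measure to the nearest flank along the floor", {
  sub <- substrate_profile("ridged")
  rd <- ridge_distance_histogram(c(2.5, 6.25, 10), substrate = sub)
  expect_equal(tidy(rd)$distance, c(0, 3.75, 0))
  all_flank <- ridge_distance_histogram(c(2.5, 10, 12.5), substrate = sub, d = 1)
  expect_equal(all_flank$fraction_within, 1)
  expect_error(ridge_distance_histogram(c(1, 2), substrate_profile("flat")),
               "ridged")
})

test_that("the settlement-by-Q table crosses per-run percentages with species", {
  cl <- tibble::tibble(
    run = rep(c(1, 2), c(64, 10)),
    species = rep(c("Dlab", "Cnat"), c(64, 10)),
    under_vortex = c(rep(TRUE, 63), FALSE, rep(TRUE, 10)))
  tab <- settlement_q_table(cl)
  expect_equal(nrow(tab), 4)
  above1 <- tab$pct[tab$run == 1 & tab$q_class == "above"]
  expect_equal(above1, 100 * 63 / 64)
  expect_equal(round(above1, 1), 98.4)
  expect_equal(tab$pct[tab$run == 2 & tab$q_class == "above"], 100)
  expect_equal(tab$pct[tab$run == 2 & tab$q_class == "below"], 0)
  # per-run percentages sum to 100
  sums <- tapply(tab$pct, tab$run, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(settlement_q_table(cl[, 1:2]), "under_vortex")
})
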