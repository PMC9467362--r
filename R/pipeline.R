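#' Configuration for the end-to-end settlement pipeline
#'
#' Bundles every stage's parameters: the three substrate scenarios (flat,
#' millimeter-scale 2.5 mm ridges, sub-millimeter 0.25 mm ridges with the
#' same spacing-to-height ratio of 3), the oscillatory forcing, fluid and
#' larval parameters, the simulation lattice, and the flow-analysis
#' settings. `scale` thins each lattice axis proportionally
#' (`floor(n * scale^(1/3))`, minimum 1) for smoke runs.
#'
#' @param forcing,fluid,larva,sim Component parameter objects.
#' @param analysis List: grid spacing `dx`, stored slices `nt`, analysis
#'   domain height `ylim_top` (mm), band height (mm), vortex `min_area`.
#' @param scale Lattice scale factor in (0, 1].
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds fixture/tracer stages).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(forcing = oscillatory_forcing(),
                            fluid = fluid_properties(),
                            larva = larva_params(),
                            sim = sim_config(),
                            analysis = list(dx = 0.05, nt = 32,
                                            ylim_top = 8, band_height = 1.5,
                                            min_area = 4),
                            scale = 1, seed = 1) {
  if (scale <= 0 || scale > 1) abort("`scale` must be in (0, 1].")
  structure(list(forcing = forcing, fluid = fluid, larva = larva, sim = sim,
                 analysis = analysis, scale = scale, seed = seed),
            class = "pipeline_config")
}

scale_config <- function(sim, scale) {
  if (scale >= 1) return(sim)
  f <- scale^(1 / 3)
  sim_config(dt = sim$dt,
             n_positions = max(1L, floor(sim$n_positions * f)),
             n_orientations = max(1L, floor(sim$n_orientations * f)),
             n_phases = max(1L, floor(sim$n_phases * f)),
             seed_height = sim$seed_height, max_time = sim$max_time)
}

pipeline_fields <- function(config) {
  list(
    flat = stokes_layer_field(config$forcing, config$fluid),
    ridged_2.5 = ridged_cavity_field(config$forcing, config$fluid,
                                     substrate_profile("ridged")),
    ridged_0.25 = ridged_cavity_field(
      config$forcing, config$fluid,
      substrate_profile("ridged", ridge_height = 0.25, ridge_spacing = 0.75))
  )
}

#' Run the full settlement pipeline
#'
#' Regenerates the whole computational experiment: synthetic oscillatory
#' boundary-layer fields for the three substrate scenarios, the agent-based
#' settlement simulation on each, near-substrate flow analysis (Q-criterion
#' and settling windows) for the flat and 2.5 mm ridged fields, and the
#' settlement statistics (per-phase replicate groups, arcsine-square-root
#' transform, one-way ANOVA with Tukey HSD across substrates). Outputs are
#' written under `out_dir` with a run manifest; the run is fully
#' deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The run manifest (invisibly a list, also written as
#'   `manifest.json`): per-stage outputs, settlement summary, ANOVA
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("larvaflow-run-")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  fields <- pipeline_fields(config)
  simcfg <- scale_config(config$sim, config$scale)
  stage_files <- list()
  timings <- list()

  sims <- list()
  for (nm in names(fields)) {
    t0 <- Sys.time()
    sims[[nm]] <- run_simulation(fields[[nm]], config$larva, simcfg)
    f <- file.path(out_dir, paste0("outcomes_", nm, ".csv"))
    readr::write_csv(tidy(sims[[nm]]), f)
    stage_files[[paste0("simulate_", nm)]] <- f
    timings[[paste0("simulate_", nm)]] <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  summary_tbl <- purrr::map_dfr(sims, glance, .id = "scenario")
  unresolved_pct <- 100 * sum(summary_tbl$unresolved) / sum(summary_tbl$n)
  if (unresolved_pct > 5) {
    warn(sprintf("%.1f%% of agents unresolved at max_time.", unresolved_pct))
  }

  t0 <- Sys.time()
  an <- config$analysis
  analysis <- list()
  for (nm in c("flat", "ridged_2.5")) {
    fld <- fields[[nm]]
    xlim <- if (nm == "flat") c(0, 2) else c(0, fld$substrate$pitch)
    g <- sample_field(fld, dx = an$dx, nt = an$nt,
                      xlim = xlim, ylim = c(0, an$ylim_top))
    bs <- band_speed(g, band_height = an$band_height,
                     cavity_only = nm != "flat")
    sw <- settling_windows(bs, u_ell = config$larva$u_ell,
                           sd_u = config$larva$sd_u)
    qf <- q_analysis(g, min_area = an$min_area)
    analysis[[nm]] <- list(windows = sw, q = qf,
                           n_vortex_regions_peak = nrow(
                             vortex_regions(qf, t = fld$forcing$period / 4)))
  }
  # classify settled agents of the ridged run by the Q-criterion overhead
  settled <- sims$ridged_2.5$agents
  settled <- settled[settled$status == "settled", ]
  qcl <- NULL
  if (nrow(settled) > 0) {
    pts <- tibble(x = settled$x_final %% fields$ridged_2.5$substrate$pitch,
                  y = pmin(settled$y_final, an$ylim_top - an$band_height))
    qcl <- classify_points_by_q(pts, analysis$ridged_2.5$q,
                                column_height = an$band_height)
    f <- file.path(out_dir, "settlers_q_class.csv")
    readr::write_csv(qcl, f)
    stage_files$classify <- f
  }
  timings$analyze <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- Sys.time()
  per_phase <- purrr::map_dfr(sims, settlement_fraction, by = "t0",
                              .id = "scenario")
  per_phase$asin_p <- arcsine_transform(per_phase$settlement_pct / 100)
  aov_res <- anova_tukey(per_phase, "asin_p", "scenario")
  f <- file.path(out_dir, "settlement_per_phase.csv")
  readr::write_csv(per_phase, f)
  stage_files$stats <- f
  timings$stats <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  manifest <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("larvaflow")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    scale = config$scale,
    n_agents = sims[[1]]$n,
    outputs = stage_files,
    timings_s = timings,
    settlement = setNames(summary_tbl$settlement_pct, summary_tbl$scenario),
    settling_window_fraction = purrr::map_dbl(analysis, ~ .x$windows$period_fraction),
    q_thresh = purrr::map_dbl(analysis, ~ .x$q$q_thresh),
    tukey = aov_res$tukey)
  jsonlite::write_json(
    purrr::map(manifest, ~ if (inherits(.x, "data.frame")) .x else .x),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  out <- list(manifest = manifest, sims = sims, analysis = analysis,
              anova = aov_res, per_phase = per_phase, out_dir = out_dir)
  class(out) <- "pipeline_result"
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  settlement (%):\n")
  print(round(x$manifest$settlement, 2))
  cat(sprintf("  outputs under %s\n", x$out_dir))
  invisible(x)
}

#' Write a small deterministic fixture bundle
#'
#' Writes compact, fully synthetic fixtures for tests and examples: a flat
#' Stokes-layer field archive, a one-cavity ridged field archive, a short
#' tracer-particle frame stack (TIFF), and a 12-agent outcome table.
#' Field archives are deterministic; the tracer stack depends on `seed`.
#'
#' @param dir Output directory.
#' @param seed Seed for tracer release positions.
#' @return Tibble of written paths and their MD5 hashes.
#' @export
make_fixtures <- function(dir = tempfile("larvaflow-fixtures-"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- stokes_layer_field()
  write_field(sample_field(flat, dx = 0.5, nt = 8,
                           xlim = c(0, 4), ylim = c(0, 8)),
              file.path(dir, "flat_field"))
  ridged <- ridged_cavity_field(substrate = substrate_profile("ridged", n_ridges = 1))
  write_field(sample_field(ridged, dx = 0.25, nt = 8,
                           xlim = c(0, 10), ylim = c(0, 6)),
              file.path(dir, "ridged_field"))
  tracks <- advect_tracers(flat, n = 50, duration = 0.2, seed = seed)
  write_frames(render_frames(tracks, ptv_optics(noise_level = 0.02),
                             seed = seed),
               file.path(dir, "tracers.tif"))
  sim <- run_simulation(flat, config = sim_config(n_positions = 3,
                                                  n_orientations = 2,
                                                  n_phases = 2,
                                                  max_time = 5))
  readr::write_csv(tidy(sim), file.path(dir, "outcomes12.csv"))
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  tibble(path = files, md5 = unname(tools::md5sum(files)))
}

#' Write / read a pipeline configuration as YAML
#'
#' Serialises every stage parameter so a run can be reproduced from a plain
#' text file.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(
    forcing = config$forcing[c("U0", "period", "phase0")],
    fluid = list(nu = config$fluid$nu),
    larva = config$larva[c("a", "b", "u_ell", "sd_u")],
    sim = unclass(config$sim),
    analysis = config$analysis,
    scale = config$scale,
    seed = config$seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    forcing = do.call(oscillatory_forcing, x$forcing),
    fluid = fluid_properties(x$fluid$nu),
    larva = do.call(larva_params, x$larva),
    sim = do.call(sim_config, x$sim),
    analysis = x$analysis,
    scale = x$scale, seed = x$seed)
}
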