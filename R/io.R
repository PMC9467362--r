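#' Write / read a gridded field archive
#'
#' A field archive is a directory holding `meta.json` (grid coordinates,
#' times, forcing/fluid/substrate metadata), `field.csv` (long format:
#' `t, x, y, u, v`) and `mask.csv` (`x, y, solid`). All numbers are written
#' with shortest round-trip precision, so write-then-read restores the
#' arrays bit for bit.
#'
#' @param field A `gridded_field` (sample analytic providers first).
#' @param path Directory to create/overwrite.
#' @return `read_field()` returns a `gridded_field`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema = "larvaflow-field-1",
    kind = field$kind,
    x = field$x, y = field$y, t = field$times,
    attrs = list(dx = field$dx,
                 period = field$forcing$period,
                 U0 = field$forcing$U0,
                 phase0 = field$forcing$phase0,
                 nu = field$fluid$nu,
                 substrate = unclass(field$substrate)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  ny <- length(field$y); nx <- length(field$x); nt <- length(field$times)
  # numbers are written as %.17g strings so that parsing restores the
  # doubles exactly
  g17 <- function(z) sprintf("%.17g", z)
  long <- tibble(
    t = g17(rep(field$times, each = ny * nx)),
    x = g17(rep(rep(field$x, each = ny), times = nt)),
    y = g17(rep(field$y, times = nx * nt)),
    u = g17(as.vector(field$u)),
    v = g17(as.vector(field$v)))
  readr::write_csv(long, file.path(path, "field.csv"))
  readr::write_csv(tibble(x = rep(field$x, each = ny),
                          y = rep(field$y, times = nx),
                          solid = as.vector(field$solid_mask)),
                   file.path(path, "mask.csv"))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  metaf <- file.path(path, "meta.json")
  if (!file.exists(metaf)) abort(sprintf("missing dataset 'meta.json' in %s", path))
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  for (nm in c("x", "y", "t")) {
    if (is.null(meta[[nm]])) abort(sprintf("archive is missing dataset '%s'", nm))
  }
  ff <- file.path(path, "field.csv")
  if (!file.exists(ff)) abort("archive is missing dataset 'field.csv'")
  # base read.csv: correctly rounded double parsing for exact round-trips
  long <- utils::read.csv(ff)
  for (nm in c("t", "x", "y", "u", "v")) {
    if (!nm %in% names(long)) abort(sprintf("archive is missing dataset '%s'", nm))
  }
  mf <- file.path(path, "mask.csv")
  if (!file.exists(mf)) abort("archive is missing dataset 'solid_mask'")
  maskdf <- utils::read.csv(mf)
  x <- meta$x; y <- meta$y; times <- meta$t
  ny <- length(y); nx <- length(x); nt <- length(times)
  if (nrow(long) != ny * nx * nt) {
    abort(sprintf("field.csv has %d rows; expected %d from the grid shape.",
                  nrow(long), ny * nx * nt))
  }
  at <- meta$attrs
  sub <- at$substrate
  substrate <- if (identical(sub$kind, "flat")) substrate_profile("flat") else
    substrate_profile("ridged", ridge_height = sub$ridge_height,
                      ridge_spacing = sub$ridge_spacing,
                      ridge_width = sub$ridge_width, n_ridges = sub$n_ridges)
  gridded_field(
    x = x, y = y, times = times,
    u = array(long$u, c(ny, nx, nt)),
    v = array(long$v, c(ny, nx, nt)),
    solid_mask = matrix(maskdf$solid, ny, nx),
    forcing = oscillatory_forcing(U0 = at$U0, period = at$period,
                                  phase0 = at$phase0),
    fluid = fluid_properties(nu = at$nu),
    substrate = substrate,
    kind = meta$kind %||% "gridded")
}
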