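#' Substrate surface profile
#'
#' Describes the settlement substrate: either flat, or with rectangular
#' ridges of a given height, width and edge-to-edge spacing. The default
#' ridged geometry has 2.5 mm tall ridges spaced 7.5 mm apart edge-to-edge
#' (spacing-to-height ratio 3); ridge width defaults to the ridge height.
#' A ridge "pitch" (spatial period) is `ridge_width + ridge_spacing`.
#'
#' Within one pitch, the ridge occupies `[0, ridge_width)` and the cavity
#' (inter-ridge gap) occupies `[ridge_width, pitch)`.
#'
#' @param kind `"flat"` or `"ridged"`.
#' @param ridge_height Ridge height in mm (ridged only).
#' @param ridge_spacing Edge-to-edge gap between ridges in mm.
#' @param ridge_width Ridge width in mm; defaults to `ridge_height`.
#' @param n_ridges Number of ridge pitches in the domain.
#' @return An object of class `substrate_profile`.
#' @examples
#' substrate_profile("ridged")
#' substrate_profile("ridged", ridge_height = 0.25, ridge_spacing = 0.75)
#' @export
substrate_profile <- function(kind = c("flat", "ridged"),
                              ridge_height = 2.5,
                              ridge_spacing = 7.5,
                              ridge_width = ridge_height,
                              n_ridges = 4) {
  kind <- match.arg(kind)
  if (kind == "ridged") {
    if (ridge_height <= 0 || ridge_spacing <= 0 || ridge_width <= 0) {
      abort("ridge dimensions must be positive.")
    }
  } else {
    ridge_height <- 0
    ridge_spacing <- NA_real_
    ridge_width <- NA_real_
  }
  structure(
    list(kind = kind,
         ridge_height = ridge_height,
         ridge_spacing = ridge_spacing,
         ridge_width = ridge_width,
         n_ridges = n_ridges,
         pitch = if (kind == "ridged") ridge_width + ridge_spacing else NA_real_),
    class = "substrate_profile"
  )
}

#' @export
print.substrate_profile <- function(x, ...) {
  if (x$kind == "flat") {
    cat("<substrate_profile> flat\n")
  } else {
    cat(sprintf(
      "<substrate_profile> ridged: height %g mm, width %g mm, gap %g mm (pitch %g mm, n = %d)\n",
      x$ridge_height, x$ridge_width, x$ridge_spacing, x$pitch, x$n_ridges))
  }
  invisible(x)
}

#' Surface elevation of a substrate
#'
#' Height of the solid surface at streamwise position(s) `x` (mm). For
#' rectangular ridges the elevation is `ridge_height` over a ridge and 0 in
#' the cavities; flat substrates have elevation 0 everywhere.
#'
#' @param substrate A [substrate_profile()].
#' @param x Streamwise position(s) in mm (wrapped periodically by pitch).
#' @return Elevation(s) in mm.
#' @export
elevation <- function(substrate, x) {
  stopifnot(inherits(substrate, "substrate_profile"))
  if (substrate$kind == "flat") return(rep(0, length(x)))
  xm <- x %% substrate$pitch
  ifelse(xm < substrate$ridge_width, substrate$ridge_height, 0)
}

#' Distance to the nearest solid surface
#'
#' Euclidean distance from points to the union of the floor (y = 0) and any
#' ridge rectangles. Points inside the solid return 0.
#'
#' @param substrate A [substrate_profile()].
#' @param x,y Coordinates in mm (vectorised; `x` wrapped by pitch).
#' @return Distance(s) in mm.
#' @export
surface_distance <- function(substrate, x, y) {
  stopifnot(inherits(substrate, "substrate_profile"))
  y0 <- pmax(y, 0)
  if (substrate$kind == "flat") {
    return(ifelse(y <= 0, 0, y0))
  }
  p <- substrate$pitch
  w <- substrate$ridge_width
  h <- substrate$ridge_height
  xm <- x %% p
  d <- y0
  for (k in -1:1) {
    ddx <- pmax(0, pmax(k * p - xm, xm - (k * p + w)))
    ddy <- pmax(0, y - h)
    d <- pmin(d, sqrt(ddx^2 + ddy^2))
  }
  ifelse(y <= elevation(substrate, x), 0, pmax(d, 0))
}

# default streamwise domain length, mm
default_domain_length <- function(substrate) {
  if (substrate$kind == "ridged") substrate$n_ridges * substrate$pitch else 40
}
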