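#' Sinusoidal oscillatory free-stream forcing
#'
#' The free stream in a wave-driven benthic boundary layer is modelled as a
#' pure sinusoid, `U0 * sin(2*pi*t/period + phase0)`. The defaults (peak speed
#' 45 mm/s, period 5.5 s) correspond to wave conditions typical of shallow
#' coral-reef habitats.
#'
#' @param U0 Peak free-stream speed in mm/s. Must be positive.
#' @param period Oscillation period in s. Must be positive.
#' @param phase0 Phase offset in radians at `t = 0`. With the default 0,
#'   `t = 0` is a turning point of the flow.
#'
#' @return An object of class `oscillatory_forcing`.
#' @examples
#' forcing <- oscillatory_forcing()
#' free_stream(forcing, seq(0, 5.5, by = 0.5))
#' @export
oscillatory_forcing <- function(U0 = 45, period = 5.5, phase0 = 0) {
  if (!is.numeric(U0) || length(U0) != 1 || U0 <= 0) {
    abort("`U0` must be a single positive number (mm/s).")
  }
  if (!is.numeric(period) || length(period) != 1 || period <= 0) {
    abort("`period` must be a single positive number (s).")
  }
  structure(
    list(U0 = U0, period = period, phase0 = phase0,
         omega = 2 * pi / period, waveform = "sinusoidal"),
    class = "oscillatory_forcing"
  )
}

#' @export
print.oscillatory_forcing <- function(x, ...) {
  cat(sprintf("<oscillatory_forcing> U0 = %g mm/s, period = %g s, phase0 = %g rad\n",
              x$U0, x$period, x$phase0))
  invisible(x)
}

#' Free-stream speed at time t
#'
#' @param forcing An [oscillatory_forcing()] object.
#' @param t Time(s) in seconds (vectorised).
#' @return Free-stream speed(s) in mm/s.
#' @export
free_stream <- function(forcing, t) {
  stopifnot(inherits(forcing, "oscillatory_forcing"))
  forcing$U0 * sin(forcing$omega * t + forcing$phase0)
}

#' Fluid properties of seawater
#'
#' Holds the kinematic viscosity and derives the oscillatory (Stokes)
#' boundary-layer thickness `delta = sqrt(2 * nu / omega)` when paired with a
#' forcing. The default viscosity, 0.85 mm^2/s, is representative of seawater
#' near 27.5 C.
#'
#' @param nu Kinematic viscosity in mm^2/s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(nu = 0.85) {
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0) {
    abort("`nu` must be a single positive number (mm^2/s).")
  }
  structure(list(nu = nu), class = "fluid_properties")
}

#' Oscillatory boundary-layer (Stokes) thickness
#'
#' `delta = sqrt(2 * nu / omega)` with `omega = 2*pi/period`.
#'
#' @param fluid A [fluid_properties()] object.
#' @param forcing An [oscillatory_forcing()] object.
#' @return Stokes layer thickness in mm.
#' @export
stokes_delta <- function(fluid, forcing) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(forcing, "oscillatory_forcing"))
  sqrt(2 * fluid$nu / forcing$omega)
}

#' Reynolds number
#'
#' `Re = U * L / nu`. With the flume's hydraulic diameter (91 mm) and peak
#' speeds of 30-50 mm/s this falls in the transitional regime.
#'
#' @param U Speed in mm/s.
#' @param L Length scale in mm.
#' @param nu Kinematic viscosity in mm^2/s.
#' @return Dimensionless Reynolds number (vectorised over inputs).
#' @examples
#' reynolds_number(45, 91, 1.0)
#' @export
reynolds_number <- function(U, L, nu) {
  if (any(U <= 0) || any(L <= 0) || any(nu <= 0)) {
    abort("`U`, `L` and `nu` must all be positive.")
  }
  U * L / nu
}
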