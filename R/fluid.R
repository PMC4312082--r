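#' Newtonian blood model and inlet condition
#'
#' Blood is treated as an incompressible Newtonian fluid. Defaults are the
#' standard coronary haemodynamics values: dynamic viscosity 3.7 mPa s,
#' density 1060 kg/m3, and a constant inlet speed of 0.17 m/s at the ostium.
#'
#' @param dynamic_viscosity Dynamic viscosity in Pa s (> 0).
#' @param density Density in kg/m3 (> 0).
#' @param inlet_speed Mean inlet speed in m/s (> 0).
#' @return An object of class `fluid_model`.
#' @export
fluid_model <- function(dynamic_viscosity = 3.7e-3, density = 1060,
                        inlet_speed = 0.17) {
  if (dynamic_viscosity <= 0 || density <= 0 || inlet_speed <= 0)
    abort("All fluid parameters must be strictly positive.")
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density,
                 inlet_speed = inlet_speed),
            class = "fluid_model")
}

#' @export
print.fluid_model <- function(x, ...) {
  cat(sprintf("<fluid_model> mu = %g Pa s, rho = %g kg/m3, inlet speed = %g m/s\n",
              x$dynamic_viscosity, x$density, x$inlet_speed))
  invisible(x)
}

#' Reynolds number
#'
#' \eqn{Re = \rho V D / \mu}. With the default fluid and a 6.16 mm diameter
#' this is about 300, the laminar regime assumed throughout.
#'
#' @param fluid A [fluid_model()].
#' @param diameter Vessel diameter in m.
#' @param speed Flow speed in m/s (defaults to the fluid's inlet speed).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, diameter, speed = fluid$inlet_speed) {
  stopifnot(inherits(fluid, "fluid_model"))
  if (diameter <= 0 || speed < 0) abort("`diameter` must be positive and `speed` non-negative.")
  fluid$density * speed * diameter / fluid$dynamic_viscosity
}
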