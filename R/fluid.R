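#' Fluid properties
#'
#' Newtonian fluid constants used when converting shear rate to stress.
#' Defaults describe degassed water at room temperature (roughly 25 degrees C),
#' the carrier fluid of a microbubble flow phantom; the viscosity actually used
#' is configurable because dilute microbubble suspensions are still Newtonian
#' to good approximation.
#'
#' @param mu Dynamic viscosity in Pa s. Must be positive.
#' @param rho Density in kg/m^3. Must be positive.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()          # water, 0.9e-3 Pa s
#' fluid_properties(mu = 1e-3)
#' @export
fluid_properties <- function(mu = 0.9e-3, rho = 998) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (mu <= 0) stop("viscosity `mu` must be positive (Pa s)")
  if (rho <= 0) stop("density `rho` must be positive (kg/m^3)")
  structure(list(mu = mu, rho = rho), class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> mu = %g Pa s, rho = %g kg/m^3\n", x$mu, x$rho))
  invisible(x)
}
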