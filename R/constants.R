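#' Physical constants of the haemodynamic model
#'
#' Bundles the blood properties and unit conversion used throughout the
#' solver. All internal computation is in cgs units (cm, g, s); pressures are
#' converted to mmHg only at interfaces, using \code{conv} exactly once.
#'
#' @param rho blood density, g/ml.
#' @param mu blood viscosity, g/(cm s).
#' @param conv conversion factor, mmHg per (g cm^-1 s^-2).
#' @param period length of the cardiac cycle T, s.
#'
#' @return An object of class \code{"physical_constants"}: a named list with
#'   fields \code{rho}, \code{mu}, \code{conv}, \code{period}.
#' @examples
#' pc <- physical_constants()
#' pc$rho
#' @export
physical_constants <- function(rho = 1.055, mu = 0.049, conv = 1333.22,
                               period = 0.11) {
  stopifnot(rho > 0, mu > 0, conv > 0, period > 0)
  structure(list(rho = rho, mu = mu, conv = conv, period = period),
            class = "physical_constants")
}

#' Stokes boundary-layer thickness
#'
#' The friction term of the 1D momentum balance assumes a Stokes boundary
#' layer of thickness \eqn{\delta = \sqrt{\mu T / (2 \pi \rho)}} (cm), set by
#' the cardiac period and the blood properties.
#'
#' @param constants a \code{\link{physical_constants}} object.
#' @return boundary-layer thickness, cm.
#' @examples
#' boundary_layer_thickness(physical_constants(period = 0.11))
#' @export
boundary_layer_thickness <- function(constants = physical_constants()) {
  sqrt(constants$mu * constants$period / (2 * pi * constants$rho))
}
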