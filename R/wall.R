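#' Constitutive vessel wall model
#'
#' Defines the pressure--area relation closing the 1D flow equations, and how
#' the wall stiffness \eqn{\chi = Eh/r_0} varies over the network. Two
#' constitutive laws are supported:
#' \describe{
#'   \item{linear}{\eqn{p = (4/3)\,\chi\,(\sqrt{A/A_0} - 1)}}
#'   \item{nonlinear}{\eqn{p = \chi \tan[(\pi/\gamma)(A/A_0 - 1)]}, where
#'     \eqn{\gamma > 0} sets the maximal lumen area
#'     \eqn{A_\infty = A_0 (1 + \gamma/2)} reached as \eqn{p \to \infty}.}
#' }
#' Stiffness modes:
#' \describe{
#'   \item{constant}{\eqn{f_1 = 0}; all vessels share \eqn{\chi = f_3}.}
#'   \item{radius_dependent}{\eqn{\chi(r_0) = f_1 e^{f_2 r_0} + f_3}.}
#'   \item{vessel_specific}{one \eqn{\chi_j} per vessel, supplied in
#'     \code{chi}.}
#' }
#'
#' @param kind \code{"linear"} or \code{"nonlinear"}.
#' @param stiffness_mode \code{"constant"}, \code{"radius_dependent"} or
#'   \code{"vessel_specific"}.
#' @param f1,f2,f3 stiffness-relation coefficients; \code{f1}, \code{f3} in
#'   g cm^-1 s^-2, \code{f2} in cm^-1.
#' @param gamma dimensionless lumen-area scale, required for the nonlinear
#'   law.
#' @param chi numeric vector of per-vessel stiffness values (g cm^-1 s^-2),
#'   required for \code{stiffness_mode = "vessel_specific"}; order follows
#'   the network's vessel ids.
#' @return An object of class \code{"wall_model"}.
#' @examples
#' wall_model("linear", "constant", f3 = 5.17e4)
#' wall_model("nonlinear", "radius_dependent",
#'            f1 = 5.8e4, f2 = -6, f3 = 2e4, gamma = 5.09)
#' @export
wall_model <- function(kind = c("linear", "nonlinear"),
                       stiffness_mode = c("constant", "radius_dependent",
                                          "vessel_specific"),
                       f1 = 0, f2 = 0, f3 = NULL, gamma = NULL, chi = NULL) {
  kind <- match.arg(kind)
  stiffness_mode <- match.arg(stiffness_mode)
  if (kind == "nonlinear") {
    if (is.null(gamma) || gamma <= 0)
      stop("the nonlinear wall law requires gamma > 0")
    if (stiffness_mode == "vessel_specific")
      stop("vessel-specific stiffness is not supported for the nonlinear ",
           "wall law (chi and gamma interact, requiring per-vessel pairs)")
  }
  if (stiffness_mode == "vessel_specific") {
    if (is.null(chi) || any(!is.finite(chi)) || any(chi <= 0))
      stop("vessel_specific mode requires a positive per-vessel chi vector")
  } else {
    if (is.null(f3)) stop("f3 is required")
    if (stiffness_mode == "constant" && f1 != 0)
      stop("constant stiffness mode requires f1 = 0")
  }
  structure(list(kind = kind, stiffness_mode = stiffness_mode,
                 f1 = f1, f2 = f2, f3 = f3, gamma = gamma, chi = chi),
            class = "wall_model")
}

#' Radius-dependent wall stiffness
#'
#' \eqn{\chi(r_0) = f_1 \exp(f_2 r_0) + f_3}; with \code{f1 = 0} it reduces
#' to constant stiffness \code{f3}. Small arteries stiffen as the radius
#' shrinks when \code{f1 > 0} and \code{f2 < 0}.
#'
#' @param r0 unstressed radius, cm (vectorized).
#' @param f1,f3 g cm^-1 s^-2.
#' @param f2 cm^-1.
#' @return stiffness \eqn{\chi}, g cm^-1 s^-2.
#' @examples
#' stiffness(0.05, f1 = 5.26e6, f2 = -162, f3 = 5.17e4)
#' @export
stiffness <- function(r0, f1, f2, f3) {
  chi <- f1 * exp(f2 * r0) + f3
  if (any(!is.finite(chi)) || any(chi <= 0))
    stop("stiffness chi(r0) must be positive and finite")
  chi
}

## per-vessel chi for a network under a wall model
network_stiffness <- function(network, wall) {
  r0 <- network$vessels$r0_cm
  switch(wall$stiffness_mode,
    constant = rep(wall$f3, length(r0)),
    radius_dependent = stiffness(r0, wall$f1, wall$f2, wall$f3),
    vessel_specific = {
      if (length(wall$chi) != length(r0))
        stop("chi must have one entry per vessel (", length(r0), ")")
      wall$chi
    })
}

#' Wall-law pressure from cross-sectional area
#'
#' Evaluates the constitutive pressure--area relation for one vessel.
#' Vectorized over \code{A}.
#'
#' @param A cross-sectional area, cm^2.
#' @param A0 unstressed area, cm^2.
#' @param wall a \code{\link{wall_model}}.
#' @param r0 unstressed radius, cm (used to evaluate the stiffness relation;
#'   ignored in \code{vessel_specific} mode, where \code{chi} must be given).
#' @param chi optional explicit stiffness, overriding the stiffness relation.
#' @param constants \code{\link{physical_constants}} (supplies the cgs to
#'   mmHg conversion).
#' @return transmural pressure, mmHg.
#' @examples
#' w <- wall_model("linear", "constant", f3 = 5.17e4)
#' wall_pressure(1.21 * pi * 0.05^2, pi * 0.05^2, w, r0 = 0.05)
#' @export
wall_pressure <- function(A, A0, wall, r0 = sqrt(A0 / pi), chi = NULL,
                          constants = physical_constants()) {
  stopifnot(all(A > 0), A0 > 0)
  if (is.null(chi)) {
    chi <- switch(wall$stiffness_mode,
      constant = wall$f3,
      radius_dependent = stiffness(r0, wall$f1, wall$f2, wall$f3),
      vessel_specific = stop("supply chi explicitly for vessel_specific mode"))
  }
  ratio <- A / A0
  if (wall$kind == "linear") {
    p_cgs <- (4 / 3) * chi * (sqrt(ratio) - 1)
  } else {
    arg <- (pi / wall$gamma) * (ratio - 1)
    if (any(abs(arg) >= pi / 2))
      stop("nonlinear wall law blow-up: A/A0 - 1 outside (-gamma/2, gamma/2)")
    p_cgs <- chi * tan(arg)
  }
  p_cgs / constants$conv
}

#' Wall-law area from pressure (exact inverse)
#'
#' @inheritParams wall_pressure
#' @param p transmural pressure, mmHg (vectorized).
#' @return cross-sectional area, cm^2.
#' @export
wall_area <- function(p, A0, wall, r0 = sqrt(A0 / pi), chi = NULL,
                      constants = physical_constants()) {
  if (is.null(chi)) {
    chi <- switch(wall$stiffness_mode,
      constant = wall$f3,
      radius_dependent = stiffness(r0, wall$f1, wall$f2, wall$f3),
      vessel_specific = stop("supply chi explicitly for vessel_specific mode"))
  }
  p_cgs <- p * constants$conv
  if (wall$kind == "linear") {
    A0 * (1 + p_cgs / ((4 / 3) * chi))^2
  } else {
    A0 * (1 + (wall$gamma / pi) * atan(p_cgs / chi))
  }
}

## local pulse-wave speed c(A) = sqrt((A/rho) dp~/dA), cgs
wave_speed <- function(A, A0, kind, chi, gamma, rho) {
  ratio <- A / A0
  if (kind == "linear") {
    sqrt((2 * chi / (3 * rho)) * sqrt(ratio))
  } else {
    arg <- (pi / gamma) * (ratio - 1)
    sqrt((chi * pi / (gamma * rho)) * ratio / cos(arg)^2)
  }
}
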