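#' Model catalogue
#'
#' The nine calibration models combine a wall law (linear/nonlinear), a
#' stiffness relation (constant, radius-dependent or vessel-specific) and
#' an error model (iid or GP model-mismatch), with prior boxes on the
#' biophysical parameters:
#'
#' \tabular{lllll}{
#'  \strong{abbrev} \tab \strong{wall} \tab \strong{stiffness} \tab
#'    \strong{mismatch} \tab \strong{emulated} \cr
#'  A \tab linear \tab constant \tab no \tab yes \cr
#'  B \tab linear \tab constant \tab yes \tab yes \cr
#'  C \tab linear \tab constant \tab yes \tab no \cr
#'  D \tab linear \tab radius-dependent \tab no \tab no \cr
#'  E \tab linear \tab radius-dependent \tab yes \tab no \cr
#'  F \tab linear \tab vessel-specific (hierarchical) \tab no \tab no \cr
#'  G \tab linear \tab vessel-specific (hierarchical) \tab yes \tab no \cr
#'  H \tab nonlinear \tab constant \tab yes \tab yes \cr
#'  I \tab nonlinear \tab radius-dependent \tab yes \tab no \cr
#' }
#'
#' The nonlinear wall law with vessel-specific stiffness is rejected: the
#' stiffness and lumen-area parameters interact, which would require
#' vessel-specific pairs and an impractically large parameter space.
#'
#' @param abbrev one of \code{"A"}--\code{"I"}.
#' @return object of class \code{"model_spec"}: wall kind, stiffness mode,
#'   mismatch flag, named bounds matrix for the sampled biophysical
#'   parameters, kernel hyperparameter ranges, emulator flag and a default
#'   iteration count.
#' @export
model_spec <- function(abbrev) {
  abbrev <- toupper(abbrev)
  if (!abbrev %in% LETTERS[1:9]) stop("unknown model abbreviation: ", abbrev)
  psi_b <- c(0.05, 2.50)
  bound <- function(...) {
    m <- do.call(rbind, list(...))
    colnames(m) <- c("lower", "upper")
    m
  }
  cat <- switch(abbrev,
    A = list(kind = "linear", mode = "constant", mismatch = FALSE,
             emulator = TRUE,
             bounds = bound(f3 = c(2e4, 1e5), psi1 = psi_b, psi2 = psi_b,
                            c = psi_b)),
    B = list(kind = "linear", mode = "constant", mismatch = TRUE,
             emulator = TRUE,
             bounds = bound(f3 = c(2e4, 1e5), psi1 = psi_b, psi2 = psi_b,
                            c = psi_b)),
    C = list(kind = "linear", mode = "constant", mismatch = TRUE,
             emulator = FALSE,
             bounds = bound(f3 = c(2e4, 1e5), psi1 = psi_b, psi2 = psi_b,
                            c = psi_b)),
    D = list(kind = "linear", mode = "radius_dependent", mismatch = FALSE,
             emulator = FALSE,
             bounds = bound(f1 = c(1e3, 1e7), f2 = c(-300, -50),
                            f3 = c(3e4, 6e4), psi1 = psi_b, psi2 = psi_b,
                            c = psi_b)),
    E = list(kind = "linear", mode = "radius_dependent", mismatch = TRUE,
             emulator = FALSE,
             bounds = bound(f1 = c(1e3, 1e7), f2 = c(-300, -50),
                            f3 = c(3e4, 6e4), psi1 = psi_b, psi2 = psi_b,
                            c = psi_b)),
    F = list(kind = "linear", mode = "vessel_specific", mismatch = FALSE,
             emulator = FALSE,
             bounds = bound(chi = c(2e4, 1e5), psi1 = psi_b, psi2 = psi_b,
                            c = psi_b)),
    G = list(kind = "linear", mode = "vessel_specific", mismatch = TRUE,
             emulator = FALSE,
             bounds = bound(chi = c(2e4, 1e5), psi1 = psi_b, psi2 = psi_b,
                            c = psi_b)),
    H = list(kind = "nonlinear", mode = "constant", mismatch = TRUE,
             emulator = TRUE,
             bounds = bound(f3 = c(3e4, 5e5), gamma = c(1, 2 * pi),
                            psi1 = psi_b, psi2 = psi_b, c = psi_b)),
    I = list(kind = "nonlinear", mode = "radius_dependent", mismatch = TRUE,
             emulator = FALSE,
             bounds = bound(f1 = c(5e3, 1e5), f2 = c(-200, 0),
                            f3 = c(1e4, 5e5), gamma = c(1, 2 * pi),
                            psi1 = psi_b, psi2 = psi_b, c = psi_b)))
  if (cat$kind == "nonlinear" && cat$mode == "vessel_specific")
    stop("vessel-specific stiffness is not available for the nonlinear ",
         "wall model")
  structure(c(list(abbrev = abbrev,
                   w_range = c(1e4, 9e4), b_range = c(1, 500),
                   n_iter_default = if (cat$emulator) 5000L
                                    else if (cat$mode == "vessel_specific")
                                      300000L else 150000L),
              cat),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model", x$abbrev, ":", x$kind, "wall,", x$mode, "stiffness,",
      if (x$mismatch) "GP model mismatch" else "iid errors",
      if (x$emulator) "(emulated)" else "", "\n")
  invisible(x)
}

## wall model from a named theta vector under a given model spec
wall_from_theta <- function(spec, theta, chi = NULL) {
  switch(spec$mode,
    constant = wall_model(spec$kind, "constant", f3 = theta[["f3"]],
                          gamma = if (spec$kind == "nonlinear")
                            theta[["gamma"]] else NULL),
    radius_dependent = wall_model(spec$kind, "radius_dependent",
                                  f1 = theta[["f1"]], f2 = theta[["f2"]],
                                  f3 = theta[["f3"]],
                                  gamma = if (spec$kind == "nonlinear")
                                    theta[["gamma"]] else NULL),
    vessel_specific = wall_model("linear", "vessel_specific", chi = chi))
}
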