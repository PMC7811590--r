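#' Prior specification for biophysical and error parameters
#'
#' Biophysical parameters get a rescaled beta(1, 1) prior, i.e. uniform on
#' their physiological box \eqn{[l_i, u_i]}. Error parameters depend on the
#' error model: the iid noise variance \code{sigma2} gets a weakly
#' informative conjugate inverse-gamma IG(0.001, 0.001) prior; the kernel
#' hyperparameters \code{w} and \code{b} of the mismatch model get
#' log-uniform priors on their ranges, and the residual noise variance
#' \code{sigma_n2} the same inverse-gamma prior as \code{sigma2}.
#'
#' @param theta_bounds named k x 2 matrix (columns lower, upper) of
#'   biophysical parameter bounds.
#' @param error_model \code{"iid"} or \code{"gp_mismatch"}.
#' @param sigma2_prior shape and rate (a, b) of the inverse-gamma prior.
#' @param w_range,b_range log-uniform supports for the kernel
#'   hyperparameters (mismatch model only).
#' @return object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(theta_bounds,
                       error_model = c("iid", "gp_mismatch"),
                       sigma2_prior = c(a = 0.001, b = 0.001),
                       w_range = c(1e4, 9e4), b_range = c(1, 500)) {
  error_model <- match.arg(error_model)
  stopifnot(is.matrix(theta_bounds), ncol(theta_bounds) == 2,
            !is.null(rownames(theta_bounds)),
            all(theta_bounds[, 1] < theta_bounds[, 2]))
  structure(list(theta_bounds = theta_bounds, error_model = error_model,
                 sigma2_prior = sigma2_prior,
                 w_range = w_range, b_range = b_range),
            class = "prior_spec")
}

#' Inverse-gamma log density
#' @param x evaluation points (> 0).
#' @param a shape; @param b rate.
#' @return log density.
#' @export
log_dinvgamma <- function(x, a, b) {
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}

## log-uniform density on [l, u]: proportional to 1/x
log_dloguniform <- function(x, l, u) {
  ifelse(x >= l & x <= u, -log(x) - log(log(u / l)), -Inf)
}

#' Joint log prior density
#'
#' @param theta named vector of biophysical parameters; every name must
#'   appear in the prior specification's bounds.
#' @param eta named vector of error parameters: \code{sigma2} for the iid
#'   model; \code{w}, \code{b}, \code{sigma_n2} for the mismatch model.
#' @param spec a \code{\link{prior_spec}}.
#' @return log prior density (\code{-Inf} outside the support).
#' @export
log_prior <- function(theta, eta, spec) {
  tb <- spec$theta_bounds
  if (!all(names(theta) %in% rownames(tb)))
    stop("parameter(s) missing from the prior specification: ",
         paste(setdiff(names(theta), rownames(tb)), collapse = ", "))
  l <- tb[names(theta), 1]; u <- tb[names(theta), 2]
  if (any(theta < l | theta > u)) return(-Inf)
  lp <- -sum(log(u - l))
  if (spec$error_model == "iid") {
    if (!"sigma2" %in% names(eta)) stop("eta must contain sigma2")
    lp <- lp + log_dinvgamma(eta[["sigma2"]], spec$sigma2_prior[["a"]],
                             spec$sigma2_prior[["b"]])
  } else {
    if (!all(c("w", "b", "sigma_n2") %in% names(eta)))
      stop("eta must contain w, b and sigma_n2")
    lp <- lp + log_dloguniform(eta[["w"]], spec$w_range[1], spec$w_range[2]) +
      log_dloguniform(eta[["b"]], spec$b_range[1], spec$b_range[2]) +
      log_dinvgamma(eta[["sigma_n2"]], spec$sigma2_prior[["a"]],
                    spec$sigma2_prior[["b"]])
  }
  unname(lp)
}

#' Conjugate Gibbs draw for the iid noise variance
#'
#' With an IG(a, b) prior and Gaussian iid residuals, the full conditional
#' of \eqn{\sigma^2} is IG(a + n/2, b + SSR/2).
#'
#' @param residuals residual vector y - m.
#' @param a,b prior shape and rate.
#' @return one draw of sigma^2.
#' @export
sigma2_gibbs <- function(residuals, a = 0.001, b = 0.001) {
  n <- length(residuals)
  stopifnot(n >= 1)
  1 / stats::rgamma(1, shape = a + n / 2, rate = b + sum(residuals^2) / 2)
}
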