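#' Neural-network covariance function
#'
#' Non-stationary arcsine ("neural network") kernel with augmented input
#' (1, t), bias variance \code{b} and weight variance \code{w}:
#' \deqn{k(t, t') = \frac{2}{\pi} \asin\!\left( \frac{2 (b + w t t')}
#'   {\sqrt{(1 + 2(b + w t^2))(1 + 2(b + w t'^2))}} \right).}
#' The kernel is symmetric, bounded by 1 in magnitude, and its variance
#' grows with |t|, which matches residuals whose spread changes over the
#' cardiac cycle. Time enters in seconds, unscaled.
#'
#' @param t,tprime times, s (vectorized; recycled against each other).
#' @param w weight-variance hyperparameter (> 0).
#' @param b bias-variance hyperparameter (> 0).
#' @return covariance values.
#' @examples
#' nn_kernel(0, 0, w = 5e4, b = 138)
#' @export
nn_kernel <- function(t, tprime, w, b) {
  stopifnot(w > 0, b > 0)
  num <- 2 * (b + w * t * tprime)
  den <- sqrt((1 + 2 * (b + w * t^2)) * (1 + 2 * (b + w * tprime^2)))
  (2 / pi) * asin(pmin(1, pmax(-1, num / den)))
}

#' Gaussian-process mismatch model
#'
#' Container for the error-model parameters of the correlated-error
#' likelihood: the neural-network kernel hyperparameters (\code{w},
#' \code{b}) and the residual noise variance \code{sigma_n2} (mmHg^2).
#' An optional overall variance multiplier \code{scale} rescales the whole
#' covariance \code{C = scale * (K + sigma_n2 I)}; it defaults to 1 and is
#' used by the synthetic-data generator to hit a signal-to-noise target
#' without changing the kernel shape.
#'
#' @param w,b kernel hyperparameters, positive.
#' @param sigma_n2 residual noise variance, mmHg^2.
#' @param scale overall variance multiplier.
#' @return object of class \code{"gp_mismatch"}.
#' @export
gp_mismatch <- function(w, b, sigma_n2, scale = 1) {
  stopifnot(w > 0, b > 0, sigma_n2 > 0, scale > 0)
  structure(list(w = w, b = b, sigma_n2 = sigma_n2, scale = scale),
            class = "gp_mismatch")
}

#' Error covariance matrix C = K + sigma_n^2 I
#'
#' Builds the covariance of the correlated error model on a time grid and
#' verifies it is positive definite via Cholesky, adding jitter up to 1e-10
#' (with a message) if the factorization initially fails.
#'
#' @param t time points, s.
#' @param gp a \code{\link{gp_mismatch}}.
#' @return matrix with attribute \code{"chol"} holding the upper-triangular
#'   Cholesky factor.
#' @export
build_covariance <- function(t, gp) {
  n <- length(t)
  K <- outer(t, t, nn_kernel, w = gp$w, b = gp$b)
  C <- gp$scale * (K + diag(gp$sigma_n2, n))
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    message("build_covariance: adding 1e-10 jitter to the diagonal")
    C <- C + diag(1e-10, n)
    R <- tryCatch(chol(C), error = function(e)
      stop("error covariance is not positive definite even with jitter"))
  }
  attr(C, "chol") <- R
  C
}

#' Log-likelihood under iid Gaussian errors
#'
#' \eqn{-\frac{n}{2}\log(2\pi\sigma^2) - \frac{1}{2\sigma^2}\sum_i (y_i -
#' m_i)^2}; the sum of squares is the (squared) Euclidean distance between
#' data and model prediction.
#'
#' @param y observed values (or a list of per-vessel vectors).
#' @param m model predictions, same shape as \code{y}.
#' @param sigma2 noise variance.
#' @return log-likelihood (scalar).
#' @export
loglik_iid <- function(y, m, sigma2) {
  if (is.list(y)) { y <- unlist(y, use.names = FALSE) }
  if (is.list(m)) { m <- unlist(m, use.names = FALSE) }
  if (length(y) != length(m)) stop("y and m must have equal length")
  stopifnot(sigma2 > 0)
  n <- length(y)
  -(n / 2) * log(2 * pi * sigma2) - sum((y - m)^2) / (2 * sigma2)
}

#' Log-likelihood under correlated Gaussian errors
#'
#' \eqn{-\frac12 \log\det(2\pi C) - \frac12 (y - m)^T C^{-1} (y - m)},
#' evaluated through the Cholesky factor of C. Multi-vessel data are
#' handled as a block-diagonal covariance: pass lists of per-vessel
#' \code{y}, \code{m} and covariance matrices (the same error parameters
#' generate every block; blocks are independent across vessels).
#'
#' @param y observations, vector or list of vectors.
#' @param m model predictions, same shape.
#' @param C covariance matrix (from \code{\link{build_covariance}}) or a
#'   list of per-vessel matrices.
#' @param pointwise if \code{TRUE}, also return the per-observation
#'   conditional log densities from the Cholesky factorization (they sum to
#'   the joint log-likelihood exactly); used for WAIC.
#' @return log-likelihood, or (with \code{pointwise}) a list with
#'   \code{loglik} and \code{pointwise}.
#' @export
loglik_correlated <- function(y, m, C, pointwise = FALSE) {
  if (is.list(y) && !is.data.frame(y)) {
    if (!is.list(C)) stop("list data require a list of covariance blocks")
    parts <- Map(function(yy, mm, CC)
      loglik_correlated(yy, mm, CC, pointwise = TRUE), y, m, C)
    pw <- unlist(lapply(parts, `[[`, "pointwise"), use.names = FALSE)
    ll <- sum(vapply(parts, `[[`, numeric(1), "loglik"))
    if (pointwise) return(list(loglik = ll, pointwise = pw))
    return(ll)
  }
  if (length(y) != length(m)) stop("y and m must have equal length")
  R <- attr(C, "chol")
  if (is.null(R)) R <- chol(C)
  r <- y - m
  z <- backsolve(R, r, transpose = TRUE)   # L^-1 r with L = t(R)
  ld <- diag(R)                             # sqrt of conditional variances
  pw <- -0.5 * log(2 * pi) - log(ld) - 0.5 * z^2
  ll <- sum(pw)
  if (pointwise) list(loglik = ll, pointwise = as.numeric(pw)) else ll
}

#' Euclidean distance between data and prediction
#'
#' The root-sum-of-squares residual used to compare posterior-median fits;
#' minimizing it is equivalent to least-squares calibration.
#'
#' @param y observations (vector or list).
#' @param m predictions, same shape.
#' @return sqrt of the residual sum of squares.
#' @export
euclidean_distance <- function(y, m) {
  if (is.list(y)) y <- unlist(y, use.names = FALSE)
  if (is.list(m)) m <- unlist(m, use.names = FALSE)
  sqrt(sum((y - m)^2))
}

#' Posterior prediction of the model-mismatch function
#'
#' Conditions the zero-mean mismatch GP \eqn{\Gamma(t)} on the observed
#' residuals \code{y - m}: the predictive mean at new times t* is
#' \eqn{K_*^T C^{-1}(y - m)} and the predictive covariance is
#' \eqn{K_{**} - K_*^T C^{-1} K_*}, with \eqn{scale\,\sigma_n^2 I} added
#' when predicting new noisy observations.
#'
#' @param t training times; \code{y}, \code{m} observations and model
#'   predictions at \code{t}.
#' @param gp a \code{\link{gp_mismatch}}.
#' @param tstar prediction times (default \code{t}).
#' @param noise if \code{TRUE}, add the residual noise variance to the
#'   predictive covariance (prediction of observations rather than of the
#'   latent mismatch).
#' @return list with \code{mean} and \code{cov} at \code{tstar}.
#' @export
mismatch_predict <- function(t, y, m, gp, tstar = t, noise = FALSE) {
  C <- build_covariance(t, gp)
  R <- attr(C, "chol")
  Ks <- gp$scale * outer(t, tstar, nn_kernel, w = gp$w, b = gp$b)
  Kss <- gp$scale * outer(tstar, tstar, nn_kernel, w = gp$w, b = gp$b)
  alpha <- backsolve(R, backsolve(R, y - m, transpose = TRUE))
  V <- backsolve(R, Ks, transpose = TRUE)    # L^-1 K*
  mu <- drop(crossprod(Ks, alpha))
  S <- Kss - crossprod(V)
  if (noise) S <- S + diag(gp$scale * gp$sigma_n2, length(tstar))
  list(mean = mu, cov = S)
}
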