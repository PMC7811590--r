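#' Train a Gaussian-process emulator of the log-posterior
#'
#' Builds a surrogate of an expensive log-posterior surface: a seeded
#' Latin-hypercube design on the parameter box (points with non-finite
#' target are discarded and resampled), an anisotropic squared-exponential
#' kernel whose length-scales, signal variance and nugget are fitted by
#' maximizing the marginal likelihood, and a second localization stage:
#' the posterior mode is found by direct optimization of the target, the
#' emulation box is shrunk to the mode plus-minus ten Laplace widths, and
#' the final GP is fitted to a fresh space-filling design inside that
#' box. Inputs are scaled to the current box internally.
#'
#' @param log_posterior function of a named parameter vector returning the
#'   log posterior (up to a constant).
#' @param bounds named k x 2 matrix of box bounds.
#' @param n_design design size (>= 10 per dimension recommended; default
#'   30 per dimension).
#' @param seed integer seed.
#' @param n_refine refinement points (default equal to \code{n_design}).
#' @param n_candidates unused placeholder kept for call compatibility.
#' @param scale multiplier turning the emulated surface into the log
#'   density used by the internal refinement chain (see
#'   \code{\link{emulated_mcmc}}).
#' @return object of class \code{"posterior_emulator"} with fields
#'   \code{X} (unit-box inputs), \code{y} (targets), \code{bounds},
#'   hyperparameters and a fitted predictor.
#' @export
train_emulator <- function(log_posterior, bounds, n_design = NULL,
                           seed = 1, n_refine = NULL, n_candidates = 500,
                           scale = 1) {
  k <- nrow(bounds)
  if (is.null(n_design)) n_design <- 30L * k
  if (is.null(n_refine)) n_refine <- n_design
  lo <- bounds[, 1]; up <- bounds[, 2]
  to_nat <- function(U) sweep(sweep(U, 2, up - lo, "*"), 2, lo, "+")
  eval_target <- function(U) {
    X <- to_nat(U)
    apply(X, 1, function(row)
      log_posterior(stats::setNames(row, rownames(bounds))))
  }

  set.seed(seed)
  U <- lhs::randomLHS(n_design, k)
  y <- eval_target(U)
  tries <- 0
  while (any(!is.finite(y)) && tries < 20) {
    bad <- !is.finite(y)
    U[bad, ] <- lhs::randomLHS(sum(bad), k)
    y[bad] <- eval_target(U[bad, , drop = FALSE])
    tries <- tries + 1
  }
  keep <- is.finite(y)
  if (!any(keep)) stop("all design points have non-finite log-posterior")
  U <- U[keep, , drop = FALSE]; y <- y[keep]

  fit <- fit_gp(U, y)
  ## Second-stage localization: the posterior typically occupies a tiny,
  ## strongly anisotropic fraction of the prior box, which a global
  ## stationary GP cannot resolve. Draws outside the local box carry
  ## essentially no posterior mass and are rejected by the emulated
  ## sampler.
  box_lo <- rep(0, k); box_hi <- rep(1, k)
  if (n_refine > 0) {
    ## Locate the posterior mode by direct optimization of the true
    ## target (Nelder-Mead from the best design point), then size the
    ## local box from a Laplace approximation: numerical curvature of
    ## scale * target at the mode gives per-coordinate posterior widths,
    ## and the box spans the mode +- 6 widths (clipped to the prior box,
    ## never narrower than 2% of it).
    neg <- function(u) {
      if (any(u <= 0) || any(u >= 1)) return(1e10)
      v <- eval_target(matrix(u, 1))
      if (!is.finite(v)) 1e10 else -v
    }
    opt <- if (k == 1) {
      stats::optim(U[which.max(y), ], neg, method = "Brent",
                   lower = 1e-6, upper = 1 - 1e-6)
    } else {
      stats::optim(U[which.max(y), ], neg, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-10))
    }
    mode_u <- pmin(pmax(opt$par, 1e-6), 1 - 1e-6)
    h <- 2e-3
    width <- vapply(seq_len(k), function(j) {
      e <- rep(0, k); e[j] <- h
      d2 <- (-neg(mode_u + e) + 2 * opt$value - neg(mode_u - e)) / h^2
      if (!is.finite(d2) || d2 >= -1e-8) return(0.5)
      min(0.5, 1 / sqrt(-d2 * scale))
    }, numeric(1))
    box_lo <- pmax(0, mode_u - pmax(6 * width, 0.01))
    box_hi <- pmin(1, mode_u + pmax(6 * width, 0.01))
    to_local <- function(M)
      sweep(sweep(M, 2, box_lo), 2, box_hi - box_lo, "/")
    inside <- apply(U, 1, function(r) all(r >= box_lo & r <= box_hi))
    U2 <- rbind(lhs::randomLHS(n_refine, k),
                to_local(matrix(mode_u, 1)))
    y2 <- eval_target(sweep(sweep(U2, 2, box_hi - box_lo, "*"), 2,
                            box_lo, "+"))
    ok <- is.finite(y2)
    U <- rbind(to_local(U[inside, , drop = FALSE]), U2[ok, , drop = FALSE])
    y <- c(y[inside], y2[ok])
    fit <- fit_gp(U, y)
  }
  bounds_local <- cbind(lower = lo + box_lo * (up - lo),
                        upper = lo + box_hi * (up - lo))
  rownames(bounds_local) <- rownames(bounds)
  structure(list(X = U, y = y, bounds = bounds_local,
                 prior_bounds = bounds, gp = fit, seed = seed),
            class = "posterior_emulator")
}

## Anisotropic squared-exponential GP regression on the unit box; marginal
## likelihood maximized over log length-scales, log signal sd, log nugget.
fit_gp <- function(X, y) {
  n <- nrow(X); k <- ncol(X)
  mu <- mean(y); sdy <- stats::sd(y)
  if (sdy == 0) sdy <- 1
  z <- (y - mu) / sdy
  kern <- function(A, B, ell) {
    D <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(ncol(A)))
      D <- D + outer(A[, j], B[, j], "-")^2 / ell[j]^2
    exp(-0.5 * D)
  }
  nll <- function(par) {
    ell <- exp(par[1:k]); s2 <- exp(2 * par[k + 1])
    nug <- exp(2 * par[k + 2])
    K <- s2 * kern(X, X, ell) + diag(nug + 1e-10, n)
    R <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    a <- backsolve(R, backsolve(R, z, transpose = TRUE))
    0.5 * sum(z * a) + sum(log(diag(R)))
  }
  start <- c(rep(log(0.3), k), log(1), log(0.05))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(rep(log(0.02), k), log(1e-3), log(1e-4)),
                      upper = c(rep(log(5), k), log(50), log(1)),
                      control = list(maxit = 200))
  ell <- exp(opt$par[1:k]); s2 <- exp(2 * opt$par[k + 1])
  nug <- exp(2 * opt$par[k + 2])
  K <- s2 * kern(X, X, ell) + diag(nug + 1e-10, n)
  R <- chol(K)
  alpha <- backsolve(R, backsolve(R, z, transpose = TRUE))
  list(X = X, mu = mu, sdy = sdy, ell = ell, s2 = s2, nug = nug,
       R = R, alpha = alpha, kern = kern)
}

gp_predict <- function(fit, Xnew) {
  Ks <- fit$s2 * fit$kern(fit$X, Xnew, fit$ell)
  mean <- fit$mu + fit$sdy * drop(crossprod(Ks, fit$alpha))
  V <- backsolve(fit$R, Ks, transpose = TRUE)
  var <- pmax(0, fit$s2 - colSums(V^2)) * fit$sdy^2
  list(mean = mean, var = var)
}

#' Predict from a posterior emulator
#'
#' @param object a \code{\link{train_emulator}} result.
#' @param newdata matrix (or vector) of parameter values on the natural
#'   scale.
#' @param ... unused.
#' @return list with \code{mean} and \code{var} of the emulated
#'   log-posterior.
#' @export
predict.posterior_emulator <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  lo <- object$bounds[, 1]; up <- object$bounds[, 2]
  U <- sweep(sweep(newdata, 2, lo), 2, up - lo, "/")
  gp_predict(object$gp, U)
}

#' MCMC on an emulated log-posterior surface
#'
#' Runs the adaptive Metropolis sampler with the emulator predictive mean
#' standing in for the expensive log-posterior; draws outside the training
#' box get zero posterior mass. The returned chain is flagged as emulated.
#'
#' @param emulator a \code{\link{train_emulator}} result.
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param scale multiplier applied to the emulator mean before use as a
#'   log density (used when the emulator was trained on a rescaled
#'   transform of the log-posterior).
#' @param ... passed to \code{\link{run_mcmc}}.
#' @return an \code{"uq_chain"} (attribute \code{"emulated"} set).
#' @export
emulated_mcmc <- function(emulator, n_iter = 5000, seed = 1, scale = 1,
                          ...) {
  bounds <- emulator$bounds
  k <- nrow(bounds)
  target <- function(par) {
    if (any(par < bounds[, 1] | par > bounds[, 2])) return(-Inf)
    scale * predict(emulator, par)$mean
  }
  best <- emulator$X[which.max(emulator$y), ]
  init <- bounds[, 1] + best * (bounds[, 2] - bounds[, 1])
  ## keep the start strictly inside the box for the logit transform
  init <- pmin(pmax(init, bounds[, 1] + 1e-6 * (bounds[, 2] - bounds[, 1])),
               bounds[, 2] - 1e-6 * (bounds[, 2] - bounds[, 1]))
  names(init) <- rownames(bounds)
  chain <- run_mcmc(target, init, n_iter = n_iter, seed = seed,
                    transform = rep("logit", k),
                    lower = bounds[, 1], upper = bounds[, 2], ...)
  attr(chain, "emulated") <- TRUE
  chain
}
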