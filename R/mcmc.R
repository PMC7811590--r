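## Coordinate transforms used by the sampler: the chain lives in an
## unconstrained space; box-bounded parameters are logit-transformed and
## positive parameters log-transformed, with the Jacobian added to the
## target so the chain samples the posterior of the *natural* parameters.

transform_forward <- function(v, kind, lower, upper) {
  switch(kind,
    identity = v,
    log = log(v),
    logit = log((v - lower) / (upper - v)))
}

transform_back <- function(x, kind, lower, upper) {
  switch(kind,
    identity = x,
    log = exp(x),
    logit = lower + (upper - lower) / (1 + exp(-x)))
}

## log |dv/dx| for one coordinate
transform_logjac <- function(x, kind, lower, upper) {
  switch(kind,
    identity = 0,
    log = x,
    logit = {
      s <- 1 / (1 + exp(-x))
      log(upper - lower) + log(s) + log1p(-s)
    })
}

natural_of <- function(x, kinds, lower, upper) {
  vapply(seq_along(x), function(i)
    transform_back(x[i], kinds[i], lower[i], upper[i]), numeric(1))
}

logjac_of <- function(x, kinds, lower, upper) {
  sum(vapply(seq_along(x), function(i)
    transform_logjac(x[i], kinds[i], lower[i], upper[i]), numeric(1)))
}

#' Adaptive random-walk Metropolis sampler
#'
#' Samples a target density with an adaptive Gaussian random-walk
#' Metropolis algorithm on transformed coordinates: box-bounded parameters
#' are logit-transformed, positive ones log-transformed, and the Jacobian
#' correction is applied so the returned draws follow the target in the
#' natural parameterization. The proposal covariance is re-estimated from
#' the chain history every \code{adapt_every} iterations (scaled by
#' 2.38^2/d), and a global step-size factor is tuned toward the target
#' acceptance rate. An optional Gibbs step can refresh designated
#' coordinates from their full conditional after every Metropolis move
#' (used for the conjugate iid noise variance).
#'
#' @param log_posterior function taking a named parameter vector (natural
#'   scale) and returning the log posterior density (up to a constant).
#' @param init named numeric vector of starting values; the log posterior
#'   must be finite there.
#' @param n_iter total number of iterations.
#' @param seed integer seed; chains are reproducible bit-for-bit.
#' @param transform character vector per coordinate: \code{"logit"},
#'   \code{"log"} or \code{"identity"} (default all \code{"identity"}).
#' @param lower,upper bounds for logit-transformed coordinates.
#' @param adapt_every adaptation interval, iterations.
#' @param target_accept target acceptance rate of the scale adaptation.
#' @param burnin fraction of the chain discarded as burn-in by
#'   \code{\link{chain_draws}} (stored, not dropped).
#' @param gibbs optional list with \code{index} (coordinate names) and
#'   \code{draw} (function of the full natural-scale vector returning new
#'   values for those coordinates).
#' @param init_step initial proposal standard deviation in transformed
#'   space.
#' @return An object of class \code{"uq_chain"}: matrix \code{draws}
#'   (n_iter x k, natural scale), \code{log_post} trace, acceptance rate,
#'   seed, burn-in fraction and the settings used.
#' @export
run_mcmc <- function(log_posterior, init, n_iter, seed = 1,
                     transform = NULL, lower = NULL, upper = NULL,
                     adapt_every = 100, target_accept = 0.25,
                     burnin = 0.5, gibbs = NULL, init_step = 0.05) {
  k <- length(init)
  nm <- names(init)
  if (is.null(nm)) nm <- paste0("par", seq_len(k))
  if (is.null(transform)) transform <- rep("identity", k)
  if (is.null(lower)) lower <- rep(-Inf, k)
  if (is.null(upper)) upper <- rep(Inf, k)
  stopifnot(length(transform) == k, n_iter >= 10)

  set.seed(seed)
  x <- vapply(seq_len(k), function(i)
    transform_forward(init[i], transform[i], lower[i], upper[i]), numeric(1))
  if (any(!is.finite(x)))
    stop("initial value outside the transform support")
  v <- natural_of(x, transform, lower, upper)
  names(v) <- nm
  lp_nat <- log_posterior(v)
  if (!is.finite(lp_nat)) stop("log posterior not finite at init")
  lp <- lp_nat + logjac_of(x, transform, lower, upper)

  draws <- matrix(NA_real_, n_iter, k, dimnames = list(NULL, nm))
  lp_trace <- numeric(n_iter)
  accepted <- 0L
  window_acc <- 0L
  log_scale <- 0
  S <- diag(init_step^2, k)
  cholS <- chol(S)
  hist_x <- matrix(NA_real_, n_iter, k)

  for (it in seq_len(n_iter)) {
    z <- drop(crossprod(cholS, stats::rnorm(k))) * exp(log_scale)
    xp <- x + z
    vp <- natural_of(xp, transform, lower, upper)
    names(vp) <- nm
    lpp_nat <- log_posterior(vp)
    lpp <- if (is.finite(lpp_nat))
      lpp_nat + logjac_of(xp, transform, lower, upper) else -Inf
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      x <- xp; v <- vp; lp <- lpp; lp_nat <- lpp_nat
      accepted <- accepted + 1L
      window_acc <- window_acc + 1L
    }
    if (!is.null(gibbs)) {
      vg <- v
      vg[gibbs$index] <- gibbs$draw(v)
      x[match(gibbs$index, nm)] <- vapply(match(gibbs$index, nm), function(i)
        transform_forward(vg[i], transform[i], lower[i], upper[i]),
        numeric(1))
      v <- vg
      lp_nat <- log_posterior(v)
      lp <- lp_nat + logjac_of(x, transform, lower, upper)
    }
    draws[it, ] <- v
    hist_x[it, ] <- x
    lp_trace[it] <- lp_nat

    if (it %% adapt_every == 0 && it < n_iter) {
      rate <- window_acc / adapt_every
      window_acc <- 0L
      log_scale <- log_scale + (rate - target_accept)
      if (it >= 2 * adapt_every) {
        emp <- stats::cov(hist_x[max(1, it - 2000):it, , drop = FALSE])
        S <- 2.38^2 / k * emp + diag(1e-8, k)
        cS <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(cS)) cholS <- cS
      }
      if (it >= 5 * adapt_every && accepted == 0L)
        stop("sampler diagnostic: zero acceptance after adaptation window")
    }
  }

  structure(list(draws = draws, log_post = lp_trace,
                 acceptance = accepted / n_iter, seed = seed,
                 burnin = burnin,
                 settings = list(adapt_every = adapt_every,
                                 target_accept = target_accept,
                                 transform = transform,
                                 lower = lower, upper = upper)),
            class = "uq_chain")
}

#' Post burn-in draws of a chain
#'
#' @param chain a \code{\link{run_mcmc}} result.
#' @param n optional number of evenly spaced draws to return.
#' @return matrix of draws (natural scale).
#' @export
chain_draws <- function(chain, n = NULL) {
  d <- chain$draws
  start <- floor(nrow(d) * chain$burnin) + 1
  d <- d[start:nrow(d), , drop = FALSE]
  if (!is.null(n) && n < nrow(d))
    d <- d[round(seq(1, nrow(d), length.out = n)), , drop = FALSE]
  d
}

#' @export
print.uq_chain <- function(x, ...) {
  cat("MCMC chain:", nrow(x$draws), "iterations,", ncol(x$draws),
      "parameters, acceptance rate", sprintf("%.2f", x$acceptance), "\n")
  med <- apply(chain_draws(x), 2, stats::median)
  cat("posterior medians (post burn-in):\n")
  print(signif(med, 4))
  invisible(x)
}
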