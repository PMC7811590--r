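#' Watanabe--Akaike information criterion
#'
#' Computes WAIC from a matrix of pointwise log predictive densities:
#' \eqn{lppd = \sum_i \log( \frac1S \sum_s e^{\ell_{si}} )} (log-sum-exp
#' stabilized), the effective parameter count
#' \eqn{p_{waic} = \sum_i \mathrm{var}_s(\ell_{si})} (sample variance,
#' denominator S - 1) and \eqn{WAIC = -2 (lppd - p_{waic})}. Lower is
#' better. Under a correlated likelihood the per-point entries are the
#' conditional per-observation log densities from the Cholesky
#' factorization (see \code{\link{loglik_correlated}}), which sum exactly
#' to the joint log-likelihood; a joint variant (a single column holding
#' the full log-likelihood per draw) is obtained by passing that matrix
#' directly.
#'
#' @param pointwise_loglik S x n matrix: S posterior draws, n data points.
#' @return list of class \code{"waic_result"} with \code{lppd},
#'   \code{p_waic} and \code{waic}.
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2) stop("WAIC needs at least two posterior draws")
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihood entries")
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC = %.2f (lppd = %.2f, p_waic = %.2f)\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}

#' Relative sum of squared errors
#'
#' \eqn{\sum_i ((\theta_i - \hat\theta_i)/\theta_i)^2}: the relative
#' deviation of estimated from true parameter values.
#'
#' @param theta_hat estimated parameter vector.
#' @param theta_true true parameter vector, nonzero entries.
#' @return scalar.
#' @export
relative_sse <- function(theta_hat, theta_true) {
  if (length(theta_hat) != length(theta_true))
    stop("theta_hat and theta_true must have equal length")
  if (any(theta_true == 0)) stop("theta_true must have nonzero coordinates")
  sum(((theta_true - theta_hat) / theta_true)^2)
}

## Welch-style spectral density at frequency zero: average the lowest
## nonzero periodogram ordinates of 8 half-overlapping Hann-windowed
## segments of the mean-removed series.
spectrum0 <- function(x, segments = 8) {
  n <- length(x)
  x <- x - mean(x)
  if (stats::var(x) == 0) return(0)
  seg_len <- max(8, floor(2 * n / (segments + 1)))
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  wnorm <- sum(win^2) / seg_len
  vals <- vapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1)] * win
    pg <- Mod(stats::fft(seg))^2 / (seg_len * wnorm)
    mean(pg[2:4])  # lowest nonzero frequencies
  }, numeric(1))
  mean(vals)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of an early and a late chain segment with a Z test
#' whose standard errors come from spectral density estimates at frequency
#' zero (Welch periodogram averaging), so autocorrelation is accounted
#' for. Defaults: first 10\% vs last 50\%.
#'
#' @param x numeric chain (one parameter), length >= 100.
#' @param first_frac,last_frac fractions of the chain used for the early
#'   and late segments.
#' @return list with \code{z} and two-sided \code{p_value}.
#' @export
geweke <- function(x, first_frac = 0.1, last_frac = 0.5) {
  n <- length(x)
  if (n < 100) stop("geweke needs a chain of length >= 100")
  a <- x[seq_len(floor(first_frac * n))]
  b <- x[(n - floor(last_frac * n) + 1):n]
  va <- spectrum0(a) / length(a)
  vb <- spectrum0(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(z = 0, p_value = 1))
    stop("degenerate variance in Geweke segments")
  }
  z <- (mean(a) - mean(b)) / sqrt(va + vb)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Brooks--Gelman multivariate potential scale reduction factor
#'
#' \eqn{MPSRF = (n-1)/n + \frac{m+1}{m} \lambda_{max}(W^{-1} B / n)} with
#' W the mean within-chain covariance and B/n the between-chain covariance
#' of the chain means. Values at or below 1.1 indicate convergence.
#'
#' @param chains list of m >= 2 draw matrices (n x k) with equal
#'   dimensions, or a 3-d array (m, n, k).
#' @return scalar MPSRF.
#' @export
mpsrf <- function(chains) {
  if (is.array(chains) && length(dim(chains)) == 3)
    chains <- lapply(seq_len(dim(chains)[1]), function(i) chains[i, , ])
  m <- length(chains)
  if (m < 2) stop("mpsrf needs at least two chains")
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]])
  if (!all(vapply(chains, nrow, 1L) == n))
    stop("all chains must have equal length")
  k <- ncol(chains[[1]])
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  means <- t(vapply(chains, colMeans, numeric(k)))
  Bn <- stats::cov(means)  # = B / n
  if (all(Bn == 0)) return((n - 1) / n)
  WB <- tryCatch(solve(W, Bn), error = function(e)
    stop("singular within-chain covariance"))
  lam <- max(Re(eigen(WB, only.values = TRUE)$values))
  (n - 1) / n + (m + 1) / m * lam
}

#' Gaussian kernel density estimate
#'
#' Univariate: normal-optimal bandwidth \eqn{1.06\,\hat\sigma\,S^{-1/5}}.
#' Multivariate: product Gaussian kernel with diagonal Silverman
#' bandwidths \eqn{h_i = \hat\sigma_i (4/(d+2))^{1/(d+4)} S^{-1/(d+4)}}.
#' For multivariate use the samples should be pre-scaled to a common order
#' of magnitude (see \code{\link{scale_to_unit_magnitude}}).
#'
#' @param samples numeric vector (univariate) or matrix with one row per
#'   sample (multivariate).
#' @param eval_points points at which to evaluate the density; vector or
#'   matrix matching \code{samples}.
#' @return density values at \code{eval_points}.
#' @export
kde_density <- function(samples, eval_points) {
  if (is.matrix(samples) && ncol(samples) > 1) {
    S <- nrow(samples); d <- ncol(samples)
    sds <- apply(samples, 2, stats::sd)
    if (any(sds == 0)) stop("zero variance in a KDE coordinate")
    h <- sds * (4 / (d + 2))^(1 / (d + 4)) * S^(-1 / (d + 4))
    ep <- if (is.matrix(eval_points)) eval_points else
      matrix(eval_points, ncol = d)
    apply(ep, 1, function(p) {
      z <- sweep(sweep(samples, 2, p), 2, h, "/")
      mean(exp(rowSums(stats::dnorm(z, log = TRUE)))) / prod(h)
    })
  } else {
    x <- as.numeric(samples)
    S <- length(x)
    if (S < 2) stop("need at least two samples")
    sdx <- stats::sd(x)
    if (sdx == 0) stop("zero variance in KDE samples")
    h <- 1.06 * sdx * S^(-1 / 5)
    vapply(as.numeric(eval_points), function(p)
      mean(stats::dnorm((x - p) / h)) / h, numeric(1))
  }
}

#' Scale posterior samples to a common order of magnitude
#'
#' Divides each column by a power of ten so the column medians have
#' magnitude in [0.1, 1); the same factors must be applied to the point at
#' which a joint density is evaluated. Used before multivariate kernel
#' density estimation of parameters spanning many orders of magnitude.
#'
#' @param samples matrix of samples (rows) by parameters (columns).
#' @return list with \code{samples} (scaled) and \code{factors} (the
#'   divisors applied per column).
#' @export
scale_to_unit_magnitude <- function(samples) {
  samples <- as.matrix(samples)
  med <- apply(abs(samples), 2, stats::median)
  med[med == 0] <- 1
  factors <- 10^ceiling(log10(med))
  list(samples = sweep(samples, 2, factors, "/"), factors = factors)
}
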