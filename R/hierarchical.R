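#' Gibbs-within-Metropolis sampler for vessel-specific stiffness
#'
#' Bayesian hierarchical model for per-vessel wall stiffness under the
#' linear wall law: each vessel's stiffness is drawn from a common
#' population law \eqn{\chi_j \sim N(m_\chi, \sigma_\chi^2)} truncated to
#' positive values, with hyperpriors \eqn{m_\chi \sim N(\mu_0, \tau_0^2)}
#' and \eqn{\sigma_\chi^2 \sim IG(a_0, b_0)}. The default hyperpriors are
#' calibrated so the prior predictive places about 90\% of its mass on
#' stiffness values between 2e4 and 1e5 g cm^-1 s^-2. The sampler
#' alternates (i) a conjugate normal draw of \eqn{m_\chi}, (ii) a
#' conjugate inverse-gamma draw of \eqn{\sigma_\chi^2}, (iii) random-walk
#' Metropolis updates of each \eqn{\chi_j} on the log scale (each requires
#' a forward solve), and (iv) a joint Metropolis update of the Windkessel
#' scaling factors and the error parameters. The population truncation at
#' zero is treated as negligible in the conjugate updates (the population
#' mass below zero is ~1e-6 at the default hyperpriors). Limiting cases:
#' with \code{fix_sigma2_chi} near zero all stiffness values are pulled to
#' the population mean (shared-stiffness model); with it very large and a
#' flat mean hyperprior the stiffness posteriors decouple
#' (independent-stiffness model).
#'
#' @param data named list of per-vessel pressure data frames
#'   (\code{time_s}, \code{value}); names are vessel ids.
#' @param network a \code{\link{vessel_network}}.
#' @param inflow root inflow waveform.
#' @param mismatch logical: GP mismatch likelihood (model G) or iid
#'   (model F).
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param hyper list with \code{m_mean}, \code{m_sd} (population-mean
#'   hyperprior; \code{m_sd = Inf} gives the flat prior), \code{s2_shape},
#'   \code{s2_rate} (population-variance hyperprior).
#' @param init optional list with \code{chi}, \code{psi}, \code{eta}.
#' @param fix_sigma2_chi optional fixed value of the population variance
#'   (skips its Gibbs update).
#' @param forward optional replacement forward map
#'   \code{function(chi, psi)} returning the predicted per-vessel series
#'   (used in tests with a frozen cheap model); default runs the PDE
#'   solver.
#' @param nominal,mean_pressure,grid,constants,obs_frac as in
#'   \code{\link{pcirc_fit}}.
#' @param step_chi,step_block random-walk standard deviations (log-chi
#'   scale; transformed block scale).
#' @return an \code{"uq_chain"} with columns \code{chi_1..chi_k},
#'   \code{m_chi}, \code{sigma2_chi}, \code{psi1}, \code{psi2}, \code{c}
#'   and the error parameters.
#' @export
gibbs_hierarchical <- function(data, network, inflow, mismatch = FALSE,
                               n_iter = 1000, seed = 1,
                               hyper = list(m_mean = 6e4, m_sd = 2.4e4,
                                            s2_shape = 2, s2_rate = 2e8),
                               init = NULL, fix_sigma2_chi = NULL,
                               forward = NULL, nominal = NULL,
                               mean_pressure = 17.5,
                               grid = sim_grid(dx = 0.05, dt = 6e-5,
                                               n_cycles = 8),
                               constants = physical_constants(),
                               obs_frac = 0.5,
                               step_chi = 0.05, step_block = 0.08) {
  k <- if (!is.null(init$chi)) length(init$chi) else nrow(network$vessels)
  ids <- as.integer(names(data))
  t_obs <- data[[1]]$time_s
  y <- lapply(data, `[[`, "value")
  psi_b <- c(0.05, 2.50)
  w_range <- c(1e4, 9e4); b_range <- c(1, 500)

  if (is.null(forward)) {
    if (is.null(nominal)) {
      sv <- sum(inflow$value[-1] * diff(inflow$time_s))
      nominal <- nominal_windkessel(network, sv / constants$period,
                                    mean_pressure, constants = constants)
    }
    forward <- function(chi, psi) {
      wall <- wall_model("linear", "vessel_specific", chi = chi)
      wk <- tryCatch(apply_scalings(nominal, psi[1], psi[2], psi[3]),
                     error = function(e) NULL)
      if (is.null(wk)) return(NULL)
      sim <- tryCatch(
        simulate_network(network, wall, wk, inflow, grid, constants),
        error = function(e) NULL)
      if (is.null(sim)) return(NULL)
      out <- lapply(ids, function(id)
        sim_series(sim, id, frac = obs_frac, times = t_obs)$value)
      names(out) <- as.character(ids)
      out
    }
  }

  loglik <- function(m, eta) {
    if (is.null(m)) return(-Inf)
    if (mismatch) {
      gp <- tryCatch(gp_mismatch(eta[["w"]], eta[["b"]],
                                 eta[["sigma_n2"]]),
                     error = function(e) NULL)
      if (is.null(gp)) return(-Inf)
      C <- tryCatch(build_covariance(t_obs, gp), error = function(e) NULL)
      if (is.null(C)) return(-Inf)
      loglik_correlated(y, m, rep(list(C), length(y)))
    } else {
      loglik_iid(y, m, eta[["sigma2"]])
    }
  }

  set.seed(seed)
  chi <- if (!is.null(init$chi)) init$chi else rep(6e4, k)
  psi <- if (!is.null(init$psi)) init$psi else c(1, 1, 1)
  eta <- if (!is.null(init$eta)) init$eta else {
    if (mismatch) c(w = 3e4, b = 22, sigma_n2 = 0.05) else c(sigma2 = 1)
  }
  m_chi <- mean(chi)
  s2_chi <- if (!is.null(fix_sigma2_chi)) fix_sigma2_chi else
    stats::var(chi) + 1e6
  m_cur <- forward(chi, psi)
  ll_cur <- loglik(m_cur, eta)
  if (!is.finite(ll_cur)) stop("non-finite log-likelihood at init")

  eta_names <- names(eta)
  cols <- c(paste0("chi_", seq_len(k)), "m_chi", "sigma2_chi",
            "psi1", "psi2", "c", eta_names)
  draws <- matrix(NA_real_, n_iter, length(cols),
                  dimnames = list(NULL, cols))
  lp_trace <- numeric(n_iter)
  acc_chi <- 0L; acc_block <- 0L

  log_prior_chi <- function(chi, m, s2)
    sum(stats::dnorm(chi, m, sqrt(s2), log = TRUE)) +
      ifelse(all(chi > 0), 0, -Inf)
  log_prior_block <- function(psi, eta) {
    if (any(psi < psi_b[1]) || any(psi > psi_b[2])) return(-Inf)
    lp <- 0
    if (mismatch) {
      lp <- lp + log_dloguniform(eta[["w"]], w_range[1], w_range[2]) +
        log_dloguniform(eta[["b"]], b_range[1], b_range[2]) +
        log_dinvgamma(eta[["sigma_n2"]], 0.001, 0.001)
    } else {
      lp <- lp + log_dinvgamma(eta[["sigma2"]], 0.001, 0.001)
    }
    lp
  }

  for (it in seq_len(n_iter)) {
    ## (i) population mean: conjugate normal (flat prior when m_sd = Inf)
    if (is.finite(hyper$m_sd)) {
      prec <- 1 / hyper$m_sd^2 + k / s2_chi
      mu <- (hyper$m_mean / hyper$m_sd^2 + sum(chi) / s2_chi) / prec
      m_chi <- stats::rnorm(1, mu, sqrt(1 / prec))
    } else {
      m_chi <- stats::rnorm(1, mean(chi), sqrt(s2_chi / k))
    }
    ## (ii) population variance: conjugate inverse gamma
    if (is.null(fix_sigma2_chi)) {
      s2_chi <- 1 / stats::rgamma(1, hyper$s2_shape + k / 2,
                                  hyper$s2_rate +
                                    sum((chi - m_chi)^2) / 2)
    }
    ## (iii) per-vessel stiffness: Metropolis on log chi_j
    for (j in seq_len(k)) {
      prop <- chi
      prop[j] <- chi[j] * exp(step_chi * stats::rnorm(1))
      m_prop <- forward(prop, psi)
      ll_prop <- loglik(m_prop, eta)
      lr <- ll_prop - ll_cur +
        log_prior_chi(prop, m_chi, s2_chi) -
        log_prior_chi(chi, m_chi, s2_chi) +
        log(prop[j]) - log(chi[j])     # log-scale proposal Jacobian
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        chi <- prop; m_cur <- m_prop; ll_cur <- ll_prop
        acc_chi <- acc_chi + 1L
      }
    }
    ## (iv) Windkessel scalings + error parameters: joint Metropolis
    z <- step_block * stats::rnorm(3 + length(eta))
    psi_p <- psi * exp(z[1:3])
    eta_p <- eta * exp(z[-(1:3)])
    m_prop <- if (any(psi_p < psi_b[1]) || any(psi_p > psi_b[2])) NULL
      else forward(chi, psi_p)
    ll_prop <- loglik(m_prop, eta_p)
    lr <- ll_prop - ll_cur +
      log_prior_block(psi_p, eta_p) - log_prior_block(psi, eta) +
      sum(z)                            # multiplicative proposal Jacobian
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      psi <- psi_p; eta <- eta_p; m_cur <- m_prop; ll_cur <- ll_prop
      acc_block <- acc_block + 1L
    }
    draws[it, ] <- c(chi, m_chi, s2_chi, psi, eta)
    lp_trace[it] <- ll_cur + log_prior_chi(chi, m_chi, s2_chi) +
      log_prior_block(psi, eta)
  }

  structure(list(draws = draws, log_post = lp_trace,
                 acceptance = acc_chi / (n_iter * k),
                 acceptance_block = acc_block / n_iter,
                 seed = seed, burnin = 0.5,
                 settings = list(hyper = hyper, mismatch = mismatch,
                                 step_chi = step_chi,
                                 step_block = step_block)),
            class = "uq_chain")
}
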