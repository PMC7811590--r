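#' Parametric inflow waveform specification
#'
#' Stand-in for a measured main-pulmonary-artery flow wave: a squared-sine
#' systolic ejection of duration \code{t_sys}, a small negative lobe just
#' after valve closure, and near-zero diastolic flow. The default values
#' are calibrated once so that forward simulation of the default network
#' with representative posterior-median parameters produces physiological
#' mouse pressures (systolic max between 12 and 35 mmHg).
#'
#' @param period cardiac period T, s.
#' @param t_sys systolic ejection duration, s (0 < t_sys < T).
#' @param q_peak peak ejection flow, ml/s.
#' @param reverse_fraction amplitude of the retrograde lobe relative to
#'   \code{q_peak}.
#' @return object of class \code{"inflow_spec"} with the analytic stroke
#'   volume (ml) attached.
#' @export
inflow_spec <- function(period = 0.11, t_sys = 0.045, q_peak = 0.80,
                        reverse_fraction = 0.05) {
  stopifnot(t_sys > 0, t_sys < period, q_peak > 0,
            reverse_fraction >= 0, reverse_fraction < 1)
  t_rev <- 0.2 * t_sys
  sv <- q_peak * t_sys / 2 - reverse_fraction * q_peak * t_rev / 2
  if (sv <= 0) stop("stroke volume must be positive")
  structure(list(period = period, t_sys = t_sys, q_peak = q_peak,
                 reverse_fraction = reverse_fraction, t_rev = t_rev,
                 stroke_volume = sv),
            class = "inflow_spec")
}

#' Evaluate the synthetic inflow waveform
#'
#' @param spec an \code{\link{inflow_spec}}.
#' @param n number of grid points over one period (>= 16).
#' @return data frame with columns \code{time_s}, \code{value} (ml/s), on
#'   \code{n} points spanning [0, T] inclusive; the waveform is periodic
#'   (equal endpoints).
#' @export
synthetic_inflow <- function(spec = inflow_spec(), n = 128) {
  if (n < 16) stop("n must be at least 16")
  tt <- seq(0, spec$period, length.out = n)
  q <- numeric(n)
  sys <- tt <= spec$t_sys
  q[sys] <- spec$q_peak * sin(pi * tt[sys] / spec$t_sys)^2
  rev <- tt > spec$t_sys & tt <= spec$t_sys + spec$t_rev
  q[rev] <- -spec$reverse_fraction * spec$q_peak *
    sin(pi * (tt[rev] - spec$t_sys) / spec$t_rev)^2
  data.frame(time_s = tt, value = q)
}

#' Data-generating truth of the synthetic study
#'
#' Linear wall model with exponential radius-dependent stiffness and
#' Windkessel scaling factors at representative posterior-median values,
#' plus neural-network-kernel error parameters shared by all vessels.
#'
#' @return list with \code{wall} (a \code{\link{wall_model}}), \code{psi}
#'   (named vector psi1, psi2, c), \code{theta} (the named biophysical
#'   vector f1, f2, f3, psi1, psi2, c) and \code{eta} (a
#'   \code{\link{gp_mismatch}}; its overall scale is calibrated per
#'   dataset by \code{\link{generate_dataset}}).
#' @export
default_truth <- function() {
  list(wall = wall_model("linear", "radius_dependent",
                         f1 = 5.11e6, f2 = -171, f3 = 4.32e4),
       psi = c(psi1 = 0.29, psi2 = 0.87, c = 1.34),
       theta = c(f1 = 5.11e6, f2 = -171, f3 = 4.32e4,
                 psi1 = 0.29, psi2 = 0.87, c = 1.34),
       eta = gp_mismatch(w = 5.39e4, b = 138, sigma_n2 = 0.05))
}

#' Cycle-averaged pressure monotonicity check
#'
#' Physiologically, mean pressure decreases from the root toward the
#' periphery. The check passes iff the cycle-averaged pressure is
#' non-increasing along every parent-to-child edge both of whose endpoints
#' are observed. A single observed vessel passes vacuously.
#'
#' @param series named list (names are vessel ids) of numeric vectors or
#'   data frames with a \code{value} column: one pressure series per
#'   observed vessel.
#' @param network the \code{\link{vessel_network}} the ids refer to.
#' @return logical.
#' @export
check_monotonicity <- function(series, network) {
  ids <- names(series)
  v <- network$vessels
  if (!all(ids %in% as.character(v$id)))
    stop("unknown vessel id(s): ",
         paste(setdiff(ids, as.character(v$id)), collapse = ", "))
  means <- vapply(series, function(s) {
    if (is.data.frame(s)) mean(s$value) else mean(s)
  }, numeric(1))
  for (key in ids) {
    par <- v$parent_id[match(as.integer(key), v$id)]
    if (!is.na(par) && as.character(par) %in% ids &&
        means[[key]] > means[[as.character(par)]] + 1e-12)
      return(FALSE)
  }
  TRUE
}

#' Generate synthetic pressure datasets with correlated noise
#'
#' Runs the forward model once at the data-generating truth, then adds
#' non-stationary additive Gaussian correlated noise drawn from the
#' neural-network-kernel GP (plus residual white noise) to the pressure in
#' each observed vessel, using the same error parameters in every vessel.
#' The overall noise variance is calibrated per instantiation (shared
#' across vessels) so the realized variance-ratio signal-to-noise,
#' var(signal)/var(noise) averaged over observed vessels, equals
#' \code{snr_target}; the calibrated scale is stored with the returned
#' truth so whitening by the generating covariance remains exact. Any
#' instantiation whose cycle-averaged noisy pressure violates
#' proximal-to-distal monotonicity across the observed vessels is
#' discarded and redrawn (capped, with the rejection count reported).
#'
#' @param network a \code{\link{vessel_network}}; default the 21-vessel
#'   synthetic tree.
#' @param truth list with elements \code{wall}, \code{psi}, \code{eta} as
#'   in \code{\link{default_truth}}.
#' @param vessels vessel ids to observe; default the root (MPA) only.
#' @param n_instantiations number of noisy datasets (default 20).
#' @param snr_target variance-ratio signal-to-noise target (default 100).
#' @param n_obs observation time points per vessel over one period.
#' @param seed integer seed; each (seed, instantiation) pair is
#'   reproducible.
#' @param inflow inflow waveform (data frame) or \code{NULL} for the
#'   default synthetic waveform.
#' @param mean_pressure nominal mean pressure (mmHg) used to initialize
#'   the Windkessel parameters.
#' @param grid a \code{\link{sim_grid}}.
#' @param constants \code{\link{physical_constants}}.
#' @param max_redraws rejection cap per instantiation.
#' @param obs_frac relative position along each vessel where pressure is
#'   observed.
#' @return object of class \code{"synthetic_dataset"}: per-instantiation
#'   named lists of data frames (\code{time_s}, \code{value}), the
#'   noise-free signal, the truth (with per-instantiation realized noise
#'   scale), realized SNR values, rejection counts and seeds.
#' @export
generate_dataset <- function(network = NULL, truth = default_truth(),
                             vessels = NULL, n_instantiations = 20,
                             snr_target = 100, n_obs = 64, seed = 1,
                             inflow = NULL, mean_pressure = 17.5,
                             grid = sim_grid(dx = 0.05, dt = 6e-5,
                                             n_cycles = 8),
                             constants = physical_constants(),
                             max_redraws = 1000, obs_frac = 0.5) {
  if (is.null(network)) network <- generate_tree(11, seed = 1)
  if (is.null(inflow)) inflow <- synthetic_inflow(inflow_spec(), n = 128)
  if (is.null(vessels)) vessels <- network$root
  vessels <- as.integer(vessels)
  spec_sv <- sum(inflow$value[-1] * diff(inflow$time_s))
  mean_flow <- spec_sv / constants$period
  nominal <- nominal_windkessel(network, mean_flow, mean_pressure,
                                constants = constants)
  wk <- apply_scalings(nominal, truth$psi[["psi1"]], truth$psi[["psi2"]],
                       truth$psi[["c"]])
  sim <- simulate_network(network, truth$wall, wk, inflow, grid, constants)

  t_obs <- seq(0, constants$period, length.out = n_obs + 1)[seq_len(n_obs)]
  signal <- lapply(vessels, function(id)
    sim_series(sim, id, frac = obs_frac, times = t_obs)$value)
  names(signal) <- as.character(vessels)
  v_signal <- mean(vapply(signal, stats::var, numeric(1)))

  C1 <- build_covariance(t_obs, truth$eta)      # unit-scale covariance
  R1 <- attr(C1, "chol")
  n <- n_obs
  target_noise_var <- v_signal / snr_target

  datasets <- vector("list", n_instantiations)
  scales <- numeric(n_instantiations)
  snr_realized <- numeric(n_instantiations)
  rejections <- integer(n_instantiations)
  seeds <- integer(n_instantiations)

  for (i in seq_len(n_instantiations)) {
    inst_seed <- (seed + 7919L * i) %% 2147483647L
    seeds[i] <- inst_seed
    set.seed(inst_seed)
    accepted <- FALSE
    tries <- 0L
    while (!accepted) {
      if (tries > max_redraws)
        stop("monotonicity rejection cap exceeded for instantiation ", i,
             " (", max_redraws, " redraws)")
      eps <- lapply(vessels, function(id)
        drop(crossprod(R1, stats::rnorm(n))))
      names(eps) <- as.character(vessels)
      v_noise_raw <- mean(vapply(eps, stats::var, numeric(1)))
      beta <- sqrt(target_noise_var / v_noise_raw)
      noisy <- Map(function(s, e) s + beta * e, signal, eps)
      if (check_monotonicity(noisy, network)) {
        accepted <- TRUE
        datasets[[i]] <- Map(function(y)
          data.frame(time_s = t_obs, value = y), noisy)
        scales[i] <- beta^2
        snr_realized[i] <- v_signal /
          mean(vapply(names(noisy), function(k)
            stats::var(noisy[[k]] - signal[[k]]), numeric(1)))
      } else {
        tries <- tries + 1L
        rejections[i] <- tries
      }
    }
  }

  structure(list(datasets = datasets,
                 signal = Map(function(y)
                   data.frame(time_s = t_obs, value = y), signal),
                 t_obs = t_obs, vessels = vessels,
                 truth = truth, noise_scales = scales,
                 snr_realized = snr_realized, snr_target = snr_target,
                 rejections = rejections, seeds = seeds, seed = seed,
                 network = network, inflow = inflow,
                 nominal = nominal, mean_pressure = mean_pressure,
                 grid = grid, constants = constants,
                 obs_frac = obs_frac, sim = sim),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$datasets), "instantiations in",
      length(x$vessels), "vessel(s),", length(x$t_obs),
      "time points each\n")
  cat(sprintf("  realized SNR %.1f (target %g); %d total rejections\n",
              mean(x$snr_realized), x$snr_target, sum(x$rejections)))
  invisible(x)
}
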