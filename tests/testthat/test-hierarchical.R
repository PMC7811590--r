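## Cheap frozen forward map used to validate the sampler's conditionals
## without PDE solves: vessel j's predicted series is chi_j / 1e4 at every
## time point.
frozen_forward <- function(ids, n_t) {
  function(chi, psi) {
    out <- lapply(seq_along(ids), function(j) rep(chi[j] / 1e4, n_t))
    names(out) <- as.character(ids)
    out
  }
}

frozen_data <- function(ids, n_t, levels) {
  d <- lapply(seq_along(ids), function(j)
    data.frame(time_s = seq(0, 0.1, length.out = n_t),
               value = rep(levels[j], n_t)))
  names(d) <- as.character(ids)
  d
}

test_that("population-mean full conditional is N(mean(chi), s2/k) under a flat prior", {
  net <- tiny_network()
  ids <- c(1, 2, 3)
  chi0 <- c(4e4, 5e4, 7e4)
  ch <- gibbs_hierarchical(
    frozen_data(ids, 8, chi0 / 1e4), net, inflow = NULL,
    n_iter = 4000, seed = 2,
    hyper = list(m_mean = 0, m_sd = Inf, s2_shape = 2, s2_rate = 2e8),
    init = list(chi = chi0, psi = c(1, 1, 1), eta = c(sigma2 = 1)),
    fix_sigma2_chi = 9e8,
    forward = frozen_forward(ids, 8),
    step_chi = 0, step_block = 0)     # chi frozen: m_chi is pure conjugacy
  m <- ch$draws[, "m_chi"]
  expect_lt(abs(mean(m) - mean(chi0)), 4 * sqrt(9e8 / 3 / 4000))
  expect_equal(var(m), 9e8 / 3, tolerance = 0.1)
})

test_that("population-variance Gibbs update matches its inverse-gamma law", {
  net <- tiny_network()
  ids <- c(1, 2, 3)
  chi0 <- c(4e4, 5e4, 7e4)
  ch <- gibbs_hierarchical(
    frozen_data(ids, 8, chi0 / 1e4), net, inflow = NULL,
    n_iter = 4000, seed = 3,
    hyper = list(m_mean = 5e4, m_sd = 1e-6, s2_shape = 3, s2_rate = 5e8),
    init = list(chi = chi0, psi = c(1, 1, 1), eta = c(sigma2 = 1)),
    forward = frozen_forward(ids, 8),
    step_chi = 0, step_block = 0)     # m_chi pinned at 5e4, chi frozen
  s2 <- ch$draws[, "sigma2_chi"]
  a_post <- 3 + 1.5
  b_post <- 5e8 + sum((chi0 - 5e4)^2) / 2
  expect_equal(mean(s2), b_post / (a_post - 1),
               tolerance = 0.05 * b_post / (a_post - 1))
})

test_that("Gibbs marginals match a brute-force grid posterior (2-vessel toy)", {
  net2 <- vessel_network(data.frame(
    id = 1:3, parent_id = c(NA, 1, 1), length_cm = 0.4, r0_cm = 0.04,
    terminal = c(FALSE, TRUE, TRUE)))
  ids <- c(2, 3)
  y_lev <- c(5.2, 4.6)       # implies chi ~ 5.2e4, 4.6e4
  n_t <- 6
  sigma2 <- 0.04
  m0 <- 5e4; s20 <- 4e8
  ch <- gibbs_hierarchical(
    frozen_data(ids, n_t, y_lev), net2, inflow = NULL,
    n_iter = 60000, seed = 4,
    hyper = list(m_mean = m0, m_sd = 1e-6, s2_shape = 2, s2_rate = 2e8),
    init = list(chi = c(5e4, 5e4), psi = c(1, 1, 1),
                eta = c(sigma2 = sigma2)),
    fix_sigma2_chi = s20,
    forward = frozen_forward(ids, n_t),
    step_chi = 0.12, step_block = 0)
  d <- chain_draws(ch)
  ## with m_chi and s2_chi pinned the chi_j posteriors factorize; compare
  ## each sampled marginal to its 1-D grid posterior on 25 cells
  grid <- seq(3e4, 7e4, length.out = 1000)
  breaks <- seq(3e4, 7e4, length.out = 26)
  for (j in 1:2) {
    logp <- dnorm(y_lev[j], grid / 1e4, sqrt(sigma2), log = TRUE) * n_t +
      dnorm(grid, m0, sqrt(s20), log = TRUE)
    p <- exp(logp - max(logp)); p <- p / sum(p)
    p_bin <- vapply(seq_len(25), function(b)
      sum(p[grid >= breaks[b] & grid < breaks[b + 1]]), numeric(1))
    emp <- as.numeric(table(cut(d[, paste0("chi_", ids[j] - 1)],
                                c(-Inf, breaks[2:25], Inf))))
    emp <- emp / sum(emp)
    tv <- 0.5 * sum(abs(emp - p_bin))
    expect_lt(tv, 0.05)
  }
})

test_that("population variance limits recover shared and independent stiffness", {
  net2 <- vessel_network(data.frame(
    id = 1:3, parent_id = c(NA, 1, 1), length_cm = 0.4, r0_cm = 0.04,
    terminal = c(FALSE, TRUE, TRUE)))
  ids <- c(2, 3)
  y_lev <- c(5.6, 4.4)
  base <- list(
    data = frozen_data(ids, 6, y_lev), network = net2, inflow = NULL,
    n_iter = 6000, seed = 5,
    init = list(chi = c(5e4, 5e4), psi = c(1, 1, 1),
                eta = c(sigma2 = 0.25)),
    forward = frozen_forward(ids, 6),
    step_chi = 0.08, step_block = 0)
  ## sigma2_chi -> 0: both stiffness values collapse onto the mean
  tight <- do.call(gibbs_hierarchical, c(base, list(
    hyper = list(m_mean = 5e4, m_sd = 1e-6, s2_shape = 2, s2_rate = 2e8),
    fix_sigma2_chi = 1e2)))
  dt_ <- chain_draws(tight)
  expect_lt(abs(median(dt_[, "chi_1"]) - median(dt_[, "chi_2"])), 500)
  ## sigma2_chi -> infinity with a flat mean hyperprior: decoupled, each
  ## chi_j tracks its own data
  loose <- do.call(gibbs_hierarchical, c(base, list(
    hyper = list(m_mean = 0, m_sd = Inf, s2_shape = 2, s2_rate = 2e8),
    fix_sigma2_chi = 1e12)))
  dl <- chain_draws(loose)
  expect_equal(median(dl[, "chi_1"]), 5.6e4, tolerance = 0.03)
  expect_equal(median(dl[, "chi_2"]), 4.4e4, tolerance = 0.03)
  ## hierarchical shrinkage: learned population variance pulls the two
  ## estimates closer together than the decoupled run
  hier <- do.call(gibbs_hierarchical, c(base, list(
    hyper = list(m_mean = 5e4, m_sd = 2.4e4, s2_shape = 2,
                 s2_rate = 2e8))))
  dh <- chain_draws(hier)
  gap_h <- abs(median(dh[, "chi_1"]) - median(dh[, "chi_2"]))
  gap_l <- abs(median(dl[, "chi_1"]) - median(dl[, "chi_2"]))
  expect_lt(gap_h, gap_l)
})

test_that("hierarchical sampler runs against the PDE forward model", {
  ## constant-stiffness truth: posterior stiffness medians come out
  ## approximately equal across vessels and near the truth
  net <- generate_tree(2, seed = 1)
  g <- desk_grid()
  truth_chi <- 5.17e4
  wall <- wall_model("linear", "vessel_specific",
                     chi = rep(truth_chi, 3))
  nom <- desk_nominal(net)
  wk <- apply_scalings(nom, 1, 1, 1.3)
  sim <- simulate_network(net, wall, wk, desk_inflow(), g)
  t_obs <- seq(0, 0.11, length.out = 33)[1:32]
  set.seed(6)
  d <- lapply(c(1, 2, 3), function(id) {
    v <- sim_series(sim, id, times = t_obs)$value
    data.frame(time_s = t_obs, value = v + rnorm(32, 0, 0.15))
  })
  names(d) <- c("1", "2", "3")
  ch <- gibbs_hierarchical(d, net, desk_inflow(), n_iter = 250, seed = 7,
                           init = list(chi = rep(6e4, 3),
                                       psi = c(1, 1, 1.3),
                                       eta = c(sigma2 = 0.04)),
                           nominal = nom, grid = g, step_chi = 0.04,
                           step_block = 0.02)
  dd <- chain_draws(ch)
  med <- apply(dd[, c("chi_1", "chi_2", "chi_3")], 2, median)
  expect_true(all(abs(med - truth_chi) / truth_chi < 0.25))
  expect_lt(diff(range(med)) / truth_chi, 0.3)
})

test_that("the fitting interface routes vessel-specific models elsewhere", {
  net <- tiny_network()
  d <- frozen_data(c(1), 8, 5)
  expect_error(pcirc_fit(d, net, model = "F", inflow = desk_inflow()),
               "gibbs_hierarchical")
})
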