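test_that("rest state is an exact fixed point of the solver", {
  net <- tiny_network()
  wall <- wall_model("linear", "constant", f3 = 5e4)
  wk <- data.frame(id = c(2, 3), R1 = 2e4, R2 = 8e4, C = 3e-7)
  qin <- data.frame(time_s = seq(0, 0.11, length.out = 32), value = 0)
  sim <- simulate_network(net, wall, wk, qin, desk_grid(2))
  expect_equal(max(abs(unlist(sim$p))), 0)
  expect_equal(max(abs(unlist(sim$q))), 0)
})

test_that("constant inflow settles to the Windkessel steady state", {
  single <- vessel_network(data.frame(id = 1, parent_id = NA,
                                      length_cm = 0.5, r0_cm = 0.05,
                                      terminal = TRUE))
  wall <- wall_model("linear", "constant", f3 = 5e4)
  R1 <- 2e4; R2 <- 8e4; q0 <- 0.2
  wk <- data.frame(id = 1, R1 = R1, R2 = R2, C = 3e-7)
  qin <- data.frame(time_s = seq(0, 0.11, length.out = 32), value = q0)
  sim <- simulate_network(single, wall, wk, qin,
                          sim_grid(dx = 0.025, dt = 5e-5, n_cycles = 40,
                                   convergence_tol = 1e-8))
  p_out <- sim_series(sim, 1, frac = 1)$value
  expect_equal(mean(tail(p_out, 5)),
               q0 * (R1 + R2) / physical_constants()$conv,
               tolerance = 1e-3)
})

test_that("small pulses propagate at the linearized wave speed", {
  chi <- 5.17e4
  c0 <- sqrt(2 * chi / (3 * 1.055))
  long <- vessel_network(data.frame(id = 1, parent_id = NA, length_cm = 4,
                                    r0_cm = 0.05, terminal = TRUE))
  wall <- wall_model("linear", "constant", f3 = chi)
  A0 <- pi * 0.05^2
  Zc <- 1.055 * c0 / A0
  wk <- data.frame(id = 1, R1 = Zc, R2 = 4 * Zc, C = 0.025 / (4 * Zc))
  tt <- seq(0, 0.11, length.out = 256)
  qin <- data.frame(time_s = tt,
                    value = ifelse(tt < 0.01,
                                   0.002 * sin(pi * tt / 0.01)^2, 0))
  sim <- simulate_network(long, wall, wk, qin,
                          sim_grid(dx = 0.01, dt = 2e-5, n_cycles = 1,
                                   n_out = 512))
  p1 <- sim_series(sim, 1, frac = 0.25)
  p3 <- sim_series(sim, 1, frac = 0.75)
  c_meas <- 2 / (p3$time_s[which.max(p3$value)] -
                 p1$time_s[which.max(p1$value)])
  expect_lt(abs(c_meas - c0) / c0, 0.05)
})

test_that("one converged cycle conserves mass to under half a percent", {
  sim <- desk_sim()
  expect_true(sim$converged)
  mb <- mass_balance(sim)
  expect_lt(mb$relative_error, 0.005)
})

test_that("grid refinement converges at second order", {
  net <- generate_tree(2, seed = 1)
  truth <- default_truth()
  wk <- apply_scalings(desk_nominal(net), 0.29, 0.87, 1.34)
  probe <- seq(0.001, 0.109, length.out = 50)
  ref <- function(f) {
    g <- sim_grid(dx = 0.04 / f, dt = 4.8e-5 / f, n_cycles = 4,
                  convergence_tol = 1e-12, n_out = 64)
    sim <- simulate_network(net, truth$wall, wk, desk_inflow(), g)
    sim_series(sim, 1, times = probe)$value
  }
  e1 <- max(abs(ref(1) - ref(2)))
  e2 <- max(abs(ref(2) - ref(4)))
  expect_gt(log2(e1 / e2), 1.8)
})

test_that("noise-free mean pressure decreases from root to periphery", {
  sim <- desk_sim()
  cap <- cycle_average_pressure(sim)
  v <- sim$network$vessels
  for (k in seq_len(nrow(v))) {
    par <- v$parent_id[k]
    if (!is.na(par))
      expect_lte(cap[[as.character(v$id[k])]],
                 cap[[as.character(par)]] + 1e-9)
  }
  ## the same holds on the paper-scale 21-vessel stand-in
  net21 <- generate_tree(11, seed = 1)
  wallA <- wall_model("linear", "constant", f3 = 5.17e4)
  wkA <- apply_scalings(desk_nominal(net21), 0.21, 0.88, 1.44)
  simA <- simulate_network(net21, wallA, wkA, desk_inflow(),
                           sim_grid(dx = 0.05, dt = 6e-5, n_cycles = 8))
  capA <- cycle_average_pressure(simA)
  vA <- net21$vessels
  for (k in seq_len(nrow(vA))) {
    par <- vA$parent_id[k]
    if (!is.na(par))
      expect_lte(capA[[as.character(vA$id[k])]],
                 capA[[as.character(par)]] + 1e-9)
  }
})

test_that("the CFL monitor reports sane Courant numbers", {
  sim <- desk_sim()
  cf <- check_cfl(sim)
  expect_true(cf$ok)
  expect_gt(cf$courant, 0)
  expect_lte(cf$courant, sim$courant_max + 1e-8)
  ## rest state, linear wall: Courant number equals dt c0 / dx
  net <- tiny_network()
  wall <- wall_model("linear", "constant", f3 = 5.17e4)
  wk <- data.frame(id = c(2, 3), R1 = 2e4, R2 = 8e4, C = 3e-7)
  qin <- data.frame(time_s = seq(0, 0.11, length.out = 32), value = 0)
  g <- desk_grid(2)
  sim0 <- simulate_network(net, wall, wk, qin, g)
  c0 <- sqrt(2 * 5.17e4 / (3 * 1.055))
  dxv <- vapply(sim0$x, function(x) x[2] - x[1], numeric(1))
  expect_equal(check_cfl(sim0)$courant, max(sim0$dt * c0 / dxv),
               tolerance = 1e-10)
})

test_that("a CFL-violating grid aborts with a diagnostic", {
  net <- tiny_network()
  truth <- default_truth()
  wk <- apply_scalings(desk_nominal(net), 1, 1, 1)
  expect_error(
    simulate_network(net, truth$wall, wk, desk_inflow(),
                     sim_grid(dx = 0.02, dt = 5e-4, n_cycles = 2)),
    "CFL")
})

test_that("the nonlinear wall law also produces physiological pulses", {
  net <- tiny_network()
  wall <- wall_model("nonlinear", "constant", f3 = 9.17e4, gamma = 5.18)
  wk <- apply_scalings(desk_nominal(net), 0.37, 0.94, 1.60)
  sim <- simulate_network(net, wall, wk, desk_inflow(), desk_grid(6))
  mpa <- sim_series(sim, 1)$value
  expect_true(all(is.finite(mpa)))
  expect_gt(max(mpa), 5)
  expect_lt(max(mpa), 40)
  mb <- mass_balance(sim)
  expect_lt(mb$relative_error, 0.01)
})
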