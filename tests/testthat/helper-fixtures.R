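## Shared desk-scale fixtures. Heavy objects (simulations, synthetic
## datasets, MCMC fits) are built once per test run and cached here so
## several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## smallest bifurcation: root + two terminals
tiny_network <- function() {
  vessel_network(data.frame(
    id = 1:3, parent_id = c(NA, 1L, 1L),
    length_cm = c(0.42, 0.34, 0.33), r0_cm = c(0.047, 0.038, 0.037),
    terminal = c(FALSE, TRUE, TRUE)))
}

## desk grid: coarse but CFL-safe for stiffness up to ~4e5
desk_grid <- function(n_cycles = 3) {
  sim_grid(dx = 0.1, dt = 1.5e-4, n_cycles = n_cycles)
}

desk_inflow <- function() synthetic_inflow(inflow_spec(), n = 128)

desk_nominal <- function(network) {
  q <- desk_inflow()
  sv <- sum(q$value[-1] * diff(q$time_s))
  nominal_windkessel(network, sv / 0.11, 17.5)
}

## one converged pulsatile simulation on the 3-vessel tree at the truth
desk_sim <- function() {
  fixture("desk_sim", function() {
    net <- generate_tree(2, seed = 1)
    truth <- default_truth()
    wk <- apply_scalings(desk_nominal(net), truth$psi[["psi1"]],
                         truth$psi[["psi2"]], truth$psi[["c"]])
    simulate_network(net, truth$wall, wk, desk_inflow(), desk_grid(8))
  })
}

## default synthetic study: 10 instantiations, all 3 vessels observed
desk_dataset <- function() {
  fixture("desk_dataset", function() {
    net <- generate_tree(2, seed = 1)
    generate_dataset(network = net, vessels = net$vessels$id,
                     n_instantiations = 10, n_obs = 64, seed = 11,
                     grid = desk_grid())
  })
}

## The scaled-down bias-correction / multi-vessel study shared by the
## acceptance tests: for each of 10 synthetic replicates, calibrate the
## data-generating model with the mismatch likelihood (MPA data and
## 3-vessel data) and with the iid likelihood (MPA data).
bias_study <- function() {
  fixture("bias_study", function() {
    ds <- desk_dataset()
    truth <- ds$truth$theta
    idpar <- c("f3", "psi1", "psi2", "c")
    fit1 <- function(model, data, seed, n_iter = 2000)
      pcirc_fit(data, ds$network, model, inflow = ds$inflow,
                nominal = ds$nominal, grid = ds$grid, n_iter = n_iter,
                seed = seed, waic_draws = 300)
    reps <- lapply(seq_len(10), function(r) {
      fe1 <- fit1("E", ds$datasets[[r]]["1"], 100 + r)
      fd1 <- fit1("D", ds$datasets[[r]]["1"], 200 + r)
      fe3 <- fit1("E", ds$datasets[[r]], 300 + r, n_iter = 4000)
      de1 <- chain_draws(fe1$chain)
      dd1 <- chain_draws(fd1$chain)
      de3 <- chain_draws(fe3$chain)
      jointdens <- function(d) {
        th <- names(truth)
        s <- scale_to_unit_magnitude(d[, th])
        kde_density(s$samples, matrix(truth[th] / s$factors, 1))
      }
      list(
        covered = vapply(idpar, function(p) {
          q <- stats::quantile(de1[, p], c(0.025, 0.975))
          q[1] <= truth[p] && truth[p] <= q[2]
        }, logical(1)),
        dens_e = vapply(idpar, function(p)
          kde_density(de1[, p], truth[p]), numeric(1)),
        dens_d = vapply(idpar, function(p)
          kde_density(dd1[, p], truth[p]), numeric(1)),
        waic_e = fe1$waic$waic, waic_d = fd1$waic$waic,
        euclid_e = fe1$euclidean_distance,
        euclid_d = fd1$euclidean_distance,
        sse_e = relative_sse(apply(de1[, names(truth)], 2,
                                   stats::median), truth),
        sse_d = relative_sse(apply(dd1[, names(truth)], 2,
                                   stats::median), truth),
        joint_1v = jointdens(de1), joint_3v = jointdens(de3),
        w_med = stats::median(de1[, "w"]),
        f1_3v = de3[seq(1, nrow(de3), by = 8), "f1"],
        f2_3v = de3[seq(1, nrow(de3), by = 8), "f2"])
    })
    list(ds = ds, truth = truth, reps = reps)
  })
}
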