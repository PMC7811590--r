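test_that("network validation enforces binary-tree topology", {
  net <- tiny_network()
  expect_s3_class(net, "vessel_network")
  expect_equal(nrow(net$junctions), 1)
  expect_equal(sum(net$vessels$terminal), 2)
  expect_equal(net$vessels$A0_cm2, pi * net$vessels$r0_cm^2,
               tolerance = 1e-12)

  bad_parent <- data.frame(id = 1:3, parent_id = c(NA, 1, 9),
                           length_cm = 1, r0_cm = 0.05,
                           terminal = c(FALSE, TRUE, TRUE))
  expect_error(vessel_network(bad_parent), "nonexistent parent")

  two_roots <- data.frame(id = 1:2, parent_id = c(NA, NA), length_cm = 1,
                          r0_cm = 0.05, terminal = TRUE)
  expect_error(vessel_network(two_roots), "exactly one root")

  one_child <- data.frame(id = 1:2, parent_id = c(NA, 1), length_cm = 1,
                          r0_cm = 0.05, terminal = c(FALSE, TRUE))
  expect_error(vessel_network(one_child), "one daughter")
})

test_that("network files round-trip losslessly through CSV and JSON", {
  net <- generate_tree(4, seed = 3)
  for (ext in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_network(net, path)
    back <- read_network(path)
    expect_equal(back$vessels$length_cm, net$vessels$length_cm,
                 tolerance = 1e-12)
    expect_equal(back$vessels$r0_cm, net$vessels$r0_cm, tolerance = 1e-12)
    expect_identical(back$vessels$parent_id, net$vessels$parent_id)
    unlink(path)
  }
  expect_error(read_network(tempfile()), "not found")
})

test_that("generated trees satisfy the full binary tree identity", {
  for (nt in c(2, 5, 11)) {
    net <- generate_tree(nt, seed = 7)
    expect_equal(nrow(net$vessels), 2 * nt - 1)
    expect_equal(sum(net$vessels$terminal), nt)
  }
  ## paper-scale stand-in: 21 vessels, 11 terminal, 10 internal
  net21 <- generate_tree(11, seed = 1)
  expect_equal(nrow(net21$vessels), 21)
  expect_equal(sum(net21$vessels$terminal), 11)
  expect_equal(nrow(net21$junctions), 10)
  ## determinism
  expect_identical(generate_tree(6, seed = 42)$vessels,
                   generate_tree(6, seed = 42)$vessels)
  expect_error(generate_tree(1), "at least 2")
})

test_that("nominal Windkessel reproduces the target total resistance", {
  pc <- physical_constants()
  ## one-outlet limit with negligible vessel resistance
  single <- vessel_network(data.frame(id = 1, parent_id = NA,
                                      length_cm = 0.01, r0_cm = 0.2,
                                      terminal = TRUE))
  nom <- nominal_windkessel(single, mean_flow = 0.2, mean_pressure = 15)
  R_target <- pc$conv * 15 / 0.2
  R_path <- 8 * pc$mu * 0.01 / (pi * 0.2^4)
  expect_equal(nom$R01 + nom$R02 + R_path, R_target, tolerance = 1e-10)
  expect_equal(nom$R01 / (nom$R01 + nom$R02), 0.2, tolerance = 1e-12)
  expect_equal(nom$C0 * nom$R02, 0.025, tolerance = 1e-12)

  ## two identical terminals get identical triples
  sym <- vessel_network(data.frame(id = 1:3, parent_id = c(NA, 1, 1),
                                   length_cm = c(0.4, 0.3, 0.3),
                                   r0_cm = c(0.05, 0.04, 0.04),
                                   terminal = c(FALSE, TRUE, TRUE)))
  nom2 <- nominal_windkessel(sym, 0.16, 14)
  expect_equal(nom2$R01[1], nom2$R01[2], tolerance = 1e-12)
  expect_equal(nom2$C0[1], nom2$C0[2], tolerance = 1e-12)

  ## conductance bookkeeping: parallel sum of terminal paths equals the
  ## target total conductance
  net <- generate_tree(4, seed = 2)
  nom4 <- nominal_windkessel(net, 0.16, 14)
  paths <- pulmouq:::path_poiseuille(net, pc$mu)
  term <- as.character(nom4$id)
  g_tot <- sum(1 / (nom4$R01 + nom4$R02 + paths[term]))
  expect_equal(g_tot, 0.16 / (14 * pc$conv), tolerance = 1e-8)

  ## configuration error when the tree itself exceeds the target
  thin <- vessel_network(data.frame(id = 1, parent_id = NA,
                                    length_cm = 2, r0_cm = 0.01,
                                    terminal = TRUE))
  expect_error(nominal_windkessel(thin, 10, 1), "exceeds the target")
})

test_that("Windkessel scaling is exact and linear in each factor", {
  nom <- data.frame(id = 1:2, R01 = c(1, 1), R02 = c(1, 1), C0 = c(1, 1))
  s <- apply_scalings(nom, 0.21, 0.88, 1.44)
  expect_equal(unique(s$R1), 0.21)
  expect_equal(unique(s$R2), 0.88)
  expect_equal(unique(s$C), 1.44)
  ident <- apply_scalings(nom, 1, 1, 1)
  expect_equal(ident$R1, nom$R01)
  doubled <- apply_scalings(nom, 0.21, 2 * 0.88, 1.44)
  expect_equal(doubled$R2, 2 * s$R2)
  expect_error(apply_scalings(nom, -1, 1, 1), "positive")
})

test_that("windkessel initialization matches a series/parallel reduction", {
  ## independent oracle: recursively reduce the RCR-terminated tree to a
  ## single steady-flow resistance. The per-path Poiseuille accounting
  ## used by the initialization coincides with the network reduction
  ## exactly when shared (internal) segments carry negligible resistance,
  ## so the check uses a tree whose internal vessels are short and wide.
  pc <- physical_constants()
  net <- vessel_network(data.frame(
    id = 1:7,
    parent_id = c(NA, 1, 1, 2, 2, 3, 3),
    length_cm = c(0.01, 0.01, 0.01, 0.35, 0.33, 0.34, 0.32),
    r0_cm = c(0.2, 0.15, 0.15, 0.04, 0.038, 0.039, 0.037),
    terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)))
  nom <- nominal_windkessel(net, 0.18, 15)
  v <- net$vessels
  r_self <- 8 * pc$mu * v$length_cm / (pi * v$r0_cm^4)
  reduce <- function(id) {
    k <- match(id, v$id)
    if (v$terminal[k]) {
      row <- nom[match(id, nom$id), ]
      return(r_self[k] + row$R01 + row$R02)
    }
    kids <- v$id[!is.na(v$parent_id) & v$parent_id == id]
    r_self[k] + 1 / sum(1 / vapply(kids, reduce, numeric(1)))
  }
  expect_equal(reduce(net$root), pc$conv * 15 / 0.18,
               tolerance = 1e-4)
})
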