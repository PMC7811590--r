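test_that("the model catalogue matches the study design", {
  specs <- lapply(LETTERS[1:9], model_spec)
  names(specs) <- LETTERS[1:9]
  expect_true(all(vapply(specs[c("B", "C", "E", "G", "H", "I")],
                         `[[`, TRUE, "mismatch")))
  expect_false(any(vapply(specs[c("A", "D", "F")], `[[`, TRUE,
                          "mismatch")))
  expect_equal(vapply(specs, `[[`, "", "kind"),
               c(A = "linear", B = "linear", C = "linear", D = "linear",
                 E = "linear", F = "linear", G = "linear",
                 H = "nonlinear", I = "nonlinear"))
  expect_true(all(vapply(specs[c("A", "B", "H")], `[[`, TRUE,
                         "emulator")))
  ## nonlinear models sample gamma; radius-dependent ones sample f1, f2
  expect_true("gamma" %in% rownames(specs$H$bounds))
  expect_true(all(c("f1", "f2") %in% rownames(specs$E$bounds)))
  expect_error(model_spec("Z"), "unknown model")
})

test_that("a short calibration run produces a complete fit object", {
  ds <- desk_dataset()
  net <- ds$network
  d <- ds$datasets[[1]]["1"]
  fit <- pcirc_fit(d, net, model = "A", inflow = ds$inflow,
                   nominal = ds$nominal, grid = desk_grid(),
                   n_iter = 300, seed = 1, waic_draws = 60)
  expect_s3_class(fit, "pcirc_fit")
  co <- coef(fit)
  expect_named(co, c("f3", "psi1", "psi2", "c", "sigma2"))
  expect_true(all(is.finite(co)))
  s <- summary(fit)
  expect_true(all(s$table[, "q2.5"] <= s$table[, "median"]))
  expect_true(all(s$table[, "median"] <= s$table[, "q97.5"]))
  expect_true(is.finite(fit$waic$waic))
  expect_gte(fit$waic$p_waic, 0)
  r <- residuals(fit)
  expect_length(r[["1"]], 64)
  ## same seed, same data: identical chain and WAIC
  fit2 <- pcirc_fit(d, net, model = "A", inflow = ds$inflow,
                    nominal = ds$nominal, grid = desk_grid(),
                    n_iter = 300, seed = 1, waic_draws = 60)
  expect_identical(fit$chain$draws, fit2$chain$draws)
  expect_equal(fit$waic$waic, fit2$waic$waic, tolerance = 1e-12)
})

test_that("interval bands are ordered and collapse without noise", {
  ds <- desk_dataset()
  d <- ds$datasets[[1]]["1"]
  fit <- fixture("fit_bands", function()
    pcirc_fit(d, ds$network, model = "A", inflow = ds$inflow,
              nominal = ds$nominal, grid = desk_grid(),
              n_iter = 400, seed = 2, waic_draws = 60))
  b <- interval_bands(fit, n_draws = 120, seed = 3)
  expect_true(all(b$ci_lo <= b$median + 1e-9))
  expect_true(all(b$median <= b$ci_hi + 1e-9))
  ## prediction band contains the credible band pointwise
  expect_true(all(b$pi_lo <= b$ci_lo + 1e-9))
  expect_true(all(b$pi_hi >= b$ci_hi - 1e-9))
  ## iid case: prediction band is approximately the credible band
  ## widened by +-1.96 sigma
  s2 <- median(chain_draws(fit$chain)[, "sigma2"])
  widen <- mean((b$pi_hi - b$ci_hi)[10:50])
  expect_equal(widen, 1.96 * sqrt(s2), tolerance = 0.35)

  ## a degenerate chain with essentially zero noise collapses both bands
  fit0 <- fit
  dr <- fit0$chain$draws
  dr[, ] <- rep(colMeans(chain_draws(fit$chain)), each = nrow(dr))
  dr[, "sigma2"] <- 1e-12
  fit0$chain$draws <- dr
  b0 <- interval_bands(fit0, n_draws = 110, seed = 4)
  expect_lt(max(b0$pi_hi - b0$pi_lo), 1e-4)
  expect_lt(max(b0$ci_hi - b0$ci_lo), 1e-12)
})

test_that("model comparison ranks by WAIC with stable tie-breaking", {
  ds <- desk_dataset()
  d <- ds$datasets[[2]]["1"]
  fitA <- fixture("cmp_A", function()
    pcirc_fit(d, ds$network, model = "A", inflow = ds$inflow,
              nominal = ds$nominal, grid = desk_grid(),
              n_iter = 300, seed = 5, waic_draws = 60))
  fitD <- fixture("cmp_D", function()
    pcirc_fit(d, ds$network, model = "D", inflow = ds$inflow,
              nominal = ds$nominal, grid = desk_grid(),
              n_iter = 300, seed = 6, waic_draws = 60))
  tab <- compare_models(fitA, fitD)
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$waic) >= 0))
  ## single fit: trivial ranking
  expect_equal(nrow(compare_models(fitA)), 1)
  ## duplicated run: tie broken lexicographically
  tie <- compare_models(fitA, fitA)
  expect_equal(tie$model, c("A", "A"))
  ## different data are rejected
  other <- ds$datasets[[3]]["1"]
  fitO <- fixture("cmp_O", function()
    pcirc_fit(other, ds$network, model = "A", inflow = ds$inflow,
              nominal = ds$nominal, grid = desk_grid(),
              n_iter = 300, seed = 7, waic_draws = 60))
  expect_error(compare_models(fitA, fitO), "different data")
})

test_that("run_experiment writes chain, manifest and bands", {
  ds <- desk_dataset()
  d <- ds$datasets[[1]]["1"]
  out <- file.path(tempdir(), "runA")
  fit <- suppressMessages(
    run_experiment("A", d, ds$network, ds$inflow, out, seed = 1,
                   nominal = ds$nominal, grid = desk_grid(),
                   n_iter = 300, waic_draws = 60))
  expect_true(file.exists(file.path(out, "chain.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "bands.csv")))
  man <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  expect_equal(man$model, "A")
  expect_true(is.finite(man$waic))
  ch <- utils::read.csv(file.path(out, "chain.csv"))
  expect_equal(nrow(ch), 150)
  unlink(out, recursive = TRUE)
})
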