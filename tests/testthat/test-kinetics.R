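wt <- kinetics_params(kon = 1e5, koff = 2.8e-4, rmax = 1.0)

test_that("parameter validation and the derived KD are correct", {
  expect_equal(wt$kd, 2.8e-9, tolerance = 1e-12)
  expect_error(kinetics_params(-1, 1e-3, 1), "kon")
  expect_error(kinetics_params(1e5, 0, 1), "koff")
  expect_error(kinetics_params(1e5, 1e-3, -2), "rmax")
})

test_that("simulated traces follow the closed-form 1:1 Langmuir model", {
  # association plateau at C = KD is half of Rmax
  tr <- simulate_trace(wt, wt$kd, t_assoc = 2e5, t_dissoc = 2000, dt = 1000)
  assoc_end <- tr$responses[max(which(tr$times <= tr$t_assoc_end))]
  expect_equal(assoc_end, wt$rmax / 2, tolerance = 1e-6)

  # independently evaluated closed form at the end of a 300 s association
  cc <- 250e-9
  tr2 <- simulate_trace(wt, cc, t_assoc = 300, t_dissoc = 600, dt = 1)
  kobs <- wt$kon * cc + wt$koff
  req <- wt$rmax * cc / (cc + wt$kd)
  expect_equal(tr2$responses[tr2$times == 300], req * (1 - exp(-kobs * 300)),
               tolerance = 1e-12)
  # dissociation decays exponentially from the association end value
  r600 <- tr2$responses[tr2$times == 600]
  expect_equal(r600, tr2$responses[tr2$times == 300] * exp(-wt$koff * 300),
               tolerance = 1e-12)

  # fast off-rate with weak on-signal: plateau collapses toward zero
  weak <- kinetics_params(kon = 1e3, koff = 10, rmax = 1)
  tr3 <- simulate_trace(weak, 1e-9, t_assoc = 300, t_dissoc = 300, dt = 5)
  expect_lt(max(tr3$responses), 1e-6)

  expect_error(simulate_trace(wt, -1e-9), "positive")
  expect_error(simulate_trace(wt, 1e-9, dt = 500), "dt")
})

test_that("noise is seed-controlled and zero-noise is exact", {
  a <- simulate_trace(wt, 1e-8, noise_sd = 0.02, seed = 7, dt = 5)
  b <- simulate_trace(wt, 1e-8, noise_sd = 0.02, seed = 7, dt = 5)
  c <- simulate_trace(wt, 1e-8, noise_sd = 0.02, seed = 8, dt = 5)
  expect_identical(a$responses, b$responses)
  expect_false(identical(a$responses, c$responses))
})

test_that("global fit recovers generating parameters from noise-free data", {
  traces <- lapply(250e-9 / 2^(0:5), function(cc) simulate_trace(wt, cc, dt = 2))
  fit <- fit_langmuir_global(traces)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["kd"]), wt$kd, tolerance = 0.01)
  expect_equal(unname(coef(fit)["kon"]), wt$kon, tolerance = 0.01)
  expect_equal(unname(coef(fit)["koff"]), wt$koff, tolerance = 0.01)
  expect_equal(fit$n_traces, 6)
  expect_true(all(fit$per_trace_rss >= 0))
})

test_that("fitting requires two concentrations and a binding signal", {
  one <- list(simulate_trace(wt, 1e-8, dt = 5), simulate_trace(wt, 1e-8, dt = 5))
  expect_error(fit_langmuir_global(one), "identifiable|distinct")
  flat <- lapply(c(1e-8, 2e-8), function(cc) {
    tr <- simulate_trace(wt, cc, dt = 5)
    tr$responses[] <- 0.5
    tr
  })
  expect_error(fit_langmuir_global(flat), "flat|signal")
})

test_that("scaling all responses rescales Rmax and preserves the rates", {
  traces <- lapply(100e-9 / 2^(0:3), function(cc) simulate_trace(wt, cc, dt = 5))
  fit1 <- fit_langmuir_global(traces)
  scaled <- lapply(traces, function(tr) { tr$responses <- tr$responses * 3.7; tr })
  fit2 <- fit_langmuir_global(scaled)
  expect_equal(coef(fit2)["rmax"], coef(fit1)["rmax"] * 3.7, tolerance = 1e-6)
  expect_equal(coef(fit2)["kon"], coef(fit1)["kon"], tolerance = 1e-6)
  expect_equal(coef(fit2)["koff"], coef(fit1)["koff"], tolerance = 1e-6)
})

test_that("fitted model curves rise monotonically in concentration", {
  traces <- lapply(250e-9 / 2^(0:4), function(cc) simulate_trace(wt, cc, dt = 2))
  fit <- fit_langmuir_global(traces)
  concs <- sort(vapply(traces, `[[`, numeric(1), "concentration"))
  plateaus <- vapply(concs, function(cc)
    predict(fit, cc, times = 300, t_assoc_end = 300), numeric(1))
  expect_true(all(diff(plateaus) > 0))
  kobs <- coef(fit)["kon"] * concs + coef(fit)["koff"]
  expect_true(all(diff(kobs) > 0))
})

test_that("steady-state fit is exact on exact equilibrium data", {
  kd <- 1e-7
  p <- kinetics_params(kon = 1e6, koff = 1e6 * kd, rmax = 2.0)
  traces <- lapply(c(kd / 4, kd, 4 * kd), function(cc)
    simulate_trace(p, cc, t_assoc = 300, t_dissoc = 100, dt = 1))
  fit <- fit_steady_state(traces)
  expect_equal(unname(coef(fit)["kd"]), kd, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["rmax"]), 2.0, tolerance = 1e-6)
  expect_true(is.na(coef(fit)["kon"]) && is.na(coef(fit)["koff"]))
  expect_false(fit$nonsaturating)
})

test_that("weak-binder series recovers KD and raises the non-saturating flag", {
  weak <- kinetics_params(kon = 1e5, koff = 1e5 * 1650e-9, rmax = 1.0)
  traces <- lapply(500e-9 / 2^(0:5), function(cc) simulate_trace(weak, cc, dt = 2))
  expect_warning(fit <- fit_steady_state(traces), "non-saturating")
  expect_true(fit$nonsaturating)
  expect_equal(unname(coef(fit)["kd"]), 1650e-9, tolerance = 0.2)
})

test_that("steady-state and global KD agree on well-behaved data", {
  p <- kinetics_params(kon = 1e5, koff = 1e-3, rmax = 1.5)   # KD 10 nM
  traces <- lapply(100e-9 / 2^(0:4), function(cc)
    simulate_trace(p, cc, t_assoc = 3000, t_dissoc = 600, dt = 10))
  kd_global <- coef(fit_langmuir_global(traces))["kd"]
  kd_steady <- coef(fit_steady_state(traces))["kd"]
  expect_equal(unname(kd_steady), unname(kd_global), tolerance = 0.05)
})

test_that("datasets written to disk round-trip through the manifest", {
  d <- make_bli_dataset(wt, n_dilutions = 3, dt = 10, noise_sd = 0.01,
                        seed = 5, out_dir = tempfile("bli"))
  traces <- read_bli_dataset(d$manifest)
  expect_length(traces, 3)
  expect_equal(vapply(traces, `[[`, numeric(1), "concentration"),
               d$concentrations)
  expect_equal(traces[[2]]$responses, d$traces[[2]]$responses)
  expect_false(d$insufficient_for_global_fit)
  d1 <- make_bli_dataset(wt, n_dilutions = 1, dt = 10, out_dir = tempfile("bli"))
  expect_true(d1$insufficient_for_global_fit)
})
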