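test_that("residue metrics have their closed forms", {
  f <- rep(10, 250)
  expect_equal(residue_L2_scaled(f, f), 0)
  expect_equal(residue_L1_per_point(f, f), 0)
  # constant 1 N offset scales to sqrt(1000) regardless of point count
  expect_equal(residue_L2_scaled(f + 1, f), sqrt(1000))
  expect_equal(residue_L2_scaled(rep(1, 77), rep(0, 77)), sqrt(1000))
  expect_equal(residue_L1_per_point(f + 1, f), 1)
  # 2 N on half the points: sqrt(1000 * 4 / 2); L1 mean of {1,3} halves
  half <- c(rep(2, 50), rep(0, 50))
  expect_equal(residue_L2_scaled(half, rep(0, 100)), sqrt(2000))
  expect_equal(residue_L1_per_point(c(rep(1, 50), rep(3, 50)),
                                    rep(0, 100)), 2)
  # invariant to experiment ordering (stacked lists)
  a <- list(c(1, 2), c(3, 4, 5)); b <- list(c(0, 0), c(0, 0, 0))
  expect_equal(residue_L2_scaled(a, b), residue_L2_scaled(rev(a), rev(b)))
  expect_error(residue_L2_scaled(1:5, 1:4), "aligned")
})

test_that("experiment records validate their grids", {
  expect_error(experiment_record("GAS", 0.12, c(0, 0.2, 0.1), c(1, 2, 3)),
               "increasing")
  expect_error(experiment_record("GAS", 0.12, c(0, 0.1), c(1, NA)),
               "finite")
  r <- experiment_record("GAS", 0.12, c(0, 0.1), c(1, 2))
  expect_s3_class(r, "experiment_record")
})

test_that("single-parameter recovery from noiseless synthetic traces", {
  mc <- met_const()
  p_true <- gas_plus()
  prot <- short_protocol()
  spec <- fixture_spec("GAS_plus", lengths = c(0.116, 0.126, 0.130),
                       noise_sd = 0, seed = 1, protocol = prot)
  exps <- generate_fixtures(spec, p_true, mc)
  cases <- list(khyd_hat = 2.0, Fmax = 110, lCEopt = 0.021, m_act = 10)
  for (nm in names(cases)) {
    start <- p_true
    start[[nm]] <- cases[[nm]]
    fit <- mtu_fit(exps, start, free = nm, metabolic = mc, n_starts = 1)
    expect_lt(abs(fit$estimate[[nm]] / p_true[[nm]] - 1), 0.01,
              label = sprintf("recovery of %s", nm))
    expect_true(fit$converged)
  }
})

test_that("two-parameter recovery and data-at-start fixed point", {
  mc <- met_const()
  p_true <- pla_plus()
  prot <- short_protocol()
  spec <- fixture_spec("PLA_plus", lengths = c(0.114, 0.120, 0.124),
                       noise_sd = 0, seed = 2, protocol = prot)
  exps <- generate_fixtures(spec, p_true, mc)
  start <- p_true
  start$khyd_hat <- 1.4
  start$Fmax <- 55
  fit <- mtu_fit(exps, start, free = c("khyd_hat", "Fmax"),
                 metabolic = mc, n_starts = 1)
  expect_lt(abs(fit$estimate[["khyd_hat"]] / p_true$khyd_hat - 1), 0.01)
  expect_lt(abs(fit$estimate[["Fmax"]] / p_true$Fmax - 1), 0.01)
  # data generated at the start point: objective already 0, optimizer stays
  fit0 <- mtu_fit(exps, p_true, free = "khyd_hat", metabolic = mc,
                  n_starts = 1, maxiter = 5)
  expect_lt(fit0$residue_L2_1000, 1e-6)
  expect_equal(fit0$estimate[["khyd_hat"]], p_true$khyd_hat,
               tolerance = 1e-6)
})

test_that("fit is deterministic per seed and multi-start never hurts", {
  mc <- met_const()
  p_true <- gas_plus()
  prot <- default_protocol(stim_duration = 0.3, onset = 0.05, tail = 0.1,
                           sample_rate = 200)
  exps <- generate_fixtures(
    fixture_spec("GAS_plus", lengths = c(0.118, 0.128), noise_sd = 0.5,
                 seed = 3, protocol = prot), p_true, mc)
  start <- p_true; start$khyd_hat <- 2.5
  f1 <- mtu_fit(exps, start, free = "khyd_hat", metabolic = mc,
                n_starts = 3, seed = 11)
  f2 <- mtu_fit(exps, start, free = "khyd_hat", metabolic = mc,
                n_starts = 3, seed = 11)
  expect_identical(f1$estimate, f2$estimate)
  # best objective over the first k starts is non-increasing in k
  best_so_far <- cummin(f1$start_objectives)
  expect_true(all(diff(best_so_far) <= 0))
  expect_gte(min(f1$start_objectives), f1$residue_L2_1000 - 1e-8)
})

test_that("khyd estimate is unbiased under measurement noise", {
  mc <- met_const()
  p_true <- gas_plus()
  prot <- short_protocol()
  ests <- vapply(1:20, function(i) {
    exps <- generate_fixtures(
      fixture_spec("GAS_plus", lengths = c(0.120, 0.128), noise_sd = 0.5,
                   seed = 100 + i, protocol = prot), p_true, mc)
    start <- p_true; start$khyd_hat <- 2
    fit <- mtu_fit(exps, start, free = "khyd_hat", metabolic = mc,
                   n_starts = 1, rtol = 1e-7)
    fit$estimate[["khyd_hat"]]
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - p_true$khyd_hat), 3 * se)
  # the per-replicate scatter is small relative to the estimate
  expect_lt(sd(ests), 0.05)
})

test_that("sensitivity time courses behave as documented", {
  p <- gas_plus(); mc <- met_const()
  prot <- default_protocol(sample_rate = 200)
  S <- sensitivity_timecourse(p, mc, lmtu = 0.132, protocol = prot,
                              parameters = c("khyd_hat", "lSEE0",
                                             "m_act"),
                              rel_step = c(khyd_hat = 1e-4,
                                           lSEE0 = 1e-5, m_act = 0))
  t <- attr(S, "time")
  # khyd_hat does not influence the pre-stimulation force
  expect_lt(max(abs(S["khyd_hat", t < 0.095])), 1e-3)
  # ... but does influence it late in the stimulation
  expect_gt(max(abs(S["khyd_hat", t > 0.6 & t < 0.8])), 1e-3)
  # frozen parameter (zero perturbation) gives a zero row
  expect_true(all(S["m_act", ] == 0))
  # tendon slack length dominates: far beyond the truncation level and
  # the largest magnitude of the tested set
  expect_gt(max(abs(S["lSEE0", ])), 10)
  expect_gt(max(abs(S["lSEE0", ])), max(abs(S["khyd_hat", ])))
  # exported matrix is clipped at the truncation level, internal is not
  E <- export_sensitivity(S)
  expect_lte(max(abs(E)), 1)
  expect_gt(max(abs(S)), 1)
})

test_that("fit object methods expose the usual modelling interface", {
  mc <- met_const()
  p_true <- gas_plus()
  prot <- short_protocol()
  exps <- generate_fixtures(
    fixture_spec("GAS_plus", lengths = c(0.120, 0.128), noise_sd = 0,
                 seed = 5, protocol = prot), p_true, mc)
  fit <- mtu_fit(exps, p_true, free = "khyd_hat", metabolic = mc,
                 n_starts = 1, maxiter = 2)
  expect_named(coef(fit), "khyd_hat")
  expect_length(coef(fit, full = TRUE), 24)
  r <- residuals(fit)
  expect_length(r, 2)
  expect_lt(max(abs(unlist(r))), 1e-6)
  preds <- predict(fit)
  expect_length(preds, 2)
  expect_equal(preds[[1]]$time_s, exps[[1]]$t)
  expect_output(print(fit), "least-squares")
})
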